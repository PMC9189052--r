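## running-sum gene-set enrichment and over-representation testing

#' Running-sum enrichment score
#'
#' Classic GSEA statistic: walking down the metric-ranked gene list,
#' the running sum increases by \eqn{|metric|^p} (normalized over
#' in-set genes) at set members and decreases by \eqn{1/(N - N_{set})}
#' otherwise; the ES is the signed maximum deviation from zero. Ties in
#' the metric are broken by gene identifier (lexicographic), making the
#' score deterministic.
#'
#' @param ranked named numeric vector of the ranking metric (names are
#'   gene ids); sorted in decreasing order internally.
#' @param geneSet character vector of gene ids.
#' @param weightP non-negative weighting exponent \eqn{p}; \code{p = 1}
#'   (default) is the standard weighted statistic, \code{p = 0} the
#'   unweighted Kolmogorov-Smirnov-like form.
#' @return ES in \eqn{[-1, 1]}.
#' @examples
#' r <- c(a = 3, b = 2, c = 1)
#' enrichmentScore(r, "a", weightP = 0)   # 1
#' @export
enrichmentScore <- function(ranked, geneSet, weightP = 1) {
    stopifnot(is.numeric(ranked), !is.null(names(ranked)), weightP >= 0)
    ord <- order(-ranked, names(ranked))
    ranked <- ranked[ord]
    hit <- names(ranked) %in% geneSet
    nHit <- sum(hit)
    N <- length(ranked)
    if (nHit == 0L) stop("gene set has no overlap with the ranked list")
    if (nHit == N) stop("gene set equals the full ranked list")
    w <- abs(ranked)^weightP
    inc <- numeric(N)
    denomHit <- sum(w[hit])
    if (denomHit == 0) {            # all in-set metrics are zero
        inc[hit] <- 1 / nHit
    } else {
        inc[hit] <- w[hit] / denomHit
    }
    inc[!hit] <- -1 / (N - nHit)
    rs <- cumsum(inc)
    rs[which.max(abs(rs))]
}

#' Normalized enrichment score with permutation p-value
#'
#' Builds a null distribution of enrichment scores from random gene
#' sets of the same size (gene-label permutation), normalizes the
#' observed ES by the mean magnitude of same-sign null scores
#' (NES = ES / mean|null ES, same sign|), and reports the one-sided
#' permutation p-value \eqn{(1 + k)/(1 + n_{same sign})} where \eqn{k}
#' counts null scores at least as extreme with the same sign. Seeded
#' and deterministic.
#'
#' @inheritParams enrichmentScore
#' @param nPerm number of permutations (>= 100).
#' @param seed integer seed for the permutation null.
#' @param setName label stored in the result.
#' @return an [EnrichmentResult-class].
#' @export
nesAndPvalue <- function(ranked, geneSet, weightP = 1, nPerm = 1000L,
                         seed = 1L, setName = "set") {
    if (nPerm < 100L) stop("'nPerm' must be >= 100")
    es <- enrichmentScore(ranked, geneSet, weightP)
    nSet <- sum(names(ranked) %in% geneSet)
    genes <- names(ranked)
    withr::with_seed(as.integer(seed), {
        nullES <- vapply(seq_len(nPerm), function(i)
            enrichmentScore(ranked, sample(genes, nSet), weightP),
            numeric(1))
    })
    sameSign <- if (es >= 0) nullES >= 0 else nullES <= 0
    nSame <- sum(sameSign)
    flag <- ""
    if (nSame == 0L) {
        nes <- sign(es) * abs(es) / mean(abs(nullES))
        p <- 1 / (nPerm + 1)
        flag <- "no same-sign permutations; p bounded at 1/(nPerm+1)"
    } else {
        nes <- es / mean(abs(nullES[sameSign]))
        k <- sum(abs(nullES[sameSign]) >= abs(es))
        p <- (1 + k) / (1 + nSame)
    }
    new("EnrichmentResult", setName = setName, ES = es, NES = nes,
        pPerm = p, nPerm = as.integer(nPerm), seed = as.integer(seed),
        flag = flag)
}

#' Upper-tail hypergeometric over-representation test
#'
#' Exact probability \eqn{P[X \ge k]} for
#' \eqn{X \sim Hypergeometric(N, K, n)}: drawing \code{n} genes from a
#' universe of \code{N} of which \code{K} are in the set, the chance of
#' at least the observed overlap \code{k}.
#'
#' @param k observed overlap.
#' @param n number of genes drawn (e.g. the top list size).
#' @param K gene-set size in the universe.
#' @param N universe size.
#' @return upper-tail p-value.
#' @examples
#' hypergeometricTest(2, 3, 3, 6)   # 0.5
#' @export
hypergeometricTest <- function(k, n, K, N) {
    if (any(c(k, n, K, N) < 0) || n > N || K > N || k > min(n, K))
        stop("inconsistent counts: need 0 <= k <= min(n, K), n <= N, K <= N")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT dialect: one set per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}.
#'
#' @param path file path.
#' @return \code{readGMT}: named list of character vectors with a
#'   \code{"description"} attribute per set.
#' @export
readGMT <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    sets <- list()
    for (i in seq_along(lines)) {
        f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
        if (length(f) < 3L)
            stop("GMT line ", i, " has fewer than 3 fields")
        genes <- unique(f[-(1:2)])
        attr(genes, "description") <- f[2]
        sets[[f[1]]] <- genes
    }
    sets
}

#' @rdname readGMT
#' @param sets named list of character vectors.
#' @export
writeGMT <- function(sets, path) {
    stopifnot(is.list(sets), !is.null(names(sets)))
    lines <- vapply(names(sets), function(nm) {
        d <- attr(sets[[nm]], "description")
        if (is.null(d)) d <- nm
        paste(c(nm, d, as.character(sets[[nm]])), collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
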