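## negative-binomial differential-expression engine:
## transcript/ortholog aggregation, median-of-ratios size factors,
## dispersion trend + shrinkage, IRLS Wald tests, LFC shrinkage, VST

#' Aggregate transcript-level abundances to gene-level counts
#'
#' Sums estimated transcript counts within each gene and rounds to the
#' nearest integer, the tximport-style contract between quantifier
#' output and count-based differential expression.
#'
#' @param txAbundance named numeric vector or matrix (transcripts x
#'   samples) of estimated counts.
#' @param tx2gene named character: transcript id -> gene id.
#' @return integer matrix (genes x samples); genes with no transcripts
#'   are absent.
#' @export
aggregateTranscripts <- function(txAbundance, tx2gene) {
    if (is.vector(txAbundance))
        txAbundance <- matrix(txAbundance, ncol = 1,
                              dimnames = list(names(txAbundance), "sample"))
    unmapped <- setdiff(rownames(txAbundance), names(tx2gene))
    if (length(unmapped))
        stop("transcripts without a gene mapping: ",
             paste(unmapped, collapse = ", "))
    g <- tx2gene[rownames(txAbundance)]
    out <- rowsum(txAbundance, group = g)
    mode(out) <- "numeric"
    round(out)
}

#' Convert a count matrix across species via an ortholog map
#'
#' Re-indexes a source-species (CHO) count matrix onto target (human)
#' gene identifiers. Source genes without an ortholog are dropped (their
#' number is reported via a message). Under policy \code{"sum"},
#' many-to-one source genes are summed into their shared target and
#' one-to-many source genes are dropped; under \code{"drop_ambiguous"},
#' any gene on either side of a non-bijective pair is removed.
#'
#' @param counts genes x samples count matrix or
#'   \linkS4class{SummarizedExperiment}.
#' @param map data.frame with columns \code{cho_gene_id} (source) and
#'   \code{human_gene_id} (target), or any two-column frame ordered
#'   source, target.
#' @param policy \code{"sum"} (default) or \code{"drop_ambiguous"}.
#' @return count matrix on target gene identifiers.
#' @export
aggregateOrthologs <- function(counts, map, policy = c("sum", "drop_ambiguous")) {
    policy <- match.arg(policy)
    m <- .countsMatrix(counts)
    if (is.null(map) || nrow(map) == 0L) stop("empty ortholog map")
    src <- as.character(map[[1]]); tgt <- as.character(map[[2]])
    keep <- !duplicated(paste(src, tgt))
    src <- src[keep]; tgt <- tgt[keep]
    present <- src %in% rownames(m)
    if (!any(present))
        stop("no overlap between the ortholog map and the count matrix")
    nDropped <- sum(!(rownames(m) %in% src))
    if (nDropped)
        message(nDropped, " source gene(s) without an ortholog dropped")
    src <- src[present]; tgt <- tgt[present]
    one2many <- src %in% src[duplicated(src)]
    many2one <- tgt %in% tgt[duplicated(tgt)]
    if (policy == "sum") {
        drop <- one2many
        if (any(drop))
            message(sum(!duplicated(src[drop])),
                    " one-to-many source gene(s) dropped")
        src <- src[!drop]; tgt <- tgt[!drop]
    } else {
        drop <- one2many | many2one
        src <- src[!drop]; tgt <- tgt[!drop]
        if (!length(src))
            stop("no unambiguous pairs left under 'drop_ambiguous'")
    }
    out <- rowsum(m[src, , drop = FALSE], group = tgt)
    mode(out) <- "integer"
    out
}

#' Median-of-ratios size factors
#'
#' Per-sample normalization factors: for each sample, the median over
#' genes (expressed in every sample) of the ratio of its count to the
#' gene's geometric mean across samples, re-centered so the factors
#' have geometric mean 1.
#'
#' @param counts genes x samples count matrix or
#'   \linkS4class{SummarizedExperiment}.
#' @return named positive numeric, one factor per sample.
#' @export
medianRatioSizeFactors <- function(counts) {
    m <- .countsMatrix(counts)
    logGeo <- rowMeans(log(m))
    use <- is.finite(logGeo)          # genes with nonzero count everywhere
    if (!any(use))
        stop("no gene is expressed in all samples; ",
             "consider a pseudo-reference fallback")
    sf <- apply(m[use, , drop = FALSE], 2, function(col)
        exp(median(log(col) - logGeo[use])))
    sf <- sf / exp(mean(log(sf)))
    sf
}

## pooled within-group residual variance per gene, groups = distinct
## model-matrix rows; returns list(var, df)
.pooledVar <- function(q, modelMatrix) {
    grp <- apply(modelMatrix, 1, paste, collapse = "\r")
    groups <- split(seq_along(grp), grp)
    p <- qr(modelMatrix)$rank
    m <- ncol(q)
    ss <- matrix(0, nrow(q), 1)
    for (idx in groups) {
        if (length(idx) < 2L) next
        sub <- q[, idx, drop = FALSE]
        mu <- rowMeans(sub)
        ss <- ss + rowSums((sub - mu)^2)
    }
    list(var = ss / (m - p), df = m - p)
}

#' Estimate per-gene NB dispersions with trend shrinkage
#'
#' Three stages, mirroring the standard count-based DE workflow:
#' (1) gene-wise method-of-moments estimates
#' \eqn{\hat\alpha_g = (v_g - \bar{s^{-1}}\,\mu_g)/\mu_g^2} from pooled
#' within-group variances of normalized counts; (2) a parametric trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu} fit by iterated Gamma
#' (identity-link) regression with outlier exclusion; (3) empirical-Bayes
#' shrinkage of \eqn{\log\alpha_g} toward the trend, with the sampling
#' variance approximated by \eqn{trigamma((m-p)/2)} and the prior
#' variance estimated from the excess spread of the residuals.
#' Gene-wise estimates far above the trend are kept unshrunk (dispersion
#' outliers). All dispersions are floored at 1e-8.
#'
#' @param counts count matrix or \linkS4class{SummarizedExperiment}.
#' @param sizeFactors per-sample factors from [medianRatioSizeFactors()].
#' @param modelMatrix design matrix defining replicate groups; defaults
#'   to an intercept-only design (all samples one group).
#' @return list with \code{geneEst}, \code{trend}, \code{shrunk}
#'   (per-gene numerics), \code{trendCoef} \code{c(a0, a1)},
#'   \code{priorVar} and \code{baseMean}.
#' @export
estimateDispersionsNB <- function(counts, sizeFactors, modelMatrix = NULL) {
    m <- .countsMatrix(counts)
    if (all(m == 0)) stop("all counts are zero")
    if (is.null(modelMatrix))
        modelMatrix <- matrix(1, ncol(m), 1)
    stopifnot(ncol(m) == length(sizeFactors), ncol(m) == nrow(modelMatrix))
    q <- sweep(m, 2, sizeFactors, `/`)
    baseMean <- rowMeans(q)
    pv <- .pooledVar(q, modelMatrix)
    if (pv$df < 1L)
        stop("no residual degrees of freedom: need replicates")
    xim <- mean(1 / sizeFactors)
    geneEst <- (pv$var[, 1] - xim * baseMean) / baseMean^2
    geneEst[!is.finite(geneEst)] <- NA
    geneEst <- pmax(geneEst, 1e-8)

    ## parametric trend by iterated Gamma GLM with outlier exclusion
    useForFit <- !is.na(geneEst) & geneEst > 1e-7 & baseMean > 0.5
    if (sum(useForFit) < 10)
        useForFit <- !is.na(geneEst) & baseMean > 0
    disp <- geneEst[useForFit]; mu <- baseMean[useForFit]
    coefs <- c(a0 = max(median(disp, na.rm = TRUE), 0.01), a1 = 1)
    for (iter in seq_len(10)) {
        pred <- coefs[1] + coefs[2] / mu
        ratio <- disp / pred
        ok <- ratio > 1e-4 & ratio < 15
        fit <- try(glm(disp[ok] ~ I(1 / mu[ok]),
                       family = Gamma(link = "identity"),
                       start = coefs), silent = TRUE)
        if (inherits(fit, "try-error")) break
        newCoefs <- pmax(coef(fit), c(1e-8, 0))
        if (max(abs(newCoefs - coefs) / (coefs + 1e-8)) < 1e-4) {
            coefs <- newCoefs; break
        }
        coefs <- newCoefs
    }
    names(coefs) <- c("a0", "a1")
    trend <- pmax(coefs[1] + coefs[2] / baseMean, 1e-8)

    ## log-scale shrinkage toward the trend; the gene-wise log estimate
    ## carries the chi-square log bias digamma(df/2) - log(df/2), which is
    ## removed before combining (the trend, fit on the natural scale, is
    ## unaffected)
    sVar <- trigamma(pv$df / 2)           # sampling variance of log disp
    logBias <- digamma(pv$df / 2) - log(pv$df / 2)
    logGene <- log(geneEst) - logBias
    logRes <- logGene - log(trend)
    usable <- is.finite(logRes) & geneEst > 1e-7
    priorVar <- max(var(logRes[usable], na.rm = TRUE) - sVar, 0.25)
    w <- (1 / sVar) / (1 / sVar + 1 / priorVar)
    logShrunk <- w * logGene + (1 - w) * log(trend)
    shrunk <- exp(logShrunk)
    ## dispersion outliers: keep the gene-wise estimate
    outlier <- logGene > log(trend) + 2 * sqrt(sVar + priorVar)
    shrunk[outlier] <- geneEst[outlier]
    shrunk <- pmax(shrunk, 1e-8)
    shrunk[is.na(shrunk)] <- trend[is.na(shrunk)]

    list(geneEst = geneEst, trend = trend, shrunk = shrunk,
         trendCoef = coefs, priorVar = priorVar, baseMean = baseMean)
}

## IRLS fit of the NB log-link GLM with fixed dispersion, per gene.
## Returns beta (genes x p), covariance arrays, convergence flags.
.fitNBGLM <- function(m, sizeFactors, dispersions, X,
                      maxIter = 50L, tol = 1e-6, penalty = NULL) {
    nG <- nrow(m); p <- ncol(X)
    offset <- log(sizeFactors)
    Lambda <- if (is.null(penalty)) diag(1e-8, p) else diag(penalty, p)
    beta <- matrix(NA_real_, nG, p, dimnames = list(rownames(m), colnames(X)))
    covs <- array(NA_real_, c(nG, p, p))
    converged <- logical(nG)
    qrX <- qr(X)
    if (qrX$rank < p) stop("design matrix is not full rank")
    for (g in seq_len(nG)) {
        y <- m[g, ]
        alpha <- dispersions[g]
        b <- qr.coef(qrX, log((y + 0.5) / sizeFactors))
        ok <- FALSE
        for (it in seq_len(maxIter)) {
            eta <- pmin(pmax(drop(X %*% b) + offset, -30), 30)
            mu <- exp(eta)
            w <- mu / (1 + alpha * mu)
            z <- (eta - offset) + (y - mu) / mu
            XtW <- t(X * w)
            H <- XtW %*% X + Lambda
            bNew <- tryCatch(solve(H, XtW %*% z), error = function(e) NULL)
            if (is.null(bNew) || any(!is.finite(bNew))) break
            delta <- max(abs(bNew - b))
            b <- drop(bNew)
            if (delta < tol) { ok <- TRUE; break }
        }
        if (ok) {
            eta <- pmin(pmax(drop(X %*% b) + offset, -30), 30)
            mu <- exp(eta)
            w <- mu / (1 + alpha * mu)
            H <- t(X * w) %*% X + Lambda
            covs[g, , ] <- tryCatch(solve(H), error = function(e) {
                ok <<- FALSE; matrix(NA_real_, p, p)
            })
        }
        beta[g, ] <- b
        converged[g] <- ok
    }
    list(beta = beta, covs = covs, converged = converged, X = X)
}

.resolveContrast <- function(contrast, X) {
    if (is.character(contrast)) {
        if (!(contrast %in% colnames(X)))
            stop("unknown coefficient '", contrast, "'; available: ",
                 paste(colnames(X), collapse = ", "))
        cvec <- as.numeric(colnames(X) == contrast)
    } else {
        cvec <- as.numeric(contrast)
        if (length(cvec) != ncol(X))
            stop("contrast length must equal the number of coefficients")
    }
    cvec
}

.makeDEResult <- function(fit, cvec, baseMean, meta) {
    nG <- nrow(fit$beta)
    est <- drop(fit$beta %*% cvec)
    se <- vapply(seq_len(nG), function(g)
        sqrt(drop(t(cvec) %*% fit$covs[g, , ] %*% cvec)), numeric(1))
    lfcRaw <- est / log(2)
    seLog2 <- se / log(2)
    stat <- est / se
    pvalue <- 2 * pnorm(-abs(stat))
    pvalue[!fit$converged] <- NA
    padj <- p.adjust(pvalue, method = "BH")
    df <- DataFrame(
        baseMean = baseMean,
        lfc_raw = lfcRaw,
        lfc_shrunk = NA_real_,
        se = seLog2,
        stat = stat,
        pvalue = pvalue,
        padj = padj,
        converged = fit$converged,
        row.names = rownames(fit$beta))
    res <- new("DEResult", df)
    metadata(res) <- c(meta, list(
        pseudocountPolicy = "pseudocount +1 only in descriptive log2 ratios, never in the GLM",
        nNotConverged = sum(!fit$converged)))
    res
}

#' Fit NB GLMs and Wald-test a contrast
#'
#' Per gene, fits the negative-binomial log-link GLM by iteratively
#' reweighted least squares with the gene's (fixed) dispersion and the
#' log size factors as offset, then tests a linear contrast of the
#' coefficients with a Wald statistic against the standard normal.
#' Benjamini-Hochberg adjustment is applied across tested genes;
#' non-converged genes get a missing p-value and are excluded from the
#' BH denominator.
#'
#' @param counts count matrix or \linkS4class{SummarizedExperiment}.
#' @param sizeFactors per-sample size factors.
#' @param dispersions per-gene dispersions (typically
#'   \code{estimateDispersionsNB(...)$shrunk}).
#' @param modelMatrix full-rank design matrix (samples x coefficients).
#' @param contrast a coefficient name or a numeric contrast vector.
#' @return a [DEResult-class] with columns \code{baseMean},
#'   \code{lfc_raw}, \code{lfc_shrunk} (NA until [shrinkLFC()]),
#'   \code{se}, \code{stat}, \code{pvalue}, \code{padj} (log2 scale for
#'   effect sizes).
#' @export
fitWaldNB <- function(counts, sizeFactors, dispersions, modelMatrix,
                      contrast) {
    m <- .countsMatrix(counts)
    stopifnot(length(dispersions) == nrow(m),
              length(sizeFactors) == ncol(m))
    fit <- .fitNBGLM(m, sizeFactors, dispersions, modelMatrix)
    cvec <- .resolveContrast(contrast, modelMatrix)
    baseMean <- rowMeans(sweep(m, 2, sizeFactors, `/`))
    .makeDEResult(fit, cvec, baseMean,
                  list(design = colnames(modelMatrix), contrast = contrast))
}

## select the zero-centered normal prior width by maximizing the
## Gaussian marginal likelihood prod_g N(lfc_g; 0, s^2 + se_g^2);
## genes with unstable fits (huge se) carry no information here
.selectPriorSd <- function(lfc, se, priorSdGrid) {
    use <- is.finite(lfc) & is.finite(se) & se > 0 & se < 10
    if (!any(use)) use <- is.finite(lfc) & is.finite(se) & se > 0
    marginal <- vapply(priorSdGrid, function(s)
        sum(dnorm(lfc[use], 0, sqrt(s^2 + se[use]^2), log = TRUE)),
        numeric(1))
    priorSdGrid[which.max(marginal)]
}

#' Shrink log2 fold changes with a zero-centered normal prior
#'
#' Reimplements the adaptive-prior shrinkage of fold changes as a
#' posterior mode under a zero-centered normal prior on the
#' (non-intercept) GLM coefficients, with the prior width selected from
#' a grid by maximizing the Gaussian marginal likelihood
#' \eqn{\prod_g N(lfc_g; 0, s^2 + se_g^2)}.
#'
#' Two posterior-mode routes are available. Without count data
#' (default), the normal-likelihood closed form
#' \eqn{lfc_g \cdot s^2/(s^2 + se_g^2)} is used — exact when the
#' likelihood is well approximated by its Wald summary. When
#' \code{counts}, \code{sizeFactors}, \code{dispersions} and
#' \code{modelMatrix} are supplied, the mode is found under the actual
#' NB likelihood by ridge-penalized IRLS; this is essential for genes
#' with one all-zero condition, whose Wald summary (enormous standard
#' error) would otherwise erase a genuinely extreme fold change. In
#' both routes the shrunken LFC never exceeds the raw LFC in magnitude.
#'
#' @param de a [DEResult-class] with \code{lfc_raw} and \code{se}.
#' @param priorSdGrid positive grid of candidate prior sds (log2 units).
#' @param counts,sizeFactors,dispersions,modelMatrix optional fit
#'   context enabling the NB-likelihood posterior mode.
#' @param contrast contrast used for \code{de} (required with the NB
#'   route).
#' @return the [DEResult-class] with \code{lfc_shrunk} filled in and the
#'   selected prior sd recorded in \code{metadata()}.
#' @export
shrinkLFC <- function(de, priorSdGrid = exp(seq(log(0.05), log(20),
                                                length.out = 50)),
                      counts = NULL, sizeFactors = NULL,
                      dispersions = NULL, modelMatrix = NULL,
                      contrast = NULL) {
    if (!length(priorSdGrid)) stop("empty prior sd grid")
    stopifnot(is(de, "DEResult"))
    lfc <- de$lfc_raw; se <- de$se
    s <- .selectPriorSd(lfc, se, priorSdGrid)
    if (is.null(counts)) {
        shrunk <- lfc * s^2 / (s^2 + se^2)
        use <- is.finite(lfc) & is.finite(se) & se > 0
        shrunk[!use] <- NA_real_
        method <- "normal-approximation posterior mode"
    } else {
        stopifnot(!is.null(sizeFactors), !is.null(dispersions),
                  !is.null(modelMatrix), !is.null(contrast))
        m <- .countsMatrix(counts)[rownames(de), , drop = FALSE]
        cvec <- .resolveContrast(contrast, modelMatrix)
        lambda <- 1 / (s * log(2))^2   # prior precision on natural-log scale
        pen <- rep(lambda, ncol(modelMatrix))
        pen[colnames(modelMatrix) == "(Intercept)"] <- 0
        fit <- .fitNBGLM(m, sizeFactors, dispersions, modelMatrix,
                         penalty = pen)
        shrunk <- drop(fit$beta %*% cvec) / log(2)
        ## the mode under a zero-centered prior cannot exceed the MLE
        cap <- abs(lfc)
        shrunk <- sign(shrunk) * pmin(abs(shrunk), cap)
        method <- "NB-likelihood posterior mode (penalized IRLS)"
    }
    de$lfc_shrunk <- shrunk
    metadata(de)$lfcPriorSd <- s
    metadata(de)$lfcShrinkMethod <- method
    de
}

#' Run the full differential-expression pipeline
#'
#' Excludes all-zero genes, estimates size factors and dispersions,
#' fits the NB GLMs, Wald-tests the contrast, and (by default) shrinks
#' the LFCs. This is the engine behind both the between-host contrast
#' and the producer-vs-control activation contrasts.
#'
#' @param counts count matrix or \linkS4class{SummarizedExperiment}.
#' @param sampleTable data.frame (or \code{DataFrame}) of per-sample
#'   covariates, rows aligned with the columns of \code{counts}.
#' @param design one-sided formula over \code{sampleTable} columns.
#' @param contrast coefficient name or numeric contrast vector.
#' @param shrink logical; apply [shrinkLFC()].
#' @return a [DEResult-class]; excluded all-zero genes are reported in
#'   \code{metadata()}.
#' @export
runDiffExp <- function(counts, sampleTable, design, contrast,
                       shrink = TRUE) {
    m <- .countsMatrix(counts)
    sampleTable <- as.data.frame(sampleTable)
    stopifnot(nrow(sampleTable) == ncol(m))
    X <- model.matrix(design, data = sampleTable)
    if (qr(X)$rank < ncol(X))
        stop("design matrix is not full rank on these samples")
    allZero <- rowSums(m) == 0
    m <- m[!allZero, , drop = FALSE]
    sf <- medianRatioSizeFactors(m)
    dsp <- estimateDispersionsNB(m, sf, X)
    de <- fitWaldNB(m, sf, dsp$shrunk, X, contrast)
    metadata(de)$nAllZeroExcluded <- sum(allZero)
    metadata(de)$dispersionTrendCoef <- dsp$trendCoef
    metadata(de)$simplifications <-
        "no Cook's-distance outlier replacement; no independent filtering"
    if (shrink)
        de <- shrinkLFC(de, counts = m, sizeFactors = sf,
                        dispersions = dsp$shrunk, modelMatrix = X,
                        contrast = contrast)
    de
}

#' Differential activation within one cell line
#'
#' Compares producer samples with empty-vector controls within the
#' given cell line; the shrunken LFC is the gene's "activation" upon
#' transgene expression.
#'
#' @param counts count matrix or \linkS4class{SummarizedExperiment}
#'   (if an SE, \code{colData} is used as the sample table).
#' @param sampleTable per-sample covariates with columns
#'   \code{cell_line} and \code{condition} (\code{"producer"} /
#'   \code{"control"}); ignored if \code{counts} carries its own.
#' @param cellLine which cell line to analyse.
#' @param shrink logical; apply [shrinkLFC()].
#' @return a [DEResult-class] of producers vs controls.
#' @export
differentialActivation <- function(counts, sampleTable = NULL,
                                   cellLine, shrink = TRUE) {
    if (is(counts, "SummarizedExperiment") && is.null(sampleTable))
        sampleTable <- as.data.frame(colData(counts))
    m <- .countsMatrix(counts)
    stopifnot(!is.null(sampleTable),
              all(c("cell_line", "condition") %in% colnames(sampleTable)))
    sel <- sampleTable$cell_line == cellLine
    if (!any(sel))
        stop("no samples for cell line '", cellLine, "'")
    st <- sampleTable[sel, , drop = FALSE]
    if (!any(st$condition == "control"))
        stop("cell line '", cellLine, "' has no control samples")
    if (!any(st$condition == "producer"))
        stop("cell line '", cellLine, "' has no producer samples")
    st$condition <- factor(st$condition, levels = c("control", "producer"))
    runDiffExp(m[, sel, drop = FALSE], st, ~condition,
               "conditionproducer", shrink = shrink)
}

#' Per-r-protein interaction activation between cell lines
#'
#' Fits the expanded design with an interaction between cell line and
#' r-protein identity on the combined (ortholog-mapped) samples of both
#' hosts, producers and controls: for each r-protein, the interaction
#' coefficient measures how much more that r-protein activates a gene
#' in HEK293 than in CHO.
#'
#' @param counts combined count matrix on a shared gene universe.
#' @param sampleTable per-sample covariates with \code{cell_line},
#'   \code{condition} and \code{r_protein} (\code{"none"} for controls).
#' @param shrink logical; shrink each interaction LFC via [shrinkLFC()].
#' @return list with \code{lfc} (genes x r-proteins matrix of
#'   interaction log2 fold changes, shrunk if requested) and
#'   \code{results} (one [DEResult-class] per r-protein).
#' @export
interactionActivation <- function(counts, sampleTable, shrink = TRUE) {
    m <- .countsMatrix(counts)
    sampleTable <- as.data.frame(sampleTable)
    stopifnot(all(c("cell_line", "condition", "r_protein") %in%
                  colnames(sampleTable)))
    st <- sampleTable
    st$cell_line <- factor(st$cell_line, levels = c("CHO", "HEK293"))
    rp <- setdiff(unique(st$r_protein), "none")
    st$r_protein <- factor(st$r_protein, levels = c("none", sort(rp)))
    X <- model.matrix(~ cell_line + r_protein + cell_line:r_protein,
                      data = st)
    if (qr(X)$rank < ncol(X))
        stop("interaction design not full rank: every (cell line, r-protein) cell needs samples")
    allZero <- rowSums(m) == 0
    m <- m[!allZero, , drop = FALSE]
    sf <- medianRatioSizeFactors(m)
    dsp <- estimateDispersionsNB(m, sf, X)
    fit <- .fitNBGLM(m, sf, dsp$shrunk, X)
    baseMean <- rowMeans(sweep(m, 2, sf, `/`))
    results <- list()
    for (p in sort(rp)) {
        cname <- paste0("cell_lineHEK293:r_protein", p)
        cvec <- .resolveContrast(cname, X)
        de <- .makeDEResult(fit, cvec, baseMean,
                            list(design = colnames(X), contrast = cname))
        if (shrink) de <- shrinkLFC(de)
        results[[p]] <- de
    }
    lfc <- vapply(results, function(d)
        if (shrink) d$lfc_shrunk else d$lfc_raw,
        numeric(nrow(m)))
    rownames(lfc) <- rownames(m)
    list(lfc = lfc, results = results)
}

#' Variance-stabilizing transformation for NB counts
#'
#' Closed-form VST for the dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}: applied to normalized counts
#' \eqn{q},
#' \deqn{vst(q) = \log_2\!\frac{1 + a_1 + 2 a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0} - c_0,}
#' where \eqn{c_0} anchors the transform at \eqn{vst(0) = 0} (so zero
#' counts map to zero, as for \eqn{\log_2(1+x)}). The transform is
#' monotone increasing, grows like \eqn{\log_2 q} for large \eqn{q},
#' and renders the variance approximately independent of the mean.
#'
#' @param counts count matrix or \linkS4class{SummarizedExperiment}.
#' @param sizeFactors per-sample size factors.
#' @param trendCoef \code{c(a0, a1)} with \code{a0 > 0} (from
#'   [estimateDispersionsNB()]).
#' @return transformed matrix with the dimnames of \code{counts}.
#' @export
vstTransform <- function(counts, sizeFactors, trendCoef) {
    m <- .countsMatrix(counts)
    a0 <- trendCoef[[1]]; a1 <- trendCoef[[2]]
    if (a0 <= 0) stop("'a0' (dispersion asymptote) must be > 0")
    q <- sweep(m, 2, sizeFactors, `/`)
    f <- function(q) log2((1 + a1 + 2 * a0 * q +
          2 * sqrt(a0 * q * (1 + a1 + a0 * q))) / (4 * a0))
    f(q) - f(0)
}
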