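## secretory-pathway outlier classification, activation-disparity
## ranking, and activation/titer correlation

#' Classify between-host expression outliers into groups I/II/III
#'
#' On mean variance-stabilized expression per gene in each host, genes
#' within a band of half-width \code{bandHalfwidth} around the identity
#' line are conserved; the rest are outliers classified as: group I —
#' essentially silent in CHO (\code{< lowThresh}) but at least
#' moderately expressed in HEK293 (\code{>= highThresh}); group II —
#' moderate in CHO (between the thresholds) and higher in HEK293 by
#' more than the band; group III — higher in CHO by more than the band.
#'
#' Default thresholds (band 2, low 2, high 6, in VST log2-like units)
#' are qualitative reading of the conserved-band scatter; all are
#' configurable.
#'
#' @param vstCho,vstHek named per-gene mean transformed expression in
#'   each host (same gene universe, post-ortholog mapping).
#' @param bandHalfwidth half-width of the identity band.
#' @param lowThresh,highThresh low/moderate expression thresholds
#'   (\code{lowThresh < highThresh} required).
#' @return data.frame with columns \code{gene_id}, \code{cho},
#'   \code{hek}, \code{in_identity_band}, \code{group} (factor I / II /
#'   III / none).
#' @export
classifyOutlierGroups <- function(vstCho, vstHek, bandHalfwidth = 2,
                                  lowThresh = 2, highThresh = 6) {
    if (lowThresh >= highThresh)
        stop("'lowThresh' must be smaller than 'highThresh'")
    stopifnot(!is.null(names(vstCho)),
              setequal(names(vstCho), names(vstHek)))
    vstHek <- vstHek[names(vstCho)]
    inBand <- abs(vstHek - vstCho) <= bandHalfwidth
    group <- rep("none", length(vstCho))
    gI <- !inBand & vstCho < lowThresh & vstHek >= highThresh
    gII <- !inBand & !gI & vstCho >= lowThresh & vstCho < highThresh &
        (vstHek - vstCho) > bandHalfwidth
    gIII <- !inBand & (vstHek < vstCho - bandHalfwidth)
    group[gIII] <- "III"; group[gII] <- "II"; group[gI] <- "I"
    data.frame(gene_id = names(vstCho),
               cho = unname(vstCho), hek = unname(vstHek),
               in_identity_band = unname(inBand),
               group = factor(group, levels = c("I", "II", "III", "none")),
               stringsAsFactors = FALSE)
}

#' Rank genes by activation disparity between hosts
#'
#' The activation disparity of a gene is the absolute difference
#' between its producer-vs-control activation LFCs in the two hosts.
#' Genes are ranked in decreasing disparity (ties broken by gene id)
#' and the top \code{topK} returned — the study's "top 20" most
#' differentially activated genes.
#'
#' @param actCho,actHek [DEResult-class] activation results for CHO and
#'   HEK293 on a shared gene universe (shrunken LFCs are used when
#'   available).
#' @param topK number of rows to return.
#' @return data.frame with \code{gene_id}, \code{lfc_act_cho},
#'   \code{lfc_act_hek}, \code{disparity}, \code{rank}.
#' @export
rankActivationDisparity <- function(actCho, actHek, topK = 20L) {
    genes <- intersect(rownames(actCho), rownames(actHek))
    if (topK > length(genes))
        stop("'topK' exceeds the number of shared genes")
    pick <- function(de) {
        l <- de[genes, ]
        ifelse(is.na(l$lfc_shrunk), l$lfc_raw, l$lfc_shrunk)
    }
    a <- pick(actCho); b <- pick(actHek)
    disparity <- abs(b - a)
    ord <- order(-disparity, genes)
    top <- head(ord, topK)
    data.frame(gene_id = genes[top],
               lfc_act_cho = a[top], lfc_act_hek = b[top],
               disparity = disparity[top],
               rank = seq_len(topK),
               stringsAsFactors = FALSE)
}

#' Over-representation of secretory genes in a top list
#'
#' Thin composition over [hypergeometricTest()]: tests whether a top
#' gene list (e.g. the top-20 activation-disparity genes) is enriched
#' for secretory-pathway members relative to the gene universe.
#'
#' @param topGenes character vector, the selected genes.
#' @param secretoryGenes character vector, the secretory set.
#' @param universe character vector, all tested genes.
#' @return upper-tail hypergeometric p-value.
#' @export
topSetEnrichment <- function(topGenes, secretoryGenes, universe) {
    if (!all(topGenes %in% universe) || !all(secretoryGenes %in% universe))
        stop("'topGenes' and 'secretoryGenes' must be subsets of 'universe'")
    hypergeometricTest(k = length(intersect(topGenes, secretoryGenes)),
                       n = length(topGenes),
                       K = length(secretoryGenes),
                       N = length(universe))
}

#' Correlate per-gene differential activation with titer change
#'
#' For each gene, the Pearson correlation across r-proteins between its
#' interaction activation LFC (how much more the r-protein activates
#' the gene in HEK293 than CHO) and the r-protein's titer log2 fold
#' change from CHO to HEK293. Genes whose activation vector has zero
#' variance have an undefined correlation and are excluded from the
#' ranking (reported separately).
#'
#' @param actDiff genes x r-proteins matrix of interaction LFCs (see
#'   [interactionActivation()]).
#' @param titerLfc named per-r-protein titer log2 fold change.
#' @return data.frame of defined correlations sorted decreasing by
#'   \code{r}, with the excluded gene ids in
#'   \code{attr(, "undefined")}.
#' @export
activationTiterCorrelation <- function(actDiff, titerLfc) {
    shared <- intersect(colnames(actDiff), names(titerLfc))
    if (length(shared) < 3L)
        stop("need at least 3 r-proteins with both activation and titer data")
    a <- actDiff[, shared, drop = FALSE]
    t <- titerLfc[shared]
    sds <- apply(a, 1, sd)
    defined <- is.finite(sds) & sds > 0 & rowSums(is.na(a)) == 0
    r <- rep(NA_real_, nrow(a))
    r[defined] <- apply(a[defined, , drop = FALSE], 1,
                        function(x) cor(x, t))
    out <- data.frame(gene_id = rownames(a)[defined],
                      r = r[defined], stringsAsFactors = FALSE)
    out <- out[order(-out$r, out$gene_id), ]
    rownames(out) <- NULL
    attr(out, "undefined") <- rownames(a)[!defined]
    out
}
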