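## transcriptome-usage decomposition, QC fractions, titer fold-change rules

.countsMatrix <- function(x) {
    if (is(x, "SummarizedExperiment")) assay(x, "counts")
    else if (is.matrix(x)) x
    else stop("expected a SummarizedExperiment or a matrix")
}

#' Transcripts per million
#'
#' Length-normalizes a count matrix to TPM: per sample,
#' \eqn{TPM_g \propto count_g / length_g}, scaled to sum to 1e6.
#'
#' @param counts genes x samples count matrix (or a
#'   \linkS4class{SummarizedExperiment} with a \code{counts} assay).
#' @param geneLengths named numeric of positive lengths (bases). Genes
#'   missing a length are an error; with \code{geneLengths = NULL} all
#'   lengths default to 1 kb (with a warning), appropriate for synthetic
#'   data without real gene models.
#' @return matrix of TPM values with the dimnames of \code{counts}.
#' @examples
#' m <- matrix(c(10, 10), 2, 1, dimnames = list(c("a", "b"), "s1"))
#' computeTPM(m, c(a = 1000, b = 2000))
#' @export
computeTPM <- function(counts, geneLengths = NULL) {
    m <- .countsMatrix(counts)
    if (is.null(geneLengths)) {
        warning("no gene lengths supplied; defaulting all lengths to 1 kb")
        geneLengths <- setNames(rep(1000, nrow(m)), rownames(m))
    }
    missing <- setdiff(rownames(m), names(geneLengths))
    if (length(missing))
        stop("missing gene length for: ",
             paste(head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
    len <- geneLengths[rownames(m)]
    if (any(len <= 0)) stop("gene lengths must be positive")
    rate <- m / len
    tot <- colSums(rate)
    if (any(tot == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(m)[tot == 0], collapse = ", "))
    sweep(rate, 2, tot, `/`) * 1e6
}

#' Transcriptome usage by functional group
#'
#' Decomposes each sample's transcriptome (TPM mass) into fractions per
#' functional group, Proteomaps-style. Excluded genes (typically the
#' transgene transcript) contribute zero mass and fractions are
#' renormalized over the remainder; genes without an annotation fall
#' into an explicit \code{"unassigned"} group so that fractions always
#' sum to one.
#'
#' @param tpm TPM matrix from [computeTPM()].
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{group}.
#' @param exclude character vector of gene ids to drop before
#'   renormalization.
#' @return matrix of fractions, groups x samples; columns sum to 1.
#' @export
transcriptomeUsage <- function(tpm, annotation, exclude = character(0)) {
    stopifnot(is.matrix(tpm))
    if (is.null(annotation) || nrow(annotation) == 0L)
        stop("empty functional annotation")
    keep <- !(rownames(tpm) %in% exclude)
    tpm <- tpm[keep, , drop = FALSE]
    grp <- annotation$group[match(rownames(tpm), annotation$gene_id)]
    grp[is.na(grp)] <- "unassigned"
    mass <- rowsum(tpm, group = grp)
    sweep(mass, 2, colSums(mass), `/`)
}

#' Mitochondrial fraction of the transcriptome
#'
#' Per-sample fraction of TPM mass on mitochondrially encoded genes, a
#' between-sample normalization check (expected to sit near 10\% and be
#' stable across samples).
#'
#' @param tpm TPM matrix.
#' @param mitoGenes character vector of mitochondrial gene ids.
#' @return named numeric, one fraction in \eqn{[0, 1]} per sample.
#' @export
mitoFraction <- function(tpm, mitoGenes) {
    stopifnot(is.matrix(tpm), length(mitoGenes) > 0)
    hit <- rownames(tpm) %in% mitoGenes
    colSums(tpm[hit, , drop = FALSE]) / colSums(tpm)
}

#' Titer log2 fold change with pseudocount
#'
#' \code{titerLog2FC} computes \eqn{\log_2((a+1)/(b+1))}; the +1
#' pseudocount accommodates samples with undetectable r-protein (titer
#' 0). \code{classifyImproved} implements the "more than two-fold
#' improved" rule as a strict inequality: improved iff the LFC exceeds
#' 1 (exactly two-fold is not improved).
#'
#' @param titerA,titerB non-negative titers (\eqn{\mu g/ml}).
#' @param lfc a log2 fold change.
#' @return \code{titerLog2FC}: numeric LFC; \code{classifyImproved}:
#'   logical.
#' @examples
#' titerLog2FC(7, 0)            # 3
#' classifyImproved(titerLog2FC(3, 1))  # exactly two-fold: FALSE
#' @export
titerLog2FC <- function(titerA, titerB) {
    if (any(titerA < 0) || any(titerB < 0))
        stop("titers must be >= 0")
    log2((titerA + 1) / (titerB + 1))
}

#' @rdname titerLog2FC
#' @export
classifyImproved <- function(lfc) lfc > 1

#' Mean transformed expression per secretory subsystem
#'
#' For each sample, the arithmetic mean of variance-stabilized
#' expression over the genes of each secretory-pathway subsystem
#' (typically the 11 curated subsystems, but any grouping is accepted).
#' Subsystems with no genes present in the matrix are dropped with a
#' warning.
#'
#' @param vstExpr transformed expression matrix (see [vstTransform()]).
#' @param subsystemAnnotation named character: gene id -> subsystem.
#' @return matrix, subsystems x samples.
#' @export
secretorySubgroupMeans <- function(vstExpr, subsystemAnnotation) {
    stopifnot(is.matrix(vstExpr))
    genes <- intersect(rownames(vstExpr), names(subsystemAnnotation))
    ss <- subsystemAnnotation[genes]
    missing <- setdiff(unique(subsystemAnnotation), unique(ss))
    if (length(missing))
        warning("subsystem(s) with no genes in the matrix dropped: ",
                paste(missing, collapse = ", "))
    if (!length(genes)) stop("no annotated genes present in the matrix")
    m <- rowsum(vstExpr[genes, , drop = FALSE], group = ss)
    sweep(m, 1, as.vector(table(ss)[rownames(m)]), `/`)
}
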