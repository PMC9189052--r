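#' Simulation configuration for the synthetic host-comparison study
#'
#' Holds every parameter of the synthetic-data generator: gene universe
#' sizes, the negative-binomial mean/dispersion structure, planted
#' between-host and activation effects, ortholog-map coverage, the
#' mitochondrial library-mass target, and the generative truth of the
#' titer-improvement regression.
#'
#' @slot nGenes number of genes in the (human) gene universe.
#' @slot nSecretoryGenes number of secretory-pathway genes (subset of
#'   \code{nGenes}), partitioned into 11 subsystems.
#' @slot nMitoGenes number of mitochondrially encoded genes.
#' @slot nRProteins number of recombinant proteins in the expression panel.
#' @slot replicatesPerCondition biological replicates per (r-protein,
#'   cell line) producer group and per empty-vector control group.
#' @slot baselineMeanLogRange range (natural log) of baseline NB means.
#' @slot dispersionTrend numeric(2), \code{c(a0, a1)} of the dispersion
#'   trend \eqn{\alpha(\mu) = a0 + a1/\mu}.
#' @slot celllineEffectSD sd (log2) of per-gene between-host expression
#'   differences.
#' @slot activationEffectSD named numeric, per cell line, sd (log2) of
#'   producer-vs-control activation effects on activated genes.
#' @slot nActivatedGenes number of genes carrying a nonzero activation
#'   effect.
#' @slot nPlantedOutliers number of secretory genes planted as extreme
#'   between-host outliers (silent in CHO, high in HEK293).
#' @slot outlierLFC log2 fold change of the planted outliers.
#' @slot orthologCoverage fraction of CHO genes with a human ortholog.
#' @slot manyToOneFraction fraction of mapped CHO genes sharing their
#'   human target with another CHO gene.
#' @slot mitoFractionTarget target fraction of library mass on
#'   mitochondrial genes.
#' @slot transgeneShare fraction of producer library mass on the
#'   transgene transcript.
#' @slot nTiterLinkedGenes genes whose HEK-vs-CHO activation difference
#'   tracks the per-r-protein titer log2 fold change.
#' @slot regressionTruth named numeric \code{c(a, bPTM, bEnz, bInt,
#'   sigma)} of the titer-improvement model.
#' @slot seed integer master seed.
#'
#' @seealso [simConfig()] for the user-facing constructor with defaults.
#' @exportClass SimConfig
setClass("SimConfig", representation(
    nGenes = "integer",
    nSecretoryGenes = "integer",
    nMitoGenes = "integer",
    nRProteins = "integer",
    replicatesPerCondition = "integer",
    baselineMeanLogRange = "numeric",
    dispersionTrend = "numeric",
    celllineEffectSD = "numeric",
    activationEffectSD = "numeric",
    nActivatedGenes = "integer",
    nPlantedOutliers = "integer",
    outlierLFC = "numeric",
    orthologCoverage = "numeric",
    manyToOneFraction = "numeric",
    mitoFractionTarget = "numeric",
    transgeneShare = "numeric",
    nTiterLinkedGenes = "integer",
    regressionTruth = "numeric",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    pos <- function(x, nm) if (length(x) != 1L || is.na(x) || x <= 0L)
        sprintf("'%s' must be a single positive value", nm) else NULL
    msg <- c(msg,
        pos(object@nGenes, "nGenes"),
        pos(object@nSecretoryGenes, "nSecretoryGenes"),
        pos(object@nMitoGenes, "nMitoGenes"),
        pos(object@nRProteins, "nRProteins"),
        pos(object@replicatesPerCondition, "replicatesPerCondition"))
    if (object@nSecretoryGenes + object@nMitoGenes > object@nGenes)
        msg <- c(msg, "nSecretoryGenes + nMitoGenes must be <= nGenes")
    if (object@replicatesPerCondition < 2L)
        msg <- c(msg, "replicatesPerCondition must be >= 2 (differential expression needs replication)")
    if (length(object@dispersionTrend) != 2L || any(object@dispersionTrend < 0) ||
        object@dispersionTrend[1] <= 0)
        msg <- c(msg, "dispersionTrend must be c(a0 > 0, a1 >= 0)")
    if (object@celllineEffectSD < 0)
        msg <- c(msg, "celllineEffectSD must be >= 0")
    if (any(object@activationEffectSD < 0))
        msg <- c(msg, "activationEffectSD values must be >= 0")
    if (is.null(names(object@activationEffectSD)) ||
        !all(c("CHO", "HEK293") %in% names(object@activationEffectSD)))
        msg <- c(msg, "activationEffectSD must be named with 'CHO' and 'HEK293'")
    if (object@orthologCoverage <= 0 || object@orthologCoverage > 1)
        msg <- c(msg, "orthologCoverage must be in (0, 1]")
    if (object@mitoFractionTarget <= 0 || object@mitoFractionTarget >= 1)
        msg <- c(msg, "mitoFractionTarget must be in (0, 1)")
    if (object@manyToOneFraction < 0 || object@manyToOneFraction >= 1)
        msg <- c(msg, "manyToOneFraction must be in [0, 1)")
    if (object@transgeneShare < 0 || object@transgeneShare >= 1)
        msg <- c(msg, "transgeneShare must be in [0, 1)")
    if (length(object@regressionTruth) != 5L ||
        !all(c("a", "bPTM", "bEnz", "bInt", "sigma") %in% names(object@regressionTruth)))
        msg <- c(msg, "regressionTruth must be named c(a, bPTM, bEnz, bInt, sigma)")
    else if (object@regressionTruth[["sigma"]] <= 0)
        msg <- c(msg, "regressionTruth['sigma'] must be > 0")
    if (length(msg)) msg else TRUE
})

#' Bundle of synthetic pipeline inputs
#'
#' Everything the analysis consumes, generated from one [SimConfig]:
#' per-host count matrices (as \linkS4class{SummarizedExperiment}s with
#' the sample sheet in \code{colData}), the partial ortholog map, the
#' functional annotation, gene-set collections, titers, PTM annotations,
#' and the full record of planted truth.
#'
#' @slot countsCHO,countsHEK \linkS4class{SummarizedExperiment} with a
#'   \code{counts} assay and per-sample metadata.
#' @slot orthologMap data.frame with columns \code{cho_gene_id},
#'   \code{human_gene_id}.
#' @slot annotation data.frame with columns \code{gene_id},
#'   \code{group}, \code{subgroup}.
#' @slot geneSets named list of character vectors (gene sets).
#' @slot titers data.frame: \code{r_protein}, \code{cell_line},
#'   \code{titer_ug_ml}, \code{detected}.
#' @slot ptm data.frame: \code{r_protein}, \code{length_aa},
#'   \code{n_glyc_sites}, \code{o_glyc_sites}, \code{disulfide_bonds},
#'   \code{gpi_anchor}.
#' @slot truth list recording planted effects (outlier genes, activation
#'   LFCs, titer-linked genes, enzyme scores, regression coefficients).
#' @slot config the [SimConfig] used.
#'
#' @exportClass SyntheticBundle
setClass("SyntheticBundle", representation(
    countsCHO = "SummarizedExperiment",
    countsHEK = "SummarizedExperiment",
    orthologMap = "data.frame",
    annotation = "data.frame",
    geneSets = "list",
    titers = "data.frame",
    ptm = "data.frame",
    truth = "list",
    config = "SimConfig"
))

setValidity("SyntheticBundle", function(object) {
    msg <- character()
    ann <- object@annotation$gene_id
    for (se in list(object@countsCHO, object@countsHEK)) {
        g <- rownames(se)
        if (!all(g %in% ann))
            msg <- c(msg, "all count genes must appear in the functional annotation")
    }
    if (length(object@truth$outlierGenes) &&
        !all(object@truth$outlierGenes %in% object@geneSets[["secretory"]]))
        msg <- c(msg, "planted outlier genes must be secretory genes")
    if (any(object@titers$titer_ug_ml < 0))
        msg <- c(msg, "titers must be >= 0")
    if (length(msg)) msg else TRUE
})

#' Differential-expression result table
#'
#' Per-gene results of the negative-binomial Wald test, in the style of
#' a results \code{DataFrame}: normalized base mean, raw and shrunken
#' log2 fold change, standard error, Wald statistic, p-value and
#' BH-adjusted p-value. Row names are gene identifiers; the contrast,
#' design and pseudocount policy are recorded in \code{metadata()}.
#'
#' @exportClass DEResult
setClass("DEResult", contains = "DFrame")

#' Gene-set enrichment result
#'
#' Result of the running-sum enrichment statistic for one gene set:
#' enrichment score (ES), permutation-normalized enrichment score (NES)
#' and the permutation p-value.
#'
#' @slot setName character, the gene-set name.
#' @slot ES enrichment score in \eqn{[-1, 1]}.
#' @slot NES normalized enrichment score (same sign as ES).
#' @slot pPerm permutation p-value in \eqn{(0, 1]}.
#' @slot nPerm number of permutations.
#' @slot seed seed used for the permutation null.
#' @slot flag character, e.g. noting that no same-sign permutations
#'   occurred.
#'
#' @exportClass EnrichmentResult
setClass("EnrichmentResult", representation(
    setName = "character", ES = "numeric", NES = "numeric",
    pPerm = "numeric", nPerm = "integer", seed = "integer",
    flag = "character"))

setValidity("EnrichmentResult", function(object) {
    msg <- character()
    if (abs(object@ES) > 1 + 1e-12)
        msg <- c(msg, "ES must lie in [-1, 1]")
    if (length(object@NES) && !is.na(object@NES) && object@NES != 0 &&
        sign(object@NES) != sign(object@ES))
        msg <- c(msg, "NES must have the sign of ES")
    if (object@pPerm <= 0 || object@pPerm > 1)
        msg <- c(msg, "pPerm must be in (0, 1]")
    if (length(msg)) msg else TRUE
})

#' Posterior of the titer-improvement interaction regression
#'
#' MCMC draws for the Bayesian linear model of titer log2 fold change on
#' PTM index, enzyme-expression score and their interaction, with
#' residual scale sigma.
#'
#' @slot draws numeric matrix, post-warmup draws x 5 columns
#'   \code{(a, bPTM, bEnz, bInt, sigma)}.
#' @slot acceptanceRate per-parameter Metropolis acceptance rates.
#' @slot rhat split-Rhat per parameter.
#' @slot seed integer seed.
#' @slot priors list of prior settings (a_sd, b_sd, sigma_rate).
#' @slot nWarmup warmup iterations discarded.
#'
#' @exportClass RegressionPosterior
setClass("RegressionPosterior", representation(
    draws = "matrix", acceptanceRate = "numeric", rhat = "numeric",
    seed = "integer", priors = "list", nWarmup = "integer"))

setValidity("RegressionPosterior", function(object) {
    msg <- character()
    if (ncol(object@draws) != 5L ||
        !identical(colnames(object@draws), c("a", "bPTM", "bEnz", "bInt", "sigma")))
        msg <- c(msg, "draws must have columns (a, bPTM, bEnz, bInt, sigma)")
    else if (any(object@draws[, "sigma"] <= 0))
        msg <- c(msg, "sigma draws must be positive")
    if (length(msg)) msg else TRUE
})

#' @describeIn SimConfig-class compact display
#' @param object a \code{SimConfig}
#' @export
setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes (",
        object@nSecretoryGenes, "secretory,", object@nMitoGenes, "mito ),",
        object@nRProteins, "r-proteins,",
        object@replicatesPerCondition, "replicates/condition\n")
    cat("  dispersion trend a0 =", object@dispersionTrend[1],
        ", a1 =", object@dispersionTrend[2],
        "; planted outliers:", object@nPlantedOutliers,
        "at LFC", object@outlierLFC, "\n")
    cat("  seed:", object@seed, "\n")
})

#' @describeIn SyntheticBundle-class compact display
#' @param object a \code{SyntheticBundle}
#' @export
setMethod("show", "SyntheticBundle", function(object) {
    cat("SyntheticBundle\n")
    cat("  CHO   :", nrow(object@countsCHO), "genes x",
        ncol(object@countsCHO), "samples\n")
    cat("  HEK293:", nrow(object@countsHEK), "genes x",
        ncol(object@countsHEK), "samples\n")
    cat("  ortholog map:", nrow(object@orthologMap), "pairs;",
        length(object@geneSets), "gene sets;",
        nrow(object@titers), "titer rows\n")
})

#' @describeIn EnrichmentResult-class compact display
#' @param object an \code{EnrichmentResult}
#' @export
setMethod("show", "EnrichmentResult", function(object) {
    cat(sprintf("EnrichmentResult '%s': ES = %.4f, NES = %.4f, p = %.4g (%d permutations)\n",
        object@setName, object@ES, object@NES, object@pPerm, object@nPerm))
    if (length(object@flag) && nzchar(object@flag))
        cat("  flag:", object@flag, "\n")
})

#' @describeIn RegressionPosterior-class compact display
#' @param object a \code{RegressionPosterior}
#' @export
setMethod("show", "RegressionPosterior", function(object) {
    cat("RegressionPosterior:", nrow(object@draws), "post-warmup draws\n")
    m <- colMeans(object@draws)
    cat("  posterior means:",
        paste(sprintf("%s = %.3f", names(m), m), collapse = ", "), "\n")
    cat("  split-Rhat max:", round(max(object@rhat), 4), "\n")
})
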