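#' Construct a simulation configuration
#'
#' Builds a validated [SimConfig-class] describing the synthetic
#' two-host expression study: a shared (human) gene universe observed in
#' HEK293 and, through a partial ortholog map, in CHO; producer samples
#' for a panel of recombinant proteins plus empty-vector controls;
#' negative-binomial counts with a DESeq2-style dispersion trend
#' \eqn{\alpha(\mu) = a_0 + a_1/\mu}; planted extreme secretory outliers
#' (silent in CHO, high in HEK293); a mitochondrial library-mass target;
#' a transgene transcript in producer samples; and titers drawn from the
#' Bayesian interaction model of titer improvement.
#'
#' Defaults mirror the study design: a 24-protein panel expressed in
#' duplicate per host with empty-vector controls, mitochondrial genes
#' near 10\% of library mass, and around 20 extreme secretory outliers.
#'
#' @param nGenes,nSecretoryGenes,nMitoGenes gene universe sizes.
#' @param nRProteins size of the recombinant-protein panel.
#' @param replicatesPerCondition replicates per producer group and per
#'   control group (must be >= 2).
#' @param baselineMeanLogRange natural-log range of baseline NB means.
#' @param dispersionTrend \code{c(a0, a1)} of \eqn{\alpha(\mu) = a0 + a1/\mu}.
#' @param celllineEffectSD sd (log2) of per-gene between-host effects.
#' @param activationEffectSD named numeric \code{c(CHO=, HEK293=)}, sd
#'   (log2) of producer-induced activation on activated genes.
#' @param nActivatedGenes number of genes with nonzero activation.
#' @param nPlantedOutliers,outlierLFC planted extreme outliers and their
#'   between-host log2 fold change.
#' @param orthologCoverage fraction of CHO genes with a human ortholog.
#' @param manyToOneFraction fraction of mapped CHO genes sharing a human
#'   target (exercises the aggregation policy).
#' @param mitoFractionTarget target mitochondrial fraction of library mass.
#' @param transgeneShare fraction of producer library mass on the
#'   transgene transcript.
#' @param nTiterLinkedGenes genes whose per-r-protein activation
#'   difference between hosts tracks the titer log2 fold change.
#' @param regressionTruth named \code{c(a, bPTM, bEnz, bInt, sigma)}
#'   generative coefficients of the titer model. The defaults produce
#'   titer log2 fold changes with a spread of roughly two log2 units, a
#'   positive overall shift (about a third of the panel more than
#'   two-fold improved in HEK293) and the glycosylation sign-flip
#'   (enzyme expression helping heavily glycosylated, hurting
#'   non-glycosylated products).
#' @param seed integer master seed; all generators are pure functions of
#'   (config, seed).
#'
#' @return a [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nGenes = 500, nRProteins = 6, seed = 7)
#' cfg
#' @export
simConfig <- function(nGenes = 2000L,
                      nSecretoryGenes = 200L,
                      nMitoGenes = 40L,
                      nRProteins = 24L,
                      replicatesPerCondition = 2L,
                      baselineMeanLogRange = c(1, 8),
                      dispersionTrend = c(0.05, 2),
                      celllineEffectSD = 1,
                      activationEffectSD = c(CHO = 0.3, HEK293 = 0.3),
                      nActivatedGenes = 200L,
                      nPlantedOutliers = 20L,
                      outlierLFC = 10,
                      orthologCoverage = 0.9,
                      manyToOneFraction = 0.05,
                      mitoFractionTarget = 0.10,
                      transgeneShare = 0.02,
                      nTiterLinkedGenes = 1L,
                      regressionTruth = c(a = 0.5, bPTM = 0, bEnz = -0.3,
                                          bInt = 2, sigma = 1.5),
                      seed = 1L) {
    new("SimConfig",
        nGenes = as.integer(nGenes),
        nSecretoryGenes = as.integer(nSecretoryGenes),
        nMitoGenes = as.integer(nMitoGenes),
        nRProteins = as.integer(nRProteins),
        replicatesPerCondition = as.integer(replicatesPerCondition),
        baselineMeanLogRange = as.numeric(baselineMeanLogRange),
        dispersionTrend = as.numeric(dispersionTrend),
        celllineEffectSD = as.numeric(celllineEffectSD),
        activationEffectSD = activationEffectSD,
        nActivatedGenes = as.integer(nActivatedGenes),
        nPlantedOutliers = as.integer(nPlantedOutliers),
        outlierLFC = as.numeric(outlierLFC),
        orthologCoverage = as.numeric(orthologCoverage),
        manyToOneFraction = as.numeric(manyToOneFraction),
        mitoFractionTarget = as.numeric(mitoFractionTarget),
        transgeneShare = as.numeric(transgeneShare),
        nTiterLinkedGenes = as.integer(nTiterLinkedGenes),
        regressionTruth = regressionTruth,
        seed = as.integer(seed))
}

## The 11 secretory-pathway subsystems used for subgroup annotation.
.SECRETORY_SUBSYSTEMS <- c(
    "Translocation", "Protein folding", "ER glycosylation",
    "Golgi glycosylation", "ERAD", "UPR", "COPI", "COPII",
    "Clathrin vesicles", "Trafficking", "Secretion")

.OTHER_GROUPS <- c("translation", "transcription", "metabolism",
                   "biosynthesis", "signaling", "other")

#' Simulate a negative-binomial count matrix
#'
#' Draws integer counts with \eqn{K_{gs} \sim NB(\mu_{gs}, \alpha_g)}
#' under the mean/dispersion parameterization
#' \eqn{Var = \mu + \alpha \mu^2}. \code{dispersion} of 0 gives Poisson
#' counts.
#'
#' @param mu matrix of expected counts (genes x samples).
#' @param dispersion per-gene dispersion, recycled across samples, or a
#'   matrix conformable with \code{mu}.
#' @param seed integer seed.
#' @return integer matrix with the dimnames of \code{mu}.
#' @export
simulateNBCounts <- function(mu, dispersion, seed) {
    stopifnot(is.matrix(mu), all(mu >= 0), all(dispersion >= 0))
    alpha <- if (is.matrix(dispersion)) dispersion
             else matrix(dispersion, nrow = nrow(mu), ncol = ncol(mu))
    size <- ifelse(alpha > 0, 1 / alpha, Inf)
    withr::with_seed(as.integer(seed), {
        k <- rnbinom(length(mu), mu = as.vector(mu), size = as.vector(size))
    })
    out <- matrix(as.integer(k), nrow = nrow(mu), dimnames = dimnames(mu))
    out
}

#' Generate annotations, gene sets, ortholog map and PTM table
#'
#' Deterministically (given the config seed) creates the functional
#' annotation partitioning all genes into Proteomaps-style groups with
#' 11 secretory subsystems as subgroups, a gene-set collection
#' (secretory pathway, its subsystems, mitochondrial genes, and the
#' glycosyltransferase / disulfide-enzyme sets used by the PTM model), a
#' partial CHO-to-human ortholog map with a configurable many-to-one
#' fraction, and a PTM annotation table for the r-protein panel.
#'
#' All secretory and mitochondrial genes are guaranteed an ortholog (the
#' cross-host secretory analysis needs them); coverage is completed by a
#' random sample of the remaining genes.
#'
#' @param config a [SimConfig-class].
#' @return list with elements \code{annotation} (data.frame gene_id /
#'   group / subgroup, covering human and CHO identifiers), \code{geneSets}
#'   (named list), \code{orthologMap} (data.frame cho_gene_id /
#'   human_gene_id) and \code{ptm} (data.frame).
#' @export
generateAnnotations <- function(config) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    n <- config@nGenes
    genes <- sprintf("g%05d", seq_len(n))
    choGenes <- paste0("cho_", genes)

    secIdx <- seq_len(config@nSecretoryGenes)
    mitoIdx <- config@nSecretoryGenes + seq_len(config@nMitoGenes)
    restIdx <- setdiff(seq_len(n), c(secIdx, mitoIdx))

    group <- character(n)
    subgroup <- character(n)
    group[secIdx] <- "secretory"
    subgroup[secIdx] <- rep_len(.SECRETORY_SUBSYSTEMS, length(secIdx))
    group[mitoIdx] <- "mitochondrial"
    subgroup[mitoIdx] <- "mitochondrial"
    withr::with_seed(config@seed + 11L, {
        group[restIdx] <- sample(rep_len(.OTHER_GROUPS, length(restIdx)))
    })
    subgroup[restIdx] <- group[restIdx]

    annotation <- data.frame(
        gene_id = c(genes, choGenes, "transgene", "cho_transgene"),
        group = c(group, group, "transgene", "transgene"),
        subgroup = c(subgroup, subgroup, "transgene", "transgene"),
        stringsAsFactors = FALSE)

    ## ortholog map: secretory + mito always mapped, remainder sampled
    nMapped <- max(length(secIdx) + length(mitoIdx),
                   ceiling(config@orthologCoverage * n))
    withr::with_seed(config@seed + 12L, {
        extra <- sample(restIdx, min(nMapped, n) - length(secIdx) - length(mitoIdx))
        mappedIdx <- sort(c(secIdx, mitoIdx, extra))
        target <- genes[mappedIdx]
        ## many-to-one: a fraction of mapped non-secretory genes point at the
        ## human target of another mapped gene
        m2o <- intersect(mappedIdx, restIdx)
        nM2o <- floor(config@manyToOneFraction * length(mappedIdx))
        if (nM2o > 0 && length(m2o) >= 2 * nM2o) {
            pick <- sample(m2o, nM2o)
            ## donors restricted to non-secretory genes so that the
            ## aggregation policy never folds unrelated counts into the
            ## secretory-pathway analysis
            donors <- sample(setdiff(m2o, pick), nM2o, replace = TRUE)
            target[match(pick, mappedIdx)] <- genes[donors]
        }
    })
    orthologMap <- unique(data.frame(
        cho_gene_id = choGenes[mappedIdx],
        human_gene_id = target,
        stringsAsFactors = FALSE))

    ## gene sets
    secGenes <- genes[secIdx]
    geneSets <- list(secretory = secGenes,
                     mitochondrial = genes[mitoIdx])
    for (ss in .SECRETORY_SUBSYSTEMS)
        geneSets[[paste0("secretory:", ss)]] <-
            secGenes[subgroup[secIdx] == ss]
    geneSets[["glycosyltransferases"]] <- secGenes[
        subgroup[secIdx] %in% c("ER glycosylation", "Golgi glycosylation")]
    geneSets[["disulfide_enzymes"]] <- secGenes[
        subgroup[secIdx] == "Protein folding"]
    geneSets <- geneSets[vapply(geneSets, length, 1L) > 0L]

    ## PTM annotation table. Glycosylation site densities span the whole
    ## regime the conditional-effect analysis covers: non-glycosylated,
    ## lightly N-glycosylated, and heavily O-glycosylated (mucin-type)
    ## proteins with site densities up to ~0.5 per residue.
    nr <- config@nRProteins
    withr::with_seed(config@seed + 13L, {
        lengthAA <- as.integer(round(runif(nr, 100, 1000)))
        regime <- sample(c("none", "light", "heavy"), nr, replace = TRUE,
                         prob = c(0.35, 0.35, 0.30))
        nGlyc <- integer(nr); oGlyc <- integer(nr)
        light <- regime == "light"
        nGlyc[light] <- as.integer(1 + stats::rpois(sum(light), 3))
        oGlyc[light] <- as.integer(stats::rpois(sum(light), 1))
        heavy <- regime == "heavy"
        dens <- runif(sum(heavy), 0.3, 0.55)
        oGlyc[heavy] <- as.integer(round(dens * lengthAA[heavy]))
        nGlyc[heavy] <- as.integer(stats::rpois(sum(heavy), 2))
        ss <- as.integer(stats::rpois(nr, 5))
        gpi <- as.integer(rbinom(nr, 1, 0.1))
    })
    if (nr >= 2L && all(nGlyc + oGlyc > 0L)) {
        ## keep at least one non-glycosylated protein in the panel
        i0 <- which.min(nGlyc + oGlyc)
        nGlyc[i0] <- 0L; oGlyc[i0] <- 0L
    }
    ptm <- data.frame(
        r_protein = sprintf("P%02d", seq_len(nr)),
        length_aa = lengthAA,
        n_glyc_sites = nGlyc,
        o_glyc_sites = oGlyc,
        disulfide_bonds = ss,
        gpi_anchor = gpi,
        stringsAsFactors = FALSE)

    list(annotation = annotation, geneSets = geneSets,
         orthologMap = orthologMap, ptm = ptm)
}

## expected per-gene NB means for one host, before activation effects
## returns list(mu = named vector on human ids, outliers, delta)
.hostBaseMeans <- function(config) {
    n <- config@nGenes
    genes <- sprintf("g%05d", seq_len(n))
    secGenes <- genes[seq_len(config@nSecretoryGenes)]
    mitoGenes <- genes[config@nSecretoryGenes + seq_len(config@nMitoGenes)]
    withr::with_seed(config@seed + 21L, {
        mu0 <- exp(runif(n, config@baselineMeanLogRange[1],
                         config@baselineMeanLogRange[2]))
        delta <- rnorm(n, 0, config@celllineEffectSD)   # log2 HEK - CHO
        outliers <- sample(secGenes, min(config@nPlantedOutliers,
                                         length(secGenes)))
    })
    names(mu0) <- names(delta) <- genes
    muCHO <- mu0 * 2^(-delta / 2)
    muHEK <- mu0 * 2^(+delta / 2)
    ## planted extreme outliers: essentially silent in CHO, high in HEK293
    muCHO[outliers] <- 0.5
    muHEK[outliers] <- 0.5 * 2^config@outlierLFC
    delta[outliers] <- config@outlierLFC
    ## rescale mitochondrial means so their expected library share hits the
    ## configured target in each host
    for (nm in c("muCHO", "muHEK")) {
        mu <- get(nm)
        m <- sum(mu[mitoGenes]); rest <- sum(mu) - m
        s <- config@mitoFractionTarget * rest /
            ((1 - config@mitoFractionTarget) * m)
        mu[mitoGenes] <- mu[mitoGenes] * s
        assign(nm, mu)
    }
    list(muCHO = muCHO, muHEK = muHEK, delta = delta, outliers = outliers,
         genes = genes, mitoGenes = mitoGenes)
}

#' Generate synthetic count matrices for both hosts
#'
#' Draws negative-binomial counts for CHO and HEK293 samples covering
#' every (r-protein, host) producer group plus empty-vector controls.
#' Per-gene baseline means are shared between hosts up to a log2
#' between-host effect; planted outliers get the configured extreme
#' between-host LFC; activated genes respond to transgene expression
#' with host-specific log2 activation effects; mitochondrial genes
#' jointly receive about \code{mitoFractionTarget} of library mass; and
#' a transgene transcript carries \code{transgeneShare} of producer
#' library mass. Identical config (and seed) gives bit-identical output.
#'
#' @param config a [SimConfig-class].
#' @param titerLFC optional named per-r-protein titer log2 fold change;
#'   when supplied, \code{nTiterLinkedGenes} genes receive per-r-protein
#'   activation differences between hosts tracking these values (used by
#'   [generateBundle()] to plant the activation/titer correlation).
#' @return list with \code{countsCHO} and \code{countsHEK}
#'   (\linkS4class{SummarizedExperiment}s with a \code{counts} assay and
#'   the sample sheet as \code{colData}) and \code{truth} (planted
#'   effects).
#' @export
generateCounts <- function(config, titerLFC = NULL) {
    stopifnot(is(config, "SimConfig"))
    validObject(config)
    base <- .hostBaseMeans(config)
    genes <- base$genes
    n <- length(genes)
    a0 <- config@dispersionTrend[1]; a1 <- config@dispersionTrend[2]
    reps <- config@replicatesPerCondition
    rproteins <- sprintf("P%02d", seq_len(config@nRProteins))

    ## activation truth: genes responding to transgene expression are
    ## drawn half from the secretory pathway, half from the rest of the
    ## transcriptome — producer-induced activation concentrates in the
    ## secretory machinery
    secGenes <- genes[seq_len(config@nSecretoryGenes)]
    withr::with_seed(config@seed + 22L, {
        nAct <- min(config@nActivatedGenes, n)
        nActSec <- min(floor(nAct / 2), length(secGenes))
        activated <- c(sample(secGenes, nActSec),
                       sample(setdiff(genes, secGenes), nAct - nActSec))
        actCHO <- setNames(numeric(n), genes)
        actHEK <- setNames(numeric(n), genes)
        actCHO[activated] <- rnorm(length(activated), 0,
                                   config@activationEffectSD[["CHO"]])
        actHEK[activated] <- rnorm(length(activated), 0,
                                   config@activationEffectSD[["HEK293"]])
        linked <- character(0)
        dLinked <- NULL
        if (!is.null(titerLFC) && config@nTiterLinkedGenes > 0L) {
            pool <- setdiff(genes, base$outliers)
            linked <- sample(pool, config@nTiterLinkedGenes)
            dLinked <- matrix(
                rep(titerLFC[rproteins], each = length(linked)) +
                    rnorm(length(linked) * length(rproteins), 0, 0.1),
                nrow = length(linked),
                dimnames = list(linked, rproteins))
        }
    })

    makeHost <- function(line, mu, act, seedOff) {
        sampleTable <- rbind(
            data.frame(r_protein = rep(rproteins, each = reps),
                       condition = "producer",
                       replicate = rep(seq_len(reps), length(rproteins))),
            data.frame(r_protein = "none", condition = "control",
                       replicate = seq_len(reps)))
        sampleTable$cell_line <- line
        sampleTable$sample_id <- ifelse(
            sampleTable$condition == "producer",
            sprintf("%s_%s_r%d", line, sampleTable$r_protein,
                    sampleTable$replicate),
            sprintf("%s_ctrl_r%d", line, sampleTable$replicate))
        m <- nrow(sampleTable)
        muMat <- matrix(mu, nrow = n, ncol = m,
                        dimnames = list(genes, sampleTable$sample_id))
        prod <- sampleTable$condition == "producer"
        muMat[, prod] <- muMat[, prod] * 2^act
        if (length(linked)) {
            sgn <- if (line == "CHO") -0.5 else +0.5
            for (j in which(prod)) {
                p <- sampleTable$r_protein[j]
                muMat[linked, j] <- muMat[linked, j] *
                    2^(sgn * dLinked[, p])
            }
        }
        ## transgene transcript in producers only
        tgMean <- ifelse(prod,
                         config@transgeneShare / (1 - config@transgeneShare) *
                             colSums(muMat), 0)
        muMat <- rbind(muMat, transgene = tgMean)
        ## per-sample library depth variation
        withr::with_seed(config@seed + seedOff + 1L, {
            depth <- exp(rnorm(m, 0, 0.15))
        })
        muMat <- sweep(muMat, 2, depth, `*`)
        alpha <- a0 + a1 / pmax(c(mu, mean(tgMean[prod])), 1e-8)
        counts <- simulateNBCounts(muMat, alpha,
                                   seed = config@seed + seedOff)
        if (line == "CHO")
            rownames(counts) <- c(paste0("cho_", genes), "cho_transgene")
        SummarizedExperiment(
            assays = list(counts = counts),
            colData = DataFrame(sampleTable[, c("sample_id", "cell_line",
                                                "condition", "r_protein",
                                                "replicate")],
                                row.names = sampleTable$sample_id))
    }

    seCHO <- makeHost("CHO", base$muCHO, actCHO, 100L)
    seHEK <- makeHost("HEK293", base$muHEK, actHEK, 200L)

    truth <- list(
        outlierGenes = base$outliers,
        celllineLFC = base$delta,
        activation = list(CHO = actCHO, HEK293 = actHEK),
        titerLinked = list(genes = linked, d = dLinked),
        mitoGenes = base$mitoGenes,
        dispersionTrend = config@dispersionTrend,
        baseMeans = list(CHO = base$muCHO, HEK293 = base$muHEK))
    list(countsCHO = seCHO, countsHEK = seHEK, truth = truth)
}

#' Generate titers from the interaction model of titer improvement
#'
#' Draws, for each r-protein, a titer log2 fold change
#' \eqn{LFC_i \sim Normal(\mu_i, \sigma)} with
#' \eqn{\mu_i = a + b_{PTM} x_i + b_{Enz} z_i + b_{Int} x_i z_i}, where
#' \eqn{x_i} is the glycosylation PTM index and \eqn{z_i} the enzyme
#' expression score, then anchors a CHO titer (log-normal, arbitrary
#' \eqn{\mu g/ml} scale) and solves the HEK293 titer so that
#' \eqn{\log_2((HEK+1)/(CHO+1))} equals the drawn LFC exactly. Titers
#' are always non-negative: when the implied HEK293 titer would be
#' negative, the HEK293 titer is set to 0 and the CHO titer adjusted to
#' preserve the drawn LFC.
#'
#' @param ptm PTM annotation table (see [generateAnnotations()]).
#' @param enzymeScores named numeric, per r-protein enzyme-expression
#'   score in \eqn{[-1, 1]}.
#' @param truth named numeric \code{c(a, bPTM, bEnz, bInt, sigma)}.
#' @param seed integer seed.
#' @return data.frame with columns \code{r_protein}, \code{cell_line},
#'   \code{titer_ug_ml}, \code{detected}, plus attribute \code{"lfc"}
#'   holding the drawn log2 fold changes.
#' @export
generateTiters <- function(ptm, enzymeScores, truth, seed) {
    stopifnot(all(c("a", "bPTM", "bEnz", "bInt", "sigma") %in% names(truth)),
              all(is.finite(truth)))
    if (truth[["sigma"]] <= 0)
        stop("'sigma' must be > 0")
    idx <- (ptm$n_glyc_sites + ptm$o_glyc_sites) / ptm$length_aa
    z <- enzymeScores[ptm$r_protein]
    mu <- truth[["a"]] + truth[["bPTM"]] * idx + truth[["bEnz"]] * z +
        truth[["bInt"]] * idx * z
    withr::with_seed(as.integer(seed), {
        lfc <- rnorm(length(mu), mu, truth[["sigma"]])
        cho <- rlnorm(length(mu), meanlog = log(5), sdlog = 1)
    })
    hek <- (cho + 1) * 2^lfc - 1
    neg <- hek < 0
    if (any(neg)) {   # keep the drawn LFC exact while keeping titers >= 0
        hek[neg] <- 0
        cho[neg] <- 2^(-lfc[neg]) - 1
    }
    out <- data.frame(
        r_protein = rep(ptm$r_protein, 2L),
        cell_line = rep(c("CHO", "HEK293"), each = nrow(ptm)),
        titer_ug_ml = c(cho, hek),
        detected = c(cho, hek) > 0,
        stringsAsFactors = FALSE)
    attr(out, "lfc") <- setNames(lfc, ptm$r_protein)
    out
}

#' Generate the full synthetic study bundle
#'
#' Orchestrates [generateAnnotations()], [generateTiters()] and
#' [generateCounts()] into one [SyntheticBundle-class]: annotations and
#' PTM table first, then per-r-protein enzyme-expression truth and
#' titers from the interaction model, then counts with titer-linked
#' activation planted so the downstream activation/titer correlation is
#' recoverable.
#'
#' @param config a [SimConfig-class].
#' @return a [SyntheticBundle-class].
#' @examples
#' b <- generateBundle(simConfig(nGenes = 300, nSecretoryGenes = 60,
#'                               nMitoGenes = 12, nRProteins = 4, seed = 1))
#' b
#' @export
generateBundle <- function(config) {
    ann <- generateAnnotations(config)
    withr::with_seed(config@seed + 31L, {
        enzymeScores <- setNames(runif(config@nRProteins, -0.8, 0.8),
                                 ann$ptm$r_protein)
    })
    titers <- generateTiters(ann$ptm, enzymeScores,
                             truth = config@regressionTruth,
                             seed = config@seed + 32L)
    titerLFC <- attr(titers, "lfc")
    cnt <- generateCounts(config, titerLFC = titerLFC)
    truth <- c(cnt$truth,
               list(enzymeScores = enzymeScores,
                    titerLFC = titerLFC,
                    regression = config@regressionTruth))
    new("SyntheticBundle",
        countsCHO = cnt$countsCHO,
        countsHEK = cnt$countsHEK,
        orthologMap = ann$orthologMap,
        annotation = ann$annotation,
        geneSets = ann$geneSets,
        titers = titers,
        ptm = ann$ptm,
        truth = truth,
        config = config)
}
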