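## end-to-end report: simulate -> usage -> DE (three contrasts) ->
## enrichment -> outliers -> activation/titer correlation -> PTM model

.stage <- function(name, manifest, expr, quiet = FALSE) {
    t0 <- Sys.time()
    if (!quiet) message("[hostcomp] stage '", name, "' ...")
    out <- tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             " (earlier outputs are preserved)", call. = FALSE))
    if (!quiet)
        message(sprintf("[hostcomp] stage '%s' done (%.1fs)", name,
                        as.numeric(difftime(Sys.time(), t0, units = "secs"))))
    out
}

## descriptive per-r-protein log2 FC of normalized mean counts
## (pseudocount +1, the descriptive-ratio policy)
.perProteinLFC <- function(counts, sampleTable) {
    sf <- medianRatioSizeFactors(counts)
    q <- sweep(.countsMatrix(counts), 2, sf, `/`)
    st <- as.data.frame(sampleTable)
    rp <- setdiff(unique(st$r_protein), "none")
    out <- sapply(sort(rp), function(p) {
        hek <- st$cell_line == "HEK293" & st$r_protein == p
        cho <- st$cell_line == "CHO" & st$r_protein == p
        log2((rowMeans(q[, hek, drop = FALSE]) + 1) /
             (rowMeans(q[, cho, drop = FALSE]) + 1))
    })
    rownames(out) <- rownames(q)
    out
}

#' Run the full host-comparison pipeline on a synthetic study
#'
#' Chains every stage of the analysis on data generated from a
#' [SimConfig-class]: synthetic inputs, transcriptome usage and
#' mitochondrial QC, the three differential-expression contrasts
#' (between hosts; producer-vs-control activation within each host),
#' secretory-pathway gene-set enrichment of the between-host ranking,
#' outlier classification and activation-disparity ranking with
#' secretory over-representation, the per-gene activation/titer
#' correlation, and the Bayesian PTM-interaction model of titer
#' improvement. All tabular outputs and a JSON manifest (parameters,
#' seeds, file hashes) are written to \code{outDir}; deterministic
#' stages reproduce identical hashes on rerun.
#'
#' @param config a [SimConfig-class].
#' @param outDir output directory.
#' @param nPerm permutations for the enrichment stage.
#' @param mcmcDraws,mcmcWarmup MCMC settings of the PTM model.
#' @param topK size of the activation-disparity top list.
#' @param bandHalfwidth,lowThresh,highThresh outlier-classification
#'   thresholds (see [classifyOutlierGroups()]).
#' @param quiet suppress per-stage progress messages.
#' @return (invisibly) a list with the manifest and the in-memory stage
#'   results.
#' @export
runReport <- function(config = simConfig(), outDir,
                      nPerm = 200L, mcmcDraws = 2000L, mcmcWarmup = 1000L,
                      topK = 20L, bandHalfwidth = 2, lowThresh = 2,
                      highThresh = 6, quiet = FALSE) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(outDir, f)
    files <- character(0)
    addFile <- function(f) files <<- c(files, f)

    bundle <- .stage("simulate", quiet = quiet, expr = {
        b <- generateBundle(config)
        addFile(writeBundle(b, file.path(outDir, "inputs")))
        b
    })
    st <- rbind(as.data.frame(colData(choCounts(bundle))),
                as.data.frame(colData(hekCounts(bundle))))

    usage <- .stage("usage", quiet = quiet, expr = {
        res <- lapply(list(CHO = choCounts(bundle),
                           HEK293 = hekCounts(bundle)), function(se) {
            m <- .countsMatrix(se)
            lens <- setNames(rep(1000, nrow(m)), rownames(m))
            tpm <- computeTPM(m, lens)
            ann <- functionalAnnotation(bundle)
            list(usage = transcriptomeUsage(
                     tpm, ann, exclude = c("transgene", "cho_transgene")),
                 mito = mitoFraction(
                     tpm, c(geneSets(bundle)$mitochondrial,
                            paste0("cho_", geneSets(bundle)$mitochondrial))))
        })
        u <- cbind(res$CHO$usage,
                   res$HEK293$usage[rownames(res$CHO$usage), ])
        write.table(data.frame(group = rownames(u), u, check.names = FALSE),
                    p("usage.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addFile(p("usage.tsv"))
        list(usage = u, mito = c(res$CHO$mito, res$HEK293$mito))
    })

    de <- .stage("de", quiet = quiet, expr = {
        ## between-host analyses use unambiguous 1:1 orthologs only;
        ## many-to-one summation would manufacture spurious extreme
        ## fold changes from unrelated baselines
        choMapped <- aggregateOrthologs(choCounts(bundle),
                                        orthologMap(bundle),
                                        policy = "drop_ambiguous")
        hek <- .countsMatrix(hekCounts(bundle))
        shared <- intersect(rownames(choMapped), rownames(hek))
        stCho <- as.data.frame(colData(choCounts(bundle)))
        stHek <- as.data.frame(colData(hekCounts(bundle)))
        combined <- cbind(choMapped[shared, ], hek[shared, ])
        stAll <- rbind(stCho, stHek)
        prod <- stAll$condition == "producer"
        stProd <- stAll[prod, ]
        stProd$cell_line <- factor(stProd$cell_line,
                                   levels = c("CHO", "HEK293"))
        deCell <- runDiffExp(combined[, prod], stProd, ~cell_line,
                             "cell_lineHEK293")
        actCho <- differentialActivation(choMapped, stCho, "CHO")
        actHek <- differentialActivation(hek, stHek, "HEK293")
        for (nm in c("deCell", "actCho", "actHek")) {
            d <- get(nm)
            write.table(data.frame(gene_id = rownames(d),
                                   as.data.frame(d)),
                        p(paste0(nm, ".tsv")), sep = "\t", quote = FALSE,
                        row.names = FALSE)
            addFile(p(paste0(nm, ".tsv")))
        }
        list(deCell = deCell, actCho = actCho, actHek = actHek,
             combined = combined, stAll = stAll, shared = shared)
    })

    enrich <- .stage("enrich", quiet = quiet, expr = {
        ranking <- setNames(de$deCell$lfc_shrunk, rownames(de$deCell))
        ranking <- ranking[is.finite(ranking)]
        subsystems <- grep("^secretory:", names(geneSets(bundle)),
                           value = TRUE)
        rows <- lapply(subsystems, function(s) {
            gs <- intersect(geneSets(bundle)[[s]], names(ranking))
            if (length(gs) < 2) return(NULL)
            r <- nesAndPvalue(ranking, gs, nPerm = nPerm,
                              seed = config@seed + 41L, setName = s)
            data.frame(set = s, ES = enrichScore(r),
                       NES = normalizedScore(r), p_perm = permPvalue(r))
        })
        tab <- do.call(rbind, rows)
        write.table(tab, p("enrichment.tsv"), sep = "\t", quote = FALSE,
                    row.names = FALSE)
        addFile(p("enrichment.tsv"))
        tab
    })

    outliers <- .stage("outliers", quiet = quiet, expr = {
        sf <- medianRatioSizeFactors(de$combined)
        dsp <- estimateDispersionsNB(de$combined, sf)
        v <- vstTransform(de$combined, sf, dsp$trendCoef)
        prod <- de$stAll$condition == "producer"
        isHek <- de$stAll$cell_line == "HEK293"
        mCho <- rowMeans(v[, prod & !isHek, drop = FALSE])
        mHek <- rowMeans(v[, prod & isHek, drop = FALSE])
        cls <- classifyOutlierGroups(mCho, mHek, bandHalfwidth,
                                     lowThresh, highThresh)
        disp <- rankActivationDisparity(de$actCho, de$actHek, topK = topK)
        pEnrich <- topSetEnrichment(
            disp$gene_id,
            intersect(geneSets(bundle)$secretory, de$shared),
            de$shared)
        write.table(cls, p("outlier_classification.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        write.table(disp, p("activation_disparity.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        addFile(p("outlier_classification.tsv"))
        addFile(p("activation_disparity.tsv"))
        list(classification = cls, disparity = disp,
             enrichment_p = pEnrich, vst = v)
    })

    corr <- .stage("activation-corr", quiet = quiet, expr = {
        ia <- interactionActivation(de$combined, de$stAll)
        titers <- titerTable(bundle)
        w <- reshape(titers[, c("r_protein", "cell_line", "titer_ug_ml")],
                     idvar = "r_protein", timevar = "cell_line",
                     direction = "wide")
        titerLfc <- setNames(
            titerLog2FC(w$titer_ug_ml.HEK293, w$titer_ug_ml.CHO),
            w$r_protein)
        ac <- activationTiterCorrelation(ia$lfc, titerLfc)
        write.table(ac, p("activation_titer_correlation.tsv"), sep = "\t",
                    quote = FALSE, row.names = FALSE)
        addFile(p("activation_titer_correlation.tsv"))
        list(correlations = ac, interaction = ia, titerLfc = titerLfc)
    })

    ptmFit <- .stage("ptm-model", quiet = quiet, expr = {
        perProt <- .perProteinLFC(de$combined, de$stAll)
        glyco <- geneSets(bundle)$glycosyltransferases
        scores <- vapply(colnames(perProt), function(pn)
            enzymeExpressionScore(setNames(perProt[, pn],
                                           rownames(perProt)),
                                  glyco, rProtein = pn), numeric(1))
        ptm <- ptmTable(bundle)
        dat <- data.frame(
            lfc_titer = corr$titerLfc[ptm$r_protein],
            ptm_index = ptmIndex(ptm, "glycosylation"),
            enzyme_expr = scores[ptm$r_protein])
        post <- fitBayesianInteraction(
            dat, mcmc = list(nWarmup = mcmcWarmup, nDraws = mcmcDraws,
                             step = 0.2, seed = config@seed + 51L))
        smry <- posteriorSummary(post)
        write.csv(posteriorDraws(post), p("posterior_draws.csv"),
                  row.names = FALSE, quote = FALSE)
        write.csv(smry, p("posterior_summary.csv"), row.names = FALSE,
                  quote = FALSE)
        addFile(p("posterior_draws.csv"))
        addFile(p("posterior_summary.csv"))
        list(posterior = post, summary = smry, data = dat)
    })

    manifest <- list(
        package = "hostcomp",
        version = as.character(utils::packageVersion("hostcomp")),
        seed = config@seed,
        parameters = list(nPerm = nPerm, mcmcDraws = mcmcDraws,
                          mcmcWarmup = mcmcWarmup, topK = topK,
                          bandHalfwidth = bandHalfwidth,
                          lowThresh = lowThresh, highThresh = highThresh),
        stages = c("simulate", "usage", "de", "enrich", "outliers",
                   "activation-corr", "ptm-model"),
        files = as.list(setNames(unname(tools::md5sum(unlist(files))),
                                 basename(unlist(files)))))
    jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE)
    invisible(list(manifest = manifest, bundle = bundle, usage = usage,
                   de = de, enrichment = enrich, outliers = outliers,
                   correlation = corr, ptm = ptmFit))
}
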