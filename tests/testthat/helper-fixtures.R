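# shared small fixtures, built once per test run

smallConfig <- function(seed = 3, ...) {
    simConfig(nGenes = 400, nSecretoryGenes = 80, nMitoGenes = 16,
              nRProteins = 6, seed = seed, ...)
}

# memoized small bundle used by several files
.bundleCache <- new.env()
smallBundle <- function() {
    if (is.null(.bundleCache$b))
        .bundleCache$b <- generateBundle(smallConfig())
    .bundleCache$b
}

# combined 1:1-ortholog count matrix + sample table for a bundle
combinedCounts <- function(bundle, policy = "drop_ambiguous") {
    cho <- suppressMessages(
        aggregateOrthologs(choCounts(bundle), orthologMap(bundle), policy))
    hek <- SummarizedExperiment::assay(hekCounts(bundle), "counts")
    shared <- intersect(rownames(cho), rownames(hek))
    st <- rbind(
        as.data.frame(SummarizedExperiment::colData(choCounts(bundle))),
        as.data.frame(SummarizedExperiment::colData(hekCounts(bundle))))
    list(counts = cbind(cho[shared, ], hek[shared, ]), samples = st,
         shared = shared)
}

# build a DEResult directly from summary columns (for unit tests of
# consumers that only need lfc/se)
makeDE <- function(genes, lfc, se = rep(0.1, length(lfc)),
                   lfcShrunk = lfc) {
    df <- S4Vectors::DataFrame(
        baseMean = rep(100, length(lfc)), lfc_raw = lfc,
        lfc_shrunk = lfcShrunk, se = se, stat = lfc / se,
        pvalue = 2 * pnorm(-abs(lfc / se)),
        padj = p.adjust(2 * pnorm(-abs(lfc / se)), "BH"),
        converged = TRUE, row.names = genes)
    new("DEResult", df)
}
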