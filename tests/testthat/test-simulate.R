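test_that("generators are pure functions of (config, seed)", {
    cfg <- smallConfig(seed = 11)
    b1 <- generateCounts(cfg)
    b2 <- generateCounts(cfg)
    expect_identical(SummarizedExperiment::assay(b1$countsCHO),
                     SummarizedExperiment::assay(b2$countsCHO))
    expect_identical(SummarizedExperiment::assay(b1$countsHEK),
                     SummarizedExperiment::assay(b2$countsHEK))
    b3 <- generateCounts(smallConfig(seed = 12))
    expect_false(identical(SummarizedExperiment::assay(b1$countsCHO),
                           SummarizedExperiment::assay(b3$countsCHO)))

    ptm <- generateAnnotations(cfg)$ptm
    enz <- setNames(runif(nrow(ptm), -0.5, 0.5), ptm$r_protein)
    tr <- c(a = 0, bPTM = 0, bEnz = 0, bInt = 1, sigma = 0.2)
    expect_identical(generateTiters(ptm, enz, tr, seed = 4),
                     generateTiters(ptm, enz, tr, seed = 4))
})

test_that("config validation rejects impossible designs", {
    expect_error(simConfig(replicatesPerCondition = 1), "replication")
    expect_error(simConfig(nSecretoryGenes = 300, nMitoGenes = 200,
                           nGenes = 400), "nGenes")
    expect_error(simConfig(activationEffectSD = c(CHO = -1, HEK293 = 1)),
                 ">= 0")
    expect_error(simConfig(mitoFractionTarget = 1.2), "mitoFractionTarget")
    expect_error(simConfig(orthologCoverage = 0), "orthologCoverage")
    expect_error(simConfig(regressionTruth = c(a = 0, bPTM = 0, bEnz = 0,
                                               bInt = 1, sigma = 0)),
                 "sigma")
})

test_that("count marginals follow the configured NB dispersion trend", {
    # chi-square GOF of per-gene variance against the trend-implied
    # variance: non-rejection at alpha = 0.01 for >= 95% of genes
    n <- 2000; m <- 60
    set.seed(21)
    mu <- exp(runif(n, 2, 7))
    a0 <- 0.05; a1 <- 2
    alpha <- a0 + a1 / mu
    muMat <- matrix(mu, n, m, dimnames = list(sprintf("g%d", 1:n), NULL))
    k <- simulateNBCounts(muMat, alpha, seed = 22)
    s2 <- apply(k, 1, var)
    v <- mu + alpha * mu^2
    # (m-1) s^2 / sigma^2 ~ approx chi^2_(m-1) for each gene
    stat <- (m - 1) * s2 / v
    pv <- pmin(pchisq(stat, m - 1), 1 - pchisq(stat, m - 1)) * 2
    expect_gt(mean(pv > 0.01), 0.95)
    # sample means track the configured means
    expect_lt(median(abs(rowMeans(k) - mu) / mu), 0.1)
})

test_that("mitochondrial genes receive about the configured library share", {
    b <- smallBundle()
    tpm <- computeTPM(SummarizedExperiment::assay(hekCounts(b)),
                      setNames(rep(1000, 401), rownames(hekCounts(b))))
    fr <- mitoFraction(tpm, geneSets(b)$mitochondrial)
    expect_true(all(fr > 0.07 & fr < 0.13))
    expect_gt(mean(fr), 0.07)
    expect_lt(mean(fr), 0.13)
})

test_that("titers follow the interaction model exactly and stay non-negative", {
    ptm <- generateAnnotations(smallConfig())$ptm
    enz <- setNames(seq(-0.8, 0.8, length.out = nrow(ptm)), ptm$r_protein)
    # degenerate noise: coefficients 0, sigma -> 0 gives equal titers
    tr0 <- c(a = 0, bPTM = 0, bEnz = 0, bInt = 0, sigma = 1e-12)
    t0 <- generateTiters(ptm, enz, tr0, seed = 1)
    w <- split(t0$titer_ug_ml, t0$cell_line)
    expect_equal(w$HEK293, w$CHO, tolerance = 1e-6)
    expect_equal(unname(attr(t0, "lfc")), rep(0, nrow(ptm)),
                 tolerance = 1e-9)
    # the recorded LFC is exactly log2((HEK+1)/(CHO+1)), titers >= 0
    tr <- c(a = -1, bPTM = 0.5, bEnz = -0.3, bInt = 2, sigma = 1.5)
    tt <- generateTiters(ptm, enz, tr, seed = 9)
    expect_true(all(tt$titer_ug_ml >= 0))
    wc <- tt$titer_ug_ml[tt$cell_line == "CHO"]
    wh <- tt$titer_ug_ml[tt$cell_line == "HEK293"]
    expect_equal(log2((wh + 1) / (wc + 1)), unname(attr(tt, "lfc")),
                 tolerance = 1e-12)
    expect_error(generateTiters(ptm, enz,
                                c(a = 0, bPTM = 0, bEnz = 0, bInt = 0,
                                  sigma = -1), seed = 1), "sigma")
})

test_that("annotations partition genes, subsystems are disjoint, coverage holds", {
    cfg <- smallConfig(seed = 7)
    ann <- generateAnnotations(cfg)
    genes <- sprintf("g%05d", seq_len(cfg@nGenes))
    # every gene annotated exactly once per id space
    expect_true(all(genes %in% ann$annotation$gene_id))
    expect_false(anyDuplicated(ann$annotation$gene_id) > 0)
    # secretory subsystem sets are disjoint and cover the secretory set
    ss <- ann$geneSets[grep("^secretory:", names(ann$geneSets))]
    all_ss <- unlist(ss)
    expect_false(anyDuplicated(all_ss) > 0)
    expect_setequal(all_ss, ann$geneSets$secretory)
    # ortholog map coverage
    covered <- length(unique(ann$orthologMap$cho_gene_id)) / cfg@nGenes
    expect_gte(covered, cfg@orthologCoverage - 0.01)
    # full coverage config: every CHO gene mapped
    annFull <- generateAnnotations(smallConfig(seed = 7,
                                               orthologCoverage = 1,
                                               manyToOneFraction = 0))
    expect_setequal(unique(annFull$orthologMap$cho_gene_id),
                    paste0("cho_", genes))
    # PTM table sanity: a non-glycosylated protein exists, counts valid
    expect_true(any(ann$ptm$n_glyc_sites + ann$ptm$o_glyc_sites == 0))
    expect_true(all(ann$ptm$length_aa > 0))
    expect_true(all(ann$ptm$n_glyc_sites >= 0))
    # zero glycosylation sites force a zero glycosylation index
    i0 <- which(ann$ptm$n_glyc_sites + ann$ptm$o_glyc_sites == 0)[1]
    expect_identical(ptmIndex(ann$ptm[i0, ], "glycosylation"), 0)
})

test_that("bundle invariants hold and GMT round-trips", {
    b <- smallBundle()
    expect_true(validObject(b))
    expect_true(all(simTruth(b)$outlierGenes %in% geneSets(b)$secretory))
    tmp <- tempfile(fileext = ".gmt")
    writeGMT(geneSets(b), tmp)
    back <- readGMT(tmp)
    expect_identical(names(back), names(geneSets(b)))
    for (nm in names(back))
        expect_setequal(back[[nm]], geneSets(b)[[nm]])
})
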