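test_that("transcript aggregation sums and rounds within genes", {
    tx <- c(t1 = 10.4, t2 = 20.3, t3 = 5)
    t2g <- c(t1 = "gA", t2 = "gA", t3 = "gB")
    out <- aggregateTranscripts(tx, t2g)
    expect_equal(out["gA", 1], 31)   # round(30.7)
    expect_equal(out["gB", 1], 5)
    # one transcript per gene: identity
    out1 <- aggregateTranscripts(c(t1 = 3, t3 = 5),
                                 c(t1 = "gA", t3 = "gB"))
    expect_equal(unname(out1[, 1]), c(3, 5))
    expect_error(aggregateTranscripts(c(tX = 1), t2g), "tX")
})

test_that("ortholog aggregation follows the stated policies", {
    m <- matrix(c(5, 7, 2), 3, 1,
                dimnames = list(c("c1", "c2", "c3"), "s1"))
    # bijective map: permuted identity
    bij <- data.frame(src = c("c3", "c1", "c2"), tgt = c("h3", "h1", "h2"))
    out <- suppressMessages(aggregateOrthologs(m, bij))
    expect_equal(out[c("h1", "h2", "h3"), 1], c(h1 = 5, h2 = 7, h3 = 2))
    # many-to-one: sum vs drop
    m2o <- data.frame(src = c("c1", "c2", "c3"),
                      tgt = c("h1", "h1", "h3"))
    sum_out <- suppressMessages(aggregateOrthologs(m, m2o, "sum"))
    expect_equal(sum_out["h1", 1], 12)
    drop_out <- suppressMessages(aggregateOrthologs(m, m2o,
                                                    "drop_ambiguous"))
    expect_false("h1" %in% rownames(drop_out))
    expect_true("h3" %in% rownames(drop_out))
    # one-to-many dropped under sum as well
    o2m <- data.frame(src = c("c1", "c1", "c2"),
                      tgt = c("h1", "h2", "h3"))
    s2 <- suppressMessages(aggregateOrthologs(m, o2m, "sum"))
    expect_setequal(rownames(s2), "h3")
    expect_error(aggregateOrthologs(m, data.frame(src = "zz", tgt = "h")),
                 "no overlap")
})

test_that("median-of-ratios size factors match hand computations", {
    m <- matrix(c(10, 20, 5, 10, 20, 5), 3, 2,
                dimnames = list(paste0("g", 1:3), c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(m)), c(1, 1))
    # second column three times the first: factors (1/sqrt(3), sqrt(3))
    m3 <- cbind(s1 = c(10, 20, 5), s2 = c(30, 60, 15))
    rownames(m3) <- paste0("g", 1:3)
    expect_equal(unname(medianRatioSizeFactors(m3)),
                 c(1 / sqrt(3), sqrt(3)), tolerance = 1e-12)
    # single gene (4, 9): ratios to geometric mean 6, centered
    m1 <- matrix(c(4, 9), 1, 2, dimnames = list("g1", c("s1", "s2")))
    expect_equal(unname(medianRatioSizeFactors(m1)), c(4 / 6, 9 / 6),
                 tolerance = 1e-12)
    # gene-order invariance
    b <- smallBundle()
    mm <- SummarizedExperiment::assay(hekCounts(b))
    expect_equal(medianRatioSizeFactors(mm),
                 medianRatioSizeFactors(mm[sample(nrow(mm)), ]))
    # scaling one sample scales its factor (up to geometric-mean centering)
    sf1 <- medianRatioSizeFactors(mm)
    mm2 <- mm; mm2[, 1] <- mm2[, 1] * 4
    sf2 <- medianRatioSizeFactors(mm2)
    rel <- sf2 / sf1
    expect_equal(unname(rel[1] / median(rel[-1])), 4, tolerance = 1e-6)
    expect_error(medianRatioSizeFactors(matrix(c(0, 1, 1, 0), 2, 2)),
                 "pseudo-reference")
})

test_that("dispersion estimation recovers simulated regimes", {
    # Poisson data (alpha = 0): gene-wise estimates collapse to the floor
    set.seed(31)
    n <- 500; m <- 50
    mu <- exp(runif(n, 3, 6))
    k <- simulateNBCounts(matrix(mu, n, m,
                                 dimnames = list(sprintf("g%d", 1:n), NULL)),
                          rep(0, n), seed = 32)
    d0 <- estimateDispersionsNB(k, rep(1, m))
    expect_lte(median(d0$geneEst), 0.01)
    # NB alpha = 0.2: median shrunk dispersion in [0.15, 0.25]
    k2 <- simulateNBCounts(matrix(mu[1:500], 500, 6,
                                  dimnames = list(sprintf("g%d", 1:500), NULL)),
                           rep(0.2, 500), seed = 33)
    d2 <- estimateDispersionsNB(k2, rep(1, 6))
    expect_gt(median(d2$shrunk), 0.15)
    expect_lt(median(d2$shrunk), 0.25)
    # constant gene: variance <= mean, floored
    kc <- rbind(k2, gconst = rep(50L, 6))
    dc <- estimateDispersionsNB(kc, rep(1, 6))
    expect_equal(unname(dc$geneEst["gconst"]), 1e-8)
    expect_error(estimateDispersionsNB(matrix(0L, 3, 4), rep(1, 4)),
                 "zero")
})

test_that("IRLS coefficients match an independent likelihood maximization", {
    set.seed(41)
    n <- 20; m <- 6
    x <- rep(c(0, 1), each = 3)
    mu <- exp(runif(n, 3, 6))
    lfc <- rnorm(n, 0, 1)
    muMat <- outer(mu, rep(1, m)) * exp(outer(lfc, x))
    rownames(muMat) <- sprintf("g%d", 1:n)
    alpha <- 0.1
    k <- simulateNBCounts(muMat, rep(alpha, n), seed = 42)
    X <- cbind(1, x)
    de <- fitWaldNB(k, rep(1, m), rep(alpha, n), X, c(0, 1))
    for (g in seq_len(n)) {
        nll <- function(b)
            -sum(dnbinom(k[g, ], mu = exp(b[1] + b[2] * x),
                         size = 1 / alpha, log = TRUE))
        opt <- optim(c(log(mean(k[g, ]) + 1), 0), nll,
                     control = list(reltol = 1e-14, maxit = 5000))
        expect_equal(unname(de$lfc_raw[g]) * log(2), opt$par[2],
                     tolerance = 1e-3)
    }
})

test_that("Wald testing behaves on degenerate and null designs", {
    b <- smallBundle()
    mm <- SummarizedExperiment::assay(hekCounts(b))[1:100, 1:4]
    # two identical groups (columns copied): raw LFC exactly zero
    dup <- cbind(mm, mm)
    colnames(dup) <- paste0("s", 1:8)
    st <- data.frame(condition = factor(rep(c("a", "b"), each = 4)))
    keep <- rowSums(dup) > 0
    de <- runDiffExp(dup[keep, ], st, ~condition, "conditionb",
                     shrink = FALSE)
    expect_equal(unname(de$lfc_raw), rep(0, sum(keep)), tolerance = 1e-8)
    # BH adjustment: padj column equals p.adjust and dominates pvalue
    de2 <- differentialActivation(hekCounts(b), cellLine = "HEK293",
                                  shrink = FALSE)
    ok <- !is.na(de2$pvalue)
    expect_equal(de2$padj[ok], p.adjust(de2$pvalue[ok], "BH"))
    expect_true(all(de2$padj[ok] >= de2$pvalue[ok]))
    expect_error(differentialActivation(hekCounts(b), cellLine = "CHO"),
                 "no samples")
})

test_that("LFC shrinkage follows the zero-centered normal prior contract", {
    genes <- sprintf("g%d", 1:3)
    # conjugate closed form: lfc 2, se 1, prior sd 1 -> posterior mode 1
    de <- makeDE(genes, lfc = c(2, 2, 2), se = c(1, 1e-6, 1e6))
    s <- shrinkLFC(de, priorSdGrid = 1)
    expect_equal(s$lfc_shrunk[1], 1, tolerance = 1e-6)
    expect_equal(s$lfc_shrunk[2], 2, tolerance = 1e-4)   # data dominate
    expect_equal(s$lfc_shrunk[3], 0, tolerance = 1e-6)   # prior dominates
    expect_error(shrinkLFC(de, priorSdGrid = numeric(0)), "empty")
    # shrinkage never increases magnitude, on real results either route
    b <- smallBundle()
    act <- differentialActivation(hekCounts(b), cellLine = "HEK293")
    ok <- !is.na(act$lfc_shrunk)
    expect_true(all(abs(act$lfc_shrunk[ok]) <= abs(act$lfc_raw[ok]) + 1e-8))
    cc <- combinedCounts(b)
    prod <- cc$samples$condition == "producer"
    stP <- cc$samples[prod, ]
    stP$cell_line <- factor(stP$cell_line, levels = c("CHO", "HEK293"))
    deC <- runDiffExp(cc$counts[, prod], stP, ~cell_line,
                      "cell_lineHEK293")
    ok <- !is.na(deC$lfc_shrunk) & is.finite(deC$lfc_raw)
    expect_true(all(abs(deC$lfc_shrunk[ok]) <= abs(deC$lfc_raw[ok]) + 1e-8))
})

test_that("planted activation effects are recovered by the activation contrast", {
    set.seed(51)
    n <- 300; reps <- 6
    mu <- exp(runif(n, 3, 7))
    genes <- sprintf("g%d", 1:n)
    act <- setNames(numeric(n), genes)
    act[sample(genes, 50)] <- 2
    muMat <- cbind(matrix(mu, n, reps), matrix(mu * 2^act, n, reps))
    dimnames(muMat) <- list(genes, paste0("s", 1:(2 * reps)))
    alpha <- 0.05 + 2 / mu
    k <- simulateNBCounts(muMat, alpha, seed = 52)
    st <- data.frame(cell_line = "HEK293",
                     condition = rep(c("control", "producer"), each = reps))
    de <- differentialActivation(k, st, "HEK293")
    planted <- names(act)[act == 2]
    expect_gt(mean(de[planted, "lfc_shrunk"]), 1.6)
    expect_lt(mean(de[planted, "lfc_shrunk"]), 2.4)
})

test_that("the VST stabilizes variance and is monotone", {
    tc <- c(a0 = 0.1, a1 = 0)
    x <- 0:5000
    v <- vstTransform(matrix(x, ncol = 1,
                             dimnames = list(paste0("g", x), "s1")),
                      1, tc)
    expect_true(all(diff(v[, 1]) > 0))
    expect_equal(unname(v[1, 1]), 0)    # anchored at zero counts
    # large-mean behavior: differences proportional to log2 differences
    big <- c(2000, 4000, 8000)
    vb <- vstTransform(matrix(big, ncol = 1,
                              dimnames = list(paste0("g", 1:3), "s1")),
                       1, tc)
    d <- unname(diff(vb[, 1]))
    expect_equal(d[1] / d[2], 1, tolerance = 0.01)  # both one log2 step
    # stabilization: sd roughly flat across mean bins under the matched
    # dispersion trend, and strictly flatter than raw log2(x + 1)
    set.seed(61)
    n <- 2000; m <- 20
    mu <- exp(runif(n, -1, 7))
    alpha <- 0.05 + 2 / mu
    k <- simulateNBCounts(matrix(mu, n, m,
                                 dimnames = list(sprintf("g%d", 1:n), NULL)),
                          alpha, seed = 62)
    vk <- vstTransform(k, rep(1, m), c(0.05, 2))
    bins <- cut(rank(mu), 5)
    sdV <- tapply(apply(vk, 1, sd), bins, median)
    sdRaw <- tapply(apply(log2(k + 1), 1, sd), bins, median)
    expect_lt(max(sdV) / min(sdV), 2)
    expect_gt(max(sdRaw) / min(sdRaw), max(sdV) / min(sdV) * 1.5)
    expect_error(vstTransform(k, rep(1, m), c(-1, 0)), "a0")
})
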