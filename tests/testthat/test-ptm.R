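test_that("PTM indices are site densities per residue", {
    row <- data.frame(length_aa = 400, n_glyc_sites = 4, o_glyc_sites = 0,
                      disulfide_bonds = 2, gpi_anchor = 0)
    expect_equal(ptmIndex(row, "glycosylation"), 0.01)
    expect_equal(ptmIndex(row, "disulfide"), 0.005)
    expect_equal(ptmIndex(row, "gpi"), 0)
    row2 <- data.frame(length_aa = 160, n_glyc_sites = 2, o_glyc_sites = 2,
                       disulfide_bonds = 0, gpi_anchor = 1)
    expect_equal(ptmIndex(row2, "glycosylation"), 0.025)
    # doubling length with fixed sites halves the index
    row3 <- row; row3$length_aa <- 800
    expect_equal(ptmIndex(row3, "glycosylation"),
                 ptmIndex(row, "glycosylation") / 2)
    expect_error(ptmIndex(row, "phospho"))
    expect_error(ptmIndex(transform(row, length_aa = 0), "glycosylation"),
                 "positive")
})

test_that("enzyme-expression scores summarize rankings like the ES", {
    set.seed(14)
    N <- 1000
    r <- setNames(sort(rnorm(N, 0, 2), decreasing = TRUE),
                  sprintf("g%04d", 1:N))
    topEnz <- names(r)[sample(25, 20)]       # 20 enzymes in the top 25
    expect_gte(enzymeExpressionScore(r, topEnz), 0.8)
    # delegation identity
    expect_identical(enzymeExpressionScore(r, topEnz),
                     enrichmentScore(r, topEnz, weightP = 1))
    # scattered enzymes: |score| stays inside the permutation null band
    # (95th percentile ~ 0.45 for 20-gene sets), far below the
    # concentrated-set score
    scattered <- vapply(seq_len(60), function(i) {
        set.seed(100 + i)
        abs(enzymeExpressionScore(r, sample(names(r), 20)))
    }, numeric(1))
    expect_gte(mean(scattered <= 0.5), 0.95)
    expect_lt(median(scattered), 0.4)
    expect_error(enzymeExpressionScore(r, "absent", rProtein = "P01"),
                 "P01")
})

test_that("the sampler is seeded and satisfies its convergence contract", {
    set.seed(15)
    n <- 20
    dat <- data.frame(lfc_titer = rnorm(n, 0, 1),
                      ptm_index = runif(n, 0, 0.5),
                      enzyme_expr = runif(n, -0.8, 0.8))
    mc <- list(nWarmup = 500, nDraws = 1000, step = 0.3, seed = 5)
    p1 <- fitBayesianInteraction(dat, mcmc = mc)
    p2 <- fitBayesianInteraction(dat, mcmc = mc)
    expect_identical(posteriorDraws(p1), posteriorDraws(p2))
    expect_true(all(posteriorDraws(p1)[, "sigma"] > 0))
    expect_true(all(splitRhat(p1)[1:4] < 1.2))
    expect_error(fitBayesianInteraction(dat[1:3, ]), "at least 5")
    expect_error(fitBayesianInteraction(dat, mcmc = c(mc[-2],
                                                      list(nDraws = 10))),
                 "nDraws")
})

test_that("with an uninformative likelihood the prior is recovered", {
    # sigma fixed far above the response scale: the likelihood is flat
    # and the coefficient posterior must reproduce the Normal(0, 0.25)
    # prior (and Normal(0, 1) for the intercept)
    set.seed(16)
    n <- 10
    dat <- data.frame(lfc_titer = rep(0, n),
                      ptm_index = runif(n, 0, 0.5),
                      enzyme_expr = runif(n, -0.8, 0.8))
    post <- fitBayesianInteraction(
        dat, mcmc = list(nWarmup = 2000, nDraws = 8000, step = 1, seed = 6),
        sigmaFixed = 100)
    d <- posteriorDraws(post)
    for (b in c("bPTM", "bEnz", "bInt")) {
        expect_lt(abs(mean(d[, b])), 0.03)
        expect_gt(sd(d[, b]), 0.25 * 0.8)
        expect_lt(sd(d[, b]), 0.25 * 1.2)
    }
    expect_gt(sd(d[, "a"]), 0.8)
    expect_lt(sd(d[, "a"]), 1.2)
})

test_that("sigma-fixed posterior matches the Gaussian closed form", {
    set.seed(17)
    n <- 40
    x <- runif(n, 0, 0.5); z <- runif(n, -0.8, 0.8)
    y <- 0.3 + 1.2 * x * z + rnorm(n, 0, 0.2)
    dat <- data.frame(lfc_titer = y, ptm_index = x, enzyme_expr = z)
    post <- fitBayesianInteraction(
        dat, mcmc = list(nWarmup = 2000, nDraws = 6000, step = 0.2,
                         seed = 8), sigmaFixed = 0.2)
    d <- posteriorDraws(post)[, 1:4]
    X <- cbind(1, x, z, x * z)
    V <- solve(crossprod(X) / 0.04 + diag(1 / c(1, rep(0.0625, 3))))
    mExact <- drop(V %*% crossprod(X, y) / 0.04)
    ess <- function(v) {
        a <- acf(v, plot = FALSE, lag.max = 300)$acf[-1]
        cut <- which(a < 0.05)[1]
        if (is.na(cut)) cut <- length(a)
        max(length(v) / (1 + 2 * sum(a[seq_len(cut)])), 10)
    }
    mcse <- apply(d, 2, function(v) sd(v) / sqrt(ess(v)))
    expect_true(all(abs(colMeans(d) - mExact) <= 3 * mcse))
    # posterior sds agree with the closed form as well (looser check)
    expect_equal(unname(apply(d, 2, sd)), unname(sqrt(diag(V))),
                 tolerance = 0.1)
})

test_that("credible intervals contract as the panel grows", {
    widths <- vapply(c(10, 50, 200), function(n) {
        w <- vapply(1:8, function(s) {
            set.seed(1000 * n + s)
            x <- rep(c(0, 0.5), length.out = n)
            z <- sample(c(-1, 1), n, TRUE) * runif(n, 0.6, 0.95)
            y <- 0.8 * x * z + rnorm(n, 0, 0.3)
            dat <- data.frame(lfc_titer = y, ptm_index = x,
                              enzyme_expr = z)
            post <- fitBayesianInteraction(
                dat, mcmc = list(nWarmup = 500, nDraws = 1500, step = 0.3,
                                 seed = s))
            s <- posteriorSummary(post)
            s$ci89_high[s$parameter == "bInt"] -
                s$ci89_low[s$parameter == "bInt"]
        }, numeric(1))
        mean(w)
    }, numeric(1))
    expect_true(all(diff(widths) < 0))
})

test_that("posterior summaries and conditional slopes are exact on degenerate draws", {
    draws <- matrix(rep(c(0.1, 0.2, -0.5, 1, 0.3), each = 1000), 1000, 5)
    colnames(draws) <- c("a", "bPTM", "bEnz", "bInt", "sigma")
    post <- new("RegressionPosterior", draws = draws,
                acceptanceRate = c(a = 0.4), rhat = rep(1, 5),
                seed = 1L, priors = list(), nWarmup = 0L)
    s <- posteriorSummary(post)
    expect_equal(s$mean, c(0.1, 0.2, -0.5, 1, 0.3))
    expect_equal(s$sd, rep(0, 5))
    expect_equal(s$ci95_low, s$ci95_high)
    # slope at index 0 equals the bEnz draws; at 0.5 it crosses zero
    cc <- conditionalEffectCurve(post, c(0, 0.5))
    expect_equal(cc$slope_mean, c(-0.5, 0))
    expect_equal(attr(cc, "sign_change")[1], 0.5)
    # P(>0) is about half for symmetric draws
    set.seed(18)
    draws2 <- draws; draws2[, "bEnz"] <- rnorm(1000)
    post2 <- new("RegressionPosterior", draws = draws2,
                 acceptanceRate = c(a = 0.4), rhat = rep(1, 5),
                 seed = 1L, priors = list(), nWarmup = 0L)
    s2 <- posteriorSummary(post2)
    expect_equal(s2$p_positive[s2$parameter == "bEnz"], 0.5,
                 tolerance = 0.1)
    # 10k standard-normal draws: 95% interval near (-1.96, 1.96)
    set.seed(19)
    draws3 <- matrix(rep(abs(rnorm(10000)) + 0.1, 5), ncol = 5)
    colnames(draws3) <- colnames(draws)
    draws3[, "bPTM"] <- rnorm(10000)
    post3 <- new("RegressionPosterior", draws = draws3,
                 acceptanceRate = c(a = 0.4), rhat = rep(1, 5),
                 seed = 1L, priors = list(), nWarmup = 0L)
    s3 <- posteriorSummary(post3)
    expect_equal(s3$ci95_low[s3$parameter == "bPTM"], -1.96,
                 tolerance = 0.07 / 1.96)
    expect_equal(s3$ci95_high[s3$parameter == "bPTM"], 1.96,
                 tolerance = 0.07 / 1.96)
})
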