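## PTM-index scoring, enzyme-expression summarization, and the
## Bayesian interaction regression of titer improvement

#' PTM site density of an r-protein
#'
#' Number of occurrences of a PTM type divided by the protein's
#' amino-acid length: glycosylation counts N- plus O-linked sites,
#' disulfide counts bonds (interchain included), GPI counts the anchor.
#'
#' @param annotation one row (or a data.frame) with columns
#'   \code{length_aa}, \code{n_glyc_sites}, \code{o_glyc_sites},
#'   \code{disulfide_bonds}, \code{gpi_anchor}.
#' @param ptmType one of \code{"glycosylation"}, \code{"disulfide"},
#'   \code{"gpi"}.
#' @return non-negative numeric, sites per residue (one per row).
#' @examples
#' ptmIndex(data.frame(length_aa = 400, n_glyc_sites = 4, o_glyc_sites = 0,
#'                     disulfide_bonds = 2, gpi_anchor = 0), "glycosylation")
#' @export
ptmIndex <- function(annotation, ptmType = c("glycosylation", "disulfide",
                                             "gpi")) {
    ptmType <- match.arg(ptmType)
    if (any(annotation$length_aa <= 0))
        stop("'length_aa' must be positive")
    sites <- switch(ptmType,
        glycosylation = annotation$n_glyc_sites + annotation$o_glyc_sites,
        disulfide = annotation$disulfide_bonds,
        gpi = annotation$gpi_anchor)
    sites / annotation$length_aa
}

#' Enzyme-expression score of a PTM-enzyme set
#'
#' Summarizes the between-host expression change of the enzymes
#' responsible for a PTM (e.g. glycosyltransferases) as the running-sum
#' enrichment score (weight 1) of the enzyme set within the r-protein's
#' ranked fold-change list. Delegates to [enrichmentScore()], so there
#' is a single ES definition package-wide.
#'
#' @param ranked named numeric ranking metric (e.g. shrunken LFCs of
#'   the HEK293-vs-CHO contrast).
#' @param enzymeSet character vector of enzyme gene ids.
#' @param rProtein optional label used in error messages.
#' @return score in \eqn{[-1, 1]}.
#' @export
enzymeExpressionScore <- function(ranked, enzymeSet, rProtein = NULL) {
    if (!any(names(ranked) %in% enzymeSet))
        stop("enzyme set has no overlap with the ranking",
             if (!is.null(rProtein)) paste0(" for r-protein '", rProtein, "'"))
    enrichmentScore(ranked, enzymeSet, weightP = 1)
}

## log posterior of (a, b1, b2, b3, log sigma); y ~ N(mu, sigma)
.lpost <- function(theta, x, z, y, aSd, bSd, sigmaRate, sigmaFixed) {
    a <- theta[1]; b1 <- theta[2]; b2 <- theta[3]; b3 <- theta[4]
    sigma <- if (is.null(sigmaFixed)) exp(theta[5]) else sigmaFixed
    mu <- a + b1 * x + b2 * z + b3 * x * z
    lp <- dnorm(a, 0, aSd, log = TRUE) +
        sum(dnorm(c(b1, b2, b3), 0, bSd, log = TRUE))
    if (is.null(sigmaFixed))
        lp <- lp - sigmaRate * sigma + log(sigmaRate) + theta[5]  # prior + Jacobian
    if (length(y))
        lp <- lp + sum(dnorm(y, mu, sigma, log = TRUE))
    lp
}

.splitRhat <- function(x) {
    n <- floor(length(x) / 2)
    chains <- cbind(x[seq_len(n)], x[n + seq_len(n)])
    mns <- colMeans(chains)
    W <- mean(apply(chains, 2, var))
    B <- n * var(mns)
    if (W == 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
}

#' Fit the Bayesian interaction model of titer improvement
#'
#' Samples the posterior of the linear model
#' \deqn{LFC_i \sim Normal(\mu_i, \sigma), \quad
#'   \mu_i = a + b_{PTM} x_i + b_{Enz} z_i + b_{Int} x_i z_i}
#' with priors \eqn{a \sim N(0, 1)},
#' \eqn{b_{PTM}, b_{Enz}, b_{Int} \sim N(0, 0.25)} and
#' \eqn{\sigma \sim Exponential(rate)}, using random-walk
#' Metropolis-within-Gibbs with diagonal proposals adapted during
#' warmup to an acceptance rate near 0.3-0.45. \eqn{\sigma} is sampled
#' on the log scale (with the Jacobian correction). Predictors are used
#' on their raw scale by default, matching the prior scales; set
#' \code{standardize = TRUE} to center and scale them (recorded in the
#' result). A convergence warning is raised if any split-Rhat exceeds
#' 1.05.
#'
#' @param data data.frame with columns \code{lfc_titer},
#'   \code{ptm_index} and \code{enzyme_expr}; at least 5 complete rows.
#' @param priors list with \code{a_sd} (default 1), \code{b_sd}
#'   (default 0.25) and \code{sigma_rate} (default 1).
#' @param mcmc list with \code{nWarmup}, \code{nDraws}, \code{step}
#'   (initial proposal sd) and \code{seed}.
#' @param sigmaFixed optional positive value: hold \eqn{\sigma} fixed
#'   (the coefficient posterior is then Gaussian in closed form, used
#'   for validation).
#' @param standardize center/scale the predictors before fitting.
#' @return a [RegressionPosterior-class].
#' @export
fitBayesianInteraction <- function(data,
                                   priors = list(a_sd = 1, b_sd = 0.25,
                                                 sigma_rate = 1),
                                   mcmc = list(nWarmup = 1000L,
                                               nDraws = 4000L,
                                               step = 0.2, seed = 1L),
                                   sigmaFixed = NULL,
                                   standardize = FALSE) {
    stopifnot(all(c("lfc_titer", "ptm_index", "enzyme_expr") %in%
                  colnames(data)))
    data <- data[complete.cases(data[, c("lfc_titer", "ptm_index",
                                         "enzyme_expr")]), ]
    if (nrow(data) < 5L)
        stop("need at least 5 r-proteins with complete data")
    y <- data$lfc_titer; x <- data$ptm_index; z <- data$enzyme_expr
    if (!all(is.finite(c(y, x, z)))) stop("non-finite inputs")
    if (sd(x) == 0 || sd(z) == 0)
        warning("zero-variance predictor: interaction coefficients are not identifiable")
    if (standardize) {
        x <- as.numeric(scale(x)); z <- as.numeric(scale(z))
    }
    aSd <- priors$a_sd %||% 1
    bSd <- priors$b_sd %||% 0.25
    sigmaRate <- priors$sigma_rate %||% 1
    nWarmup <- as.integer(mcmc$nWarmup %||% 1000L)
    nDraws <- as.integer(mcmc$nDraws %||% 4000L)
    step0 <- mcmc$step %||% 0.2
    seed <- as.integer(mcmc$seed %||% 1L)
    if (nDraws < 1000L) stop("'nDraws' must be >= 1000")

    nPar <- if (is.null(sigmaFixed)) 5L else 4L
    theta <- c(0, 0, 0, 0, if (is.null(sigmaFixed)) log(1 / sigmaRate))
    scales <- rep(step0, nPar)
    draws <- matrix(NA_real_, nDraws, 5L,
                    dimnames = list(NULL, c("a", "bPTM", "bEnz", "bInt",
                                            "sigma")))
    accWindow <- matrix(0, 50L, nPar)
    accPost <- numeric(nPar); nProp <- 0L
    lp <- .lpost(theta, x, z, y, aSd, bSd, sigmaRate, sigmaFixed)
    withr::with_seed(seed, {
        for (it in seq_len(nWarmup + nDraws)) {
            for (j in seq_len(nPar)) {
                prop <- theta
                prop[j] <- prop[j] + rnorm(1, 0, scales[j])
                lpProp <- .lpost(prop, x, z, y, aSd, bSd, sigmaRate,
                                 sigmaFixed)
                acc <- log(runif(1)) < lpProp - lp
                if (acc) { theta <- prop; lp <- lpProp }
                if (it <= nWarmup) {
                    accWindow[1 + (it - 1) %% 50, j] <- acc
                } else {
                    accPost[j] <- accPost[j] + acc
                }
            }
            if (it <= nWarmup && it %% 50 == 0) {
                rate <- colMeans(accWindow)
                scales <- ifelse(rate > 0.45, scales * 1.3,
                          ifelse(rate < 0.30, scales * 0.75, scales))
            }
            if (it > nWarmup) {
                sig <- if (is.null(sigmaFixed)) exp(theta[5]) else sigmaFixed
                draws[it - nWarmup, ] <- c(theta[1:4], sig)
            }
        }
    })
    rhat <- apply(draws[, if (is.null(sigmaFixed)) 1:5 else 1:4,
                        drop = FALSE], 2, .splitRhat)
    if (any(rhat > 1.05, na.rm = TRUE))
        warning("split-Rhat above 1.05 for: ",
                paste(names(rhat)[rhat > 1.05], collapse = ", "),
                " - increase warmup or draws")
    post <- new("RegressionPosterior",
                draws = draws,
                acceptanceRate = setNames(accPost / nDraws,
                                          colnames(draws)[seq_len(nPar)]),
                rhat = if (is.null(sigmaFixed)) rhat
                       else c(rhat, sigma = NA_real_),
                seed = seed,
                priors = list(a_sd = aSd, b_sd = bSd,
                              sigma_rate = sigmaRate,
                              sigmaFixed = sigmaFixed,
                              standardize = standardize),
                nWarmup = nWarmup)
    post
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize a regression posterior
#'
#' Per-parameter posterior mean, sd, central 89\% and 95\% credible
#' intervals (empirical quantiles) and the posterior probability of a
#' positive coefficient.
#'
#' @param post a [RegressionPosterior-class].
#' @return data.frame, one row per parameter.
#' @export
posteriorSummary <- function(post) {
    stopifnot(is(post, "RegressionPosterior"))
    d <- posteriorDraws(post)
    out <- data.frame(
        parameter = colnames(d),
        mean = colMeans(d),
        sd = apply(d, 2, sd),
        ci89_low = apply(d, 2, quantile, 0.055),
        ci89_high = apply(d, 2, quantile, 0.945),
        ci95_low = apply(d, 2, quantile, 0.025),
        ci95_high = apply(d, 2, quantile, 0.975),
        p_positive = colMeans(d > 0),
        row.names = NULL, stringsAsFactors = FALSE)
    out
}

#' Conditional effect of enzyme expression on titer improvement
#'
#' At a given PTM index \eqn{x}, the slope of titer LFC on enzyme
#' expression is \eqn{b_{Enz} + b_{Int} x} per posterior draw. The
#' sign-change point \eqn{-b_{Enz}/b_{Int}} (per draw with
#' \eqn{b_{Int} \ne 0}) is returned as an attribute — the PTM index at
#' which increased enzyme expression flips from hurting to helping (or
#' vice versa).
#'
#' @param post a [RegressionPosterior-class].
#' @param ptmIndexValues numeric vector of PTM indices to evaluate.
#' @return data.frame per index value: posterior mean slope, sd, 89\%
#'   and 95\% intervals, \code{p_positive}; attribute
#'   \code{"sign_change"} holds the sign-change-point draws.
#' @export
conditionalEffectCurve <- function(post, ptmIndexValues) {
    stopifnot(is(post, "RegressionPosterior"))
    d <- posteriorDraws(post)
    out <- do.call(rbind, lapply(ptmIndexValues, function(v) {
        slope <- d[, "bEnz"] + d[, "bInt"] * v
        data.frame(ptm_index = v,
                   slope_mean = mean(slope), slope_sd = sd(slope),
                   ci89_low = quantile(slope, 0.055),
                   ci89_high = quantile(slope, 0.945),
                   ci95_low = quantile(slope, 0.025),
                   ci95_high = quantile(slope, 0.975),
                   p_positive = mean(slope > 0))
    }))
    rownames(out) <- NULL
    nz <- d[, "bInt"] != 0
    attr(out, "sign_change") <- -d[nz, "bEnz"] / d[nz, "bInt"]
    out
}
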