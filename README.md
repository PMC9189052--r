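# hostcomp

Comparative transcriptomics of two recombinant-protein expression
hosts, CHO and HEK293. Difficult-to-express human proteins are often
rescued by swapping the host from CHO to HEK293; the transcriptomes of
the two hosts, collected during production, explain part of why. This
package implements the analysis chain for that question as reusable,
tested R functions, for bioprocess and systems-biology researchers
working with cross-species expression data:

- **Transcriptome usage** — decomposition of each sample's TPM mass
  into functional gene groups (Proteomaps-style), mitochondrial
  library-mass QC, and the "more than two-fold improved" titer rule
  with a +1 pseudocount.
- **Differential expression** — a from-scratch negative-binomial
  engine: median-of-ratios size factors, method-of-moments dispersions
  shrunk toward a parametric trend α(μ) = a₀ + a₁/μ, per-gene GLM fits
  by IRLS, Wald tests with BH adjustment, log fold-change shrinkage
  under a zero-centered normal prior (closed-form and NB-likelihood
  posterior modes), and a closed-form variance-stabilizing
  transformation. Supports the three study designs: between hosts,
  producer vs. empty-vector control within a host ("activation"), and
  the cell line × r-protein interaction.
- **Cross-species mapping** — transcript-to-gene aggregation and
  CHO-to-human ortholog conversion with explicit many-to-one /
  one-to-many policies.
- **Enrichment** — the running-sum gene-set enrichment score,
  permutation-normalized NES with a permutation p-value, and the exact
  hypergeometric over-representation test.
- **Secretory outliers** — classification of between-host expression
  outliers into groups I/II/III around the identity band,
  activation-disparity ranking (top-20 rule), and per-gene correlation
  of differential activation with titer change.
- **PTM model** — the Bayesian interaction regression of titer
  improvement,

  LFC_titer[i] ~ Normal(μ[i], σ),
  μ[i] = a + b_PTM·PTMindex[i] + b_Enz·Enzymeexpr[i] + b_Int·PTMindex[i]·Enzymeexpr[i],

  with priors a ~ N(0, 1), b ~ N(0, 0.25), σ ~ Exponential(1), sampled
  by adaptive Metropolis-within-Gibbs. PTMindex is PTM sites per
  residue; Enzymeexpr is the enrichment score of the PTM-enzyme set in
  the r-protein's between-host fold-change ranking.
- **Synthetic data** — a generator producing every pipeline input
  (two-host NB count matrices joined by a partial ortholog map, planted
  extreme outliers, host-specific activation, titers drawn from the
  interaction model, gene sets, PTM tables) with recorded ground truth,
  so the entire pipeline is testable without sequencing data.

## Worked example

Fit the PTM × enzyme interaction model to a 50-protein panel whose
titers were generated from the model itself (truth: b_Enz = −0.3,
b_Int = 2, σ = 0.1):

```r
library(hostcomp)

n <- 50
withr::with_seed(77, {
  x <- rep(c(0, 0.5), length.out = n)                 # glycosylation index
  z <- sample(c(-1, 1), n, TRUE) * runif(n, 0.7, 1.0) # enzyme score
})
ptm <- data.frame(r_protein = sprintf("P%02d", 1:n), length_aa = 500L,
                  n_glyc_sites = as.integer(round(x * 500)),
                  o_glyc_sites = 0L, disulfide_bonds = 3L, gpi_anchor = 0L)
enz <- setNames(z, ptm$r_protein)
titers <- generateTiters(ptm, enz,
    c(a = 0, bPTM = 0, bEnz = -0.3, bInt = 2, sigma = 0.1), seed = 9)

dat <- data.frame(lfc_titer   = attr(titers, "lfc"),
                  ptm_index   = ptmIndex(ptm, "glycosylation"),
                  enzyme_expr = enz)
post <- fitBayesianInteraction(dat,
    mcmc = list(nWarmup = 2000, nDraws = 4000, step = 0.2, seed = 10))
posteriorSummary(post)
#>   parameter    mean     sd ci89_low ci89_high
#> 1         a  0.0247 0.0205 -0.00789    0.0559
#> 2      bPTM -0.1295 0.0582 -0.21788   -0.0346
#> 3      bEnz -0.2342 0.0267 -0.27562   -0.1900
#> 4      bInt  1.7828 0.0779  1.65031    1.8997
#> 5     sigma  0.1035 0.0125  0.08586    0.1245
```

The generative coefficients are recovered (b_Int slightly shrunk by its
N(0, 0.25) prior). The conditional slope of titer improvement on enzyme
expression flips sign with glycosylation load — negative for
non-glycosylated products, positive for heavily glycosylated ones:

```r
conditionalEffectCurve(post, c(0, 0.25, 0.5))
#>   ptm_index slope_mean ci89_low ci89_high p_positive
#> 1      0.00     -0.234   -0.276    -0.190          0
#> 2      0.25      0.211    0.183     0.240          1
#> 3      0.50      0.657    0.614     0.697          1
```

A full synthetic two-host study runs end to end with

```r
res <- runReport(simConfig(seed = 1), outDir = "report")
```

which writes usage tables, the three differential-expression contrasts,
secretory-subsystem enrichment, outlier classification, the
activation/titer correlation, posterior draws and a JSON manifest of
parameters, seeds and file hashes.

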