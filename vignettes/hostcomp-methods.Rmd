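---
title: "Methods: comparing CHO and HEK293 expression hosts at the transcriptome level"
author: "hostcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing CHO and HEK293 expression hosts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific setting

A panel of difficult-to-express human secreted proteins is produced in
two hosts — CHO and HEK293 — alongside empty-vector controls, and
bulk RNA-seq of the producing cells is used to ask three questions:
how differently the two hosts allocate their transcriptomes; which
secretory-pathway genes behave as extreme between-host outliers or
respond differently to transgene expression; and whether the
product-to-product variation in titer improvement (CHO to HEK293) is
explained jointly by the product's PTM composition and the host's
expression of the corresponding PTM enzymes.

`hostcomp` implements that analysis from the gene-level count matrix
onward. Upstream read processing (QC, trimming, quasi-mapping) is out
of scope; counts are the entry point, obtained externally or from the
package's synthetic generator.

# Models and procedures

## Counts and differential expression

Counts are modeled as negative binomial with mean/dispersion
parameterization, $Var = \mu + \alpha\mu^2$, and a parametric
dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$. The engine follows the
standard count-based DE workflow, reimplemented:

1. **Size factors** by median-of-ratios over genes expressed in all
   samples, re-centered to geometric mean 1. If no gene is expressed
   everywhere the function stops and advises a pseudo-reference
   fallback rather than silently changing estimator.
2. **Dispersions**: gene-wise method-of-moments estimates
   $\hat\alpha_g = (v_g - \overline{s^{-1}}\mu_g)/\mu_g^2$ from pooled
   within-group variances (groups = distinct design-matrix rows,
   residual df $m - p$); the trend fit by iterated Gamma
   (identity-link) regression excluding ratio outliers (outside
   $[10^{-4}, 15]$ of the current trend), at most 10 iterations,
   convergence at $10^{-4}$ relative change; then log-scale shrinkage
   toward the trend. The gene-wise log estimate carries the chi-square
   log bias $\psi(df/2) - \log(df/2)$, which is removed before
   combining; the sampling variance of a log dispersion estimate is
   approximated by $\psi_1(df/2)$ and the prior variance by the excess
   spread of the log residuals (floored at 0.25). Estimates more than
   $2\sqrt{\psi_1(df/2) + \sigma^2_{prior}}$ above the trend are kept
   unshrunk (dispersion outliers). All dispersions are floored at
   $10^{-8}$. The bias correction matters: without it the null type-I
   rate of the Wald test runs visibly above nominal at 3+3 replicates.
3. **GLM fits** per gene by IRLS (log link, log size factors as
   offset), fixed dispersion, initialization from a log-linear
   regression of $\log((y+0.5)/s)$, linear predictor clamped to
   $[-30, 30]$, convergence at $10^{-6}$ on the coefficient change,
   at most 50 iterations. Non-converged genes are flagged, their
   p-value set missing, and they are excluded from the BH denominator.
4. **Wald tests** of a linear contrast against the standard normal,
   Benjamini–Hochberg adjustment across tested genes. All-zero genes
   are removed before estimation. A pseudocount of 1 is used only in
   descriptive log2 ratios of normalized counts, never inside the GLM.

Three designs cover the study: `~ cell_line` on producers (between
hosts, after ortholog mapping), `~ condition` within one host
(producer vs. control "activation"), and
`~ cell_line + r_protein + cell_line:r_protein` with controls as the
r-protein reference level, whose interaction coefficients give each
r-protein's activation difference between hosts.

## Fold-change shrinkage

Raw fold changes of low-information genes are noisy; the engine
shrinks them toward zero under a zero-centered normal prior whose
width is selected from a grid (50 log-spaced values in [0.05, 20]
log2 units) by maximizing the Gaussian marginal likelihood
$\prod_g N(\widehat{lfc}_g;\, 0,\, s^2 + se_g^2)$. Two posterior-mode
routes exist:

- the **closed form** $\widehat{lfc}_g \cdot s^2/(s^2 + se_g^2)$,
  exact under a Gaussian likelihood summary; and
- the **NB-likelihood mode**, found by ridge-penalized IRLS (prior
  precision on all non-intercept coefficients, natural-log scale).

The second is what `runDiffExp()` uses. The distinction is essential
for genes with an all-zero condition: their Wald summary has an
enormous standard error, so the closed form would erase a genuinely
extreme fold change, while the exact likelihood still supports a
large (finite) estimate. This mirrors why likelihood-aware shrinkage
replaced Wald-summary shrinkage in the wider DE ecosystem. In both
routes $|lfc_{shrunk}| \le |lfc_{raw}|$.

## Variance-stabilizing transformation

For the fitted trend, the closed form
$vst(q) = \log_2\frac{1 + a_1 + 2a_0 q + 2\sqrt{a_0 q (1 + a_1 + a_0 q)}}{4 a_0} - c_0$
is applied to normalized counts, with $c_0$ chosen so $vst(0) = 0$.
The anchoring is a display/thresholding convention: it puts
transformed values on $\log_2(1+x)$-like units so that the outlier
classification thresholds below have interpretable defaults, and it
does not affect monotonicity or variance. $a_0 \le 0$ is an error
(the asymptotic dispersion must be positive for the integral to
converge).

## Cross-species mapping

CHO counts are converted to human gene identifiers with an ortholog
table. `aggregateOrthologs()` implements two policies: `sum`
(many-to-one summed, one-to-many dropped — the function default) and
`drop_ambiguous` (1:1 pairs only). The pipeline's between-host
analyses use `drop_ambiguous`: summing many-to-one pairs splices
together unrelated baseline expression levels and manufactures
spurious extreme between-host fold changes, which would contaminate
exactly the outlier lists this analysis is about. Restricting
cross-species DE to unambiguous 1:1 orthologs is standard practice;
the cost (a few percent of genes) is logged.

## Usage, QC and titer rules

Transcriptome usage is computed on TPM (length-normalized; the
compositional mass should not be dominated by long genes), with the
transgene excluded and fractions renormalized; unannotated genes go to
an explicit `unassigned` group so fractions always sum to 1.
Synthetic data carry no real gene models, so lengths default to 1 kb
with a warning when absent. The mitochondrial TPM fraction serves as a
between-sample normalization check (expected ≈ 10% and stable).
Titer fold changes use $\log_2((a+1)/(b+1))$ — the +1 pseudocount
accommodates undetectable titers — and "more than two-fold improved"
is the strict inequality $lfc > 1$ (a titer exactly two-fold higher is
not "more than two-fold").

## Outlier classification and disparity ranking

On mean VST expression per host, genes within a band of half-width 2
around the identity line are conserved. Outliers split into group I
(CHO below 2, HEK293 at or above 6 — silent in CHO, clearly expressed
in HEK293), group II (CHO between the thresholds, HEK293 higher by
more than the band) and group III (CHO higher by more than the band).
These thresholds are qualitative conventions for reading the
expression scatter, not derived quantities, so all three are
arguments with the defaults above, in VST (log2-like) units. Activation disparity is
$|lfc^{HEK}_{act} - lfc^{CHO}_{act}|$ per gene, ranked descending with
lexicographic gene-id tie-breaks; the top 20 are kept, and their
secretory over-representation is an exact hypergeometric upper tail.

Correlation of per-gene interaction LFCs with per-r-protein titer LFCs
is Pearson across r-proteins (Pearson matches the linear framing of
the titer model and is recorded in output metadata; Spearman would be
a defensible alternative). Genes with zero-variance activation vectors are undefined
and reported separately. At least 3 shared r-proteins are required.

## Enrichment statistics

The running-sum enrichment score walks the metric-ranked list,
incrementing by $|r|^p$ (normalized over in-set genes) at hits and
$1/(N - N_{set})$ at misses; the ES is the signed maximum deviation.
`weightP` defaults to 1 (the standard weighted statistic); 0 gives the
unweighted form used in hand-checkable tests. Ties are broken by gene
id, making scores deterministic. The permutation null draws random
same-size gene sets (gene-label permutation): sample-label permutation
is not available for rankings derived from shrunken LFCs, and the
divergence from sample-permutation GSEA is deliberate and documented.
NES is the ES divided by the mean magnitude of same-sign null scores;
the p-value is $(1 + k)/(1 + n_{same})$, never zero. If no same-sign
permutation occurs, the p is bounded at $1/(n_{perm}+1)$ and flagged.

## The Bayesian interaction model

Titer improvement is modeled as
$LFC_i \sim N(a + b_{PTM} x_i + b_{Enz} z_i + b_{Int} x_i z_i,\ \sigma)$
with $x$ the PTM site density (sites per residue) and $z$ the enzyme
expression score in $[-1, 1]$. Priors: $a \sim N(0,1)$,
$b \sim N(0, 0.25)$, $\sigma \sim Exponential(rate)$; the exponential
rate is a parameter with default 1, the common convention for this
weakly informative choice. Phospho-type PTMs are excluded
(not represented in the panel); glycosylation and disulfide indices
are first-class, GPI optional. Predictors are not standardized by
default because the priors are stated on the raw scale; a
`standardize` flag exists and is recorded.

The sampler is random-walk Metropolis-within-Gibbs with per-parameter
normal proposals, $\sigma$ sampled on the log scale with the Jacobian
correction. Proposal scales adapt every 50 warmup iterations toward an
acceptance rate of 0.30–0.45 (scale × 1.3 above, × 0.75 below) and are
frozen after warmup. Split-$\hat R$ (chain halves) above 1.05 raises a
convergence warning. A Hamiltonian sampler would be overkill for a
5-parameter conjugate-like posterior; Metropolis-within-Gibbs keeps
the implementation dependency-free and directly checkable against the
closed-form Gaussian posterior when $\sigma$ is held fixed (the
`sigmaFixed` argument exists for exactly that validation).

**Identifiability of the interaction.** With the N(0, 0.25) prior,
$\sigma = 0.1$ and 50 proteins, the posterior for $b_{Int}$ is
informative only if the PTM index varies on the scale of the
conditional-effect analysis (0 to about 0.5 sites per residue). A
panel of lightly N-glycosylated proteins (index ~0.01) leaves the
interaction prior-dominated — a closed-form computation, not an
empirical accident. The parameter-recovery studies therefore use a
designed, balanced panel: half the proteins non-glycosylated, half at
index 0.5 (mucin-type O-glycosylation density), with enzyme scores
strongly differential in both directions ($|z| \in [0.7, 1]$). This
is the design a simulation study would choose on purpose; it is fixed
a priori and shared by the tests and the acceptance script.

# The synthetic generator

`generateBundle()` emulates the study design: a human gene universe
observed in HEK293 and, through a partial ortholog map (default 90%
coverage, 5% many-to-one), in CHO; for each host, producer samples
for every r-protein plus empty-vector controls (default 2 replicates,
matching duplicate-well practice; at least 2 enforced because DE
needs replication); NB counts with the trend
$\alpha(\mu) = 0.05 + 2/\mu$ and log-normal library-depth variation
(sd 0.15); per-gene between-host effects $N(0, 1)$ in log2;
producer-induced activation $N(0, 0.3)$ on 200 genes drawn half from
the secretory pathway (activation concentrates in the secretory
machinery); 20 planted extreme outliers (CHO mean 0.5, HEK293
$2^{10}$-fold higher — silent in one host, high in the other);
mitochondrial genes rescaled to 10% of expected library mass; and a
transgene transcript carrying 2% of producer library mass. Titers are
drawn from the interaction model itself; the default truth
$(a, b_{PTM}, b_{Enz}, b_{Int}, \sigma) = (0.5, 0, -0.3, 2, 1.5)$
produces titer LFC spread of roughly two log2 units, about a third of
the panel more than two-fold improved, and the glycosylation
sign-flip. One gene per bundle tracks the titer LFC in its
per-r-protein activation difference (the planted signal for the
activation/titer correlation). All ground truth is recorded in the
bundle.

What the generator does **not** emulate: GC/length biases and other
technical covariates, batch effects, correlated gene programs,
isoform-level variation, heavy-tailed dispersion outliers, partial
ortholog homology (mapping is exact where present), and detection
limits in titer measurement. Passing tests therefore demonstrate that
the estimators recover the structure they assume, at realistic sizes
and noise — not that real cross-species data meet those assumptions.

# Numerical choices and degenerate inputs

- IRLS: tolerance $10^{-6}$, max 50 iterations, $10^{-8}$ ridge for
  numerical stability of the unpenalized fit, clamped linear
  predictor; separation (all-zero condition) converges to a large
  finite capped estimate and is handled by the NB-likelihood
  shrinkage route.
- Dispersion floor $10^{-8}$; constant genes (variance ≤ mean) land on
  the floor.
- Tie-breaks: gene-id lexicographic order in rankings and in the
  enrichment walk.
- TPM requires positive lengths and nonzero library mass; both are
  errors, named per gene/sample.
- `generateTiters()` keeps the drawn LFC exact while enforcing
  non-negative titers: when the implied HEK293 titer would be
  negative, the HEK293 titer is set to 0 and the CHO titer adjusted.
- Zero-variance predictors in the regression trigger an
  identifiability warning, not an error.

# Problem sizes

Simulation-based checks run at small scale, chosen to finish in seconds
while leaving comfortable statistical margins: 2000-gene null
calibration at 3+3 replicates; a 2000-gene two-host bundle with 20
planted outliers for recovery; 300–500 gene bundles for pipeline and
correlation checks; 50-protein panels with 4000 post-warmup draws for
the Bayesian model; 500 × 200 permutations for the enrichment null.

# Known limitations

- The Wald test with a normal reference is slightly anticonservative
  at very small replicate numbers (measured ~0.065 at nominal 0.05
  with 3+3; the same order as the established implementations of this
  workflow). No Cook's-distance outlier replacement or independent
  filtering is performed; both exclusions are recorded in result
  metadata.
- The shrinkage estimator is a stated normal-prior approximation of
  adaptive heavy-tailed-prior shrinkage estimators, not a
  reimplementation of one;
  exact numerical agreement with other tools is not expected.
- Gene-label permutation NES is not exchangeable with
  sample-permutation NES; compare NES values only within one scheme.
- The single-chain split-$\hat R$ detects slow mixing but not
  multimodality; for this unimodal posterior that risk is minimal.
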