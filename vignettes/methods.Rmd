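---
title: "Mixed-model variance partitioning for microbiome count tables: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mixed-model variance partitioning for microbiome count tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`microglmm` treats an amplicon sequence variant (ASV) count table as the
response of a single generalized linear mixed model rather than as many
per-taxon problems. Every cell of the ASV-by-sample matrix becomes one
observation, and the read count $y_{h,a,g}$ of ASV $a$ in the sample taken
from host $h$ under group level $g$ (a season, an age class, a treatment)
is modelled with Poisson errors and a log link:

$$\log \lambda_{h,a,g} = \beta_0 + \beta_g
  + u_h + u_a + u_{h:g} + u_{a:h} + u_{a:g} + u_{a:h:g},$$

with each random term drawn from its own Gaussian,
$u_t \sim N(0, \sigma^2_t)$. The terms have distinct scientific roles:

* technical: $u_h$ (host-level differences in total reads), $u_a$
  (overall abundance differences between common and rare taxa),
  $u_{h:g}$ (per-sample library size), and the observation-level term
  $u_{a:h:g}$, which absorbs over-dispersion the way an
  observation-level random effect does in any Poisson GLMM;
* biological: $u_{a:h}$ (consistent host-specific taxon abundances —
  the basis of repeatability) and $u_{a:g}$ (taxon-specific shifts
  between group levels — the basis of differential abundance).

`make_2016_spec()` builds exactly this structure for repeated-measures
designs (two samples per host). `make_2013_spec()` is the single-sample
variant: with one sample per host, host and sample coincide, so the model
drops the sample term and the ASV-by-host interaction becomes the
row-level residual. Because the levels of one term are conditionally
independent given the others, interactions are defined over observed
factor tuples only; unobserved combinations get no phantom levels. When
hierarchical taxonomy matters, `add_taxonomy_terms()` appends
rank-by-group terms (e.g. phylum:group, family:group) so group shifts can
be read at several taxonomic depths at once; missing rank labels pool
into a single "unclassified" level per rank rather than dropping rows,
which would break the complete observation grid the Poisson likelihood
needs (zeros are real data here, and are materialised as explicit rows).

A shared model across thousands of taxa buys shrinkage: each taxon's
group effect is pulled toward the community-level distribution, which
stabilises estimates for rare taxa, and community-level questions — how
much variance is technical, how repeatable is an individual's microbiota
— become direct functions of the variance components.

## Posterior computation

The posterior is sampled by Markov chain Monte Carlo implemented in
compiled code. Variance components take the scalar inverse-Wishart
convention $\sigma^2_t \sim \mathrm{IG}(\nu/2,\ \nu V/2)$ with defaults
$V = 1$, $\nu = 0.002$ (close to flat on the variance); fixed effects
take $N(0, 10^8)$ priors. For the Poisson family, random-effect levels
are updated by vectorised single-site Metropolis moves with per-term
proposal scales adapted toward a 0.44 acceptance rate during burn-in
only, so retained draws come from a fixed kernel; variance components
are drawn from their conjugate inverse-gamma conditionals.

Single-site updates alone mix badly here, because sums like
$\beta_0 + \bar u_t$ are strongly likelihood-identified while their
difference is informed only by the priors. Each iteration therefore adds
*sweep* moves: Gibbs draws along the likelihood-invariant directions
(intercept versus each term's level mean; each treatment-coded fixed
effect versus the matching levels of group-bearing terms; each nested
term pair, translating mass between a coarse term and the finer term it
is contained in). Because these translations leave every linear
predictor unchanged, their conditionals are Gaussian in the priors and
cost little; they raise the intercept's effective sample size by two
orders of magnitude on typical tables. The Gaussian family replaces the
Metropolis steps with fully conjugate Gibbs updates and keeps the same
sweeps. The linear predictor is clamped at $\pm 50$ on the log scale
before exponentiation, a numeric guard that is inert for any converged
fit.

Defaults (65,000 iterations, 15,000 burn-in, thinning 50, two chains)
mirror common practice for these models and retain about 2,000 draws.
The examples and validation harnesses in this package use shorter chains
(typically 5,000 iterations, 1,500 burn-in, thinning 5) at the package's
standard simulation scale; `diagnostics()` reports effective sample
sizes (Geyer initial positive sequence), lag-1 autocorrelations and,
with two or more chains, potential scale reduction factors, flagging
anything with ESS below 100. Chains are seeded `seed, seed + 1, ...` and
runs are exactly reproducible from (data, spec, prior, config).

Parameter-expanded priors, sometimes used to improve mixing of weakly
identified variance components, are deliberately not implemented: the
sweep moves already target the dominant slow directions, and the
non-expanded sampler is verified directly against a brute-force
grid-integration posterior and an independent conjugate Gibbs sampler in
the test suite. Very weakly identified terms (few levels, tiny variance)
can still mix slowly; the diagnostics are the guard rail.

## Variance partition, repeatability, differential abundance

All variance components live on the link scale, so their shares can be
compared directly. For the Poisson family a distribution-specific
component completes the partition, following the
Nakagawa–Schielzeth formulation for log-link Poisson models:
$\omega = \ln(1 + 1/\bar\lambda)$ with
$\bar\lambda = \exp(\beta_0 + \tfrac12\sum_t \sigma^2_t)$, the expected
count at the fixed-effect reference level under lognormal random
effects. The literature offers several variants of $\bar\lambda$ (e.g.
averaging the fixed effect over groups); `partition_variance()` uses the
reference-level form, computes every proportion *within each posterior
draw* — so shares sum to one exactly, draw by draw, and carry HPD
intervals — and reports the Gaussian residual $\sigma^2_e$ in the
distribution row for Gaussian fits. Fixed-effect variance is excluded
from the denominator by default (the partition covers random components
plus the distribution term); `include_fixed = TRUE` switches to the full
marginal form.

Repeatability of community composition across repeated samples of the
same host is the ratio of the ASV-by-host variance to the non-technical
compositional variance,
$R = \sigma^2_{a:h} / (\sigma^2_{a:g} + \sigma^2_{a:h} +
\sigma^2_{a:h:g})$, again evaluated per draw and summarised by its
posterior mean and HPD interval.

Differential abundance is a posterior contrast, not a test statistic:
for each ASV the draws of $u_{a,g_2} - u_{a,g_1}$ give a posterior mean
difference on the log scale, a highest posterior density interval, and a
robustness flag — robust when the interval excludes zero. The HPDI is
the shortest window containing $\lceil p \cdot n \rceil$ sorted draws
(ties broken at the lowest start, making results deterministic). No
multiplicity correction is applied by default, matching how these
posterior contrasts are usually read; a Benjamini–Hochberg option on
two-sided posterior tail probabilities is available
(`bh_correct = TRUE`) for users who want a familiar error-rate knob.
`summarize_shifts()` then decomposes the robust set by direction and
taxonomic rank.

Model adequacy for count data hinges on zeros:
`predicted_zero_ratio()` compares the observed zero count with the
posterior-predictive expectation $\sum_i e^{-\lambda_i}$ averaged over
draws. Ratios near one say the over-dispersed Poisson accounts for the
zeros; ratios well above one point to zero inflation this model does not
capture (zero-inflated families are out of scope here).

## The compositional route

`clr_transform()` implements the centered log-ratio of Aitchison with a
pseudocount (default 1, recorded in the output), taking each sample as
the compositional unit; `run_clr_pipeline()` then fits the
Gaussian-identity model to the transformed values. The Gaussian residual
plays the row-level role, so the specification passes
`residual = NULL` — keeping an observation-level random term as well
would duplicate the same variance. The CLR removes library-size
differences by construction, at the price of treating transformed
real values as the data; it is the pragmatic route when counts are
awkward (extreme depth variation, heavy tails) or when complex random
structures make the Poisson sampler expensive.

## The synthetic-data generator

`simulate_dataset()` draws data from the generative form of the model
itself: a complete host-by-group design with one sample per host and
group, level effects drawn once per level, counts Poisson given the
linear predictor. Its defaults define the package's standard validation
scale — 30 hosts × 2 groups × 150 ASVs (9,000 observations),
$\beta_0 = 3$, $\sigma^2 = (1.0, 0.1, 0.2, 0.5)$ for the ASV, sample,
ASV-by-group and residual terms — sizes at which a full fit takes
seconds to a few tens of seconds, so multi-seed coverage, false-positive
and power checks stay cheap. The host and ASV-by-host variances default
to zero and are switched on where a harness needs them; library-size
heterogeneity enters through the sample (host-by-group) term. Spiked
group offsets (`spike_fraction`, `spike_delta`, alternating signs) give
power checks fixed, non-shrunk targets with balanced directions.

What the generator does *not* emulate bounds what passing tests can
claim: real tables are far sparser and more skewed than the lognormal-
Poisson form produces at these settings, taxonomy here is a round-robin
fabrication with no phylogenetic signal, there is no sequencing error or
taxonomy misassignment, and real data violate the Gaussian-random-effect
assumption in ways simulation from the model cannot reveal. The suite
demonstrates correctness of the machinery (sampler, formulas, callers)
under the model's own assumptions, not robustness to their violation.

## Numerical and design notes

* Identifiers match exactly and case-sensitively; silent coercion hides
  sample mix-ups.
* Level indexing is lexicographic by label tuple, so design
  realizations, and therefore fits, are deterministic.
* The treatment-coded fixed factor uses the first sorted level as
  reference.
* Filtering (`filter_taxa()`) happens on the count matrix before long
  assembly and defaults to off — with shrinkage, rare taxa are
  informative rather than harmful, and threshold choices are a
  sensitivity analysis, not a default.
* Degenerate inputs are handled without crashing: constant posterior
  draws are flagged as degenerate in diagnostics; an all-equal CLR
  matrix collapses variance components to the prior floor; a table with
  no observed zeros returns a zero ratio of 0 with a warning, and a
  model predicting essentially no zeros returns `Inf` with a warning.
* The repeated-measures template retains both the host term and the
  host-by-group (sample) term. With only two samples per host the two
  are hard to separate and the host term often shrinks toward zero;
  `make_2016_spec(drop_host = TRUE)` removes it.
* Oracle-based verification in the test suite uses informative
  inverse-gamma priors (e.g. $\nu = 5$) so that posterior moments of
  variance components exist and quadrature grids can cover the tails;
  with the near-flat default prior and very few levels, a variance
  posterior can have effectively infinite variance, which is a property
  of that prior, not a sampler defect.

## Limitations

Zero-inflated and maximum-likelihood backends are out of scope, as are
phylogenetic or relatedness covariance structures among hosts or taxa.
The fixed-effect side is deliberately minimal (intercept plus one
categorical factor); richer fixed formulas belong to general-purpose
mixed-model software. Fits at real-study scale (thousands of ASVs,
hundreds of samples) are feasible but call for the long default chains
and patience; the short chains used in the validation harnesses are
sized for the synthetic scale above.
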