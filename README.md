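# microglmm

Bayesian generalized linear mixed models for microbiome metabarcoding
count tables: partition the variance of community composition into
technical and biological components, estimate how repeatable an
individual host's microbiota is across repeated sampling, and call
per-taxon differential abundance from posterior contrasts — all from one
model fitted to the whole ASV-by-sample table.

## Who this is for

Ecologists and microbiome researchers with an amplicon sequence variant
(ASV) count table, per-sample metadata (host, season/age/treatment) and,
optionally, a taxonomy table. Typical questions: how much of the
variation in composition is library size versus real biology? Do
individuals keep a recognisable microbiota across seasons? Which taxa
shift between groups, and in which direction?

## The model

Each cell of the count table is one observation. The read count of ASV
*a* in the sample from host *h* at group level *g* is modelled as
over-dispersed Poisson with a log link:

```
log lambda = b0 + b_g + u_h + u_a + u_{h:g} + u_{a:h} + u_{a:g} + u_{a:h:g}
u_t ~ N(0, sigma2_t)
```

Host, ASV and sample (`h:g`) terms absorb technical variation (the
row-level `a:h:g` term carries over-dispersion); `a:h` captures
consistent host-specific taxon abundances and `a:g` taxon-by-group
shifts. From the posterior the package computes:

* a **variance partition** per draw, with the Poisson
  distribution-specific component `omega = ln(1 + 1/lambda_bar)`,
  `lambda_bar = exp(b0 + sum(sigma2)/2)` (Nakagawa–Schielzeth), so the
  shares sum to one in every draw and carry credible intervals;
* **repeatability**
  `R = sigma2_{a:h} / (sigma2_{a:g} + sigma2_{a:h} + sigma2_{a:h:g})`;
* **differential abundance** per ASV as the posterior contrast
  `u_{a,g2} - u_{a,g1}` with a highest posterior density interval
  (HPDI); a shift is robust when the interval excludes zero;
* a **zero-adequacy ratio** (observed / posterior-predicted zeros) and
  MCMC diagnostics (ESS, autocorrelation, R-hat);
* a **centered log-ratio (CLR)** alternative: Gaussian-family fits on
  CLR-transformed abundances for compositional analysis.

Sampling runs in compiled code (Metropolis-within-Gibbs with
likelihood-invariant sweep moves along the intercept/term-mean
directions; fully conjugate Gibbs for the Gaussian family) and is
exactly reproducible from a seed.

## Worked example

Simulate a repeated-measures study from the model's own generative form
(12 hosts sampled in both of 2 groups, 50 ASVs, known variance
components, 10% of ASVs spiked by ±1.5 on the log scale), then fit and
summarise:

```r
library(microglmm)

cfg <- synth_config(n_hosts = 12, n_asvs = 50, beta0 = 2,
                    sigma2 = c(asv = 1.0, "host:group" = 0.1,
                               "asv:host" = 0.5, "asv:group" = 0.2,
                               residual = 0.5),
                    spike_fraction = 0.1, spike_delta = 1.5, seed = 7)
sim <- simulate_dataset(cfg)
obs <- assemble_long(sim$counts, sim$meta, sim$tax)

ps <- fit_glmm(obs, spec_for_synth(cfg), prior_spec(),
               mcmc_config(6000, 1500, 5, 2, seed = 1))
partition_variance(ps)
```

```
                  term sigma2_mean sigma2_lower sigma2_upper prop_mean
1               asv_id      1.0194       0.5461       1.5395    0.4253
2        host_id:group      0.0652       0.0197       0.1250    0.0277
3       asv_id:host_id      0.4258       0.3263       0.5372    0.1819
4         asv_id:group      0.2860       0.1558       0.4287    0.1220
5 asv_id:host_id:group      0.5372       0.4500       0.6191    0.2299
6         distribution      0.0305       0.0175       0.0418    0.0133
```

The posterior means sit on the simulated truths (1.0, 0.1, 0.5, 0.2,
0.5): about 43% of latent-scale variance is between-taxon abundance,
18% is consistent host-by-taxon structure, 12% is taxon-by-group shifts
(inflated above its generative share by the spiked taxa), and only ~3%
is per-sample library size.

```r
repeatability(ps)
#> repeatability R = 0.3413  [95% HPDI 0.2625, 0.4121]

da <- differential_abundance(ps, "asv_id:group", "G1", "G2", tax = sim$tax)
summarize_shifts(da, "Phylum")
#> 15 of 50 ASVs robust (30.00%): 9 positive (60.00%), 6 negative (40.00%)

predicted_zero_ratio(ps)
#> [1] 0.953
```

A zero ratio near 1 says the over-dispersed Poisson accounts for the
zeros in this table. All 5 spiked-up and most spiked-down ASVs are in
the robust set with the correct sign.

Real data enter through `read_count_matrix()` (wide TSV or BIOM),
`read_metadata()` and `read_taxonomy()`; `make_2016_spec()` /
`make_2013_spec()` give the repeated-measures and single-sample model
templates, and `run_clr_pipeline()` is the compositional route. A
command-line interface wraps the workflow
(`exec/microglmm simulate|fit|diffabund|clr-fit|diagnose --config
cfg.yaml`), writing plain TSV/JSON outputs that are byte-identical
across reruns with the same seed.

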