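# burstfit

Tools for analysing stochastic gene expression from single-cell mRNA
copy-number data (smFISH / RNA-FISH counts), built around the telegraph
model of transcriptional bursting with an extrinsic-noise extension.

## Who this is for

Groups counting transcripts per cell for a gene of interest — typically
a few hundred to a thousand cells per strain and replicate — who want
to ask: how often does this promoter burst, how large are the bursts,
how much of the observed cell-to-cell variability is intrinsic to the
promoter versus inherited from upstream regulators, and does variability
in one gene demonstrably propagate to another?

## The model

In the bursty limit of the two-state promoter (telegraph) model the
stationary mRNA copy number is negative binomial with shape equal to
the normalized burst frequency $r = \lambda/\delta$ and success
parameter $b/(1+b)$ with burst size $b = K/\nu$, so the mean is $rb$
and the variance $rb(1+b)$. Extrinsic noise is modelled as cell-to-cell
variation of the burst frequency: each cell draws its own $r$ from a
log-normal distribution with mean $\bar r$ and SD $\sigma_r$, giving
the compound distribution

$$q(n) = \int_0^\infty \mathrm{NB}\!\left(n; r, \tfrac{b}{1+b}\right)\,
\mathrm{LogNormal}(r; \bar r, \sigma_r)\,dr,$$

with variance $\bar r b(1+b) + b^2\sigma_r^2$ by the law of total
variance. The package provides:

* `fit_telegraph()` — Bayesian MCMC fit of $(\bar r, b, \sigma_r)$
  (affine-invariant ensemble sampler, log-uniform priors), returning a
  classed model object with `coef()` (MAP), `confint()` (credible
  intervals), `summary()`, `plot()`, `simulate()`, `logLik()`,
  `residuals()` methods;
* `extrinsic_fraction()` / `posterior_noise_decomposition()` — the
  intrinsic/extrinsic variance split
  $e = b\sigma_r^2 / (\bar r(1+b) + b\sigma_r^2)$ with its posterior
  (mode and 68% interval over 4,000 posterior triplets);
* `plugin_entropy()`, `plugin_mutual_information()`,
  `permutation_significance()` — mutual information in bits between
  paired per-cell counts of two genes, with a seeded permutation null;
* `false_positive_threshold()`, `unit_intensity()`,
  `calibrate_spots()`, `integrate_copy_numbers()` — conversion of raw
  smFISH spot intensities into per-cell copy numbers using
  zero-expression and low-expression controls;
* `sample_compound()`, `gillespie_telegraph()`,
  `simulate_coupled_pair()`, `simulate_spot_table()` — seeded
  synthetic-data generators for every stage, including an exact
  stochastic simulation of the full telegraph scheme;
* `run_single_gene()` / `run_pair()` and a thin command-line wrapper
  (`inst/scripts/burstfit-cli.R`) for batch analyses over count
  tables, with JSON + TSV reports.

## Worked example

Simulate a bursty gene with extrinsic noise, fit it, and decompose the
variance:

```r
library(burstfit)

counts <- sample_compound(telegraph_params(burst_freq = 2,
                                           burst_size = 10,
                                           freq_sd = 1),
                          n_cells = 1000, seed = 42)
fit <- fit_telegraph(counts, fit_config(n_steps = 600, n_burn = 200,
                                        n_walkers = 16, seed = 1))
summary(fit)
#> Compound bursty-transcription model: 1000 cells, mean 19.72, variance 311.27
#>               MAP  lower   upper   rhat
#> burst_freq 2.2851 1.1891  3.2240 1.0376
#> burst_size 8.6176 6.0626 16.8585 1.0344
#> freq_sd    1.3070 0.0016  2.2855 1.0302
#> 6400 posterior samples; acceptance rate 0.57; 95% equal-tailed intervals
```

The MAP estimates recover the generating burst frequency (2), burst
size (10) and frequency SD (1) within the 95% credible intervals. The
variance decomposition propagates the posterior into the extrinsic
fraction:

```r
posterior_noise_decomposition(fit, n_triplets = 4000, seed = 2)
#> Variance decomposition (law of total variance over burst frequency):
#>   intrinsic: 189.4   extrinsic: 126.9   total: 316.3
#>   extrinsic fraction e = 0.4011
#>   posterior: e_map = 0.025, 68% CI [0.001132, 0.4553] (4000 triplets)
```

At the MAP triplet about 40% of the variance is extrinsic; the wide
68% interval (and the near-zero posterior mode) reflects a real
limitation discussed in the vignette — at a thousand cells, moderate
extrinsic noise is only weakly distinguishable from a slightly larger
burst size, and the scale-free prior resolves that ambiguity
conservatively. Strong extrinsic noise ($e \gtrsim 0.8$) is recovered
decisively.

Mutual information between a regulator and its target, with a
permutation null:

```r
pair <- simulate_coupled_pair(telegraph_params(2, 5, 0.5),
                              telegraph_params(1, 8, 0.3),
                              coupling_spec(exponent = 1,
                                            reference_count = 10),
                              n_cells = 500, seed = 3)
permutation_significance(pair, n_shuffles = 10000, seed = 4)
#> Mutual information: upstream vs downstream (500 cells)
#>   MI = 1.548 bits  (H_a = 4.717, H_b = 4.194 bits)
#>   permutation p = 0 (10000 shuffles; null 1.14 +/- 0.03122)
```

The observed MI sits far above the shuffled null (1.14 ± 0.03 bits —
note the plug-in estimator's bias appears in the null too, which is
why the test is calibrated), so noise propagation from the upstream
gene is detected; with `exponent = 0` the same analysis returns a
non-significant p-value.

## Further reading

The methods vignette
(`vignettes/bursty-transcription-noise.Rmd`) documents the model and
its assumptions, the quadrature and sampler design, what the synthetic
data do and do not emulate, and known limitations.
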