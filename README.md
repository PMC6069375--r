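# fosemg

Estimation of isometric elbow force from high-density surface
electromyograms (HD-SEMG), for researchers in biomedical signal processing,
sports biomechanics and rehabilitation engineering who want an EMG-driven
force model with a transparent, testable pipeline.

## The method

Two 4 × 8 electrode grids record the biceps brachii (agonist) and triceps
brachii (antagonist) at 1000 Hz while the subject ramps the elbow force
linearly to a target over 3 s and holds it for 3 s. Each grid signal
`S (m × t)` is reduced to one nonnegative **activation signal** per muscle,
either by averaging all channel envelopes (the AVG-ENVLP baseline) or by
factorizing

```
S ≈ W H
```

into spatial activation patterns `W (m × n)` and temporal activation curves
`H (n × t)` — with PCA, FastICA, or nonnegative matrix factorization — and
summing the curves. The activation signals `H_BI` and `H_TR` then drive a
**fast orthogonal search** (FOS) regression: the force is modeled as

```
y(t) = Σₘ aₘ pₘ(t) + e(t)
```

where the basis functions `pₘ` are chosen greedily from a 14-function pool
(bias; `H_BI`, `H_TR`, `H_BI·H_TR`; squares and cubes; square roots;
sigmoids), each step orthogonalizing the remaining candidates
(Gram–Schmidt) and selecting the one with the largest mean-square-error
reduction, until 7 functions are in the model or the best remaining
candidate would improve the training RMSD by less than 0.2 percentage
points. Performance is reported as RMSD (percent of peak force) and R²
under leave-one-repetition-in cross-validation (train on 1 repetition,
test on the other 6).

No public recording accompanies the methodology, so the package ships a
synthetic HD-SEMG generator with known ground truth (trapezoidal activation
curves modulating band-limited carriers, mixed through Gaussian spatial
patterns) that reproduces the protocol and powers the whole test suite.

## Worked example

```r
library(fosemg)

trials <- simulate_trial_set(seed = 42)              # 7 reps, 40% MVC
reps   <- extract_activation_trials(trials, "nmf", seed = 42)

m <- fos_fit(reps[[1]]$force,
             candidate_pool(reps[[1]]$h_bi, reps[[1]]$h_tr))
m
#> <fos_model> dual pool, 2 basis functions, training RMSD 7.971%
#> # A tibble: 2 × 2
#>   term       a
#>   <chr>  <dbl>
#> 1 H_BI   0.963
#> 2 H_TR^3 0.213

summarize_crossval(crossval(reps))
#> # A tibble: 1 × 6
#>   mean_rmsd sd_rmsd mean_r2  sd_r2 n_folds n_failed
#>       <dbl>   <dbl>   <dbl>  <dbl>   <int>    <int>
#> 1      8.93   0.870   0.887 0.0249      42        0
```

The fitted model says the force on this repetition is essentially
`0.96·H_BI + 0.21·H_TR³`: mostly the agonist drive, with a small nonlinear
antagonist correction. Cross-validating over all 7 × 6 train/test pairs
gives a mean error of about 8.9% of peak force with R² ≈ 0.89.

`benchmark_heterogeneity()` runs the packaged comparison (20 simulated
trial sets with disjoint activation regions and unequal channel gains, all
four processing methods, full cross-validation) and returns per-fold
metrics plus a summary table; `autoplot()` methods visualize fitted models
and decompositions, and `tidy()`/`glance()` return them as tibbles.

A thin command-line interface over the same functions is installed with
the package (`system.file("scripts", "fosemg", package = "fosemg")`), with
subcommands `simulate`, `decompose`, `fit`, `predict`, `crossval`,
`benchmark`.

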