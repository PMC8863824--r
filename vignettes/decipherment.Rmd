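---
title: "Deciphering chemical stimuli from ensemble chemotaxis responses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deciphering chemical stimuli from ensemble chemotaxis responses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(desiram)
```

## The problem

A population of *Escherichia coli* cells, tethered to glass by their
flagella, acts as a living chemical sensor. Each flagellar motor switches
stochastically between clockwise (CW) and counterclockwise (CCW) rotation;
an attractant stimulus suppresses CW rotation almost completely
(excitation) and the population then adapts back toward its pre-stimulus
switching statistics over hundreds of seconds. The ensemble **CW bias** —
the fraction of counted rotational motion that is CW in each 1-s bin —
traces out a response whose depth, duration and recovery shape depend on
*which* chemical was applied and at *what* concentration.

`desiram` implements the full decipherment pipeline: given labelled
training traces at several concentrations per chemical, it learns each
chemical's dose-response signature and then infers, for a blind trace, the
posterior probability of each candidate chemical with the unknown
concentration treated as a nuisance parameter and marginalised away.

## Pipeline overview

1. **Traces** (`classify_directions()`, `ensemble_cw_bias()`): per-frame
   angle increments (10-ms frames) are labelled CW/CCW/NONE by a
   7.5°-per-frame motion threshold (the boundary excluded; the threshold is
   more than twice the noise floor of the assay). The ensemble CW bias per
   half-open 1-s bin is `#CW / (#CW + #CCW)` pooled over cells; `NONE`
   frames enter neither count, and a bin with no counted motion is missing
   (`NA`), never imputed.
2. **Template fit** (`fit_template()`): each trace is summarised by a
   six-line geometric template — flat baseline L1 at level `b`, flat
   excitation L2 at level `r` starting at the known stimulus time, three
   linear recovery segments L3–L5 ending at levels `v3, v4, v5`, and a flat
   post-adaptation L6 at `g = v5`.
3. **Characteristic vector** (`template_to_vector()`): the template is
   encoded as 15 indices: `y1` the L2 duration; amplitude, slope and
   duration of each recovery segment (`y2..y10`); the three levels
   `y11 = b`, `y12 = r`, `y13 = g`; the total recovery duration `y14`; and
   the fit RMS `y15`.
4. **Model functions** (`fit_model_functions()`): for each chemical `s` and
   index `i`, ordinary least squares of `y_i` on a polynomial in
   `u = log10(x / 1 mM)` gives the model function `f(x | s, i)` with
   residual scale `sigma[s, i]`.
5. **Posterior** (`posterior()`, `classify()`): the evidence for chemical
   `s` is
   `integral over x of prod_i A(s,i) * exp(-(y_i - f(x|s,i))^2 / (2 sigma[s,i]^2))`,
   and the posterior over chemicals normalises these evidences under a
   uniform prior.
6. **Evaluation** (`loo_accuracy()`, `accuracy_spectrum()`, `rs_rate()`,
   `rs_tail_probability()`, `dsi()`): leave-one-out accuracy against the
   random-selection (RS) baseline, with exact tail probabilities and the
   decrease in self-information (DSI) in bits.

## What concentration marginalisation implies

The central statistical subtlety is that concentration is unknown at test
time. Any feature difference that amounts to a *shift along a shared dose
slope* is therefore invisible: if two chemicals obey
`y_i = a_s + b * log10(x)` with the same `b` for every informative index,
the likelihood explains an intercept offset by sliding the nuisance
concentration, and the posterior stays flat. Real discrimination comes from
features a concentration shift cannot mimic — different dose *slopes*,
different *shapes* of recovery, and concentration-independent levels. The
shipped synthetic profiles differ in exactly these ways, and the test suite
contains an explicit null: chemicals generated from identical profiles are
classified at chance level.

## Design choices

Several aspects of the procedure are genuinely open and were fixed as
follows; all are exposed as configuration so alternatives can be explored.

* **Amplitude `A(s, i)`** defaults to the Gaussian normalisation
  `1 / (sqrt(2 pi) sigma[s, i])`, making each likelihood factor a proper
  density so that chemicals with different residual scales compare fairly.
  `amplitude_mode = "unit"` preserves the unnormalised reading.
* **Prior over concentration**: uniform in `log10 x` over the chemical's
  training range padded by 0.5 log-units (`prior_measure`, `pad`).
  Log-uniform is the natural scale-free choice for a nuisance spanning
  orders of magnitude; `"linear_uniform"` is available.
* **Quadrature**: trapezoidal on a uniform grid of 201 points in
  `log10 x`, with every product and the quadrature sum accumulated in the
  log domain (log-sum-exp). For smooth, interior-peaked integrands the
  trapezoid rule on a uniform grid is spectrally accurate, and the test
  suite verifies that doubling the grid changes probabilities by less than
  1e-6. Integrands narrower than the grid step (possible when many indices
  are informative and residual scales are tiny) would need a denser grid;
  `grid_points` is the dial.
* **Sigma floor**: `sigma[s, i]` is floored at 5% of the across-training SD
  of index `i` (and at 1e-6). Without a floor, a chemical whose few
  training records happen to lie on a line collapses to a delta-function
  likelihood and breaks leave-one-out evaluation at small n.
* **Template fitting**: `t1` is pinned to the known stimulus time
  (solution exchange is experimental metadata, not a parameter), and the
  excitation level `r` is constrained to `[0, 0.2]` because attractant
  responses drive CW bias to approximately zero. The baseline `b` is the
  pre-stimulus mean. For fixed breakpoints the remaining levels solve a
  box-constrained linear least-squares problem; breakpoint durations are
  searched on a 25-s coarse grid, then on progressively finer local grids
  down to 5-s steps, then polished by Nelder-Mead. A single 5-s grid over
  four coupled durations would cost millions of solves; the
  multi-resolution descent reaches the same optimum (the suite checks the
  fitted objective never exceeds the true template's objective on noisy
  data) deterministically in under a second per trace. The Nelder-Mead
  polish is accepted only on strict improvement, so degenerate flat fits
  keep their exact grid solution. Monotone recovery is *not* enforced:
  overshoot of the baseline is real and allowed.
* **Index definitions `y5`–`y15`**: the semantics of `y1`–`y4` (L2
  duration; L3 amplitude, slope, duration) are fixed; the remaining indices
  follow the same amplitude/slope/duration pattern for L4 and L5 plus the
  three levels, total recovery time and fit RMS. This is a documented,
  self-consistent completion of the index set; `template_to_vector()` is
  the single place it lives, so an alternative 15-tuple can be substituted.
* **Exact tail probabilities**: the probability that uniform guessing among
  `N` chemicals reaches an observed accuracy is a binomial tail whose terms
  (`choose(n, j) * (N-1)^(n-j)`) overflow doubles long before the
  probability underflows. `rs_tail_probability()` sums the tail in exact
  integer arithmetic (a minimal base-1e7 big-integer routine) and converts
  only the final ratio to double; `ceiling(accuracy * n)` successes defines
  the tail. The RS standard deviation is defined by Monte Carlo
  (`rs_sd_mc()`), with the closed-form binomial SD as its oracle in tests.
* **Leave-one-out**: each held-out vector is classified with model
  functions *refit from scratch* on the remaining records — not merely
  re-normalised — so the reported accuracy is honestly out-of-sample.

## The synthetic tethered-cell generator

No per-cell experimental recordings are publicly deposited, so the package
ships a generator (`chemical_profile()`, `simulate_cell()`,
`simulate_ensemble()`, `simulate_training_set()`) that reproduces the
statistical structure the pipeline relies on:

* **Baseline switching**: a two-state CW/CCW Markov chain at 10-ms frame
  resolution. Per-frame transition probabilities are chosen so that the
  stationary CW fraction equals the cell's target bias and the mean run
  length equals `dwell_mean` (default 1 s): `tau_CW = 2 * dwell_mean * p`,
  `tau_CCW = 2 * dwell_mean * (1 - p)`. Switching statistics of real motors
  are not part of the published summary; `dwell_mean` is configuration.
* **Cell-to-cell variability**: each cell draws its baseline bias from a
  Beta distribution (mean 0.3, concentration 25) and scales its excitation
  duration by a lognormal factor with unit median and coefficient of
  variation `cell_cv` (default 0.3 — a deliberate guess at the strong
  heterogeneity seen in single-cell recordings, exposed as configuration).
* **Excitation**: at the stimulus, rotation is forced CCW for
  `max(0, (tau0 + beta * log10(x)) * eps)` seconds — excitation duration
  grows linearly with log concentration, the package's generative
  counterpart of the observed dose dependence.
* **Recovery**: the target CW probability then follows a piecewise-linear
  schedule (three segments with configurable duration shares and level
  fractions) toward baseline plus an optional overshoot.
* **Missing motion**: each emitted frame is independently replaced by
  `NONE` with probability 0.1. Real sub-threshold frames are likely
  autocorrelated (pauses cluster); i.i.d. thinning is an accepted
  simplification and is the main known gap between generator and assay,
  along with the absence of preparation-to-preparation batch effects and
  of any receptor-level saturation nonlinearity. Passing tests therefore
  demonstrate that the *pipeline* is correct and well-calibrated on data
  with realistic variability — not that the shipped profiles quantitatively
  match any particular chemical's real response.

Seeds are counter-based: one root seed plus (trace, cell) indices determine
every cell's stream, so enlarging `n_cells` never reshuffles earlier cells
and whole training sets are bit-reproducible.

The six shipped profiles use the assay's published training concentration
ranges verbatim (e.g. l-Ser 0.001–0.05 mM, l-Glu 0.01–50 mM) with distinct
excitation/recovery parameters chosen to give clearly separable but
overlapping responses; two additional "beverage" profiles are nearly
identical in shape (excitation durations within 10%) and differ mainly in
dose slope, emulating discrimination of two very similar complex samples.

## Problem sizes and what the checks show

The package's own evaluation (test suite and `scripts/acceptance.R`) uses
16 traces per chemical (4 concentrations x 4 replicates) with 50 cells per
trace at the full 600-s, 10-ms-frame resolution — sizes chosen so the whole
evaluation runs comfortably on a laptop while keeping per-trace sampling
noise realistic. Under those conditions the six-way leave-one-out accuracy
of the shipped profiles sits around 0.4 (random selection: 0.167), a DSI of
roughly 1.2–1.3 bits, and the six-identical-profiles control sits at
chance. Template round-trips recover noiseless traces essentially exactly,
and with bias noise of SD 0.02 recover levels to ~0.02 and breakpoints to
~10 s (median) — the residual scatter is the statistical uncertainty of the
least-squares optimum, not search error.

## Known limitations

* Indices `y5`–`y15` beyond the fixed `y1`–`y4` semantics are this
  package's own completion of the vector; other choices are possible.
* The RS standard deviation and tail probability are defined here by the
  binomial model of uniform guessing; other published definitions of these
  baselines exist and do not always coincide numerically.
* Single-cell template fits, nonparametric trace smoothing, and mechanistic
  chemotaxis signalling models are out of scope.
* `fit_template()` requires the stimulus time as metadata and at least 20
  non-missing bins.
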