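---
title: "Classifying multichannel time series with wavelet variances and correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying multichannel time series with wavelet variances and correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(wavediscr)
```

## The problem and the model

Motor-imagery EEG experiments produce labelled collections of trials, each
trial a matrix of channels by time samples (here typically 63 channels,
5.5 s at 1000 Hz). Two imagined movements — e.g. clenching a fist versus
wiggling the toes — leave different signatures in the band-limited power of
individual channels and, crucially, in the band-limited *coupling between
channels*. Univariate feature sets discard that coupling; `wavediscr`
implements a multivariate pipeline that keeps it:

1. **Per-channel normalisation.** Each channel is z-scored,
   $(x - \bar x)/\sigma_x$, so all downstream features are invariant to
   per-channel gain. We use the population convention ($\sigma$ with
   divisor $n$); any consistent convention yields identical features.

2. **MODWT decomposition.** Each channel is decomposed with the maximal
   overlap discrete wavelet transform. Given a DWT scaling/wavelet filter
   pair $(g, h)$ of length $L$, the MODWT uses the rescaled pair
   $(\tilde g, \tilde h) = (g/\sqrt2, h/\sqrt2)$ and produces, at every
   level $j$, coefficient series of the *same length* $N$ as the input via
   circular filtering,
   $$\widetilde W_{j,t} = \sum_{l=0}^{L_j-1} \tilde h_{j,l}\, X_{t-l \bmod N},
   \qquad L_j = (2^j - 1)(L - 1) + 1 .$$
   Unlike the decimated DWT, the transform is shift-equivariant and exactly
   energy-preserving, $\sum_j \|\widetilde W_j\|^2 + \|\widetilde V_J\|^2 =
   \|X\|^2$; both properties are asserted in the test suite at
   $10^{-8}$ relative tolerance or better. Level $j$ captures the octave
   band $\approx [f_s/2^{j+1},\, f_s/2^j]$ Hz. Six filters are built in
   (`haar`, `d4`, `d6`, `d8`, `la6`, `c6`); the length-6 least-asymmetric
   (symlet) filter coincides with `d6`, a known property of the symlet
   family below length 8, so the two names select numerically identical
   decompositions.

3. **Features.** For each channel and level, the *wavelet variance*
   $$\hat V^2_{X,j} = \frac1{M_j}\sum_{t=L_j-1}^{N-1} \widetilde W^2_{X,j,t},
   \qquad M_j = N - L_j + 1,$$
   and for each channel pair at the same level the *wavelet correlation*,
   computed as the Pearson correlation of the two channels' non-boundary
   coefficients. The first $L_j - 1$ coefficients at level $j$ are
   contaminated by the circular wrap-around and are excluded from both
   estimators. Using the ordinary Pearson form (mean-centred, normalised
   by the same $M_j$ in numerator and denominator) guarantees
   $|\rho| \le 1$; a literal reading of the printed estimator, which mixes
   an unnormalised cross-product with averaged variances, does not.
   For $P$ channels and $J$ levels the candidate catalog holds
   $J\,(P + P(P-1)/2)$ features — 22,176 at $P = 63$, $J = 11$.

4. **Stepwise selection by the Lawley–Hotelling trace.** With $n$ trials in
   $g$ groups, the discriminant power of a feature subset is
   $$V = (n - g)\,\mathrm{tr}\!\left(W^{-1} B\right),$$
   where $W$ is the within-groups sum-of-cross-products matrix and
   $B = \sum_k n_k (\bar X_k - \bar X)(\bar X_k - \bar X)^\top$ the
   between-groups counterpart. Starting from the empty set, the greedy
   loop adds at each step the candidate whose inclusion maximises $V$,
   until `n_variables` features are selected. The $V$ trajectory is
   non-decreasing and the greedy path is nested: the selection of size 20
   is a prefix of the selection of size 40 on the same data, which the
   parameter sweep exploits.

5. **Classification and validation.** A Gaussian discriminant with equal
   class priors — pooled covariance (linear) or per-class covariance
   (quadratic) — is evaluated by leave-one-out cross-validation, tallied
   into a confusion matrix, and summarised as accuracy, sensitivity,
   specificity, precision and F-measure. Metrics with a zero denominator
   are reported as `NA`, never coerced to 0.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `filter` | `"d6"` | wavelet filter; longer filters have better band separation but wider boundary regions ($L_j$ grows with $L$) |
| `n.levels` | max safe | number of octave levels $J$; capped by default at the largest $J$ with $M_j \ge 2$ so every level supports a variance estimate |
| `type` | `"both"` | candidate features: variances, correlations, or both |
| `n_variables` | 20 | selected features; 20–60 is the regime the sweep explores |
| `kind` | `"linear"` | pooled vs per-class covariance |
| `shrinkage` | `1e-4` | diagonal covariance regularisation $(1-\lambda)S + \lambda\,\mathrm{diag}(S)$, keeps LOOCV folds stable when $q$ approaches $n$ |
| `selection` | `"whole"` | where feature selection runs relative to LOOCV (see below) |

Requesting `n.levels` beyond the safe bound
$J < \log_2(N/(L-1) + 1)$ warns rather than fails — the transform is still
defined, but the extra levels consist entirely of boundary-affected
coefficients, and feature extraction refuses levels with $M_j < 2$.

## Selection placement and what LOOCV can promise

With `selection = "whole"` (the default, matching the procedure the method
is usually run with) the stepwise selection sees all trials, and LOOCV
cross-validates only the classifier. On data with real class structure
this is the configuration of interest; on *null* data it is optimistically
biased, because the selection has already mined $\sim 10^2$–$10^4$
candidate features for chance separation. `selection = "within_folds"`
re-runs the selection inside every fold on the training trials only and is
the honest estimate of generalisation; it is what the package's own
chance-level calibration checks use.

Two caveats that the test suite makes explicit:

* Even within-fold LOOCV accuracy on null data is not binomial: the $n$
  folds share $n-2$ training trials and tend to select overlapping feature
  sets, so fold outcomes are strongly positively dependent. Across
  replicate null datasets the spread of LOOCV accuracy is several times
  the binomial standard error, and a nominal binomial band around 0.5 will
  reject an unbiased pipeline far more often than its nominal level. The
  calibration test in this package uses one fixed-seed dataset and a 99%
  binomial band and is therefore a coarse screen, not a calibrated test.
* Plain LOOCV of a nearest-mean-type classifier is slightly pessimistic on
  null data (removing a trial shifts its own class mean away from it), an
  effect that per-fold selection amplifies. Below-chance accuracy on null
  data is thus expected behaviour, not a bug.

## The synthetic generator

The study's EEG recordings are not redistributable, so the package ships a
seeded generator that emulates the statistical structure the classifier
exploits, with a `"study"` profile (200 trials/class, 63 channels, 5500
samples at 1000 Hz) mirroring the recording geometry and a `"test"`
profile (8 channels, 512 samples) for fast suites. Each trial is white
Gaussian noise per channel; a configured coupled pair additionally
receives a shared band-limited latent source — order-4 Butterworth
band-passed white noise, redrawn per trial, scaled to unit sd — added to
both channels with a class-dependent amplitude expressed in noise-sd
units. A coupling amplitude $c$ therefore produces an in-band wavelet
correlation of roughly $c^2/(c^2 + \beta)$, where $\beta$ is the fraction
of the white-noise power falling in the band ($\approx 0.125$ for the
60–120 Hz band at 1000 Hz), i.e. $\approx 0.85$ at $c = 0.9$ — an effect
chosen to sit well above the detection threshold at 40 trials/class.
Power effects add an independent band-limited component to a single
channel, shifting its wavelet variance at the matching levels.

The generator reproduces: band-limited cross-channel coupling, band-power
differences, exact label balance, and bit-identical output under a fixed
seed. It deliberately does **not** reproduce: the $1/f$ spectral shape of
EEG, volume conduction (which correlates *all* channel pairs), artifacts,
non-stationarity within a trial, or inter-subject variability. Passing
tests on synthetic data therefore demonstrate that the pipeline recovers
the kind of structure it is designed for; they do not certify performance
on real recordings.

## Numerical choices

* **Filter conventions.** Scaling coefficients $g$ are the standard
  published tables ($\sum g = \sqrt 2$, unit energy); $h$ is derived by
  the quadrature-mirror rule $h_l = (-1)^l g_{L-1-l}$. The rescaling to
  $(\tilde g, \tilde h)$ divides *both* filters by $\sqrt 2$; this is the
  only convention under which the energy-preservation identity holds, and
  the suite verifies it to $10^{-8}$ relative.
* **Singularity handling in selection.** A candidate whose augmented $W$
  has reciprocal condition number below $10^{-12}$ is skipped at that step
  and recorded; with $p \gg n$ exact collinearity among correlation
  features is common. $W^{-1}B$ is evaluated by a linear solve, never an
  explicit inverse. For speed, $W$ and $B$ of any subset are taken as
  submatrices of the full-catalog SSCP matrices, computed once per
  selection run; equivalence with the direct per-subset definition is
  enforced by brute-force oracle tests.
* **Tie-breaking.** Candidates within relative $10^{-9}$ of the running
  maximum do not displace it, so ties resolve to the lowest catalog index
  and the procedure is deterministic.
* **Degenerate inputs.** Constant channels raise a zero-variance error
  naming channel and trial; non-finite samples are rejected; a constant
  coefficient segment makes the correlation undefined (error, not 0 or 1).

## Problem sizes used by the test suite

The suite builds all fixtures in code at small scale: oracle equivalence
on series of length $\le 64$ at $\le 3$ levels; selection oracles on
$p \le 6$, $n \le 40$; pipeline checks on 8-channel, 512-sample datasets
with 24–100 trials; the sweep demo on 6 channels. The full suite runs in
well under a minute; the acceptance script's from-scratch run (80-trial
coupled recovery plus 100-trial within-fold null calibration) takes a few
seconds. The study-scale profile (63 channels, 400 trials) is available in
the generator for users who want it but is not exercised by the tests.

## Known limitations

* Only two-class confusion-matrix evaluation is wired into LOOCV, though
  the Lawley–Hotelling machinery accepts $g \ge 2$ groups.
* The greedy forward path has no backtracking; with variances and
  correlations mixed it can select a set whose LOOCV accuracy trails the
  correlations-only path, and no remedy (floating/backward steps) is
  implemented.
* Wavelet correlations are estimated within a level only; cross-level
  coupling is invisible to the feature set.
* The number of selected variables is a user choice; no stopping criterion
  based on the $V$ gain is applied (steps with negligible gain are merely
  reported).
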