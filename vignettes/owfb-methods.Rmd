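---
title: "Designing spectral-localization-optimal wavelet filter banks and the ECG screening pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing spectral-localization-optimal wavelet filter banks and the ECG screening pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(owfb)
```

## The model

A two-channel orthogonal wavelet filter bank is determined by its analysis
low-pass filter $a_0(n)$, $n = 0,\dots,N-1$. The bank is orthonormal (and
hence perfectly reconstructing) iff the double-shift orthonormality
conditions $\sum_n a_0(n)a_0(n-2m) = \delta(m)$ hold, and it is *regular of
order $M$* when $A_0(z)$ carries $M$ zeros at $z=-1$, so that details of
polynomial trends up to degree $M-1$ vanish.

Among all such banks, `owfb()` selects the one whose low-pass filter has
minimal **mean squared spectral localization**,
$$
\sigma_f^2 \;=\; \frac{1}{\pi E}\int_0^{\pi} f^2\,\lvert
A_0(e^{jf})\rvert^2\,df ,
$$
the second moment of the energy spectrum about DC ($E$ is the filter
energy). Small $\sigma_f^2$ concentrates the low-pass response at low
frequencies without having to pick band edges a priori, which is why this
criterion suits ECG sub-band analysis: the transform adapts its roll-off
instead of being told where the stop band is.

### Convexification over the product filter

In $a_0$ the constraints are quadratic. The standard route to a convex
program is the *product filter* $P(z) = A_0(z)A_0(z^{-1})$ with
autocorrelation coefficients $p(m) = \sum_n a_0(n)a_0(n+m)$:

* orthonormality becomes the **half-band** property $p(0)=1$,
  $p(2m)=0$;
* $M$-fold regularity becomes a zero of order $2M$ of
  $P(e^{jf})$ at $f=\pi$, i.e. $P(\pi) = 0$ together with the vanishing of
  the even derivatives $\sum_m (-1)^m m^{2k} p(m) = 0$ for
  $k = 1,\dots,M-1$ (odd derivatives vanish by symmetry);
* the objective is **linear**: $\sigma_f^2 = \sum_m s(m)\,p(m)$ with
  $s(0)=\pi^2/3$, $s(m) = -4/m^2$ for odd $m$, $0$ otherwise;
* what remains is the semi-infinite constraint $P(e^{jf}) \ge 0$, which the
  Kalman–Yakubovich–Popov lemma converts into a finite one: $P \ge 0$ on
  the circle iff $p(m) = \sum_n Z_{n,n+m}$ for some symmetric positive
  semidefinite $Z \in \mathbb{R}^{N\times N}$.

The design problem is thus a small semidefinite program: minimize
$s^\top p$ over $Z \succeq 0$ subject to the linear half-band and
regularity constraints on its diagonal sums.

### The interior-point solver

No SDP machinery is assumed; `design_product_filter()` implements a
log-determinant barrier method directly, with one structural refinement
that the problem demands. Because every feasible $P$ has a zero of order
$2M$ at $\pi$, every feasible $Z$ annihilates the alternating moment
vectors $u_k = ((-1)^n n^k)_{n}$, $k < M$ — the feasible set touches the
boundary of the cone everywhere and no strictly feasible point exists.
The solver therefore performs **facial reduction** first: it writes
$Z = QYQ^\top$ with $Q$ an orthonormal basis of
$\mathrm{span}\{u_0,\dots,u_{M-1}\}^\perp$ and optimizes over
$Y \in \mathbb{S}^{N-M}$. On this face the regularity constraints hold
automatically, only the $N/2$ half-band constraints remain, and the
projection of the scaled identity onto them is strictly positive definite
for every admissible $(N, M)$ — a valid interior starting point.

From there the solver follows the central path of
$\min\, \langle F, Y\rangle - \mu \log\det Y$ (damped Newton steps in the
constraint null space, Armijo backtracking that maintains positive
definiteness, $\mu$ reduced geometrically from $1$ to $10^{-12}$). The
final duality-gap bound $\mu\,(N-M)$ sits well below the default
`solver_tolerance` of $10^{-9}$; if Newton ever stalls the result is
flagged `"inaccurate"` rather than returned silently. When $M = N/2$ the
constraints determine $p$ completely (the maximally regular, Daubechies,
solution) and the barrier phase reduces to centering.

Two invariants tie the solver output back to the analytic model and are
tested continuously: the linear objective $s^\top p$ agrees with adaptive
quadrature of the defining integral to $10^{-9}$, and the achieved MSSL
never exceeds that of the same-length Daubechies filter (computed
independently from its closed-form binomial spectrum), since the latter is
a feasible point.

### Spectral factorization

`spectral_factorize()` recovers $a_0$ from $p$ in three steps chosen for
numerical robustness:

1. **Analytic deflation.** The known factor $(1+z)^{2M}$ is divided out
   exactly, so the zero moments of the final filter are inherited from an
   exact binomial factor rather than from root finding near $z=-1$.
2. **Lift and root split.** The deflated remainder $R$ is lifted by
   $\max(0, -\min_f R) + \texttt{psd\_epsilon}$ (default $10^{-10}$) to
   absorb solver round-off; applying the lift to $R$ rather than to $p(0)$
   keeps the zero-moment factor exact. Its roots then split strictly
   across the unit circle and the minimum-phase half (all roots inside) is
   selected — a deterministic, reproducible choice among the $2^{\deg R}$
   possible factorizations.
3. **Gauss–Newton polish.** Root extraction near double roots is accurate
   only to roughly the square root of machine precision, so the deflated
   factor is refined against the designed autocorrelation while the
   binomial factor stays fixed. This drives the factorization residual
   $\max_m |\hat p(m) - p(m)|$ to the $10^{-15}$ level without touching
   the zero moments.

Conventions, stated because they fix signs and alignments everywhere
downstream: DC gain $\sum_n a_0(n) = \sqrt 2$ (equivalently $P(1) = 2$);
$a_1(n) = (-1)^n a_0(N-1-n)$, $b_0 = \mathrm{rev}(a_0)$,
$b_1(n) = (-1)^{n+1}a_0(n)$ (quadrature conjugation); analysis correlates
with the filter and keeps even-indexed outputs; synthesis is the exact
transpose.

## The transform

`subband_decompose()` iterates the two-channel split five times (by
default) on the approximation branch with **periodic extension**, the one
boundary rule under which the critically sampled transform is exactly
orthonormal: energy bookkeeping is exact and reconstruction is an
identity, both to round-off. A pleasant consequence of the half-band
structure is that periodized orthonormality survives even when a band
becomes shorter than the filter — aliasing in the circular autocorrelation
lands only on even lags, which vanish. Epoch lengths must be divisible by
$2^{\text{levels}}$; the 5-minute, 128 Hz epochs of the screening pipeline
(38\,400 samples) divide evenly, with band lengths
19200/9600/4800/2400/1200/1200.

Band numbering follows frequency from the top: SB1 is the level-1 detail
(nominally 32–64 Hz at 128 Hz sampling), SB5 the level-5 detail (2–4 Hz),
SB6 the level-5 approximation (0–2 Hz).

## Features

**Log-energy** is $\log \sum_n r(n)^2$ per band; the natural logarithm is
the default and base 10 is available, the choice being a constant factor
absorbed by any linear index downstream. For an orthonormal bank the band
energies partition the epoch energy, so $\sum_b e^{\mathrm{LOGE}_b}$
recovers the total — a property the tests exploit as an oracle.

**Signal fractal dimension** summarizes the roughness of a band's graph.
The default estimator is a variation-form box count: the graph is affinely
normalized into the unit square, and at each dyadic box side $m = 2^{-k}$,
$k = 3,\dots$, the occupied-box count of a column is measured as the
column's amplitude extent (of the interpolated polyline, including the
values at column boundaries) divided by $m$; the dimension is the
least-squares slope of $\log P_m$ against $\log(1/m)$, clamped to
$[1, 2]$. Two departures from the textbook floor-to-whole-boxes count are
deliberate. Counting whole boxes adds one box per column at every scale,
a baseline that flattens the regression at coarse scales and biases the
slope toward 1; using the extent itself removes it, and makes a straight
line score exactly 1 and the estimate exactly amplitude-scale invariant.
And the scale set stops while columns still contain at least 32 samples
(where the length permits; never finer than $2^{-9}$, never fewer than
three scales), because column extents estimated from a handful of samples
undercount systematically. On fixed-seed midpoint-displacement traces with
Hurst exponent $H = 0.5$ the estimator lands within $0.1$ of the
theoretical graph dimension $2 - H$, which is what the test suite checks.
Katz's and Higuchi's estimators are provided behind
`fractal_dimension(method=)` for comparison, since published magnitudes in
this feature family rarely pin down which estimator produced them.

## Ranking and the diagnosis index

`rank_features_ttest()` applies the two-sided two-sample *t*-test per
feature between the low-risk and high-risk epochs and ranks by $|t|$.
Pooled variance (Student's form) is the default; with strongly unbalanced
cohorts Welch's form is arguably preferable and is available via
`welch = TRUE`, but the pooled form is the package's stated default.
No multiple-testing correction is applied — the statistic is used for
ordering, not inference. A null simulation (both classes from the same
normal, 200 vs 200, 1000 replicates) holds the empirical size at
$0.05 \pm 0.02$, which the acceptance checks recompute.

The hypertension diagnosis index is the fixed linear form
$$
\mathrm{HDI} = 6 - (3\,\mathrm{LOGE}_{SB2} + 4\,\mathrm{LOGE}_{SB3}
  + \mathrm{SFD}_{SB6}) - 15\,(\mathrm{SFD}_{SB2} + \mathrm{SFD}_{SB3}
  + \mathrm{SFD}_{SB4}),
$$
implemented verbatim; its per-feature coefficients
$(-3,-4,-1,-15,-15,-15)$ are recovered exactly by finite differences in
the tests. Classification compares the value against configurable class
ranges (defaults: low-risk $[1.501, 2.355]$, high-risk $[2.774, 6.084]$,
anything else indeterminate) or against a single threshold (default
midpoint of the gap, 2.5645, when threshold mode is chosen).

**A documented inconsistency.** At feature magnitudes typical of Z-scored
38\,400-sample epochs (log-energies of order 10, dimensions in $[1,2]$)
the printed formula produces values around $-150$, far outside the default
operating ranges — evaluated at its own published low-risk feature means
it gives $-163.792$. The formula and the ranges cannot both be taken at
face value; the index as printed is likely a typeset corruption of a
rescaled form. The package refuses to guess: it implements the formula
exactly as written, keeps the ranges as configurable defaults, and offers
the `coefficients` hook of `compute_hdi()` plus the `threshold` rule so
users can substitute a calibrated index without code changes. Range-based
classification of raw pipeline output will therefore typically return
`indeterminate` unless the ranges are re-calibrated to the user's data.

## The synthetic generator

`synthesize_ecg_record()` exists so the repository builds, tests and
demos without any data download. It emulates the gross structure of
multi-channel Holter ECG: a circular train of Gaussian-derivative
QRS-like complexes at a configurable heart rate (128 Hz, three channels
with fixed relative gains 0.7/1.0/1.2) plus stationary AR(1) noise
(coefficient 0.9, configurable amplitude; default `noise_sd = 0.1`
relative to unit QRS amplitude, a mid-range Holter signal-to-noise
choice). Defaults mirror the screening study design: 2 h 10 min 12 s
records (999\,936 samples) that segment into exactly 26 five-minute
epochs, and cohorts of 122 low-risk and 17 high-risk records reproduce
the 3172/442 per-channel epoch counts.

What it does **not** emulate: P/T-wave morphology, heart-rate
variability, arrhythmia, baseline wander, electrode artifacts — and, most
importantly, any class-discriminating difference between the LRHT and
HRHT labels, which are carried as metadata only. Passing tests therefore
demonstrate the correctness of the machinery (design identities,
transform invertibility, estimator calibration, index arithmetic), not
any clinical separation on real recordings. Real-data use goes through
`read_wfdb()` (formats 16 and 80).

## Numerical choices and degenerate inputs

* Solver: path $\mu \to 10^{-12}$, Newton cap 80 steps per $\mu$, ridge
  $10^{-13}\max(\mathrm{diag}\,H)$ on the Newton system, status
  `"inaccurate"` on stall; infeasible specs ($M > N/2$, odd $N$) are
  rejected up front naming the violated family.
* Factorization: root-split failure (double roots too close to pair)
  raises an error instead of returning a wrong filter; spectra dipping
  below `-psd_epsilon` refuse to factorize.
* Z-score uses the population denominator ($1/n$); flatline epochs are
  errors naming the epoch. Trailing partial epochs are discarded, which is
  what makes the cohort counts exact integers.
* Degenerate t-tests (zero pooled variance) report $\pm\infty$ with a
  warning rather than `NaN`; identical groups give $t=0$, $p=1$.
* All-zero bands make log-energy error out by name; constant bands have
  dimension exactly 1.

Problem sizes used by the test and acceptance runs — full-length
38\,400-sample epochs for transform and pipeline checks, 4096-point
midpoint-displacement oracles, a 1000-replicate null calibration, and
cohort totals computed per record — were chosen to exercise the study-scale
arithmetic while keeping a complete run in minutes on one CPU.

## Known limitations

* The design SDP is dense and cubic-ish in $N$; it is instant for the
  filter lengths wavelet practice uses ($N \le 32$) but not written for
  long filters.
* Only single-file, single-format WFDB records (formats 16/80) are read.
* The fractal-dimension estimate, like all box-counting variants, carries
  a small finite-length bias; comparisons should use a fixed estimator
  and length, as the pipeline does.
* The index's default operating ranges are inconsistent with its printed
  formula (see above) and should be treated as placeholders pending
  calibration on the user's own cohort.
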