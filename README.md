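# owfb — spectral-localization-optimal wavelet filter banks for ECG screening

Long-term (Holter) ECG is routinely screened for markers of cardiovascular
risk in hypertensive patients. `owfb` implements one such screening pipeline
built on a custom wavelet transform: the two-channel orthogonal filter bank
is not taken off the shelf but *designed*, by convex optimization, to have
the smallest possible frequency spread in its low-pass filter, and the
resulting sub-band features feed a single linear diagnosis index.

## The design problem

For a length-`N` FIR analysis low-pass filter `a0` with unit energy, the
**mean squared spectral localization** (MSSL) is the second moment of its
energy spectrum about DC,

    sigma_f^2 = (1 / (pi E)) * Int_0^pi f^2 |A0(e^{jf})|^2 df .

`owfb` minimizes `sigma_f^2` subject to

* **orthogonality** — the double-shift orthonormality conditions
  `sum_n a0(n) a0(n-2m) = delta(m)`, which make the two-channel bank a
  perfect-reconstruction orthonormal transform, and
* **regularity** — `M` zero moments, i.e. `2M` zeros of the product filter
  at `z = -1`, so the wavelet annihilates polynomials up to degree `M-1`.

In terms of the half-band product filter `P(z) = A0(z) A0(z^-1)` the
objective is a *linear* functional `sigma_f^2 = s . p` of the
autocorrelation sequence `p`, and the semi-infinite nonnegativity constraint
`P(e^{jf}) >= 0` becomes, by the Kalman–Yakubovich–Popov lemma, a finite
positive-semidefinite constraint on a matrix `Z` with
`p(m) = sum_n Z[n, n+m]`. The package ships its own small interior-point
solver for this SDP (log-det barrier with facial reduction; see the methods
vignette), followed by minimum-phase spectral factorization of `P` to
recover `a0` and quadrature conjugation to obtain the remaining three
filters.

Downstream, 5-minute Z-scored ECG epochs are decomposed into six sub-bands
(five detail levels plus the approximation), each summarized by its
log-energy `LOGE = log sum r(n)^2` and the fractal dimension of its graph
(`SFD`, a variation-form box-counting estimate). Features are ranked by a
two-sample Student's t-test between low-risk (LRHT) and high-risk (HRHT)
epochs, and the hypertension diagnosis index

    HDI = 6 - (3 LOGE_SB2 + 4 LOGE_SB3 + SFD_SB6)
            - 15 (SFD_SB2 + SFD_SB3 + SFD_SB4)

condenses six of them into one number per epoch.

## Worked example

```r
library(owfb)

fb <- owfb(filter_length = 16, zero_moments = 4)
fb
#> Orthogonal wavelet filter bank (minimal spectral spread)
#>   N = 16 taps, M = 4 zero moments
#>   achieved MSSL sigma_f^2 = 0.846816772 rad^2
#>   solver status: optimal
#>   a0: -0.004326620  0.013621700 -0.000733474 -0.040999600  0.033440700 ...
```

The achieved localization, 0.8468 rad², beats the maximally regular
(Daubechies) filter of the same length, 0.8849 rad² — the price of the four
extra vanishing moments the Daubechies filter carries. `summary()` verifies
every defining identity:

```r
summary(fb)
#> Filter bank verification report
#>   perfect reconstruction residual : 1.332e-15
#>   double-shift orthonormality     : 6.661e-16
#>   zero-moment residuals (k=0..3) : 5.464e-17 9.784e-16 1.617e-15 8.388e-14
#>   half-band identity residual     : 1.332e-15
#>   MSSL by quadrature              : 0.846816772 rad^2
#>   |quadrature - linear objective| : 1.998e-15
```

A full pipeline run on synthetic records (no external data needed):

```r
cfg <- pipeline_config(filter_length = 16, zero_moments = 4,
                       duration_s = 900, seed = 1)
out <- run_pipeline(cfg, out_dir = "demo-run")
list.files(out)
#> [1] "bank.json" "config.txt" "features.csv" "hdi.csv" "ranks.csv" "run.log"
```

`features.csv` holds the 12 sub-band features per 5-minute epoch and
channel; `ranks.csv` the t-test ranking; `hdi.csv` the per-epoch index and
its class under the configured decision rule, e.g.
`classify_hdi(2.0)` → `"LRHT"`, `classify_hdi(3.5)` → `"HRHT"` with the
default operating ranges (low-risk 1.501–2.355, high-risk 2.774–6.084).

The same stages are available from a shell:

```sh
Rscript inst/cli/owfb-cli.R design --length 16 --zero-moments 4 --out bank.json
Rscript inst/cli/owfb-cli.R demo --out demo-run --duration 900
```

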