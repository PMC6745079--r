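# uteq — abbreviated quantitative UTE MRI for bicomponent T2\* analysis

Connective tissues such as tendon, ligament and ACL grafts contain two
water pools with very different transverse relaxation: water bound to
organized collagen decays with a T2\* of a few hundred microseconds to
~2 ms (the *fast* component), while free water decays over tens of
milliseconds (the *slow* component). The fraction of signal contributed
by the bound pool — the bound-water fraction `f_bw` — and the fast
relaxation time `T2s*` track collagen organization, which makes them
candidate imaging biomarkers for graft remodeling after ACL
reconstruction. Sampling the whole decay for a conventional
bi-exponential fit,

    S(TE) = S0 · [ f_bw · exp(−TE/T2s*) + (1 − f_bw) · exp(−TE/T2l*) ],

requires many ultrashort-echo-time (UTE) acquisitions and scan times that
patients tolerate poorly. The abbreviated paradigm implemented here
instead acquires three double-echo UTE scans (TE1/TE2 of 0.1/4.0,
0.27/5.0, 0.5/6.0 ms), treats the slow pool as a constant baseline
(estimated as the mean signal at the three TE2 echoes, where the fast
pool has died out), and fits the three TE1 echoes with a
baseline-corrected mono-exponential:

    S(TE) = baseline/(1 − f_bw,app) · exp(−TE/T2s,app*) + baseline.

The apparent values `T2s,app*` and `f_bw,app` are biased relative to the
bi-exponential truth (the baseline carries residual fast-pool signal, and
the slow pool is not perfectly flat over the TE1 window). The package
simulates this bias over ground-truth parameter grids, calibrates a
fourth-order bivariate polynomial correction in the apparent
coordinates (assuming a fixed `T2l*`, 20 ms by default), and applies it
to produce corrected estimates. Supporting modules provide full
bi-exponential fitting, mono-exponential long-T2\* fitting for
variable-TE data, a Monte-Carlo comparison of the two estimators across
SNR levels, ROI geometry analysis (graft/bone interface growth by 2 mm,
orientation to B0, Dice overlap, intra-rater error), and a synthetic
multi-echo phantom for end-to-end validation.

Intended users: researchers in quantitative musculoskeletal MRI who want
to deploy or evaluate the abbreviated protocol, and methodologists who
want a reproducible simulation harness for baseline-corrected
relaxometry.

## Worked example

```r
library(uteq)

## a noiseless ROI-mean curve from known tissue parameters
sch   <- standard_schedules()$abbreviated
truth <- tissue_params(s0 = 1, f_bw = 0.85, t2s = 1.4, t2l = 20)
curve <- decay_curve(sch$all_tes, biexp_signal(truth, sch$all_tes), sch)

## abbreviated fit: apparent (biased) estimates
app <- fit_abbreviated(curve)
app
#> <apparent_estimate> T2s,app* = 1.385 ms, f_bw,app = 0.8304
#>   baseline = 0.1451, amplitude = 0.8552, rss = 2.04e-08

## calibrate the degree-4 polynomial correction on the clinical grid
model <- fit_correction(simulate_bias_grid(seq(0.5, 2, length.out = 61),
                                           seq(0.75, 0.95, length.out = 41)))
apply_correction(app, model)
#> <corrected_estimate> T2s* = 1.4 ms, f_bw = 0.85 (T2l* assumed 20 ms, polynomial)
```

The apparent fit underestimates both parameters (1.385 ms vs 1.4 ms;
0.830 vs 0.85) because the TE2 baseline still contains fast-pool signal;
the calibrated correction recovers the generating values.

A command-line front end covering the same workflows ships in
`inst/cli/uteq`:

```sh
uteq calibrate --t2l 20 --grid clinical --out correction.json
uteq phantom --out phantom_dir --snr 1000 --seed 7
uteq roi-report --images te_0.1.nii.gz,... --masks mask_graft.nii.gz \
     --correction correction.json --out report.csv
uteq snr-study --correction correction.json --out table.csv
```

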