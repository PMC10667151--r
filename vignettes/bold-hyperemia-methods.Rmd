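---
title: "Methods: semi-quantitative analysis of cuff-occlusion muscle BOLD MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semi-quantitative analysis of cuff-occlusion muscle BOLD MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(boldpq)
```

## The measurement

Dynamic BOLD MRI of calf muscle under a thigh-cuff compression paradigm is a
probe of peripheral limb perfusion. A tourniquet inflated above systolic
pressure occludes arterial inflow; deoxyhemoglobin accumulates and shortens
the effective transverse relaxation time T2\*. On cuff release, post-occlusive
reactive hyperemia re-oxygenates the tissue and T2\* transiently overshoots
its resting value, peaking tens of seconds after deflation before relaxing
back toward baseline.

The acquisition is a multi-echo spoiled gradient-echo (FLASH) series: at each
time frame, eleven echoes between 2 and 40 ms sample the mono-exponential
magnitude decay

$$S(\mathrm{TE}) = S_0 \, e^{-\mathrm{TE}/T_2^*},$$

and a voxel-wise log-linear regression of $\ln S$ on TE yields one T2\* map
per frame (`fit_t2star_series()`). The paradigm clock — 60 s baseline, 90 s
or 300 s occlusion, 300 s post-occlusion at 3.2 s per frame — is represented
by `cuff_paradigm()`; frame indices are 1-based in all user-facing output,
and frame timestamps use the mid-frame convention because each map
integrates signal over its acquisition window.

ROI-mean T2\*-time curves for the gastrocnemius and soleus are extracted by
averaging valid voxel estimates inside a fixed label mask per frame and are
normalised by the mean of the pre-inflation frames (`normalize_baseline()`).
The inflation frame itself straddles the cuff event and is excluded from the
baseline window. The baseline mean is retained as the initial T2\*
(T2\*~init~), which also converts normalised slopes back to ms/s.

## The descriptive model

The normalised curve is summarised by a piecewise continuous model with four
knots $t_0 < t_1 < t_m \le t_2$ (`model_eval()`):

| segment | interval | form |
|---|---|---|
| baseline | $t < t_0$ | constant $b$ |
| ischemic decline | $t_0 \le t < t_1$ | $m + (b - m)\,e^{-(t - t_0)/\tau_1}$ |
| hyperemic rise | $t_1 \le t < t_2$ | logistic with midpoint $t_m$, steepness $\tau_2$, anchored to start at the segment-B value $y_1$ and approach the asymptote $p$ |
| recovery | $t \ge t_2$ | $r + (\mathrm{HPV} - r)\,e^{-(t - t_2)/\tau_3}$ |

The rise segment is rescaled so that it is continuous at $t_1$:
$y(t) = y_1 + (p - y_1)\,\frac{\sigma(t) - \sigma(t_1)}{1 - \sigma(t_1)}$
with $\sigma$ the standard logistic in $(t - t_m)/\tau_2$. The hyperemic
peak value HPV is the model value at $t_2$, which also anchors the recovery
segment, so the model is continuous everywhere by construction. The
functional forms — constant, exponential approach, anchored logistic,
exponential decay — are this package's reconstruction of the descriptive
model; they were chosen so that each derived parameter below is well defined
and so that the four knots keep their usual physiological reading. All forms
sit behind the single forward function `model_eval()`, so an alternative
parameterisation can be swapped in without touching the rest of the chain.

### Derived parameters

`derive_parameters()` reduces a fitted model to the eight standard
descriptors. Levels are in normalised (arbitrary) units, times in seconds,
and slopes are converted from 1/s to ms/s by multiplying with T2\*~init~
(reports additionally multiply slopes by 100, the conventional scale):

* **T2\*~init~** — the baseline mean T2\* in ms (from normalisation);
* **IS~down~** — magnitude of the model slope at occlusion onset,
  $(b - m)/\tau_1 \cdot$ T2\*~init~;
* **MIV** — model minimum over the occlusion interval; segment B decreases
  monotonically, so this is its value at deflation;
* **HS~up~** — maximum model slope on the rise segment (closed form at
  $t_m$ when the midpoint is interior);
* **TTHP** — time from deflation until the model first crosses the midpoint
  between its pre-deflation value and HPV. The reference level is that
  midpoint rather than HPV/2: normalised curves peak near 1.04, so half the
  *peak value* would be unreachable, and only the rise-midpoint reading
  makes "time to half peak" finite;
* **TTP** — $t_2$ minus the deflation time;
* **HPV** — model value at $t_2$;
* **TTHR** — time from the peak until the recovery has decayed halfway to
  its asymptote $r$: $\ln 2 \cdot \tau_3$ in closed form. The reference is
  the midpoint between HPV and $r$ because the curve returns to a value
  close to, but not exactly at, baseline and $r$ captures that level.

Crossing times are found by bisection on the continuous model, never on the
sampled grid, so they do not inherit the 3.2 s frame quantisation.

### Fitting

`fit_model()` minimises squared residuals over all frames with bounded
Levenberg–Marquardt (minpack.lm). Initialisation is deterministic and data
driven — occlusion minimum for $m$, post-release maximum and its time for
the peak, the observed half-rise crossing for $t_m$ — and no random restarts
are used, so a fit is a pure function of its inputs. The knot-order
invariants $t_1 < t_m \le t_2$ are enforced structurally by optimising the
non-negative offsets $t_m - t_1$ and $t_2 - t_m$.

Two numerical choices deserve a note:

* **The event knots are pinned by default.** Cuff inflation and deflation
  are timed by the protocol clock, and the curve is nearly flat around both
  events (the ischemic plateau persists until the logistic onset), so $t_0$
  and $t_1$ are barely identified from the data; left free they drift along
  their slack bounds without changing the curve, which stalls the optimiser
  and perturbs the derived slopes. `fit_config(event_slack_frames = n)`
  frees them within ±n frames for measurements whose recorded timing is
  unreliable — the analyst-set fitting windows that observer-guided curve
  fitting occasionally needs.
* **The logistic asymptote `p` is only weakly identified** once the rise
  saturates before $t_2$ (for typical parameter values $p - \mathrm{HPV}
  \sim 10^{-6}$). Every derived parameter is a function of the curve, not of
  `p` itself, so this does not affect the outputs; self-consistency should
  be judged on the fitted curve and the derived parameters.

A fit whose rise amplitude is below $10^{-3}$ (e.g. a flat input curve) is
flagged degenerate and its hyperemic parameters are reported as undefined
rather than numbers.

## The synthetic generator

No imaging data accompany this package; `render_series()` builds a synthetic
2D calf cross-section instead — two non-overlapping elliptical muscle
regions on a background at the noise floor. Every tissue voxel decays
mono-exponentially over the echo train with
$T_2^*(t) = T_{2,\mathrm{vox}}^{*\mathrm{init}} \cdot y_{\mathrm{truth}}(t)$,
where $y_{\mathrm{truth}}$ is a descriptive-model trajectory and the voxel
baselines are drawn log-normally around the tissue value (5% spread by
default). Because the heterogeneity is multiplicative and constant in time,
it cancels exactly in the normalised ROI curve, which is what makes the
noiseless pipeline closure exact to machine precision — a property the test
suite exploits.

Ground truths are specified directly in the eight physiological parameters:
`truth_from_targets()` numerically inverts `derive_parameters()` (1-D root
finding for the ischemic pair, damped Newton for the rise triple, closed
forms for the rest), and the defaults are published healthy-cohort medians
per muscle and occlusion duration (`default_targets()`): baseline T2\* near
26 ms, ischemic dip to 0.94–0.96, overshoot to 1.02–1.08 peaking ≈ 28–32 s
after release.

Noise is Rician by default — the magnitude of the clean signal plus complex
Gaussian noise, scale 2% of the tissue signal scale — because the resulting
noise-floor bias of the log-linear fit at late echoes is a real effect worth
surfacing; Gaussian and noiseless modes exist for analytic tests. The study
protocol gives no acquisition SNR, so the default noise level is a free
choice exposed in `phantom_config()`. The default matrix is 64×64 (the
scanner's 128×119 down-scaled for desk-scale speed) and motion is off by
default; when enabled it is a deterministic integer-pixel sinusoidal drift,
since registration-based motion correction is outside this package's scope.

`simulate_cohort()` draws per-subject truths log-normally around the
defaults. The coefficients of variation act on the physiological scale —
`miv_depth` (= 1 − MIV) and `hpv_rise` (= HPV − 1) rather than the levels
themselves — which keeps every draw on the physical side of baseline.
Default CVs (6% T2\*~init~, 18–25% on times, 35% on slope/rise components)
were chosen once to mirror the reported interquartile spreads of healthy
adults. All measurements of a subject share the subject draw; a small
per-measurement jitter (3%) emulates within-session physiological change.
Draws that are physiologically inconsistent (e.g. TTHP ≥ TTP, or an initial
slope below the secant minimum the occlusion window allows) are rejected and
redrawn, which introduces a mild truncation of the extreme tails.

What the generator does **not** emulate: realistic anatomy, coil
sensitivity, parallel-imaging artifacts, B0 inhomogeneity, subject motion
(by default), and the atlas-based ROI propagation of real analyses. Passing
tests therefore demonstrate the correctness of the numerical chain under a
known forward model, not robustness to everything real scanner data can do.

## Statistical layer

The repeatability statistics mirror standard practice for this measurement:

* `wilcoxon_paired()` — two-sided paired signed-rank test. Zeros are
  dropped, tied absolute differences get average ranks, and for n ≤ 15 the
  p-value is exact, from the full null distribution over all $2^n$ sign
  assignments (computed by generating-function convolution, which stays
  exact under ties); larger samples use the tie-corrected normal
  approximation with continuity correction. The 95% interval is the
  Hodges–Lehmann interval from Walsh averages.
* `cv_within()` — within-subject CV for duplicate measurements,
  $sd_i = |x_1 - x_2|/\sqrt{2}$ per subject, aggregated as the root mean
  square of per-subject CVs (the standard duplicate-measurement estimator).
* `icc_2_1()` — ICC(2,1), two-way random effects, absolute agreement,
  single measurement, with the F-distribution lower confidence bound and
  the conventional poor/moderate/good/excellent reading of that bound.
* `bland_altman()` — bias, 1.96·SD limits of agreement, and t-based
  confidence intervals for all three.
* `pct_diff_medians()` — the symmetric percentage difference
  $100\,|m_a - m_b| / \bar m$ used to contrast occlusion durations.

Quartiles use R's default linear-interpolation convention (type 7); tests
are two-sided at α = 0.05 with no multiplicity correction, matching the
analysis this package re-implements.

## Known limitations and test-scale choices

* **TTP is the least identified parameter.** For typical healthy-adult
  truths the rise saturates some seconds before the peak knot, leaving a
  plateau in which $t_2$ moves the objective very little; at a normalised
  noise of 0.005 its median absolute recovery error is about 5–6 s (just
  under two frames), while HPV and MIV recover to ~0.002 and ~0.0005. This
  is a property of the descriptive model's geometry, not of the optimiser —
  fitted solutions routinely have lower residuals than the generating truth.
* The log-linear T2\* estimator carries a small downward bias under Rician
  noise (no noise-floor correction is applied); at SNR 50 the mean estimate
  stays within ±1 ms of a 26 ms truth.
* The exact signed-rank p and its normal approximation differ by up to
  ~0.011 in the worst single case at n = 15 (two-sided doubling of the
  per-tail error); their mean difference is well below 0.01.
* Problem sizes used by the test suite and the acceptance script — a 64×64,
  207-frame phantom for the noiseless closure, 200 replicate curves for the
  noisy-recovery bands, 2000 null simulations for the type-I calibration,
  and a 3-subject, 32×32 cohort for the pipeline determinism check — were
  chosen as the smallest instances that still exercise every code path at
  full temporal resolution.

## A worked micro-example

```{r example}
paradigm <- cuff_paradigm(occlusion_s = 300)
phantom <- render_series(phantom_config(matrix = c(32L, 32L), seed = 7L),
                         paradigm = paradigm)
maps <- fit_t2star_series(phantom$series, mask = phantom$mask)
curve <- normalize_baseline(extract_curve(maps, phantom$mask, 1L), paradigm)
fit <- fit_model(curve, paradigm)
report_scaled(derive_parameters(fit$params, curve$t2init_ms, paradigm))
```

The row above is one measurement's worth of the parameter table that
`run_pipeline()` assembles for a whole simulated cohort before handing it to
`summarize_cohort()` and `summarize_repeatability()`.
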