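---
title: "Methods: hybrid imputation and short-term glucose forecasting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hybrid imputation and short-term glucose forecasting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgmforecast)
```

# The problem

Continuous glucose monitors (CGM) report interstitial glucose every five
minutes. Forecasting the level 30 minutes ahead gives a patient enough lead
time to act — fast-acting insulin needs roughly 15–30 minutes to start
lowering glucose, and carbohydrates up to 20 minutes to correct a low — so a
reliable 6-step-ahead forecast is clinically the sweet spot between
usefulness and predictive uncertainty.

Real CGM streams are gappy: sensors fall off, transmitters drop out,
warm-up periods produce holes from minutes to many hours. The pipeline in
this package treats missing-data handling as a first-class modelling
decision rather than a nuisance, routes every gap by its length, and keeps
the inference-time path deliberately different from the training path.

# Data model

A `glucose_series` is one patient's trace on a strict 5-minute grid with an
explicit missingness mask (`NA` slots), timestamps in timezone-naive local
clock time (calendar features are about the patient's local day). Raw device
events are snapped to the grid by `regularize_to_grid()`: events within 60 s
of a slot are kept (midpoint ties resolve to the earlier slot), collisions
keep the nearer event, and strays are dropped with a tally. The 60 s
tolerance is an assumption — device jitter handling is rarely documented —
and is a parameter.

# Hybrid gap imputation (training path)

Gaps are classified by their length $\ell$ in slots:

| branch | condition | method |
|---|---|---|
| SPLINE | $\ell \le 11$ (< 1 h) | interpolating cubic spline through flanking observations |
| ARIMA  | $12 \le \ell \le 50$ | ARIMA forecast from the preceding observed run |
| CUT    | $\ell \ge 51$ (> 4 h) | partition the series at the gap |

Numerical choices, all fixed for determinism:

* **Spline end conditions.** Forsythe–Malcolm–Moler ("fmm") end conditions
  (`stats::spline`), which reproduce cubic polynomials exactly — that
  exactness is pinned by an oracle test. Up to 50 observed anchors on each
  side of the gap are used. A gap with no anchor on one side (it touches the
  series boundary) cannot be interpolated and is always cut.
* **ARIMA order.** Selected by AIC over $p \in \{0,1,2\}$, $d \in \{0,1\}$,
  $q \in \{0,1,2\}$ fit to the contiguous observed run immediately before
  the gap (most recent 288 slots at most, for a tractable grid search). A
  run shorter than 50 slots falls back to spline with a warning; if nothing
  converges the fallback order (1,1,0) is tried, then the gap is cut. A
  constant history short-circuits to the constant — the conditional
  expectation of any ARIMA fit to it.
* **Outlier purge.** Multi-step ARIMA forecasts can drift to implausible
  values. An imputed slot is re-set to missing iff it leaves the
  physiological range 40–400 mg/dL or the band mean ± 3 SD of the 24
  originally observed values flanking the gap (12 per side). Only imputed
  slots are ever examined; observed values are never flagged, however
  extreme. If fewer than 12 missing slots remain afterwards a second spline
  round fills them; otherwise the whole gap region is dropped and the
  series partitioned there.

The 12-at-the-boundary case of the post-purge rule ("below 12 interpolate /
above 12 partition" leaves exactly 12 unstated) is assigned to the
partition branch, the conservative choice. Whether the gap model should be
fit per gap or once per series was open; per gap was chosen, since each
fill conditions on the history immediately before that gap.

Two invariants hold on every path and are enforced in tests: observed
values are bitwise untouched, and slot accounting is conservative
(segment slots + cut slots = input slots). Segments shorter than 29 slots —
too short to yield a single supervised window — are kept but flagged
unusable.

# Inference path

Test-time preprocessing is intentionally different: every interior gap is
spline-filled regardless of length and the frame is never cut, so the
forecast stream stays aligned with the device stream. Because very long
uncut gaps let the spline extrapolate wildly, imputed values (on either
path) are held to the 40–400 mg/dL sensor range; observed values are never
altered. The pre-imputation
observation mask is carried through, and every metric is computed only at
target slots that were observed in the original input — forecasts are never
scored against values the pipeline itself invented.

# Features

Nine channels per timestamp, derived from the trailing hour (12 samples,
current included — the inclusive convention is a documented choice):

* `glucose`; `diff1` and `diff6`, the 5-minute and 30-minute differences;
* `trend`, the OLS slope over the window, in mg/dL per 5-minute step ("trend"
  is not defined more precisely in the source methodology; the least-squares
  slope is the standard reading);
* `avg` and `std`, the window mean and sample standard deviation;
* `day_part` (1–7), `day_of_week` (Monday = 1), `hour_of_day` (1–24).

The seven day parts are the clock partition 0–4, 4–8, 8–11, 11–14, 14–17,
17–21, 21–24 h (night, early morning, morning, midday, afternoon, evening,
late night); the boundaries are a fixed package choice since only "7 parts"
is specified upstream. Glycemic labels use the clinical thresholds:
hypoglycemia < 70 mg/dL, normal 70–180 mg/dL, hyperglycemia > 180 mg/dL.

**Transformation.** The log transform deskews the strictly positive
channels: `glucose` and `avg` get $\log$, `std` gets $\log(1+x)$ (an
in-range SD can be 0), while the signed channels `diff1`/`diff6`/`trend`
stay linear. All six are then z-scored with training-set statistics;
calendar channels map onto $[0,1]$ by their fixed ranges. Parameters are
fitted once on training rows and frozen — applying them elsewhere never
recomputes statistics, which is the package's leakage guarantee. The target
transform is exactly invertible (`invert_target()`, round trip < 1e-9 over
40–400 mg/dL); the model learns in transformed space and every metric is
computed in mg/dL after inversion.

# Forecaster

Supervised windows pair the transformed $12 \times 9$ feature block ending
at a valid row $t$ with the transformed glucose at $t + 6$. No window
crosses a segment boundary, so a segment of length $L$ yields
$\max(0, L - 28)$ windows (11 warm-up rows + 12-row window + 6-step
horizon).

The model is 3 stacked vanilla recurrent layers (tanh, hidden size 64)
reading the 12-step window, followed by linear(64→64) + ReLU and a
linear(64→1) regression head — the "2 linear layers" with the second acting
as the output head, which is the natural resolution of that ambiguity.
Forward pass, backpropagation through time and the Adam optimizer
(lr $10^{-3}$, $\beta_1 = 0.9$, $\beta_2 = 0.999$) are implemented in
vectorized base R; the gradient is verified against numerical finite
differences in the test suite, and the parameter count against the
closed form
$(hc + h^2 + h) + (L{-}1)(2h^2 + h) + (h^2 + h) + (h + 1)$.

Loss is MSE in transformed target space (unstated upstream; the standard
choice). Training uses batch size 64, a chronological 80/20
train/validation split (random splits leak future information in time
series), early stopping on validation RMSE with patience 10, and at most
100 epochs; best-epoch weights are returned. All randomness — weight
initialization and per-epoch shuffling — derives from the config seed, and
shuffling permutes batch membership only, never the (input, target)
pairing, so identical seeded runs are bitwise identical. One model is fit
per patient trace.

The skill reference is the **persistence baseline**: predict that glucose
in 30 minutes equals the last observed value. It is surprisingly strong on
CGM data and any model worth deploying must beat it.

# Evaluation

`evaluate_forecasts()` reports RMSE, MAE and $R^2$ in mg/dL; the 3-class
Matthews correlation coefficient over glycemic states
$$\mathrm{MCC} = \frac{cs - \sum_k p_k t_k}
{\sqrt{(s^2 - \sum_k p_k^2)(s^2 - \sum_k t_k^2)}}$$
(verified in tests against an independent one-hot-correlation
implementation); per-class precision/recall/F1; and Clarke Error Grid zone
percentages. The grid geometry uses the canonical Clarke (1987) piecewise
inequalities with the rule order A → E → C → D → else B, pinned against an
independently coded reference on a dense grid over $[20, 600]^2$ mg/dL.
Zero-denominator cases (constant truth for $R^2$, a class never predicted,
a degenerate MCC) return NA or 0 with a warning rather than erroring.

# Synthetic CGM generator

The OhioT1DM benchmark that motivates the pipeline is distributed under a
Data Use Agreement, so the package ships a seeded generator instead of
data. A trace is

$$g_i = \mathrm{clip}\Big(\,\mu + A\cos\tfrac{2\pi(h_i - 16)}{24}
  + \textstyle\sum_m a_m\,k(t_i - \tau_m) + \eta_i,\ 40,\ 400\Big)$$

with baseline $\mu = 120$ mg/dL, circadian amplitude $A = 15$ mg/dL
(trough ~4 a.m., peak ~4 p.m.), three daily meals (8:00, 13:00, 19:00,
±15 min jitter) whose excursions have lognormal peak amplitudes clipped to
40–90 mg/dL and a gamma-shaped kernel peaking 30 minutes after onset with
an exponential tail of time constant 30 minutes (≈ 2 h total decay), and
AR(1) noise with lag-1 autocorrelation 0.8 and marginal SD 5 mg/dL.
Missingness is injected separately (independent seed) with gap lengths
drawn from the three regimes the imputation router distinguishes
(1–11 / 12–50 / 51–150 slots), placed uniformly away from the series ends.

These settings are fixed study conditions, chosen once to be
CGM-plausible: the meal kernel gives the forecaster hour-scale learnable
structure, and AR(1) noise gives persistence a realistic advantage at
short horizons. What the generator does **not** emulate: insulin dynamics
(no dose → decay coupling), exercise- or stress-induced excursions,
sensor compression artifacts and calibration jumps, or patient-specific
meal irregularity. Passing tests therefore demonstrate that the pipeline's
machinery is correct and that the model extracts real temporal structure —
not that the paper-level error magnitudes transfer to clinical data, which
remain unverifiable without the restricted benchmark.

# Problem sizes and reproducibility

The shipped end-to-end check simulates one synthetic patient for 14 days
(4032 slots, ~2500 training windows), trains on the first 11 days and
evaluates the 30-minute forecasts on the held-out 3-day tail through the
inference path — sizes chosen so a full run completes in well under a
minute on a laptop core while leaving the forecaster enough data to beat
persistence clearly. `scripts/acceptance.R` re-runs exactly this experiment
from a single seed and writes the resulting metrics as JSON.

# Known limitations

* The simulator is a statistical fixture, not a metabolic model; absolute
  error levels on it do not transfer to real CGM data.
* The ARIMA branch fits one model per gap; very gap-dense traces pay the
  AIC grid search repeatedly.
* The purge criterion (physiological range + flank 3 SD band) is a
  documented stand-in for an upstream rule that was never quantified.
* Vanilla RNN layers were chosen over gated units deliberately (short-term
  dependencies dominate at a 30-minute horizon); no LSTM/GRU comparison is
  included.
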