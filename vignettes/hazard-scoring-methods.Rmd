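---
title: "Methods: from spike timestamps to a neuronal hazard label"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from spike timestamps to a neuronal hazard label}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meahazard)
```

`meahazard` turns multiwell MEA spike-timestamp exports into a four-level
acute neuronal hazard call per compound and concentration. This vignette is
the package's own account of the model, its assumptions, the tunable
parameters and why their defaults are what they are, what the synthetic data
generator does and does not establish, and where the design was genuinely
open.

## 1. The measurement model

A recording is a set of wells, each with up to 16 extracellular electrodes,
observed for one baseline phase and one treated phase (default 1800 s each,
stored as separate 0-based timelines so per-phase features are independent of
incubation gaps). Spike sorting is out of scope: the input is one timestamp
per spike.

**Quality control.** An electrode is *active* when its mean rate strictly
exceeds `qc_electrode_rate_hz` (default 0.1 Hz — more than six spikes per
minute). A well is analyzable when strictly more than `qc_active_fraction`
(default 40%) of its 16 physical electrodes are active; absent electrodes
count in the denominator. Both inequalities are strict, so an electrode at
exactly 0.1 Hz is excluded. Wells failing baseline QC are discarded; wells
failing QC only *after* treatment are deliberately retained — silencing is
signal, and feeds the cessation flags.

## 2. The six key parameters

* **WMFR** (Hz): total spikes on active electrodes divided by
  (duration x number of active electrodes); 0 when nothing is active. The
  field uses this name without a printed formula; this is the standard
  weighted definition and degrades gracefully.
* **Mean burst duration** (s): mean extent of electrode-level bursts found
  by Poisson Surprise (below); missing when a train has no bursts.
* **AuCC**: for every unordered pair of active electrodes, the spike-time
  cross-correlogram over lags within ±`max_lag_s` (default 100 ms) with bins
  of `bin_s` (default 5 ms) is divided by the chance level
  `n_a n_b bin / T`, so independent trains give 1 per bin. AuCC is the mean
  over pairs of `sum((normalized − 1) · bin)`, clipped below at 0. One
  consequence worth knowing: jitter much smaller than the lag window moves
  pair mass *between bins* but not out of the window, so AuCC only declines
  once desynchronization is comparable to the window. A config switch
  (`aucc$on = "bursts"`) correlates burst start times instead of spikes; the
  source analysis is ambiguous on this point and spikes are the default.
* **Median/mean ISI**: spike-timing organization; exactly 1 for a clockwork
  train, ln 2 ≈ 0.693 for a Poisson train, lower for heavy-tailed,
  burst-organized firing. Missing below 2 spikes.
* **FS** (firing cessation): treated WMFR below `fs_fraction` (default 5%)
  of the well's own baseline WMFR, or treated active electrodes below the
  QC minimum. An exact-zero criterion would be brittle on finite recordings.
* **NS** (network cessation): the baseline had network bursts and the
  treated phase has none. Network bursts are intervals where
  ≥ `participation_fraction` (default 50%) of active electrodes burst
  concurrently, merged across gaps < `merge_gap_s` (default 100 ms).

An extended panel of 43 named parameters (spike counts, burst and
network-burst statistics, ISI dispersion, synchrony summaries, plus FS/NS)
is computed per well so the selection machinery has a fixed input space; the
source analysis names 43 parameters without enumerating them, so the list
here is patterned on standard multiwell-MEA outputs and is frozen in
`mea_parameter_panel()`.

### Poisson Surprise burst detection

The surprise of a candidate window holding $n$ spikes over span $T$ on a
train of background rate $r$ is
$S = -\log_{10} P(N \ge n), \; N \sim \mathrm{Poisson}(rT)$.
The classical procedure seeds on short-ISI runs and extends/trims windows to
increase $S$; that local search can stall. This package instead maximizes
$S$ *exactly*: for a fixed spike count $n$ the Poisson tail is increasing in
$T$, so the best window of size $n$ is the minimal-span one — an $O(n^2)$
scan of spans plus one tail evaluation per $n$ (with a cheap
$-\log_{10}\mathrm{dpois}$ upper bound used to skip sizes that cannot win).
The globally best window is emitted when $S \ge$ `surprise_threshold`
(default 10, in $-\log_{10}$ units) and $n \ge$ `min_spikes` (default 3),
and the search recurses on the flanking spikes, yielding maximal
non-overlapping bursts. Ties prefer more spikes, then earlier start. The
background rate defaults to the train's own mean rate. The test suite holds
this implementation to *exact* boundary agreement with an independent
exhaustive-window oracle.

## 3. Effect sizes

Every well is its own control:
$\Delta\% = 100\,(x_{treated} - x_{baseline}) / |x_{baseline}|$, missing
when the baseline value is missing or zero (logged). Vehicle normalization
subtracts the same-plate mean vehicle $\Delta\%$; the result is written
$\Delta\Delta\%$. Whether the original analysis subtracted or divided by the
vehicle mean is ambiguous ("normalized to the average of the control");
subtraction is the default because it matches the $\Delta\Delta$ notation
and stays stable when the vehicle mean change is near zero, and division is
available (`normalization = "divide"`). Conditions (7–8 replicate wells) are
summarized as mean ± SEM with a two-sided Wilcoxon–Mann–Whitney p-value
against the plate's vehicle values — exact by complete enumeration of all
$\binom{n_1+n_2}{n_1}$ assignments up to combined $n = 20$ (ties handled via
midranks), normal approximation with tie correction above. The cessation
flags aggregate across replicate wells by majority vote.

## 4. Calibrating the zones

The *no effect* zone per parameter is a two-sided normal tolerance interval
on pooled vehicle $\Delta\Delta\%$: mean ± k·sd with Howe's factor
$k = z_{(1+p)/2}\sqrt{\nu(1 + 1/n)/\chi^2_{1-\gamma,\nu}}$, $\nu = n-1$.
Coverage and confidence default to 95%/95% — the source cites tolerance
intervals without printing levels, and 95/95 is the convention in
safety-pharmacology scoring; both are config. A distribution-free
order-statistic interval is auto-substituted when a Shapiro–Wilk check
rejects normality at α = 0.01 *and* the sample is large enough to support
the requested levels (for 95/95, n ≥ 93; otherwise the normal-theory
interval is kept rather than degrading to a sample range).

Per direction, the *mild* zone runs from the vehicle bound to the near bound
of the positive-control tolerance interval, and *strong* lies beyond it.
Values exactly on a boundary go to the more severe zone. If only one
direction has a positive control, the other direction's boundary is mirrored
about the vehicle mean; a positive-control bound nested inside the vehicle
interval collapses that mild zone with a warning (the value then scores as
strong once past the vehicle bound). Vehicle TIs are pooled across plates by
default, matching how the source presents vehicle variability. FS/NS bypass
calibration entirely — they are binary and carry fixed points.

## 5. The scoring matrix

The concrete point values and score-to-label ranges of the original system
are not published, so the matrix ships as *data* (JSON-serializable,
`default_scoring_matrix()`), not as code: mild = 1 and strong = 2 severity
points per continuous key parameter (both directions weighted equally by
default, asymmetric weights supported), FS = 3, NS = 2, and label ranges
0 → non-neuroactive, 1–2 → neuroactive, 3–4 → hazard, ≥ 5 → high hazard.
Under this default, one strongly shifted parameter alone cannot exceed
"neuroactive"; silencing alone (FS + NS = 5) reaches "high hazard" — which
encodes the intent that cessation is the gravest single observation. The
total is a severity-positive sum with direction recorded separately; whether
the original used a signed or absolute-weighted total is unknown and flagged
for revision if the original constants surface. An optional gate
(`significance_gate`) zeroes points for parameters not significant vs
vehicle at p < 0.05, off by default.

## 6. Selection and direction machinery

`lasso_select()` repeats (default 100×) a stratified 70/30 split, fits a
penalized binomial/multinomial model (glmnet; penalty by internal
cross-validation, `lambda.min`), records nonzero-coefficient parameters and
test-split balanced error rate, and ranks parameters by selection frequency
(retention at ≥ 50%). Covariates like timepoint and dose can be exempted
from the penalty. `stepwise_reduce()` then greedily adds/removes parameters
against cross-validated BER (LDA as the CV classifier) and returns the
BER-versus-size trace. The metric definitions (BER, PPV, NPV, balanced
accuracy) follow the printed formulas exactly; the printed Cohen's κ
denominator "(TP+FP)(FP+TN)+(TP+FN)(FN+TN)" is adopted literally after
verifying it reproduces the standard binary κ (1 for a perfect classifier,
−1 for a perfectly inverted one).

`fit_direction_model()` is a bagged ensemble of Gini-split CART trees grown
to purity (500 trees, `mtry = floor(sqrt(p))`, vote-fraction probabilities,
out-of-bag accuracy reported). It is implemented inside the package because
the deployment environment guarantees no external tree learner; with
condition-level $\Delta\Delta\%$ rows as input (well-level rows are a
switch), matching how per-concentration probabilities are reported.

## 7. The synthetic plate generator

`simulate_plate()` emulates what the pipeline needs to see, not biophysics:

* background firing per electrode: gamma-renewal process, shape 1 (Poisson)
  by default, rate 0.8 Hz;
* network bursts: a common event train shared by all electrodes of a well —
  gamma renewal at 0.15 Hz with shape 4 (ISI CV 0.5), reflecting the
  quasi-rhythmic network bursting of mature cortical cultures; at each event
  every electrode emits ~12 spikes over 0.2 s, jittered across electrodes by
  σ = 10 ms. Total ≈ 2.6 Hz WMFR and ≈ 60 Hz intra-burst rate, typical of
  DIV28 rat cortical cultures, with packet surprise ≈ 12 (comfortably above
  the S ≥ 10 threshold);
* vehicle variability: a per-well lognormal rate factor (sdlog 0.10) shared
  by both phases, plus an independent per-phase drift factor (sdlog 0.08),
  giving vehicle per-well $\Delta\Delta\%$ sds around 10–15% — without this
  the tolerance intervals would be degenerate;
* effect profiles applied to the treated phase only: rate multiplier
  (scales background and packet spikes together, so ISI composition is
  preserved), burst-duration multiplier, packet jitter, network decoupling
  (per-electrode independent drivers; rates preserved, synchrony destroyed),
  silencing, and ISI regularization (gamma shape increase).

The default plate is 8 vehicle wells plus five conditions of 8 wells:
inhibitory and excitatory positive controls, a mild inhibitory compound
(rate ×0.6 with slight desynchronization — with vehicle variability as
above, the vehicle tolerance band spans roughly ±25–30%, so a "mild" effect
must sit clearly outside it), a silencer, and a negative control.

**What a green test establishes — and what it does not.** The generator has
controllable ground truth, exchangeable baselines, and near-ideal Poisson
statistics. Green end-to-end tests establish that the pipeline recovers
planted effects of stated sizes at stated error rates. They do not establish
performance on real cultures, which add plate-position effects, development
drift, electrode dropout, correlated noise across wells, and spike-sorting
artifacts — none of which are modeled.

## 8. Numerical and testing choices

* Burst search is exact, so tests compare boundaries with an independent
  brute-force maximizer (direct Poisson tail summation) demanding identical
  windows, not approximate agreement.
* Degenerate inputs: zero-variance tolerance samples give a degenerate
  interval with a warning; empty burst sets propagate as missing values;
  missing effect sizes score as no-effect but are annotated not-evaluable.
* Heavy acceptance checks are scaled in *size*, never in threshold: the
  100-seed end-to-end sweep uses 150 s phases instead of 1800 s (shorter
  recordings are noisier, so this scaling is conservative), and the LASSO
  recovery check replicates the full 100-repeat procedure 10 times.
* All randomness descends from one root seed through named substreams
  (plate, well, phase, stage), so every stage is independently reproducible
  and CLI reruns are byte-identical.

## 9. Known limitations

* The true scoring matrix, tolerance levels, and 43-parameter list of the
  original system are unpublished; the defaults here are documented
  stand-ins, and all three are data/config rather than code precisely so
  the originals can be dropped in.
* AuCC's area definition is insensitive to jitter far below the lag window
  (see §2); `aucc_peak`/`synchrony_index` in the extended panel are sharper
  for fine desynchronization.
* The direction classifier and selection machinery are validated on
  synthetic separable benchmarks, not on compound screening data.
* Per-plate vehicle normalization is the only batch correction; multi-plate
  batch effects beyond that are out of scope.
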