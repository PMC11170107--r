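# meahazard

Acute neuronal hazard scoring from multiwell micro-electrode array (MEA)
recordings.

## The problem

Drug-induced seizures are one of the most serious CNS liabilities in drug
development. Primary cortical neurons cultured on multiwell MEAs fire
spontaneously — spikes, electrode-level bursts, and synchronized network
bursts — and acute drug effects on that activity predict seizurogenic and
neuroactive potential. But an MEA recording yields dozens of correlated
parameters, which is hard to act on in a screening cascade. `meahazard`
condenses a plate of spike timestamps into a single, interpretable hazard
label per compound and concentration: **non-neuroactive** (green),
**neuroactive** (yellow), **hazard** (orange), or **high hazard** (red).

## The method

For each well (16 electrodes, one baseline and one treated phase):

1. **QC** — an electrode is active if its rate is strictly above 0.1 Hz
   (more than six spikes/min); a well is analyzable if strictly more than
   40% of its 16 electrodes are active.
2. **Features** — a 43-parameter panel per well/phase, with six key
   parameters driving the score: weighted mean firing rate
   (WMFR = spikes / (duration x active electrodes)), mean burst duration
   (bursts found by exact Poisson Surprise maximization,
   S = -log10 P(N >= n | Poisson), S >= 10), area under the pairwise
   cross-correlogram above chance (AuCC; 5 ms bins, +/-100 ms lags), the
   median/mean inter-spike-interval ratio (1 for clockwork trains, ln 2 for
   Poisson), and two binary flags: firing cessation (FS) and network
   cessation (NS).
3. **Effect sizes** — each well is its own control:
   `%change = 100 (treated - baseline)/|baseline|`, then normalized by
   subtracting the same-plate vehicle mean (the vehicle-normalized effect,
   written DD% here). Conditions of 7-8 replicate wells are summarized as
   mean +/- SEM with an exact Wilcoxon-Mann-Whitney p-value vs vehicle.
4. **Calibration** — two-sided normal tolerance intervals (Howe's k-factor,
   95% coverage / 95% confidence) on vehicle DD% define the *no effect*
   zone; positive-control intervals bound the *mild* vs *strong* zones per
   direction.
5. **Scoring** — a weighted point matrix (data, not code: mild = 1,
   strong = 2 per key parameter, FS = 3, NS = 2 by default) is summed and
   mapped through score ranges: 0 -> non-neuroactive, 1-2 -> neuroactive,
   3-4 -> hazard, >= 5 -> high hazard.

Supporting machinery reproduces the parameter-selection workflow
(repeated-split LASSO with selection-frequency ranking, stepwise reduction
on the balanced error rate, BER/PPV/NPV/Cohen's kappa), a random-forest
classifier of effect direction (inhibitory / excitatory / vehicle-like with
vote-fraction probabilities), reference-panel predictivity metrics, and a
seeded synthetic plate simulator so everything is testable without
instrument data.

## Worked example

```r
library(meahazard)

# a 48-well plate: 8 vehicle wells + 5 conditions x 8 wells; the default
# 30-min phases are shortened to 240 s to keep the example quick
design <- simulation_design(duration_s = 240, seed = 42)
plate  <- simulate_plate(design)
res    <- run_pipeline(plate$recordings, plate$map)
res$report[, c("compound", "concentration_um", "total_score", "label")]
```

Output from this exact call:

```
         compound concentration_um total_score           label
1 mild_inhibitory                1           0 non-neuroactive
2     neg_control               10           0 non-neuroactive
3  pos_excitatory               10           8     high hazard
4  pos_inhibitory               10           8     high hazard
5        silencer               10           7     high hazard
```

Reading: the negative control stays within vehicle variability (score 0);
the excitatory and inhibitory positive controls move several key parameters
into their strong zones; the silencing compound trips firing + network
cessation (3 + 2) on top of a strong WMFR drop. The mild inhibitory
compound lands inside the no-effect band here because the cutoffs were
calibrated from this single plate's 8 vehicle wells (a wide tolerance
interval at n = 8); with cutoffs pooled across several plates — as the
acceptance sweep does — a 40% rate reduction is scored neuroactive in the
large majority of runs.

The same pipeline runs from files via the CLI:

```sh
Rscript -e 'meahazard::mea_cli()' simulate  --seed 42 --duration 240 --out run/
Rscript -e 'meahazard::mea_cli()' calibrate --in run/spike_list.csv --in run/plate_map.csv --duration 240 --out run/
Rscript -e 'meahazard::mea_cli()' score     --in run/spike_list.csv --in run/plate_map.csv --duration 240 --config run/calibrated_config.json --out run/
```

Each stage writes a manifest (config hash, seed, input digests); identical
seed and config reproduce byte-identical outputs.

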