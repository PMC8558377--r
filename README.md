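# thermoripple

Offline analysis of hippocampal local field potentials (LFP) recorded
during thermal induction of seizures, for labs studying
temperature-sensitive epilepsies (Dravet-type models and wild-type
controls). The package detects sharp-wave ripple complexes (SPW-R),
classifies interictal epileptiform discharges and myoclonic events,
locates generalized tonic-clonic (GTC) seizure onset, and aggregates
everything against core body temperature. A seeded synthetic-session
generator with a ground-truth ledger makes every stage verifiable without
animal recordings.

## The method in brief

All detection operates on z-scored quantities anchored to a reference
epoch of quiet immobility / NREM sleep:

    z(t) = (f(t) − x̄) / σ

with x̄, σ from the baseline epoch. SPW-R candidates are epochs of
ripple-band (100–260 Hz) Hilbert power above 3 SD outside active
exploration; troughs of the ripple-band trace form cycles when their
spacing lies in 4–10 ms, and the internal ripple frequency is
1 / mean(inter-trough interval) over the five middle cycles. Interictal
spikes need simultaneous high amplitude (>1 SD) and steep first derivative
(>5 SD); a spike is myoclonic when EMG power in the 100 ms after the spike
exceeds twice the power in the 100 ms before. Event rates per temperature
are counts divided by dwell time in 0.5 °C bins, restricted to pre-ictal
immobility, aggregated per subject and then as genotype grand averages
(± SEM).

## Worked example

```r
library(thermoripple)

# a synthetic DS thermal-induction session with known ground truth
sim <- simulate_session("DS", seed = 3)
ana <- analyze_session(sim)

table(ana$epileptic$event_class)
#>              gtc interictal_spike        myoclonic
#>               91               72                5

round(ana$onsets, 2)
#> interictal_spike        myoclonic              gtc
#>             37.8             38.8             38.9

head(ana$rate_bins[, c("bin_center", "dwell_time", "event_count", "rate")], 4)
#>   bin_center dwell_time event_count      rate
#> 1       36.0      190.7          73 0.3828002
#> 2       36.5       53.3          21 0.3939962
#> 3       37.0       56.2          37 0.6583630
#> 4       37.5       67.9          69 1.0162003
```

The session ramps from 36 °C at 0.5 °C/min; the first interictal spike is
detected at 37.80 °C, the first myoclonic event at 38.80 °C, and the
seizure is localized at 38.90 °C from the signals alone (no annotation).
The dwell-normalized SPW-R rate peaks in the 37.5 °C bin and falls as
epileptic activity takes over. Comparing against the generator's ledger:

```r
tr <- sim$truth[sim$truth$type == "spwr", ]
evaluate_detection(tr$time, (ana$ripples$start + ana$ripples$end) / 2,
                   tolerance = 0.025, tr$frequency, ana$ripples$frequency)[
  c("precision", "recall", "bias")]
#> $precision [1] 0.996        $recall [1] 0.988        $bias [1] 0.91
```

`run_pipeline(run_config(preset = "DS", seed = 3, output_dir = "out"))`
writes the event tables, bin summaries, a statistics report and a run
manifest; identical config and seed reproduce the files byte for byte. A
thin command-line front end lives in `inst/scripts/thermoripple-cli.R`
(subcommands `simulate`, `detect`, `analyze`, `run-all`, `evaluate`).

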