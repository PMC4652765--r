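# gquadfret

Tools for assessing G-quadruplex (GQ) formation in single- and
double-stranded DNA, for researchers studying promoter quadruplexes,
telomeric repeats and other G-rich loci who need to connect three levels
of evidence: sequence, ensemble ligand fluorescence, and single-molecule
FRET.

G-rich sequences matching

```
G(>=3) N(1-7) G(>=3) N(1-7) G(>=3) N(1-7) G(>=3)
```

can fold into parallel or antiparallel quadruplexes, and which topology —
or whether folding happens at all — is governed by the loop-length profile
(the N-run triplet, e.g. 1-4-4) and by the strand context: in duplex DNA,
Watson–Crick pairing competes with folding, only parallel GQs survive, and
folding propensity collapses as loops lengthen. The package provides:

- **`scan_g_quadruplex()`** — exhaustive motif scanner (both strands,
  0-based half-open coordinates, BED6/JSON output) with
  **`classify_conformation()`** / **`predict_ds_folded_fraction()`**
  applying loop-profile rule tables and a calibration map of measured
  duplex folded percentages.
- **`peak_intensity()`, `normalize_to_reference()`, `fit_centroids()`,
  `classify_point()`** — NMM/CV emission-spectrum readouts (610/670 and
  640 nm peaks) normalized to a reference construct and classified by
  nearest centroid in the two-ligand plane; **`classify_cd_spectrum()`**
  applies the 260/240 (parallel) and 290 nm (antiparallel) CD signatures.
- **`simulate_dataset()`** — a full generative model of two-channel smFRET
  trace data (two FRET states at E ≈ 0.8 and 0.3, donor-only molecules,
  photobleaching, exact two-state Markov dynamics, red-pulse acceptor
  marker, 400–500 molecules per field) and **`analyze_dataset()`** — the
  matching quantitation pipeline: apparent FRET, dual-label selection,
  photobleach truncation, 60-bin FRET histogram, two-Gaussian area fit of
  the folded fraction, and dynamic-trace detection.

The folded fraction is quantified as the area of the high-FRET Gaussian
component: fitting counts ~ A_lo·exp(−(E−μ_lo)²/2σ_lo²) +
A_hi·exp(−(E−μ_hi)²/2σ_hi²) and reporting
100·area_hi/(area_lo+area_hi), with an AICc-based fallback to a single
component for one-peak histograms.

## Worked example

Scan a sequence and predict its behaviour in duplex DNA:

```r
library(gquadfret)
m <- scan_g_quadruplex("TTGGGTGGGTTTTGGGTTTTGGGTT", sequence_id = "promoter_1")
m[, c("sequence_id", "start", "end", "strand", "motif_length", "loop_profile")]
#>   sequence_id start end strand motif_length loop_profile
#> 1  promoter_1     2  23      +           21        1-4-4

classify_motifs(m, context = "ds")[, c("loop_profile", "conformation",
  "propensity_class", "predicted_folded_percent", "rule_id")]
#>   loop_profile conformation propensity_class predicted_folded_percent
#> 1        1-4-4     parallel     intermediate                       66
#>                 rule_id
#> 1 ds.one_single_nt_loop
```

The 1-4-4 motif (21 nt: four GGG tracts, loops of 1, 4 and 4 nt) is
predicted parallel with intermediate propensity; the calibration map puts
its duplex folded fraction at 66%.

Simulate a matching smFRET dataset and recover that fraction from the
traces:

```r
cfg <- gq_fixture_config("1-4-4", n_molecules = 1000, seed = 7)
rep <- analyze_dataset(simulate_dataset(cfg))
#> folded_percent: 68.4
#> mean_high: 0.800  mean_low: 0.302
#> dual-labeled: 797 of 1000
#> percent_dynamic: 0.13
```

797 of 1000 molecules carry both dyes (the rest are donor-only and are
removed via the red-pulse marker); the two-Gaussian fit finds the folded
and duplex peaks at E = 0.800 and 0.302 and a folded fraction of 68.4%,
within sampling error of the generative 66% at this size (at 5000
molecules it lands within ±2 points). See the vignette
(`vignettes/gq-folding-propensity.Rmd`) for the model, every tunable
threshold, and what the simulation does and does not emulate.

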