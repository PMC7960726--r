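# shockjet

Analysis toolkit for **X-ray pump / X-ray probe serial femtosecond
crystallography (SFX)** experiments on liquid microjets. In such an
experiment a first (pump) XFEL pulse vaporises a segment of a few-µm
liquid jet and launches a supersonic shockwave along it; a second (probe)
pulse, delayed by Δt and displaced Δx upstream toward the nozzle, records
diffraction from microcrystals that the shock has just traversed. Comparing
pump–probe data against single-pulse reference data quantifies whether, and
how much, the shock damages crystal order and perturbs the protein
structure — the question that decides usable repetition rates at MHz
X-ray free-electron lasers.

The package is aimed at SFX beamline scientists and methods developers. It
implements the full desk-side analysis chain:

- **Synthetic experiment generator** (`simulation_config()`,
  `generate_shot_series()`): per-shot pump/probe pulse energies with a
  controlled negative correlation, photodiode traces, jet snapshot images
  with explosion gaps and break-up, peak lists whose resolution responds to
  pump (damage) and probe (signal) energy — all with ground truth, so every
  downstream stage is testable without beam time.
- **Jet imaging** (`extract_jet_features()`, `gap_centre()`,
  `jet_speed()`): Otsu-threshold segmentation, gap/break-up detection,
  projected width, and jet speed from gap tracking,
  v = (y(t₁) − y(t₂))/(t₁ − t₂).
- **Shot filtering** (`diode_noise_filter()`, `pump_leakage_filter()`,
  `morphology_filter()`, `classify_hit()`, `rate_report()`): the
  diode-noise (mean + 3σ), pump-leakage (mean + 1.5σ) and jet-morphology
  acceptance rules, the ≥ 10-peak hit definition, and per-run / pooled
  hit and indexing rates.
- **Diffraction statistics** (`image_resolution()`, `half_set_metrics()`,
  `merge_observations()`, `completeness()`, `wilson_b()`,
  `auto_resolution_cutoff()`): per-image resolution at I/σ(I) ≥ 4,
  probe-energy binning, and half-dataset merging metrics

  R_split = 2^(−1/2) · Σ|I₁ − I₂| / (½ Σ(I₁ + I₂)),
  CC\* = sqrt(2·CC₁/₂ / (1 + CC₁/₂)),

  with mmm/Friedel reduction and P2₁2₁2₁ screw-axis absences handled in
  the completeness bookkeeping.
- **Structural comparison** (`pair_models()`, `superpose()`,
  `distance_difference_matrix()`, `radius_of_gyration()`,
  `bootstrap_ensemble()`, `compare_report()`): Kabsch superposition,
  Cα displacement fields, distance-difference matrices
  D_ij = d_ij(B) − d_ij(A), and bootstrap resampling of the image pool to
  estimate per-atom coordinate errors.
- **Shock kinematics** (`shock_geometry()`, `effective_delay()`,
  `equivalent_rep_rate()`, `shock_travel_distance()`):
  Δt_eff = Δt + Δx/v and d = v·Δt + Δx, mapping an offset two-pulse
  geometry onto an equivalent repetition rate.

## Worked example

```r
library(shockjet)
cfg <- pipeline_config(sim = simulation_config(n_shots = 2000, seed = 42))
rep <- run_pipeline(cfg)
print(rep)
```

```
shock pipeline summary (config 684f8e97 )
  pump-probe: 991 shots, 109 hits (11.0%), 24 indexed (25.3% of filtered hits)
  single:     1009 shots, 171 hits (16.9%), 38 indexed (23.8% of filtered hits)
  median resolution: 3.38 A (pump-probe) vs 3.02 A (single), drop 0.35 A
  CC1/2 0.980 / 0.896, Rsplit 13.6% / 32.8% (single / pump-probe)
  structural: RMSD 0.112 A over 574 pairs, Rg ratio 0.9994
  kinematics: effective delay 222.5 ns (4.49 MHz), travel 11.12 um
```

Reading the output: the pump pulse suppresses the hit rate (11.0% vs
16.9% here; crystals damaged below the 10-peak hit definition), degrades
the per-image resolution of indexed hits (median 3.38 Å vs 3.02 Å) and
the merged-data agreement metrics (R_split 32.8% vs 13.6%, CC₁/₂ 0.896 vs
0.980), while the structural comparison of the two refined models shows a
small (0.112 Å RMSD) correlated displacement with a slight net compaction
(Rg ratio < 1). The kinematics block maps the 122.5 ns delay + 5 µm
upstream offset at a 50 m/s jet onto an effective 222.5 ns pulse spacing,
i.e. ~4.5 MHz operation. `render_report(rep, "out/")` writes the JSON
report and TSV tables.

## Vignette

`vignettes/shock-analysis.Rmd` documents the models and conventions: the
resolution/damage phenomenology and its calibration, the filter
definitions and boundary conventions, the merging statistics and binning
choices, the bootstrap error model, what the synthetic generator does and
does not emulate, and known limitations.
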