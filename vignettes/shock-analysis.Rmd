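---
title: "Shock-damage analysis for X-ray pump-probe serial crystallography"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shock-damage analysis for X-ray pump-probe serial crystallography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shockjet)
```

# The experiment and the analysis model

An XFEL pulse focused into a few-micron liquid microjet vaporises a jet
segment and launches a shockwave that travels supersonically along the
stream, outrunning the explosive gap. In a two-pulse (pump-probe)
experiment the pump strikes the jet first; after a delay $\Delta t$ a probe
pulse, displaced $\Delta x$ upstream (toward the nozzle), records
diffraction from microcrystals that the upstream-travelling shock has just
passed through. Comparing the pump-probe data with single-pulse reference
data answers whether the shock degrades crystalline order (hit rates,
per-image resolution, merging statistics) and whether it perturbs the
protein structure (displacement fields, distance-difference matrices,
radius of gyration, backed by bootstrap coordinate errors).

The package implements this analysis chain on per-shot records (pulse
energies, photodiode traces, jet snapshot images, peak lists), per-image
reflection observations, and atomic models, plus a synthetic generator
that emulates the whole experiment with known ground truth.

## Shock kinematics

With jet speed $v$, the material probed at offset $\Delta x$ was reached by
a disturbance launched a time $\Delta t_{\mathrm{eff}} = \Delta t +
\Delta x / v$ earlier, so an offset two-pulse geometry emulates a
repetition rate $1/\Delta t_{\mathrm{eff}}$; the shock meanwhile travels
$d = v\,\Delta t + \Delta x$ through the co-moving liquid. All unit
conversions are exact rational factors (1 µm/ns = 1000 m/s).
`required_delay()` inverts `effective_delay()` exactly; note that
$1/(4.5\ \mathrm{MHz}) - 100\ \mathrm{ns} = 122.2\ \mathrm{ns}$, while the
conventional delay quoted for this geometry is 122.5 ns (consistent with a
222.5 ns spacing). The formula is implemented exactly and the 0.3 ns
discrepancy is left visible rather than absorbed. `attenuation_scale()` is
a deliberately phenomenological power law $p = p_{\mathrm{ref}}
(d/d_{\mathrm{ref}})^{-n}$: the exponent is a required user input and no
value is asserted as physical — shock attenuation in micro-jets is not
modelled here.

# The synthetic experiment

`simulation_config()` holds every condition of the emulated measurement;
the defaults are the study conditions: a 5 µm, 50 m/s jet; 122.5 ns delay
and 5 µm upstream offset; pump energy 0.03 ± 0.02 mJ (truncated at zero)
strongly anti-correlated ($\rho = -0.7$) with a 0.9 ± 0.2 mJ probe; a 19%
base hit probability; 5% noisy diode traces, 5% pump-leakage shots, 5%
abnormal jets; 0.5 µm/px snapshots with the pump interaction at 70 µm from
the top edge.

Two phenomenological models deserve explanation, because the experiment
itself publishes only their observable consequences:

- **Per-image resolution.** True best resolution is
  $d = \max(d_{\mathrm{best}},\ d_{\mathrm{base}} - s\,E_{\mathrm{probe}}
  + c\,E_{\mathrm{pump}})$ — a monotone phenomenology, not a physical
  claim. $d_{\mathrm{base}} = 3.45$ Å and $s = 0.5$ Å/mJ put the
  single-pulse indexed-hit median at 3.0 Å. The damage coefficient is
  calibrated at large $n$ to $c = 11.5$ Å/mJ so that the **pump-probe
  indexed-hit median is 3.3 Å**, the observable the generator is built to
  reproduce. The naive value $0.3/0.03 = 10$ Å/mJ undershoots because
  hits are themselves suppressed at high pump energy, so indexed images
  are biased toward weakly-pumped shots — an emergent selection effect
  worth remembering when interpreting energy-binned resolution plots.
- **Hit suppression.** A shot is a hit with probability
  $p_0 \exp(-k E_{\mathrm{pump}})$ with $k = 12.7$ mJ$^{-1}$, chosen so
  the average pump-probe hit rate is 13% against the 19% single-pulse
  base — the damaged fraction of ~6 percentage points.

Pulse energies are drawn from a bivariate normal with the target
correlation and redrawn until positive: the simplest controllable law for
"strongly anti-correlated". Jet snapshots are rendered with the jet axis
vertical, rows running downstream from the nozzle, positions measured in
µm from the top edge with a 0-based pixel convention — one convention
everywhere. The jet wiggle (crystal-laden jets are unstable) has no
published quantitative model; amplitude and wavelength are free parameters
defaulting to 1.5 px and 40 px. Pump-leakage shots carry a strong
below-edge component on the masked diode (a photon-energy drift),
independent of the weak pump energy; a leak signal proportional to the
pump energy would make low-pump leakers undetectable by any threshold.

All randomness flows from one master seed through named sub-streams
(modes, energies, hits, peaks, traces, jets, …), so identical
configuration gives bit-identical output and stages can be regenerated
independently. Shot records store jet *geometry parameters*; pixels are
rendered on demand (`shot_jet_image()`), deterministically, which keeps
large series small in memory.

**What the generator does not emulate:** diffraction physics (no detector
images, no partiality, no spot shapes), hydrodynamics (no real shock
propagation or gap growth), indexing ambiguities, detector artefacts, and
long-timescale drifts. Tests passing on synthetic data therefore validate
the *statistical machinery and its conventions*, not instrument-specific
behaviour.

# Filtering conventions

- **Diode noise** (`trace_noise_std()`, `diode_noise_filter()`): the noise
  of a trace is the SD over the pre-pulse window; *population* SD
  (divisor $n$) is used throughout the filters — a fixed convention for
  bit-reproducibility. The "noise-less" reference population is circular
  as stated (you need it to define noisy); it is estimated by a robust
  first pass: per-shot SDs within 3 scaled-MADs of the median are
  retained, then a shot is excluded iff its SD is strictly greater than
  mean(retained) + 3·SD(retained). Strict inequality: a shot exactly at
  threshold is kept. At least 50 shots are required for the population
  statistics to mean anything.
- **Pump leakage** (`pump_leakage_filter()`): keep shots whose integrated
  masked-diode pump-window signal is strictly below mean + 1.5·SD of all
  shots. The 1.5 multiplier is configurable (`leak_k`); a zero-variance
  population keeps everything. The integration window is centred on pump
  arrival with a half-width of a few samples (the diode response is much
  faster than the sampling used here).
- **Jet morphology** (`morphology_filter()`): pass iff the projected width
  is within one SD of the run median, the gap count is 1 or 2, and the jet
  is continuous upstream of the pump. Because the probe gap legitimately
  sits *upstream* of the pump (the probe is displaced toward the nozzle),
  gaps within `position_tol_um` (default 3 µm) of the nominal pump or
  probe positions are attributable; only an unattributable gap, or a
  break-up point, upstream of the pump fails the shot
  (`discontinuous_upstream`). A probe gap need not exist. Droplets
  downstream of the break-up point are not counted as gaps.
- **Hits and rates**: a hit has ≥ 10 peaks (boundary inclusive); the
  indexing rate divides indexed images by *filtered* hits. `rate_report()`
  returns per-run rates, their unweighted average, and pooled
  (aggregate-count) rates; zero-shot runs are dropped, zero-denominator
  rates are NA.

`extract_jet_features()` segments with Otsu's method by default (the
original analysis used an unpublished custom script; a parameter-free
standard keeps results reproducible), requires a gap to span at least 2
rows (single-row dropouts are noise), and declares break-up where, after
the last jet run of ≥ 10 contiguous rows, only short droplet-like runs
remain.

# Merging statistics

Observations are reduced to the mmm asymmetric unit ($|h|,|k|,|l|$,
including Friedel mates) and merged as unweighted means — no scaling, no
partiality correction. The sigma of a merged intensity is
SD/√multiplicity (sample SD; a multiplicity-1 reflection keeps its own
sigma estimate). Half-set metrics assign whole *images* (not
observations) randomly to two halves, merge each independently, and over
reflections present in both compute
$R_{\mathrm{split}} = 2^{-1/2} \sum |I_1 - I_2| / \tfrac12 \sum (I_1 +
I_2)$, the Pearson $CC_{1/2}$, and $CC^* = \sqrt{2 CC_{1/2} / (1 +
CC_{1/2})}$ ($CC^*$ is NA for negative $CC_{1/2}$).

Resolution bins are **equal-volume in $1/d^3$** everywhere (uniform
reciprocal-space shell volume per bin); whether binned correlations should
use equal-count or equal-volume bins is not standardised, so one choice is
fixed and stated. Completeness divides observed unique reflections by the
full enumerated unique list, with the 2₁ screw-axis absences (h00 with h
odd, 0k0 with k odd, 00l with l odd) excluded — required for a correct
denominator in P2₁2₁2₁. The Wilson B is the least-squares slope of
$\ln\langle I\rangle$ vs $s^2 = (1/2d)^2$ over bins with $d <$ 4.5 Å
(avoiding the non-Wilson low-resolution regime), $B = -\mathrm{slope}/2$;
bins with non-positive mean intensity are skipped and fewer than three
usable bins is an error. The automatic resolution cutoff walks 20 bins
from low to high resolution and returns the inner edge of the last bin
with mean I/σ(I) > 1.0 before the *first* failing bin — a first-crossing
rule, even if later bins recover; data whose first bin already fails are
rejected as unusable.

# Structural comparison and bootstrap errors

Models are paired by (chain, residue number) over Cα atoms — isomorphous
models of the same crystal form, so no sequence alignment. Superposition
is closed-form Kabsch via SVD with the determinant forced to +1
(reflections are never absorbed into the rotation); `superpose(A, A)`
returns the identity to 1e-10. Displacement statistics are computed after
superposition by default (both compared models share imposed cell
parameters in the motivating use case, so the un-superposed convention is
also available); exported arrows are scaled ×10 for visualisation only.
Distance-difference matrices need no superposition at all (pairwise
distances are rigid-motion invariant); the per-residue sum of relative
changes is the compaction/expansion summary, negative meaning the residue
moves toward the rest of the molecule. The radius of gyration defaults to
unweighted Cα — insensitive to side-chain noise, matching the main-chain
focus of the comparison.

`bootstrap_ensemble()` resamples the image pool with replacement to the
original pool size, refines a model per resample through a pluggable
`refine_engine`, and reports per-atom mean positions and per-coordinate
SDs — the coordinate-error estimate. The shipped engine is a surrogate
(per-atom weighted mean of per-image coordinate observations), for which
the truth is the closed form $\sigma/\sqrt{m}$; a crystallographic
refinement program satisfying the same contract can be substituted. A
failing resample is redrawn once, then the error propagates. The 2σ
consistency check flags atoms deviating from the ensemble mean by more
than twice the bootstrap SD in any coordinate; the experimental convention
labels this band "the 90% confidence level" although 2σ of a normal law is
~95% per coordinate — the check is literally 2σ and the label is carried
verbatim, with the discrepancy noted here.

The synthetic structure pair plants the comparison's ground truth: a
574-residue Cα tetramer (chains of 141/146/141/146 residues — a synthetic
stand-in, not a deposited structure), displaced by per-chain low-frequency
sinusoids rescaled to an exact RMS amplitude and centred to carry no net
translation, optionally compacted about the centroid. The default
conditions are an 0.11 Å RMS field with compaction 0.9995 and per-image
coordinate noise of 0.85 Å over 50 images, so the bootstrap coordinate
error lands at $0.85/\sqrt{50} \approx 0.12$ Å — the regime where
individual-atom displacements are *not* significant but coherent clusters
are, which is exactly the situation the bootstrap analysis is designed to
resolve.

# Numerical and degenerate-input choices

- Comparisons at filter thresholds are strict in the exclusion direction
  ("larger than" excludes), so a value exactly at threshold is kept.
- `image_resolution()` uses the inclusive boundary I/σ ≥ threshold and
  returns NA (a value, not an error) when nothing qualifies.
- A blank image returns a `no_jet` result distinguishable from "jet with
  no gaps"; `jet_continuous_upstream()` is FALSE for it.
- Error-of-mean statistics need n ≥ 2 and are NA otherwise; empty energy
  bins are reported with n = 0.
- Degenerate superposition geometry (collinear points giving a singular
  covariance) raises an error rather than returning an arbitrary frame.
- Zero-noise bootstrap ensembles are flagged `degenerate` rather than
  producing 0/0 significance statements.

# Problem sizes

The test suite runs the generator at 200–6,000 shots per case (the
end-to-end damage/null comparisons use 6,000), merging statistics on cells
small enough for a few thousand unique reflections, and bootstrap
ensembles of 100 members (1,000 for the convergence check). The
acceptance script uses 100,000 shots for the resolution medians (standard
error of the median difference ~0.01 Å) and 6,000 for the full filtered
pipeline. These sizes were chosen so every statistical assertion has
comfortable margin over its sampling noise.

# Known limitations

- The reflection-observation noise model (additive Gaussian with SD
  ∝ √I) is milder than real SFX partiality noise, so synthetic overall
  CC₁/₂ values run higher than typical experimental ones; orderings and
  limit laws, not absolute magnitudes, are the tested quantities.
- Only orthorhombic cells (P2₁2₁2₁/P222) are supported in the hkl
  bookkeeping; that is the lattice of the motivating system.
- The surrogate refinement engine averages coordinates; it reproduces the
  sampling statistics of bootstrap refinement but none of refinement's
  nonlinearities (restraints, map bias).
- Jet segmentation assumes a dark jet on a bright background and a
  roughly vertical axis; heavily tilted jets are only partially modelled
  (the over-wide "projected size" signature is, the geometry is not).
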