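---
title: "Methods: simulation, echo maps and the multiview classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation, echo maps and the multiview classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`bedradar` implements a radar-to-posture pipeline: simulate IR-UWB range
profiles of a body on a bed, suppress static clutter, back-project each
radar's profile onto a shared bed grid (a Spatial Radar Echo Map, SREM),
classify postures with a multiview convolutional network, and run a
sensor-subset ablation protocol. This vignette explains the models behind
each stage, the tunable parameters, and the design decisions taken where
the problem was genuinely open.

## Coordinate frame and geometry

All geometry lives in a bed-fixed frame: origin at the headboard-left bed
corner, x across the 90 cm width, y along the 196 cm length, units cm. The
grid covers the bed with square cells whose default side (0.643 cm) equals
the radar bin length expressed in cm; counts are truncated, giving
139 x 304 cells. Distances are evaluated at cell *centres* — the corner
convention would put a zero-distance artifact at the origin and break the
symmetry tests.

The eight-radar bench fixes edge offsets and spacings (all radars 20 cm
outside the nearest edge; side radars 15 cm apart, cranial to caudal) but
no absolute coordinates, so `default_placement()` documents explicit
assumptions: head radars HL/HC/HR at x = 20, 45, 70 cm facing +y; side
radars S1–S5 on the left long edge at y = 30…90 cm facing +x (upper-body
biased, covering head, torso and proximal limbs). Which long edge carries
S1–S5 is unknowable from the bench description; `side = "right"` mirrors
the layout. Antenna heights (side 78 cm, head 108 cm, bed 60 cm) are kept
as `z` offsets above the bed plane but ignored by default: the map
generation algorithm is strictly planar, and a `"3d"` distance mode is
provided only as an option.

Two published hardware parameterisations conflict: the parameter table
lists a 0–2 m detection range with 312 bins, while the map-generation
algorithm initialises 9.87 m and 1536 bins. We treat `n_bins` and
`max_range` as free parameters constrained by
`bin_length = max_range / n_bins` (validated to 1%), default to the
algorithm's values, and let the simulator emit either length.

## The frame simulator

The received pulse is a sum of delayed scatterer returns plus noise. A
posture phantom is a set of 11 point scatterers (head, shoulders, chest,
abdomen, hips, knees, feet) with posture-specific geometry: lateral
templates compress the body cross-section and offset it from the midline;
fetal templates pull both legs cranially (shorter y-extent than the
extended-leg "log"); half-stomach templates flex exactly one leg
(asymmetric); prone templates reduce torso reflectivity and offset the
head by its turn direction. Right-sided postures are exact mirrors of the
left-sided templates about the midline, applied after jitter so mirror
pairs share random draws — a property the equivariance tests rely on.
Subject anthropometry enters as per-subject height/width multipliers
(drawn once per subject, sd 5–7%).

Each scatterer deposits amplitude

`A = reflectivity x blanket_attenuation x cos-taper(azimuth) / R^p`

at its range bin, spread by a Gaussian range point-spread. Choices:

* **Path-loss exponent `p = 2`** (one-way spreading onto a reflectivity
  map). No radar equation is given for the bench hardware; the exponent is
  configurable.
* **Point spread σ = 16.6 bins**, from the range resolution implied by the
  1.4 GHz bandwidth: c/(2·B) ≈ 0.107 m ≈ 16.6 bins of 0.00643 m.
* **Blanket model**: multiplicative attenuation (thick 0.5, medium 0.7,
  thin 0.85) plus a weak diffuse scatterer layer draped over the body.
  Blankets are experimental conditions, not a physical model, in the bench
  protocol; these values are assumptions.
* **Slow-time structure.** A frame replicates the scene across
  `n_pulses` columns, adds a static clutter profile (smooth low-pass
  noise, constant over slow time) and i.i.d. Gaussian noise. Critically,
  each scatterer's return also fluctuates pulse to pulse by a
  multiplicative factor (sd `scintillation_sd`, default 0.15). This models
  channel fading and the residual micro-motion of a "stationary" sleeper,
  and it is what makes mean-subtraction clutter suppression meaningful: a
  perfectly static body would be removed together with the clutter,
  leaving pure noise. With `scintillation_sd = 0` the simulator produces
  exactly-static returns, which the invariant tests exploit. No
  quasi-periodic (respiration/heartbeat) structure is modelled — temporal
  features are deliberately out of scope for this spatial, single-instant
  pipeline.

Reproducibility uses one root seed with hashed child streams per
(subject, posture, blanket, trial, radar), so any subset of the design
regenerates identically regardless of generation order.

**What the simulator does not emulate:** electromagnetic propagation,
wall/multipath reflections, antenna coupling, elevation patterns, real
tissue scattering, or vital-sign oscillations. Phantom realism is
unvalidated by construction — no quantitative body signature is published
for the bench. Consequently, passing the posture-recovery benchmark shows
the *pipeline* separates classes whose spatial structure differs the way
the posture definitions say they differ; it says nothing about absolute
accuracy on real recordings.

## Clutter suppression and profile extraction

Suppression subtracts each range bin's slow-time mean. The published
formula's notation is internally inconsistent (the bin count is declared
as the normaliser while the summation index replaces the time index); we
implement the standard slow-time reading — the established clutter-removal
operation — and note the discrepancy here. The operation is exact on
static components, idempotent, and refuses single-pulse frames (it would
null them).

The 1D profile that feeds map generation is, by default, the per-bin RMS
over slow time (`envelope`), which is robust to which pulse is sampled;
`column` mode takes `|X'[, t]|` at one instant to match a literal
single-frame readout. Both are non-negative because map "intensity" is
interpreted as magnitude; mean-subtracted values are signed, so a signed
diagnostic path exists but is not the default.

## Echo-map generation

For each cell, the distance D to the radar selects the bracketing bins
`b_small = floor(D/d)`, `b_large = ceil(D/d)` with
`d = max_range·100/n_bins` cm (computed, never hard-coded). Two weightings
are implemented:

* `as_printed` (default): `b_small` weighted by `(D mod d)/d`, `b_large`
  by the complement — exactly as published. Note this gives the
  fractional distance to the *nearer* bin, the inverse of standard linear
  interpolation.
* `corrected`: standard linear weights.

Both weight pairs sum to 1 at every cell, coincide wherever D is an exact
bin multiple, and are linear in the profile; which one the original
production runs used cannot be determined from the text, so the faithful
reading is the default and the choice is a surfaced flag. Cells whose far
bracket exceeds the profile get zero rather than clamping — clamping would
smear the farthest bin across the remaining map. Azimuth masking (zeroing
cells outside the ±65° sector) is applied by default: the map algorithm
omits it, but the described maps are sector-shaped and signals are
presumed negligible beyond the field of view. The unmasked map is the
algorithm's literal output and remains available.

Multi-frame accumulation (summing per-profile maps) is supported alongside
single-profile generation; whether production runs summed frames or used a
single instant is ambiguous in the source, so both paths exist and are
tested for additivity.

## The multiview classifier

One echo map per active radar, in canonical slot order (HL, HC, HR,
S1–S5), min-max scaled per view (a constant view maps to zeros, not NaN),
resized bilinearly to the model input size. A shared-weight backbone
embeds each view; features are pooled element-wise across views; fully
connected layers emit logits.

* **Pooling is element-wise max** by default, following the original
  multiview-network design; the pooling type is otherwise unstated, and
  `mean` is available. Max pooling makes the model invariant to view
  order and stable under duplicated views, both covered by tests.
* **Backbones.** The network is implemented natively in vectorised R
  (im2col convolutions, exact adjoint backward pass, verified against
  finite differences). `tiny_cnn` — three 3x3 conv blocks (8, 16, 32
  channels), two 2x2 max pools, a 4x4 adaptive average pool and flatten —
  is the default and benchmark backbone (~35k parameters with the head).
  `tiny_resnet` adds an identity skip over the last block; `tiny_densenet`
  concatenates the last two blocks. The ImageNet-class extractors are
  registry stubs: at desk scale they are neither needed nor justified (two
  of the attention-based ones are reported not to converge even at bench
  scale), and the backbone interface is the extension point.
* **Input size 32** (not 224): echo maps carry structure at the scale of a
  body on a 139 x 304 grid, and 32 px preserves it while keeping one-CPU
  training in minutes. The flatten-over-4x4-regions head retains coarse
  spatial layout, which is the discriminative signal between postures.
* **Training recipe**: cross-entropy, AdamW with learning rate 0.001 and
  betas (0.9, 0.999) (the published recipe), decoupled weight decay 0.01
  excluded from biases. Epochs and batch size are unstated upstream;
  defaults are 30 and 16, both exposed. No pretrained weights: the inputs
  are single-channel synthetic maps, not natural images.
* **Determinism**: weight init, shuffling and training draw from seeded
  streams; identical seeds give identical histories.

Labels exist at two granularities; `coarse_map()` sends the nine fine
labels onto Supine/Left/Right/Prone (sizes 1/3/3/2). A fine model's
predictions mapped coarse can never be less accurate than its fine
accuracy, which is asserted as a property.

## Ablation protocol

The 22 pre-planned radar subsets ship as a registry (masks over the eight
canonical slots; popcounts 8,7,7,7,6,6,6,5×6,4×7,3,2). `run_ablation`
rebuilds view stacks per mask by subsetting a single 8-view stack,
retrains from scratch per configuration, and scores held-out subjects. One
subject split is shared across configurations — re-splitting per
configuration would confound mask effects with split effects; the original
protocol does not state its choice. Per-configuration training seeds are
offset by the configuration id. The split itself is subject-wise, and the
55:15 subject proportion is preserved for any cohort size
(`train_n = round(n·55/70)`); whether the original split was repeated or
cross-validated is unstated, so a single split is assumed.

Radar-count aggregation takes the arithmetic mean per (model, count) and
rounds half-up to 3 decimals, matching the summary tables' presentation
(R's `round()` is half-to-even, so a dedicated rounding with a 1e-9
representation-error guard is used). The published per-configuration
accuracies are packaged as a plain-text fixture so the aggregation
arithmetic is checkable without any retraining; the four-model,
seven-count table it reproduces is asserted cell by cell in the tests.

## Persistence and tooling

Arrays and manifests persist in a versioned RDS container (bit-exact
round-trip, schema checking, explicit errors naming missing radar groups);
manifests and results are CSV; configs and metrics JSON; echo maps export
to 8-bit min-max-scaled PNG. Geometry (radars + grid) serialises to a JSON
schema with cm for geometry and metres for bin lengths. A thin Rscript CLI
(`inst/cli/bedradar.R`) exposes `simulate`, `srem`, `train`, `evaluate`,
`ablate`, `aggregate` and `export-png`; every subcommand writes a JSON run
record (stage, config, config hash, seed, package version) beside its
output.

## Benchmark problem sizes

The posture-recovery benchmark (`run_posture_benchmark()`) simulates 20
subjects x 9 postures x 1 thin-blanket condition x 1 trial (180 samples)
at high SNR (noise 0.002, clutter 0.2), trains the 4-class model for 20
epochs on a subject-wise split (16 train / 4 test subjects), then compares
the 8-radar ensemble against the minimal 2-radar pair (HC + S3) over three
12-epoch training seeds. These sizes were chosen once as the smallest
configuration that leaves a clear accuracy signal while training in
minutes on a single CPU; the full 70-subject, three-blanket, three-trial
design (5670 samples) is enumerated and counted but not trained on by the
default checks.

## Limitations

* Synthetic-only validation: absolute accuracies on real bedside data are
  out of reach without a deposited dataset, and none of the published
  real-data accuracies are claimed or reproduced here.
* Point-scatterer phantoms cannot express soft-tissue scattering,
  blanket-fold geometry or limb self-occlusion; class separability in
  simulation is easier than in reality.
* The classifier is deliberately compact; conclusions about *relative*
  radar-subset value transfer only to the extent the simulator's spatial
  information structure matches a real bench.
* Single-instant spatial pipeline: no temporal or vital-sign features.
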