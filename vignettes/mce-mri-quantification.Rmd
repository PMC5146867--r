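---
title: "Quantifying transcript-targeted SPION contrast: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying transcript-targeted SPION contrast: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcemri)
```

## The measurement and its model

Molecular contrast-enhanced MRI reads out regional mRNA abundance
through a chain of linear physics. A superparamagnetic iron oxide
nanoparticle (SPION) carries a phosphorothioate antisense
oligodeoxynucleotide (sODN) at a fixed conjugation ratio (3 nmol sODN
per mg Fe, so an iron dose fixes the probe dose — `sodn_dose(4)` gives
12 nmol/kg). Probe hybridized to its target transcript is retained;
unbound probe clears within hours. Retained iron shortens T2\*, raising
the effective transverse relaxation rate R2\* = 1/T2\* by

$$\Delta R2^* = r_2 \, [\mathrm{Fe}], \qquad r_2 = 33.9\ \mathrm{s^{-1}mM^{-1}},$$

and bound iron is proportional to copy number,
$[\mathrm{Fe}] = \kappa\, c$. The signal at echo time TE of a
gradient-echo acquisition is $S(TE) = S_0 e^{-R2^* TE}$. Everything the
pipeline estimates is an inversion of one of these three lines.

The phantom generator (`generate_phantom()`) implements exactly this
forward model on a 64×64×16 grid with seven box ROIs (mPFC, NAc, CPu,
HP, SSC, MC, LS), six echoes at TE = 1.94, 3.41, 4.88, 6.35, 7.82,
9.29 ms and TR 800 ms, and retains the full ground truth
(`phantom_truth`) so every estimator can be scored against it.

## Tunable parameters and their defaults

| parameter | default | units | why |
|---|---|---|---|
| `r2` (agent) | 33.9 | s⁻¹mM⁻¹ | transverse relaxivity of the dextran-coated agent |
| `binding_coeff` (κ) | 5e-5 | mM per copy | puts the largest planted copy number (2×10⁴) at 1 mM bound Fe, i.e. ΔR2\* = 33.9 s⁻¹ — a strong but physiological contrast |
| gene panel copies | 2×10³ / 8×10³ / 2×10⁴ | copies per ng RNA | synthetic placeholders spanning a 10-fold range (no absolute values are published for these transcripts); chronic challenge halves the striatal HDAC5 entry |
| `baseline_r2star` | 18–22 (SD 2) | s⁻¹ | brain-tissue-like baseline rates |
| `noise_sigma` | 0.025 | fraction of S₀ | SNR 40 magnitude images |
| `uptake_times` / `plateau_time` | 2, 4, 6 / 4 | h | uptake rises to a plateau at 4 h and holds at 6 h |
| qPCR efficiency | 2.0 | fold/cycle | perfect doubling, the ΔΔCt model's assumption |
| `min_run` (duplex) | 12 | nt | calibrated so the in-silico duplex calls reproduce the gel-shift lane pattern of the bundled probe panel |
| beam geometry | 5 beams, 5 cm | — | activity-chamber photocell layout; distance = 0.05 m per ambulation count |

Copy-number placeholders and κ were fixed once when the generator was
written and are exposed in `phantom_config()`; they define scale, not
science — the calibration statistics are invariant to affine rescaling
of the copy axis.

## What the generator emulates — and what it does not

It emulates: per-ROI baseline R2\* with between-subject variability;
post-contrast elevation exactly linear in bound iron; a smooth uptake
time course (piecewise-linear by default, a saturating-exponential
option behind `uptake_shape`) reaching its plateau exactly at the
plateau time; Rician noise on magnitude images (the correct law for
gradient-echo magnitude data; a Gaussian option exists for closed-form
checks); Ct values under the ΔΔCt generative model with a β-actin
reference; and beam-break streams whose ambulation rate profile is
paradigm-dependent (suppressed-then-rising for acute amphetamine,
immediate full rate for the chronic challenge).

It does not emulate: real atlas geometry (ROIs are axis-aligned boxes),
B0 inhomogeneity or motion, partial-volume effects, registration error
(sessions are born aligned), probe pharmacokinetics beyond the uptake
curve, or any cell-level biology. Passing tests therefore demonstrate
that the *analysis chain* is correct and self-consistent — not that the
biological claims hold in animals, which would require the unavailable
in-vivo data.

## Numerical choices

**Relaxometry.** The default fit is log-linear weighted least squares
per voxel with weights ∝ squared signal, which is near
maximum-likelihood at moderate SNR and fully vectorized; a
Gauss-Newton refinement (`method = "nonlinear"`, `stats::nls`, port
algorithm, bounded below at zero) is available and agrees to float
precision on clean data. Voxels with non-positive signals or a
first-echo signal below 3× the estimated background noise are masked,
not errored; negative fitted slopes are clamped to R2\* = 0 with the
fit retained so downstream ΔR2\* thresholds behave.

A precision note: with six echoes ending at 9.29 ms, the sampled decay
at brain-like R2\* (~20–30 s⁻¹) is shallow, so single-voxel precision
is noise-bound — at SNR 20 the median relative error is on the order of
20%, and reaching 5% needs roughly SNR 100. This is a property of the
acquisition, not the estimator (the weighted fit sits at its variance
bound). All quantification downstream works on ROI means, which average
hundreds of voxels and recover the calibration slope to ~2% at SNR 40.

**Thresholding.** ΔR2\* uses the ROI-level baseline reference (mean and
SEM of the reference sample) rather than a voxelwise SEM — matching the
convention of thresholding against average pre-contrast values — with
the voxelwise variant exposed via `mode = "voxel"`. The subtraction
threshold of the stratification rule is strict: a subject exactly 1 SD
from the reference mean is accepted ("more than" one SD rejects).
Under a Gaussian null the 3-SEM threshold admits a false-positive rate
of P(Z > 3) ≈ 0.13%, which the test suite verifies by simulation at
10⁵ draws.

**CNR.** Implemented verbatim as ΔR2\*/√SD of the baseline —
dimensionally odd but the operative definition; the conventional
ΔR2\*/SD is available behind `conventional = TRUE`.

**Plateau detection.** Earliest time whose mean is matched within a
relative tolerance (default 5%) by all later means; a curve still
rising at the last sample returns that time flagged `no_plateau`.

**Subtraction maps.** Voxelwise difference clipped at zero; candidate
ROIs are 26-connected components above threshold (via igraph), reported
with size, centroid, and mean. Candidate count is monotone
non-increasing in the threshold.

**qPCR.** Replicates aggregate by arithmetic mean of Ct. Efficiency
defaults to 2.0 and is configurable. Copy-number conversion *requires*
an explicit reference-gene copy number: where a treatment may perturb
the internal control, the function refuses rather than guesses.

**Power.** `sample_size()` searches the exact noncentral-t power of the
two-sample two-sided t-test; at the study convention (85% power,
α 0.05) an effect of d = 2 needs n = 6 per group (the normal
approximation says 5, one too few). A simulation cross-check is in the
test suite.

**Behavior.** Only two transition classes are defined (adjacent-beam =
ambulation, same-beam = fine motor); jumps of ≥2 beams are counted as
neither and reported for audit so that classes always partition the
transitions. Strict event consecutiveness is assumed — no time window.
Binning defaults to 5 min on 1-minute recording granularity.

**Oligo checks.** `duplex_call()` scans all offsets for the longest
contiguous antiparallel Watson-Crick run (U≡T across alphabets, no G·U
wobble — these are DNA probes) and calls a pair bound at ≥12 nt, the
value at which the printed panel reproduces the gel-shift calls: the
probe binds only the target-site cDNA (20-nt run), and the precursor
binds only its designed antisense (18-nt run). The USP1 primer carries
an annotated 10-position span for a 20-mer; the amplicon computed from
those coordinates is 218 bp where 212 bp is printed. The package
surfaces this discrepancy (`span_mismatch`) and does not guess which
coordinate is the typo.

## Design choices made where the design was open

- **Reference for ΔR2\* in the end-to-end run:** the subject's own
  fitted baseline map supplies the per-ROI reference (voxel mean, SD,
  SEM). This keeps the calibration self-contained per subject; a cohort
  reference (`baseline_reference_from_maps()` on several maps) is used
  for stratification, mirroring how a normal-population reference would
  be built.
- **Plateau time point for calibration:** the regression uses ΔR2\* at
  the last uptake time (6 h), the plateau-retention window, and the
  regression is unweighted OLS with r² reported.
- **Paradigm → copy mapping:** a config table, defaulting to equal
  copies across paradigms except a halved striatal HDAC5 (and a mildly
  raised hippocampal GFAP) in the chronic challenge — the qualitative
  ordering, without inventing absolute published values.
- **Uptake shape:** piecewise linear to the plateau (only 2-h sampling
  constrains it); the exponential option approaches ~95% and is
  renormalized to hit the plateau level exactly, keeping the
  "reaches the plateau and holds" contract.
- **Workflow shape:** the repository is organized as an analysis
  workflow (numbered drivers under `analysis/` over the package
  functions) rather than a CLI tool, since the deliverable is a
  sequence of analyses over simulated data.

## Problem sizes used by the tests and drivers

Unit and property tests run on 16–34-voxel-per-side grids (the
geometry scales down with the grid), 10⁵-draw null simulations, and
300–400-replicate Monte-Carlo checks; the analysis drivers and the
acceptance script use the full 64×64×16 grid. These sizes were chosen
so the whole suite completes in well under a minute while keeping every
Monte-Carlo tolerance at 4–5 standard errors.

## Known limitations

- Box-ROI geometry and born-aligned sessions: no registration, no
  partial voluming, no atlas realism.
- Single-compartment R2\* only — no B0 correction, no complex-valued
  fitting, no multi-exponential decay.
- The CNR definition is used as printed; its units are not those of a
  conventional CNR.
- Copy-number absolute scales are placeholders; only ratios and
  linearity are meaningful.
- No thermodynamic (nearest-neighbor ΔG) hybridization model — duplex
  calls are purely combinatorial; and no genome-wide off-target
  search.
- Locomotor simulation plants Poisson counts per minute; it does not
  model within-minute autocorrelation or stereotypy taxonomies beyond
  the two beam-break classes.
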