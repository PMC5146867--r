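# mcemri

Quantification pipeline for **molecular contrast-enhanced (MCE) MRI**:
imaging regional mRNA abundance in the living brain with
superparamagnetic iron oxide nanoparticles (SPION) conjugated to
sequence-targeted antisense oligodeoxynucleotides (sODN). Probe bound to
its transcript raises the local effective transverse relaxation rate
R2\* (= 1/T2\*, s⁻¹); the elevation above baseline, ΔR2\*, is the
imaging surrogate of transcript copy number.

The package is written for imaging scientists who want to test and
calibrate this quantification chain without animal data: every input is
simulated with known ground truth, and every analysis step of the chain
is a tested function.

## The model

The forward model is linear at every stage:

- bound iron in a region: `[Fe] = κ · c`, with `c` the transcript copy
  number and `κ` the binding coefficient (mM per copy);
- relaxation: `ΔR2* = r₂ · [Fe]`, with transverse relaxivity
  `r₂ = 33.9 s⁻¹ mM⁻¹` (dextran-coated iron oxide, `r₁ = 15.4`);
- signal: `S(TE) = S₀ · exp(−R2*·TE)` sampled at six gradient echoes
  (TE = 1.94 … 9.29 ms, TR 800 ms), magnitude images with Rician noise.

The analysis inverts it: voxelwise log-linear weighted least squares
gives R2\* maps; thresholding at the baseline reference mean + 3 SEM
gives ΔR2\* maps (`ΔR2* = max(0, post − (bR2* + 3·SEM))`, percent maps
`ΔR2*/bR2* × 100`); ROI means feed contrast-to-noise ratios
(`CNR = ΔR2*/√SD`, implemented as defined), uptake-plateau detection,
subtraction maps for ROI discovery, and the headline calibration:
ordinary least squares of ROI-mean plateau ΔR2\* on copy number, which
is exactly linear (r² = 1) at zero noise. Copy numbers come from
simulated qPCR plates via the comparative-Ct (ΔΔCt) model with a
β-actin internal control; locomotor sensitization is quantified from
photocell beam-break streams (5 beams, 5 cm apart; distance = 0.05 m
per ambulation count). Oligo utilities check the probe/primer design
(reverse complements, amplicon lengths, longest-complementary-run
duplex calls).

## Worked example

```r
library(mcemri)

cfg <- phantom_config(noise_sigma = 0, subject_sd_scale = 0)
res <- run_pipeline(cfg, seed = 1, paradigm = "S1", ct_noise_sd = 0)
res$calibration$r_squared       # 1
res$calibration$slope           # 0.001695  (= 33.9 * binding_coeff)
res$plateau$plateau_time        # 4         (hours; held at 6 h)

# printed-arithmetic utilities
amplicon_length(hdac5_oligo_panel()$USP2,
                hdac5_oligo_panel()$hdac5AS2)   # 580 (bp)
sodn_dose(4)                                    # 12  (nmol/kg)
rna_aliquot_mass(2.8, 40, 4)                    # 280 (ng)
round(fe_atoms_per_np())                        # 6039 (~6000 Fe atoms/NP)
```

The zero-noise run recovers the planted linear calibration exactly:
three genes spanning a 10-fold copy range give r² = 1 and a slope equal
to `r₂ · κ`. At the default acquisition noise (SNR 40) the same run
gives r² ≈ 0.998 (median over 20 seeds; see
`analysis/05_calibration.R`).

## Analysis workflow

The `analysis/` directory holds the numbered drivers that reproduce the
study-style figures and tables on synthetic data, writing everything
under `results/`:

1. `01_simulate_phantom.R` — cohort of multi-echo phantom sessions with
   ground truth;
2. `02_fit_relaxometry.R` — voxelwise R2\* maps and accuracy vs truth;
3. `03_quantify_delta.R` — ΔR2\*/percent maps, CNR, uptake plateau,
   stratification, subtraction-map ROI discovery;
4. `04_qpcr.R` — ΔΔCt quantification and copy numbers;
5. `05_calibration.R` — the ΔR2\*-vs-copy-number regression and
   power-based sample-size planning (85% power, α 0.05);
6. `06_behavior.R` — locomotor distances and onset delays per paradigm;
7. `07_oligo_checks.R` — probe specificity and amplicon arithmetic.

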