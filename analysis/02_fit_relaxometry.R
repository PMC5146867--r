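#!/usr/bin/env Rscript
# Voxelwise R2* relaxometry on the simulated cohort: log-linear
# weighted least squares per voxel, accuracy benchmarked against the
# phantom ground truth.

library(mcemri)

out <- "results/02_relaxometry"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config()
seed <- 20260927L

rows <- list()
for (p in c("S1", "A7WA")) {
  s <- generate_phantom(cfg, p, seed = seed)
  fit <- fit_r2star_map(s$baseline)
  write_map_nifti(fit, file.path(out, sprintf("%s_baseline_r2star.nii.gz", p)))
  err <- abs(fit$r2star - s$truth$true_baseline_r2star) /
    s$truth$true_baseline_r2star
  rows[[p]] <- data.frame(
    paradigm = p, n_voxels = sum(fit$fit_ok),
    median_rel_err = median(err[fit$fit_ok]),
    p90_rel_err = quantile(err[fit$fit_ok], 0.9))
  cat(sprintf("[%s] baseline fit: median |rel err| %.3f over %d voxels\n",
              p, rows[[p]]$median_rel_err, rows[[p]]$n_voxels))
}
tab <- do.call(rbind, rows)
write.table(tab, file.path(out, "fit_accuracy.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)

# the same fit on noiseless data is exact to numerical precision
cfg0 <- phantom_config(noise_sigma = 0, subject_sd_scale = 0)
s0 <- generate_phantom(cfg0, "S1", seed = seed)
f0 <- fit_r2star_map(s0$baseline)
cat(sprintf("noiseless max |error|: %.2e s^-1\n",
            max(abs(f0$r2star - s0$truth$true_baseline_r2star))))
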