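#!/usr/bin/env Rscript
# Build the synthetic study cohort: one multi-echo phantom session per
# paradigm with known ground truth, written under results/01_phantom/.
# The forward model puts bound iron proportional to each gene's copy
# number into its target ROI and elevates R2* by 33.9 s^-1 per mM.

library(mcemri)

out <- "results/01_phantom"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config()         # 64 x 64 x 16, six echoes, SNR 40
seed <- 20260927L

sessions <- lapply(c(S1 = "S1", A7WS = "A7WS", A7WA = "A7WA"),
                   function(p) generate_phantom(cfg, p, seed = seed))

for (p in names(sessions)) {
  s <- sessions[[p]]
  write_multi_echo_nifti(s$baseline,
                         file.path(out, sprintf("%s_baseline.nii.gz", p)))
  write_truth_json(s$truth, file.path(out, sprintf("%s_truth.json", p)))
  fe <- s$truth$true_bound_fe
  cat(sprintf("[%s] plateau bound Fe (mM): %s\n", p,
              paste(sprintf("%s=%.3f", rownames(fe),
                            fe[, ncol(fe)]), collapse = ", ")))
}
write_roi_labels_nifti(cfg, file.path(out, "roi_labels.nii.gz"))

# uptake schedule used throughout: rises to the plateau at 4 h and
# holds at 6 h
print(simulate_uptake_timecourse(cfg, 1))
cat("Sessions written to", out, "\n")
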