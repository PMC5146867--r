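#!/usr/bin/env Rscript
# Probe and primer design checks on the printed oligo panel: reverse
# complements, amplicon lengths (with the USP1 coordinate discrepancy
# surfaced), and the in-silico duplex calls that mirror the gel-shift
# specificity assay.

library(mcemri)

out <- "results/07_oligo"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

panel <- hdac5_oligo_panel()
write_oligo_fasta(panel, file.path(out, "oligo_panel.fasta"))

cat("sense target 20-mer reverse-complements to the probe:",
    reverse_complement(panel$hdac5)$bases == panel$miD2861$bases, "\n")

cat(sprintf("USP2 / hdac5AS2 amplicon: %d bp\n",
            amplicon_length(panel$USP2, panel$hdac5AS2)))
cat(sprintf(paste0("USP1 / miD2861 amplicon from the annotated spans: %d bp",
                   " (USP1 span 971-980 is 10 nt for a 20-mer;",
                   " flagged, not corrected)\n"),
            amplicon_length(panel$USP1, panel$miD2861)))

nms <- names(panel)
calls <- do.call(rbind, lapply(seq_along(nms), function(i) {
  do.call(rbind, lapply(seq_along(nms), function(j) {
    if (j <= i) return(NULL)
    d <- duplex_call(panel[[i]], panel[[j]])
    data.frame(a = nms[i], b = nms[j], run = d$run, bound = d$bound)
  }))
}))
cat("bound pairs at min_run 12:\n")
print(calls[calls$bound, ], row.names = FALSE)
write.table(calls, file.path(out, "duplex_calls.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
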