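#!/usr/bin/env Rscript
# Stage 2: marker-level association and the nested conditional omnibus scan
# on the pooled synthetic study (quality filter r2 > 0.7, omnibus threshold
# 5e-5). Writes the per-marker table, the conditional ledger, and the list
# of independent positions.

library(hlafinemap)

panel <- read_panel("results/sim/panel.tsv")
dm <- read_dosage("results/sim/dosage.tsv", panel)
dm <- filter_markers(dm, r2_min = 0.7)

# per-marker logistic association (the supplementary-table layout)
mk <- do.call(rbind, lapply(seq_len(ncol(dm$dosage)), function(j) {
  r <- fit_biallelic(dm$dosage[, j], panel)
  cbind(marker = colnames(dm$dosage)[j], r)
}))
write.table(mk, "results/marker_assoc.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
top <- mk[order(mk$p), ][1:5, c("marker", "or", "p")]
cat("strongest marker associations:\n")
print(top, row.names = FALSE)

sc <- stepwise_scan(dm, panel, alpha_omnibus = 5e-5)
write.table(sc$ledger, "results/conditional_ledger.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(sc$selected, "results/independent_positions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("\nindependent positions in order of entry:\n")
print(sc$selected, row.names = FALSE)
cat("\nAt one tenth of the published sample sizes only the strongest",
    "planted signals clear 5e-5; the full set is recovered in the",
    "package's full-scale recovery experiments.\n")
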