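#!/usr/bin/env Rscript
# Stage 8: structure-coloring of per-position association strengths:
# -log10(omnibus p) linearly mapped to RGB (x, 0, 1-x), most associated
# position deep red, least associated deep blue. Emits a plain-text
# position -> RGB script.

library(hlafinemap)

led <- read.delim("results/conditional_ledger.tsv")
first <- led[led$step == 1 & led$stage == "scan" & !is.na(led$p), ]
nl <- -log10(pmax(first$p, .Machine$double.xmin))
cm <- color_map(nl)
lab <- paste0(first$gene, "_", first$aa_pos)
write_color_script(lab, cm, "results/position_colors.txt")

ord <- order(-cm$value)
cat("position color ramp (most to least associated):\n")
print(data.frame(position = lab, neglog10p = round(nl, 2),
                 r = round(cm$r, 3), b = round(cm$b, 3))[ord, ],
      row.names = FALSE)
cat("\nwrote results/position_colors.txt\n")
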