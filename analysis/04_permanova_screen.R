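#!/usr/bin/env Rscript
# PERMANOVA screen of every group pair at every day (9999 permutations,
# unadjusted P < 0.05); significant pairs feed the random-forest stage.
suppressPackageStartupMessages(library(otudyn))

D <- as.matrix(read.delim("results/bray_curtis.tsv", row.names = 1,
                          check.names = FALSE))
meta <- read.delim("results/sample_metadata.tsv")
design <- list(groups = unique(meta$group), days = sort(unique(meta$day)))
screen <- pairwise_screen(D, meta, default_contrasts(design),
                          n_perm = 9999, seed = 21)
write.table(screen, "results/permanova_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cat(sprintf("%d of %d contrasts significant at P < 0.05\n",
            sum(screen$significant, na.rm = TRUE), nrow(screen)))
print(screen[screen$significant %in% TRUE, c("contrast", "pseudo_F", "p_value")],
      row.names = FALSE)
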