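#!/usr/bin/env Rscript
# Per-OTU Mann-Whitney tests vs the DSS reference at each day, BH-adjusted
# within each contrast (FDR < 0.05), with enrichment direction.
suppressPackageStartupMessages(library(otudyn))

rar <- read.delim("results/rarefied_counts.tsv", check.names = FALSE)
counts <- as.matrix(rar[, -1]); rownames(counts) <- rar$sample_id
abund <- counts / rowSums(counts)
meta <- read.delim("results/sample_metadata.tsv")
meta <- meta[match(rownames(abund), meta$sample_id), ]

all_res <- list()
for (g in setdiff(unique(meta$group), "DSS")) {
  for (d in sort(unique(meta$day))) {
    ct <- list(a = list(group = g, day = d), b = list(group = "DSS", day = d))
    res <- differential_otus(abund, meta, ct)
    res$contrast <- sprintf("%s_vs_DSS_day%d", g, d)
    all_res[[res$contrast[1]]] <- res
    cat(sprintf("%-24s %2d enriched, %2d depleted at FDR < 0.05\n",
                res$contrast[1],
                sum(res$significant & res$direction == "enriched"),
                sum(res$significant & res$direction == "depleted")))
  }
}
out <- do.call(rbind, all_res)
write.table(out, "results/differential_otus.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
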