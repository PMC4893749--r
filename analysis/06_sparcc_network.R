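#!/usr/bin/env Rscript
# SparCC basis correlations among the key OTUs, permutation pseudo-p-values
# (100 null datasets), and the |rho| > 0.5 network.
suppressPackageStartupMessages(library(otudyn))

rar <- read.delim("results/rarefied_counts.tsv", check.names = FALSE)
counts <- as.matrix(rar[, -1]); rownames(counts) <- rar$sample_id
keys <- read.delim("results/key_otus.tsv")$otu_id
counts <- counts[, keys, drop = FALSE]

sp <- sparcc_estimate(counts, seed = 41)
pv <- sparcc_null_pvalues(counts, sp$rho, n_null = 100, seed = 42)
write.table(sp$rho, "results/sparcc_rho.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
write.table(pv, "results/sparcc_pvalues.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
net <- build_network(sp, edge_threshold = 0.5,
                     abundance = colMeans(counts / rowSums(counts)))
write_network(net, "results/network_edges.tsv", "results/network.graphml")
cat(sprintf("SparCC on %d key OTUs: %d edges with |rho| > 0.5 (%d positive)\n",
            length(keys), nrow(net$edges), sum(net$edges$sign == "positive")))
if ("OTU_invader" %in% keys) {
  corr <- invader_correlates(sp, "OTU_invader")
  cat(sprintf("invader correlates: %d positive (%s), %d negative\n",
              length(corr$positive), paste(corr$positive, collapse = ", "),
              length(corr$negative)))
}
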