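#!/usr/bin/env Rscript
# Rarefy to 9000 reads, compute alpha diversity (mean over 100 repetitions),
# Bray-Curtis distances, PCoA, and the distance-from-baseline trajectories.
suppressPackageStartupMessages(library(otudyn))

tab <- read_otu_table("results/otu_counts.tsv", "results/sample_metadata.tsv")
rar <- rarefy(tab, depth = 9000, n_rep = 100, seed = 11)
write.table(data.frame(sample_id = rownames(rar$counts), rar$counts,
                       check.names = FALSE),
            "results/rarefied_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(rar$alpha, "results/alpha_diversity.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

D <- bray_curtis(rar)
write.table(D, "results/bray_curtis.tsv", sep = "\t", quote = FALSE,
            col.names = NA)
ord <- pcoa(D)
write.table(data.frame(sample_id = rownames(ord$coordinates),
                       ord$coordinates[, 1:3]),
            "results/pcoa_coordinates.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
traj <- distance_from_baseline(D, rar$metadata)
write.table(traj, "results/baseline_distance.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("rarefied %d samples (excluded %d); PC1 explains %.1f%% of positive inertia\n",
            nrow(rar$counts), length(rar$excluded_samples),
            100 * ord$proportion_explained[1]))
d4 <- function(g) traj$mean_dist[traj$group == g & traj$day == 4]
cat(sprintf("day-4 shift from baseline: DSS+BPB5 %.3f vs DSS %.3f vs PBS %.3f\n",
            d4("DSS_BPB5"), d4("DSS"), d4("PBS")))
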