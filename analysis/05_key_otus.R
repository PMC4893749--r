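#!/usr/bin/env Rscript
# 1000-tree random forests on each screened pair; models with OOB class
# error 0 are successful, and OTUs with mean decrease in accuracy > 0.003
# in any successful model are the key OTUs.
suppressPackageStartupMessages(library(otudyn))

rar <- read.delim("results/rarefied_counts.tsv", check.names = FALSE)
counts <- as.matrix(rar[, -1]); rownames(counts) <- rar$sample_id
abund <- counts / rowSums(counts)
meta <- read.delim("results/sample_metadata.tsv")
meta <- meta[match(rownames(abund), meta$sample_id), ]
screen <- read.delim("results/permanova_screen.tsv")
design <- list(groups = unique(meta$group), days = sort(unique(meta$day)))
contrasts <- default_contrasts(design)

models <- list()
for (ci in which(screen$significant %in% TRUE)) {
  ct <- contrasts[[ci]]
  ia <- which(meta$group %in% ct$a$group & meta$day %in% ct$a$day)
  ib <- which(meta$group %in% ct$b$group & meta$day %in% ct$b$day)
  models[[ct$name]] <- fit_pair_model(
    abund[c(ia, ib), ], c(rep("a", length(ia)), rep("b", length(ib))),
    seed = 31 + ci, pair_id = ct$name
  )
}
keys <- select_key_otus(models)
write.table(data.frame(otu_id = keys$otu_ids,
                       provenance = vapply(keys$provenance, paste, "",
                                           collapse = ";")),
            "results/key_otus.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("%d/%d models successful (OOB error 0); %d non-redundant key OTUs\n",
            keys$n_models_used, length(models), length(keys$otu_ids)))
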