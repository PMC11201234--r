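#!/usr/bin/env Rscript
# Stage 4: significance filter (FDR < 0.5, |fold change| > 1.5, both as the
# published analysis states them) and top-10 selection per direction by
# change coefficient, plus the heatmap data table for the selected genes.

suppressPackageStartupMessages(library(stenoseq))
out <- "results/sim"
stopifnot(file.exists(file.path(out, "de_results.tsv")))

de <- read.delim(file.path(out, "de_results.tsv"))
sig <- filter_significant(de, fdr_threshold = 0.5, fc_threshold = 1.5)
ranked <- top_k_dysregulated(sig, k = 10)

counts <- read_count_matrix(file.path(out, "counts.tsv"))
labels <- ranked_gene_labels(ranked)
flat <- cbind(direction = rep(c("up", "down"),
                              c(nrow(ranked$up), nrow(ranked$down))),
              rank = c(seq_len(nrow(ranked$up)), seq_len(nrow(ranked$down))),
              rbind(ranked$up, ranked$down))
write.table(flat, file.path(out, "ranked_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(heatmap_table(counts, labels$gene), file.path(out, "heatmap.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

truth <- read.delim(file.path(out, "truth.tsv"))
planted <- truth$gene[truth$is_de]
cat(sprintf("%d of %d genes pass the filter; top-10 lists selected\n",
            nrow(sig), nrow(de)))
cat(sprintf("%d of the %d ranked genes carry a planted fold change\n",
            sum(labels$gene %in% planted), nrow(labels)))
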