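#!/usr/bin/env Rscript
# Stage 6: over-representation analysis of the up- and downregulated lists
# against gene sets built from the planted truth (one set per planted
# direction plus random decoys), testing that the ORA stage flags the
# matching sets.

suppressPackageStartupMessages(library(stenoseq))
out <- "results/sim"
stopifnot(file.exists(file.path(out, "ranked_genes.tsv")))

truth <- read.delim(file.path(out, "truth.tsv"))
ranked <- read.delim(file.path(out, "ranked_genes.tsv"))
de <- read.delim(file.path(out, "de_results.tsv"))

set.seed(1)
gmt <- file.path(out, "sets_synthetic.gmt")
lines <- c(
  paste(c("PLANTED_UP", "planted upregulated genes",
          truth$gene[truth$direction == "up"]), collapse = "\t"),
  paste(c("PLANTED_DOWN", "planted downregulated genes",
          truth$gene[truth$direction == "down"]), collapse = "\t"),
  vapply(1:5, function(i)
    paste(c(sprintf("DECOY_%d", i), "random decoy set",
            sample(truth$gene, 40)), collapse = "\t"), ""))
writeLines(lines, gmt)
sets <- read_gene_sets_gmt(gmt)

ranked_tab <- top_k_dysregulated(filter_significant(de), k = 10)
res <- enrich_by_direction(ranked_tab, sets, universe = de$gene, alpha = 0.05)
write.table(res, file.path(out, "enrichment.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

sig <- res[res$significant, c("direction", "set", "overlap_count", "benjamini_p")]
cat("significant sets (Benjamini p < 0.05):\n")
print(sig, row.names = FALSE)
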