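#!/usr/bin/env Rscript
# Stage 5: rank agents/families by how many of the top-ranked dysregulated
# genes they regulate, and check that the agent planted as best by the
# simulator is recovered against the planted gene list.

suppressPackageStartupMessages(library(stenoseq))
out <- "results/sim"
stopifnot(file.exists(file.path(out, "ranked_genes.tsv")))

drugs <- read_drug_gene_table(file.path(out, "drug_gene.csv"))
ranked <- read.delim(file.path(out, "ranked_genes.tsv"))
truth <- read.delim(file.path(out, "truth.tsv"))
designated <- readLines(file.path(out, "designated_agent.txt"))

# against the planted truth: the designated agent must come out on top
planted <- truth[truth$is_de, c("gene", "direction")]
vs_truth <- rank_drugs(drugs, planted, mode = "favorable")
write.table(vs_truth, file.path(out, "drug_ranking_truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
cat(sprintf("vs planted genes: best family '%s' covers %d (designated: '%s')\n",
            vs_truth$family[1], vs_truth$total[1], designated))

# against the pipeline's own top-ranked genes, as the real analysis would run
vs_ranked <- rank_drugs(drugs, ranked[, c("gene", "direction")], mode = "any")
write.table(vs_ranked, file.path(out, "drug_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
if (nrow(vs_ranked))
  cat(sprintf("vs top-ranked genes: best family '%s' covers %d of %d\n",
              vs_ranked$family[1], vs_ranked$total[1], nrow(ranked)))
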