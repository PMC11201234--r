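#!/usr/bin/env Rscript
# Stage 1: the desk-scale analysis on the packaged published tables.
# Ranks the 20 dysregulated genes by change coefficient and tallies which
# drug families regulate the most of them, in both counting modes.

suppressPackageStartupMessages(library(stenoseq))
out <- "results/fixture"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

fr_any <- fixture_report(mode = "any", k = 10)
fr_fav <- fixture_report(mode = "favorable", k = 10)

write.table(fr_any$ranked_genes, file.path(out, "ranked_genes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(rbind(fr_any$drug_ranking, fr_fav$drug_ranking),
            file.path(out, "drug_ranking.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

up1 <- fr_any$ranked$up[1, ]
dn1 <- fr_any$ranked$down[1, ]
cat(sprintf("top upregulated: %s (change coefficient %.2f, fold change %.2f)\n",
            up1$gene, up1$change_coefficient, up1$signed_fold_change))
cat(sprintf("top downregulated: %s (change coefficient %.2f, fold change %.2f)\n",
            dn1$gene, dn1$change_coefficient, dn1$signed_fold_change))
ret <- fr_any$drug_ranking[fr_any$drug_ranking$family == "retinoids", ]
vpa <- fr_any$drug_ranking[fr_any$drug_ranking$family == "valproic acid", ]
cat(sprintf("retinoids regulate %d up + %d down = %d genes (mode any);\n",
            ret$up_count, ret$down_count, ret$total))
cat(sprintf("valproic acid regulates %d up + %d down = %d (mode any).\n",
            vpa$up_count, vpa$down_count, vpa$total))
retf <- fr_fav$drug_ranking[fr_fav$drug_ranking$family == "retinoids", ]
cat(sprintf("counted favorably only, retinoids cover %d genes.\n", retf$total))
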