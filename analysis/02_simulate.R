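#!/usr/bin/env Rscript
# Stage 2: generate a synthetic dataset with the statistical structure the
# analysis assumes (11 specimens from 8 patients vs 2 controls, NB counts,
# planted fold changes, a few near-silenced genes) plus a drug-gene table
# whose best agent is known by construction.

suppressPackageStartupMessages(library(stenoseq))
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(n_genes = 2000, de_fraction = 0.05,
                         extreme_fraction = 0.1, seed = 20240614)
sim <- simulate_counts(cfg)
drugs <- simulate_drug_table(sim$truth, n_agents = 20,
                             cover_k = 7, noise_edges = 3, seed = cfg$seed)

write_count_matrix(sim$counts, file.path(out, "counts.tsv"), "tsv")
write_sample_metadata(sim$counts$metadata, file.path(out, "metadata.tsv"))
write.table(sim$truth, file.path(out, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.csv(drugs, file.path(out, "drug_gene.csv"), row.names = FALSE, quote = FALSE)
writeLines(attr(drugs, "designated_agent"), file.path(out, "designated_agent.txt"))

n_de <- sum(sim$truth$is_de)
cat(sprintf("simulated %d genes x %d samples; %d planted DE genes (%d extreme)\n",
            nrow(sim$counts$counts), ncol(sim$counts$counts),
            n_de, sum(sim$truth$is_extreme)))
cat(sprintf("designated agent '%s' favorably covers 7 planted genes\n",
            attr(drugs, "designated_agent")))
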