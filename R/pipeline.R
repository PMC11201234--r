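#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load -> differential expression -> significance
#' filter -> change-coefficient ranking -> drug-family prioritization ->
#' over-representation analysis. Inputs may be in-memory objects or file
#' paths; either real count data or a simulation config must be supplied.
#' With an output directory, all stage tables are written as TSV plus a
#' `manifest.json` (written last) echoing the configuration, seed and row
#' counts; identical configuration and seed give byte-identical outputs.
#'
#' @param counts a [count_matrix()] or path to a counts TSV.
#' @param metadata sample metadata data.frame or path (ignored if `counts`
#'   already carries metadata).
#' @param drug_table interaction data.frame or CSV path (optional).
#' @param gene_sets a gene-set collection or GMT path (optional).
#' @param sim_config a [simulation_config()] used instead of real counts;
#'   when no `drug_table` is given, one is simulated from the planted
#'   truth with the same seed.
#' @param fdr_threshold,fc_threshold significance filter, see
#'   [filter_significant()].
#' @param k top-k selection size per direction.
#' @param mode drug counting mode, `"any"` or `"favorable"`.
#' @param alpha enrichment significance level.
#' @param pseudocount CPM pseudocount.
#' @param method differential-expression test, see
#'   [differential_expression()].
#' @param family_map agent-family map for drug scoring.
#' @param out_dir optional output directory for the report bundle.
#' @return list of class `report_bundle`: de_results, ranked (a
#'   `ranked_gene_table`), ranked_genes (flat table), drug_ranking,
#'   enrichment, volcano, heatmap, truth (simulated runs only), manifest.
#' @export
run_pipeline <- function(counts = NULL, metadata = NULL, drug_table = NULL,
                         gene_sets = NULL, sim_config = NULL,
                         fdr_threshold = 0.5, fc_threshold = 1.5, k = 10,
                         mode = c("any", "favorable"), alpha = 0.05,
                         pseudocount = 0.5,
                         method = c("auto", "welch_log", "proportion_z"),
                         family_map = default_family_map(), out_dir = NULL) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  if (is.null(counts) && is.null(sim_config))
    stop_data("supply either `counts` or `sim_config`")

  truth <- NULL
  if (is.null(counts)) {
    sim <- simulate_counts(sim_config)
    counts <- sim$counts
    truth <- sim$truth
    if (is.null(drug_table)) {
      n_de <- sum(truth$is_de)
      if (n_de > 0)
        drug_table <- simulate_drug_table(truth, cover_k = min(7L, n_de),
                                          seed = sim_config$seed)
    }
  } else {
    if (is.character(counts)) counts <- read_count_matrix(counts)
    if (!is.null(metadata)) {
      if (is.character(metadata)) metadata <- read_sample_metadata(metadata)
      counts <- set_sample_metadata(counts, metadata)
    }
  }
  if (is.character(drug_table)) drug_table <- read_drug_gene_table(drug_table)
  if (is.character(gene_sets)) gene_sets <- read_gene_sets_gmt(gene_sets)

  de <- differential_expression(counts, method, pseudocount)
  sig <- filter_significant(de, fdr_threshold, fc_threshold)
  ranked <- top_k_dysregulated(sig, k)
  labels <- ranked_gene_labels(ranked)

  drug_ranking <- if (!is.null(drug_table) && nrow(labels))
    rank_drugs(drug_table, labels, family_map, mode)
  else data.frame(family = character(), mode = character(),
                  up_count = integer(), down_count = integer(),
                  total = integer(), covered_genes = character(),
                  stringsAsFactors = FALSE)

  enrichment <- if (!is.null(gene_sets))
    enrich_by_direction(ranked, gene_sets, universe = de$gene, alpha)
  else NULL

  bundle <- structure(list(
    de_results = de,
    ranked = ranked,
    ranked_genes = flatten_ranked(ranked),
    drug_ranking = drug_ranking,
    enrichment = enrichment,
    volcano = volcano_table(de),
    heatmap = if (nrow(labels)) heatmap_table(counts, labels$gene, pseudocount)
              else NULL,
    truth = truth,
    manifest = list(
      package = "stenoseq",
      version = as.character(utils::packageVersion("stenoseq")),
      seed = if (!is.null(sim_config)) sim_config$seed else NA,
      config = list(fdr_threshold = fdr_threshold, fc_threshold = fc_threshold,
                    k = k, mode = mode, alpha = alpha,
                    pseudocount = pseudocount, method = method),
      n_genes = nrow(de), n_significant = nrow(sig),
      n_ranked_up = nrow(ranked$up), n_ranked_down = nrow(ranked$down),
      n_drug_families = nrow(drug_ranking))),
    class = "report_bundle")

  if (!is.null(out_dir)) write_report_bundle(bundle, out_dir)
  bundle
}

flatten_ranked <- function(ranked) {
  up <- ranked$up; down <- ranked$down
  data.frame(
    direction = rep(c("up", "down"), c(nrow(up), nrow(down))),
    rank = c(seq_len(nrow(up)), seq_len(nrow(down))),
    rbind(up, down),
    stringsAsFactors = FALSE, row.names = NULL)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8")
  invisible(path)
}

#' Write a report bundle as TSV tables plus a JSON manifest
#'
#' The manifest is written last so a crashed run never leaves a manifest
#' describing missing files.
#'
#' @param bundle a `report_bundle` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, out_dir) {
  stopifnot(inherits(bundle, "report_bundle"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(bundle$de_results, file.path(out_dir, "de_results.tsv"))
  write_tsv(bundle$ranked_genes, file.path(out_dir, "ranked_genes.tsv"))
  write_tsv(bundle$drug_ranking, file.path(out_dir, "drug_ranking.tsv"))
  write_tsv(bundle$volcano, file.path(out_dir, "volcano.tsv"))
  if (!is.null(bundle$heatmap))
    write_tsv(bundle$heatmap, file.path(out_dir, "heatmap.tsv"))
  if (!is.null(bundle$enrichment))
    write_tsv(bundle$enrichment, file.path(out_dir, "enrichment.tsv"))
  if (!is.null(bundle$truth))
    write_tsv(bundle$truth, file.path(out_dir, "truth.tsv"))
  jsonlite::write_json(bundle$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Rank and drug-prioritization report from the packaged published tables
#'
#' Feeds the packaged table of 20 dysregulated genes through
#' [top_k_dysregulated()] and the packaged drug-gene table through
#' [rank_drugs()] — the desk-scale restriction of the pipeline to the
#' stages whose published inputs are fully reproducible.
#'
#' @param mode drug counting mode.
#' @param k selection size per direction.
#' @return list with `ranked` (a `ranked_gene_table`), `ranked_genes`
#'   (flat table) and `drug_ranking`.
#' @export
fixture_report <- function(mode = c("any", "favorable"), k = 10) {
  mode <- match.arg(mode)
  t1 <- load_fixture_table1()
  ranked <- top_k_dysregulated(t1, k)
  t2 <- load_fixture_table2()
  labels <- data.frame(gene = names(t2$gene_status),
                       direction = unname(t2$gene_status),
                       stringsAsFactors = FALSE)
  list(ranked = ranked,
       ranked_genes = flatten_ranked(ranked),
       drug_ranking = rank_drugs(t2$interactions, labels, mode = mode))
}
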