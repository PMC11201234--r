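#' Upper-tail hypergeometric p-value for a gene-set overlap
#'
#' `P(X >= overlap)` when drawing `query_size` genes without replacement
#' from a universe of `universe` genes of which `set_size` belong to the
#' set — the standard over-representation test.
#'
#' @param overlap observed overlap between query and set.
#' @param set_size number of universe genes in the set.
#' @param query_size number of query genes.
#' @param universe universe size.
#' @return p-value in (0, 1].
#' @export
hypergeometric_tail <- function(overlap, set_size, query_size, universe) {
  ok <- overlap >= 0 & set_size >= 0 & query_size >= 0 & universe >= 1 &
    overlap <= pmin(set_size, query_size) &
    set_size <= universe & query_size <= universe
  if (any(!ok)) stop_data("inconsistent hypergeometric counts")
  phyper(overlap - 1, set_size, universe - set_size, query_size,
         lower.tail = FALSE)
}

#' Over-representation analysis of a gene list against gene sets
#'
#' Hypergeometric upper-tail test of each set's overlap with the query,
#' Benjamini-Hochberg adjusted across all tested sets (the same
#' adjustment used for the differential expression stage). The universe
#' defaults in the pipeline to the genes actually tested for differential
#' expression, the standard background choice. Query genes absent from
#' the universe are dropped with a warning; only sets intersecting the
#' universe are tested.
#'
#' @param query_genes character vector of query gene symbols.
#' @param sets a `gene_set_collection` from [read_gene_sets_gmt()] or a
#'   named list of character vectors.
#' @param universe character vector of background gene symbols.
#' @param alpha significance threshold on the adjusted p (default 0.05).
#' @return data.frame with columns set, overlap_count, set_size,
#'   query_size, universe_size, raw_p, benjamini_p, significant; ordered
#'   by raw_p.
#' @export
enrich <- function(query_genes, sets, universe, alpha = 0.05) {
  universe <- unique(normalize_gene(universe))
  if (!length(universe)) stop_data("empty universe")
  query <- unique(normalize_gene(query_genes))
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) absent from universe dropped",
            call. = FALSE)
    query <- setdiff(query, outside)
  }
  members <- lapply(sets, function(s) intersect(unique(normalize_gene(s)), universe))
  keep <- vapply(members, length, 0L) > 0L
  members <- members[keep]
  if (!length(members))
    return(data.frame(set = character(), overlap_count = integer(),
                      set_size = integer(), query_size = integer(),
                      universe_size = integer(), raw_p = numeric(),
                      benjamini_p = numeric(), significant = logical(),
                      stringsAsFactors = FALSE))
  overlap <- vapply(members, function(s) length(intersect(s, query)), 0L)
  set_size <- vapply(members, length, 0L)
  raw <- hypergeometric_tail(overlap, set_size, length(query), length(universe))
  adj <- benjamini_hochberg(raw)
  out <- data.frame(
    set = names(members), overlap_count = overlap, set_size = set_size,
    query_size = length(query), universe_size = length(universe),
    raw_p = raw, benjamini_p = adj, significant = adj < alpha,
    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$raw_p, out$set), , drop = FALSE]
}

#' Direction-wise enrichment of a ranked gene table
#'
#' Runs [enrich()] separately for the up- and downregulated gene lists,
#' mirroring the practice of analyzing the two directions apart.
#'
#' @param ranked a `ranked_gene_table`.
#' @param sets,universe,alpha as in [enrich()].
#' @return data.frame as [enrich()] with a leading `direction` column.
#' @export
enrich_by_direction <- function(ranked, sets, universe, alpha = 0.05) {
  stopifnot(inherits(ranked, "ranked_gene_table"))
  parts <- lapply(c(up = "up", down = "down"), function(d) {
    genes <- if (d == "up") ranked$up$gene else ranked$down$gene
    if (!length(genes)) return(NULL)
    res <- enrich(genes, sets, universe, alpha)
    if (!nrow(res)) return(NULL)
    cbind(direction = d, res, stringsAsFactors = FALSE)
  })
  parts <- parts[!vapply(parts, is.null, TRUE)]
  if (!length(parts))
    return(data.frame(direction = character(), set = character(),
                      overlap_count = integer(), set_size = integer(),
                      query_size = integer(), universe_size = integer(),
                      raw_p = numeric(), benjamini_p = numeric(),
                      significant = logical(), stringsAsFactors = FALSE))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
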