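#' Signed change coefficient
#'
#' The composite ranking statistic combining statistical and biological
#' effect: `|coefficient| = -log2(FDR p) * log2(|fold change|)`, signed by
#' the fold-change direction so downregulated genes get negative
#' coefficients. It is zero only when the FDR p is 1 or the fold change
#' magnitude is 1, strictly increasing in |fold change| at fixed p < 1 and
#' in -log2 p at fixed |fold change| > 1.
#'
#' @param fdr_p FDR-adjusted p-value(s) in (0, 1] (floored upstream at
#'   1e-300 so the log stays finite).
#' @param signed_fc signed fold change(s), |value| >= 1.
#' @return signed change coefficient(s).
#' @export
change_coefficient <- function(fdr_p, signed_fc) {
  if (any(!is.finite(fdr_p)) || any(fdr_p <= 0) || any(fdr_p > 1))
    stop_data("fdr_p must lie in (0, 1]")
  if (any(!is.finite(signed_fc)) || any(abs(signed_fc) < 1))
    stop_data("|signed_fc| must be >= 1")
  sign(signed_fc) * (-log2(fdr_p)) * log2(abs(signed_fc))
}

#' Significance filter on differential-expression records
#'
#' Keeps genes with `fdr_p < fdr_threshold` and
#' `|signed_fold_change| > fc_threshold`, both strictly. The defaults are
#' the thresholds of the targeted analysis as printed — an FDR p below 0.5
#' and a fold change above 1.5; note the FDR cutoff is unusually
#' permissive (0.05 is conventional) and is deliberately left at its
#' printed value, adjustable via `fdr_threshold`.
#'
#' @param records data.frame from [differential_expression()].
#' @param fdr_threshold FDR cutoff in (0, 1], default 0.5.
#' @param fc_threshold fold-change magnitude cutoff >= 1, default 1.5.
#' @return the filtered subset of `records`.
#' @export
filter_significant <- function(records, fdr_threshold = 0.5, fc_threshold = 1.5) {
  stopifnot(is.data.frame(records),
            all(c("fdr_p", "signed_fold_change") %in% names(records)))
  if (fdr_threshold < 0 || fdr_threshold > 1)
    stop_data("fdr_threshold must be in [0, 1]")
  if (fc_threshold < 1) stop_data("fc_threshold must be >= 1")
  keep <- records$fdr_p < fdr_threshold &
    abs(records$signed_fold_change) > fc_threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Top-k up- and downregulated genes by change coefficient
#'
#' Scores each record (computing the change coefficient from `fdr_p` when
#' a `change_coefficient` column is not already present, as in the
#' packaged published table) and selects the `k` largest positive and `k`
#' most negative coefficients. Ties are broken by larger fold-change
#' magnitude, then lexicographic gene symbol.
#'
#' @param records data.frame with columns `gene`, `signed_fold_change` and
#'   either `change_coefficient` or `fdr_p`; normally the output of
#'   [filter_significant()].
#' @param k selection size per direction (default 10).
#' @return object of class `ranked_gene_table`: list with data.frames
#'   `up` (coefficient descending) and `down` (ascending, most negative
#'   first), each with columns gene, signed_fold_change, fdr_p (NA when
#'   unavailable), change_coefficient; plus the selection size `k`.
#' @export
top_k_dysregulated <- function(records, k = 10) {
  stopifnot(is.data.frame(records))
  if (k <= 0) stop_data("k must be positive")
  if (!"signed_fold_change" %in% names(records) && "fold_change" %in% names(records))
    records$signed_fold_change <- records$fold_change
  if (!all(c("gene", "signed_fold_change") %in% names(records)))
    stop_data("records need columns gene and signed_fold_change")
  cc <- if ("change_coefficient" %in% names(records)) records$change_coefficient
        else change_coefficient(records$fdr_p, records$signed_fold_change)
  scored <- data.frame(
    gene = records$gene,
    signed_fold_change = records$signed_fold_change,
    fdr_p = if ("fdr_p" %in% names(records)) records$fdr_p else NA_real_,
    change_coefficient = cc,
    stringsAsFactors = FALSE)

  take <- function(df, decreasing) {
    ord <- order(df$change_coefficient * if (decreasing) -1 else 1,
                 -abs(df$signed_fold_change), df$gene)
    out <- df[ord, , drop = FALSE][seq_len(min(k, nrow(df))), , drop = FALSE]
    rownames(out) <- NULL
    out
  }
  structure(list(up = take(scored[scored$change_coefficient > 0, , drop = FALSE], TRUE),
                 down = take(scored[scored$change_coefficient < 0, , drop = FALSE], FALSE),
                 k = as.integer(k)),
            class = "ranked_gene_table")
}

#' @export
print.ranked_gene_table <- function(x, ...) {
  cat(sprintf("ranked_gene_table (k = %d): %d up, %d down\n",
              x$k, nrow(x$up), nrow(x$down)))
  if (nrow(x$up)) {
    cat("top up:\n"); print(utils::head(x$up, 3))
  }
  if (nrow(x$down)) {
    cat("top down:\n"); print(utils::head(x$down, 3))
  }
  invisible(x)
}

#' Labeled gene list of a ranked table
#'
#' @param ranked a `ranked_gene_table`.
#' @return data.frame with columns gene, direction ("up"/"down").
#' @export
ranked_gene_labels <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_gene_table"))
  data.frame(
    gene = c(ranked$up$gene, ranked$down$gene),
    direction = rep(c("up", "down"), c(nrow(ranked$up), nrow(ranked$down))),
    stringsAsFactors = FALSE)
}

#' Volcano-plot data table
#'
#' One row per gene: the signed log2 fold-change magnitude and
#' `-log10(FDR p)` — the coordinates of the conventional volcano display.
#'
#' @param records output of [differential_expression()].
#' @return data.frame with columns gene, log2_fc, neg_log10_fdr.
#' @export
volcano_table <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("gene", "signed_fold_change", "fdr_p") %in% names(records)))
  data.frame(
    gene = records$gene,
    log2_fc = sign(records$signed_fold_change) * log2(abs(records$signed_fold_change)),
    neg_log10_fdr = -log10(records$fdr_p),
    stringsAsFactors = FALSE)
}

#' Heatmap data table for selected genes
#'
#' Row-standardized (zero mean, unit variance across samples) log2-CPM
#' values of the selected genes — the data behind a per-sample expression
#' heatmap of the most dysregulated genes. Genes with zero variance across
#' samples are left centered at zero.
#'
#' @param counts a [count_matrix()].
#' @param genes character vector of gene symbols to include.
#' @param pseudocount pseudocount for normalization.
#' @return data.frame, first column `gene`, then one column per sample.
#' @export
heatmap_table <- function(counts, genes, pseudocount = 0.5) {
  stopifnot(inherits(counts, "count_matrix"))
  genes <- normalize_gene(genes)
  missing <- setdiff(genes, counts$gene_ids)
  if (length(missing))
    stop_data("genes absent from counts: ", paste(missing, collapse = ", "))
  lx <- log2(cpm_normalize(counts, pseudocount))[genes, , drop = FALSE]
  z <- t(apply(lx, 1L, function(v) {
    s <- stats::sd(v)
    if (s == 0) v - mean(v) else (v - mean(v)) / s
  }))
  data.frame(gene = genes, z, check.names = FALSE, stringsAsFactors = FALSE,
             row.names = NULL)
}
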