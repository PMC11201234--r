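# p-values are floored here before any -log2 downstream, so the change
# coefficient stays finite even for vanishing FDR values
P_FLOOR <- 1e-300

#' Counts-per-million normalization with pseudocount
#'
#' `(count + pseudocount) / (library_size + n_genes * pseudocount) * 1e6`,
#' where `library_size` is the raw column total. A positive pseudocount
#' keeps every normalized value strictly positive while damping very large
#' fold changes only minimally — the analysis must be able to report fold
#' decreases on the 1e5 scale.
#'
#' @param counts a [count_matrix()] or plain counts matrix.
#' @param pseudocount non-negative real added to every count (default 0.5).
#' @return numeric matrix of CPM values, same dimnames as the counts.
#' @export
cpm_normalize <- function(counts, pseudocount = 0.5) {
  m <- if (inherits(counts, "count_matrix")) counts$counts else counts
  if (pseudocount < 0) stop_data("pseudocount must be non-negative")
  lib <- colSums(m)
  if (any(lib == 0) && pseudocount == 0)
    stop_data("zero library size with zero pseudocount")
  denom <- lib + nrow(m) * pseudocount
  sweep(m + pseudocount, 2L, denom, "/") * 1e6
}

#' Signed fold change from an expression ratio
#'
#' The reporting convention of the analysis: an expression ratio
#' (specimen over control) of at least 1 is reported as-is; a ratio below
#' 1 is reported as the negative reciprocal, so a halving is -2. The
#' magnitude is therefore always >= 1 and the sign encodes direction.
#'
#' @param ratio positive expression ratio(s), specimen / control.
#' @return signed fold change(s), |value| >= 1.
#' @export
signed_fold_change <- function(ratio) {
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop_data("ratio must be positive and finite")
  ifelse(ratio >= 1, ratio, -1 / ratio)
}

#' Two-group test for one gene
#'
#' `welch_log`: two-sided Welch t-test on `log2(value + pseudocount)`;
#' requires >= 2 samples per group. When both groups are constant the
#' p-value is 1 for equal means and `1e-300` otherwise.
#' `proportion_z`: pools raw counts per group and compares the gene's read
#' proportion between groups with the two-sided z statistic
#' \eqn{z = (p_1 - p_2) / \sqrt{p_0 (1 - p_0)(1/N_1 + 1/N_2)}} where
#' \eqn{p_0} is the pooled proportion and \eqn{N_i} the group read totals;
#' it is usable with singleton groups.
#'
#' @param specimen,control for `welch_log`, normalized expression values;
#'   for `proportion_z`, raw per-sample counts for this gene.
#' @param method `"welch_log"` or `"proportion_z"`.
#' @param pseudocount offset inside the log for `welch_log`.
#' @param specimen_totals,control_totals per-sample library sizes
#'   (required for `proportion_z`).
#' @return two-sided p-value in (0, 1].
#' @export
group_test <- function(specimen, control, method = c("welch_log", "proportion_z"),
                       pseudocount = 0.5,
                       specimen_totals = NULL, control_totals = NULL) {
  method <- match.arg(method)
  if (method == "welch_log") {
    if (length(specimen) < 2L || length(control) < 2L)
      stop_data("welch_log needs >= 2 samples per group; use proportion_z")
    x <- log2(specimen + pseudocount)
    y <- log2(control + pseudocount)
    p <- tryCatch(t.test(x, y)$p.value,
                  error = function(e) if (isTRUE(all.equal(mean(x), mean(y)))) 1 else P_FLOOR)
    max(min(p, 1), P_FLOOR)
  } else {
    if (is.null(specimen_totals) || is.null(control_totals))
      stop_data("proportion_z needs library-size totals")
    x1 <- sum(specimen); n1 <- sum(specimen_totals)
    x2 <- sum(control);  n2 <- sum(control_totals)
    if (n1 <= 0 || n2 <= 0) stop_data("proportion_z needs positive group totals")
    p1 <- x1 / n1; p2 <- x2 / n2; p0 <- (x1 + x2) / (n1 + n2)
    se <- sqrt(p0 * (1 - p0) * (1 / n1 + 1 / n2))
    if (se == 0) return(1)
    z <- (p1 - p2) / se
    max(min(2 * pnorm(-abs(z)), 1), P_FLOOR)
  }
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjusted p-values (delegates to
#' [stats::p.adjust()]), order-aligned with the input. Adjusted values
#' never fall below the raw ones and are clipped at 1.
#'
#' @param p_values numeric vector of p-values in (0, 1].
#' @return FDR-adjusted p-values, same order as input.
#' @export
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) stop_data("empty p-value vector")
  if (any(!is.finite(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop_data("p-values must lie in (0, 1]")
  p.adjust(p_values, method = "BH")
}

#' Per-gene differential expression between specimen and control
#'
#' For every gene: group-mean CPM (with pseudocount), signed fold change
#' of the specimen mean over the control mean, a raw two-group p-value and
#' the Benjamini-Hochberg FDR over all genes. Method `"auto"` uses
#' `welch_log` when both groups have >= 2 samples and `proportion_z`
#' otherwise (the targeted design, 11 specimens vs 2 controls, allows
#' Welch). Repeat biopsies from one patient are treated as independent
#' replicates.
#'
#' @param counts a [count_matrix()] with metadata attached; both groups
#'   must be non-empty.
#' @param method `"auto"`, `"welch_log"` or `"proportion_z"`.
#' @param pseudocount pseudocount for normalization and the log transform.
#' @return data.frame with columns gene, mean_cpm_specimen,
#'   mean_cpm_control, signed_fold_change, raw_p, fdr_p.
#' @export
differential_expression <- function(counts, method = c("auto", "welch_log", "proportion_z"),
                                    pseudocount = 0.5) {
  method <- match.arg(method)
  stopifnot(inherits(counts, "count_matrix"))
  spec <- group_samples(counts, "specimen")
  ctrl <- group_samples(counts, "control")
  if (!length(spec) || !length(ctrl))
    stop_data("both specimen and control groups must be non-empty")
  if (method == "auto")
    method <- if (length(spec) >= 2L && length(ctrl) >= 2L) "welch_log" else "proportion_z"

  cpm <- cpm_normalize(counts, pseudocount)
  mean_spec <- rowMeans(cpm[, spec, drop = FALSE])
  mean_ctrl <- rowMeans(cpm[, ctrl, drop = FALSE])
  sfc <- signed_fold_change(mean_spec / mean_ctrl)

  raw <- if (method == "welch_log") {
    xs <- cpm[, spec, drop = FALSE]
    xc <- cpm[, ctrl, drop = FALSE]
    vapply(seq_along(counts$gene_ids), function(i)
      group_test(xs[i, ], xc[i, ], "welch_log", pseudocount), 0)
  } else {
    lib <- colSums(counts$counts)
    cs <- counts$counts[, spec, drop = FALSE]
    cc <- counts$counts[, ctrl, drop = FALSE]
    vapply(seq_along(counts$gene_ids), function(i)
      group_test(cs[i, ], cc[i, ], "proportion_z",
                 specimen_totals = lib[spec], control_totals = lib[ctrl]), 0)
  }
  raw <- pmax(raw, P_FLOOR)
  data.frame(
    gene = counts$gene_ids,
    mean_cpm_specimen = mean_spec,
    mean_cpm_control = mean_ctrl,
    signed_fold_change = sfc,
    raw_p = raw,
    fdr_p = pmax(benjamini_hochberg(raw), P_FLOOR),
    stringsAsFactors = FALSE, row.names = NULL)
}
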