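#' Gene-level count matrix with sample metadata
#'
#' The container for raw RNA-seq counts: a genes x samples matrix of
#' non-negative integers plus optional per-sample metadata assigning each
#' sample to the `specimen` (diseased tissue) or `control` (normal tissue)
#' group. Gene symbols are uppercase-normalized and must be unique; sample
#' ids must be unique; when metadata is attached it must cover every sample.
#'
#' @param counts numeric matrix (genes x samples) of non-negative integers,
#'   with rownames as gene symbols and colnames as sample ids.
#' @param metadata optional data.frame with columns `sample_id`, `group`
#'   (one of `"specimen"`, `"control"`) and optionally `patient_id`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix), `gene_ids`, `sample_ids`, `metadata`.
#' @export
count_matrix <- function(counts, metadata = NULL) {
  if (!is.matrix(counts)) stop_data("`counts` must be a matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_data("`counts` must have gene rownames and sample colnames")
  storage <- counts
  if (any(is.na(storage))) stop_data("counts contain missing values")
  if (any(storage < 0)) stop_data("counts must be non-negative")
  if (any(storage != round(storage))) stop_data("counts must be integral")
  mode(storage) <- "integer"
  rownames(storage) <- normalize_gene(rownames(storage))
  if (anyDuplicated(rownames(storage)))
    stop_data("duplicate gene symbol after normalization: ",
              rownames(storage)[duplicated(rownames(storage))][1L])
  if (anyDuplicated(colnames(storage)))
    stop_data("duplicate sample id: ",
              colnames(storage)[duplicated(colnames(storage))][1L])
  x <- structure(
    list(counts = storage,
         gene_ids = rownames(storage),
         sample_ids = colnames(storage),
         metadata = NULL),
    class = "count_matrix")
  if (!is.null(metadata)) x <- set_sample_metadata(x, metadata)
  x
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d genes x %d samples\n",
              length(x$gene_ids), length(x$sample_ids)))
  if (!is.null(x$metadata)) {
    tab <- table(x$metadata$group)
    cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  } else cat("no sample metadata attached\n")
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Attach sample metadata to a count matrix
#'
#' @param x a [count_matrix()].
#' @param metadata data.frame with columns `sample_id`, `group` and
#'   optionally `patient_id`; every sample in `x` must appear exactly once.
#' @return `x` with validated metadata attached, rows ordered as the samples.
#' @export
set_sample_metadata <- function(x, metadata) {
  stopifnot(inherits(x, "count_matrix"))
  md <- validate_sample_metadata(metadata)
  missing <- setdiff(x$sample_ids, md$sample_id)
  if (length(missing))
    stop_data("samples missing from metadata: ", paste(missing, collapse = ", "))
  extra <- setdiff(md$sample_id, x$sample_ids)
  if (length(extra))
    stop_data("metadata sample absent from counts: ", paste(extra, collapse = ", "))
  x$metadata <- md[match(x$sample_ids, md$sample_id), , drop = FALSE]
  rownames(x$metadata) <- NULL
  x
}

validate_sample_metadata <- function(md) {
  if (!is.data.frame(md) || nrow(md) == 0L)
    stop_data("sample metadata must be a non-empty data.frame")
  need <- c("sample_id", "group")
  if (!all(need %in% names(md)))
    stop_data("sample metadata needs columns: ", paste(need, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$group <- as.character(md$group)
  if (anyDuplicated(md$sample_id))
    stop_data("duplicate sample_id in metadata")
  bad <- setdiff(unique(md$group), c("specimen", "control"))
  if (length(bad))
    stop_data("unknown group label (must be specimen/control): ",
              paste(bad, collapse = ", "))
  if (!"patient_id" %in% names(md)) md$patient_id <- NA_character_
  md$patient_id <- as.character(md$patient_id)
  md[, c("sample_id", "group", "patient_id")]
}

group_samples <- function(x, group) {
  if (is.null(x$metadata)) stop_data("count matrix has no sample metadata")
  x$metadata$sample_id[x$metadata$group == group]
}

#' Read a gene-level count matrix
#'
#' Two dialects are supported: `tsv` (tab-separated, UTF-8, header row of
#' sample ids, first column gene symbols, '.' decimal separator) and `mtx`
#' (MatrixMarket file with sidecar files `genes.txt` and `samples.txt` in
#' the same directory, one id per line, order defining the matrix axes).
#' Invalid values are rejected, never coerced: negative, missing or
#' non-integer counts and duplicate gene rows are errors.
#'
#' @param path path to the counts file.
#' @param format `"tsv"` or `"mtx"`.
#' @return a [count_matrix()] without sample metadata.
#' @seealso [read_sample_metadata()], [write_count_matrix()]
#' @export
read_count_matrix <- function(path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_data("file not found: ", path)
  if (format == "tsv") {
    df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                     colClasses = NA, fileEncoding = "UTF-8")
    if (ncol(df) < 2L) stop_data("malformed counts TSV (need gene column plus samples): ", path)
    genes <- as.character(df[[1L]])
    m <- as.matrix(df[, -1L, drop = FALSE])
    if (!is.numeric(m)) stop_data("non-numeric count in ", path)
    rownames(m) <- genes
    count_matrix(m)
  } else {
    m <- as.matrix(Matrix::readMM(path))
    dir <- dirname(path)
    gfile <- file.path(dir, "genes.txt")
    sfile <- file.path(dir, "samples.txt")
    if (!file.exists(gfile) || !file.exists(sfile))
      stop_data("MatrixMarket sidecars genes.txt/samples.txt not found next to ", path)
    genes <- readLines(gfile, encoding = "UTF-8")
    samples <- readLines(sfile, encoding = "UTF-8")
    if (length(genes) != nrow(m) || length(samples) != ncol(m))
      stop_data("sidecar lengths do not match matrix dimensions")
    dimnames(m) <- list(genes, samples)
    count_matrix(m)
  }
}

#' Write a count matrix
#'
#' Inverse of [read_count_matrix()]; round-trips exactly on valid input.
#'
#' @param x a [count_matrix()].
#' @param path output path (for `mtx`, sidecars are written next to it).
#' @param format `"tsv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(x, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "count_matrix"))
  if (format == "tsv") {
    df <- data.frame(gene = x$gene_ids, x$counts, check.names = FALSE,
                     stringsAsFactors = FALSE)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                fileEncoding = "UTF-8")
  } else {
    Matrix::writeMM(Matrix::Matrix(x$counts, sparse = TRUE), path)
    writeLines(x$gene_ids, file.path(dirname(path), "genes.txt"))
    writeLines(x$sample_ids, file.path(dirname(path), "samples.txt"))
  }
  invisible(path)
}

#' Read per-sample metadata
#'
#' TSV with columns `sample_id`, `group` (`specimen` or `control`) and
#' optionally `patient_id`. Unknown group labels are rejected.
#'
#' @param path path to the metadata TSV.
#' @return validated data.frame with columns sample_id, group, patient_id.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8"),
    error = function(e) stop_data("malformed metadata file ", path, ": ",
                                  conditionMessage(e)))
  validate_sample_metadata(df)
}

#' Write per-sample metadata
#' @param md validated metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(md, path) {
  write.table(validate_sample_metadata(md), path, sep = "\t", quote = FALSE,
              row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
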