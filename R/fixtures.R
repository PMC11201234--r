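#' Read a drug-gene interaction table
#'
#' CSV with columns `agent`, `gene`, `direction`
#' (`downregulates`/`upregulates`). Gene symbols are uppercase-normalized;
#' exact duplicate (agent, gene, direction) triples are collapsed.
#'
#' @param path path to the CSV file.
#' @return data.frame with columns agent, gene, direction.
#' @export
read_drug_gene_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  need <- c("agent", "gene", "direction")
  if (!all(need %in% names(df)))
    stop_data("drug-gene table needs columns: ", paste(need, collapse = ", "))
  drug_gene_interactions(df$agent, df$gene, df$direction)
}

drug_gene_interactions <- function(agent, gene, direction) {
  agent <- trimws(as.character(agent))
  gene <- normalize_gene(gene)
  direction <- trimws(as.character(direction))
  if (any(!nzchar(agent)) || any(!nzchar(gene)))
    stop_data("drug-gene table has empty agent or gene")
  bad <- setdiff(unique(direction), c("downregulates", "upregulates"))
  if (length(bad))
    stop_data("unknown regulation direction: ", paste(bad, collapse = ", "))
  df <- data.frame(agent = agent, gene = gene, direction = direction,
                   stringsAsFactors = FALSE)
  df <- unique(df)
  rownames(df) <- NULL
  df
}

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "stenoseq")
  if (!nzchar(p)) stop_data("packaged fixture not found: ", file)
  p
}

#' Packaged table of the 20 most dysregulated genes
#'
#' The published ranking of the ten most upregulated and ten most
#' downregulated genes in iatrogenic tracheal stenosis granulation tissue,
#' as printed: signed fold change (negative values are fold *decreases*,
#' i.e. the reciprocal expression ratio with a minus sign) and the signed
#' change coefficient. Records are returned in printed order.
#'
#' @return data.frame with columns gene, chromosome, product, fold_change,
#'   change_coefficient, direction (`"up"`/`"down"`).
#' @export
load_fixture_table1 <- function() {
  df <- read.delim(fixture_path("table1_dysregulated_genes.tsv"),
                   stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  out <- data.frame(
    gene = normalize_gene(df$gene),
    chromosome = as.character(df$chromosome),
    product = df$product,
    fold_change = df$fold_change,
    change_coefficient = df$change_coefficient,
    direction = df$status,
    stringsAsFactors = FALSE)
  stopifnot(
    nrow(out) == 20L,
    all(out$direction %in% c("up", "down")),
    all((out$fold_change > 0) == (out$direction == "up")),
    all(sign(out$fold_change) == sign(out$change_coefficient)),
    all(abs(out$fold_change) > 1))
  out
}

#' Packaged drug-gene regulation table for the dysregulated genes
#'
#' The published per-gene lists of FDA-approved agents reported to
#' downregulate or upregulate each of the 20 most dysregulated genes,
#' flattened to one row per (agent, gene, direction) interaction. Agent
#' spellings are kept as printed (both "Gentamycin" and "Gentamicin"
#' occur; [default_family_map()] aliases them). Genes with no reported
#' agent appear only in the status map.
#'
#' @return list with elements `interactions` (data.frame agent, gene,
#'   direction) and `gene_status` (named character vector mapping each of
#'   the 20 genes to `"up"` or `"down"`).
#' @export
load_fixture_table2 <- function() {
  interactions <- read_drug_gene_table(fixture_path("table2_drug_gene.csv"))
  t1 <- load_fixture_table1()
  gene_status <- setNames(t1$direction, t1$gene)
  missing <- setdiff(unique(interactions$gene), names(gene_status))
  if (length(missing))
    stop_data("fixture interaction gene without status: ",
              paste(missing, collapse = ", "))
  list(interactions = interactions, gene_status = gene_status)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>member...`. Members are uppercase-normalized
#' and deduplicated within a set; duplicate set names are an error, as are
#' lines with fewer than three fields.
#'
#' @param path path to the .gmt file.
#' @return object of class `gene_set_collection`: named list of character
#'   vectors with a `descriptions` attribute (named character vector).
#' @export
read_gene_sets_gmt <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop_data("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, 0L) < 3L)
  if (length(short))
    stop_data("GMT line ", short[1L], " has fewer than 3 fields")
  names_ <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(names_))
    stop_data("duplicate gene set name: ", names_[duplicated(names_)][1L])
  sets <- lapply(fields, function(f) unique(normalize_gene(f[-(1:2)])))
  names(sets) <- names_
  attr(sets, "descriptions") <- setNames(vapply(fields, `[[`, "", 2L), names_)
  class(sets) <- "gene_set_collection"
  sets
}
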