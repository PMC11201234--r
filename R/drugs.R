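#' Normalize an agent name
#'
#' Case-insensitive, whitespace-trimmed and -squished; spelling aliases
#' (e.g. "gentamycin" for "gentamicin") resolve before any family lookup.
#'
#' @param agent character vector of agent names.
#' @param aliases named character vector mapping variant -> canonical
#'   normalized spelling.
#' @return normalized agent names.
#' @export
normalize_agent <- function(agent, aliases = default_agent_aliases()) {
  a <- tolower(gsub("\\s+", " ", trimws(as.character(agent))))
  hit <- a %in% names(aliases)
  a[hit] <- unname(aliases[a[hit]])
  a
}

#' @rdname normalize_agent
#' @export
default_agent_aliases <- function() {
  c(gentamycin = "gentamicin")
}

#' Default agent-family map
#'
#' Maps each member of the retinoid family (retinoic-acid-derived agents)
#' to the family name `"retinoids"`. Any agent not in the map forms its
#' own singleton family under its normalized name.
#'
#' @return named character vector: normalized agent -> family name.
#' @export
default_family_map <- function() {
  retinoids <- c("tretinoin", "isotretinoin", "alitretinoin", "fenretinide",
                 "retinoic acid", "4-oxoretinoic acid")
  setNames(rep("retinoids", length(retinoids)), retinoids)
}

#' Family of each agent
#'
#' @param agent character vector of raw agent names.
#' @param family_map named character vector (normalized agent -> family);
#'   unmapped agents are their own singleton family.
#' @return character vector of family names.
#' @export
agent_family <- function(agent, family_map = default_family_map()) {
  a <- normalize_agent(agent)
  fam <- unname(family_map[a])
  ifelse(is.na(fam), a, fam)
}

check_gene_labels <- function(genes) {
  stopifnot(is.data.frame(genes), all(c("gene", "direction") %in% names(genes)))
  bad <- setdiff(unique(genes$direction), c("up", "down"))
  if (length(bad))
    stop_data("gene direction labels must be up/down, got: ",
              paste(bad, collapse = ", "))
  data.frame(gene = normalize_gene(genes$gene),
             direction = genes$direction, stringsAsFactors = FALSE)
}

#' Count dysregulated genes regulated by one drug family
#'
#' In mode `"any"` a labeled gene counts if any family member has any
#' interaction with it — the counting behind the published tallies (the
#' retinoid family regulating 7 upregulated and 2 downregulated genes).
#' In mode `"favorable"` an up-labeled gene counts only if a member
#' *down*regulates it and a down-labeled gene only if a member
#' *up*regulates it — regulation in the therapeutically desirable
#' direction. Each gene is counted at most once per direction, however
#' many family members touch it.
#'
#' @param interactions data.frame (agent, gene, direction) as from
#'   [read_drug_gene_table()] or [simulate_drug_table()].
#' @param genes data.frame with columns `gene` and `direction`
#'   (`"up"`/`"down"`): the dysregulated gene list.
#' @param family family name to score.
#' @param family_map see [default_family_map()].
#' @param mode `"any"` or `"favorable"`.
#' @return list with `up_count`, `down_count` and `covered_genes` (named
#'   list of the up and down genes counted).
#' @export
count_regulated_genes <- function(interactions, genes, family,
                                  family_map = default_family_map(),
                                  mode = c("any", "favorable")) {
  mode <- match.arg(mode)
  genes <- check_gene_labels(genes)
  ia <- interactions
  ia$family <- agent_family(ia$agent, family_map)
  ia <- ia[ia$family == family, , drop = FALSE]
  covered <- function(label) {
    g <- genes$gene[genes$direction == label]
    if (!nrow(ia) || !length(g)) return(character())
    sub <- ia[ia$gene %in% g, , drop = FALSE]
    if (mode == "favorable") {
      want <- if (label == "up") "downregulates" else "upregulates"
      sub <- sub[sub$direction == want, , drop = FALSE]
    }
    sort(unique(sub$gene))
  }
  up <- covered("up"); down <- covered("down")
  list(up_count = length(up), down_count = length(down),
       covered_genes = list(up = up, down = down))
}

#' Rank drug families by number of dysregulated genes regulated
#'
#' Scores every family with at least one interaction against the labeled
#' gene list and orders by total covered genes (descending), then
#' upregulated-gene count (descending), then family name. Families with a
#' zero total are dropped.
#'
#' @param interactions interaction data.frame (agent, gene, direction).
#' @param genes a `ranked_gene_table` or a data.frame with columns `gene`
#'   and `direction`.
#' @param family_map see [default_family_map()].
#' @param mode `"any"` or `"favorable"` (see [count_regulated_genes()]).
#' @param allow_agents optional character vector restricting scoring to
#'   these agents (e.g. an FDA-approval allow-list), matched after
#'   normalization.
#' @return data.frame with columns family, mode, up_count, down_count,
#'   total, covered_genes (semicolon-joined), ordered best first.
#' @export
rank_drugs <- function(interactions, genes, family_map = default_family_map(),
                       mode = c("any", "favorable"), allow_agents = NULL) {
  mode <- match.arg(mode)
  if (inherits(genes, "ranked_gene_table")) genes <- ranked_gene_labels(genes)
  genes <- check_gene_labels(genes)
  ia <- interactions
  if (!is.null(allow_agents))
    ia <- ia[normalize_agent(ia$agent) %in% normalize_agent(allow_agents), ,
             drop = FALSE]
  if (!nrow(ia))
    return(data.frame(family = character(), mode = character(),
                      up_count = integer(), down_count = integer(),
                      total = integer(), covered_genes = character(),
                      stringsAsFactors = FALSE))
  fams <- sort(unique(agent_family(ia$agent, family_map)))
  rows <- lapply(fams, function(f) {
    s <- count_regulated_genes(ia, genes, f, family_map, mode)
    data.frame(family = f, mode = mode,
               up_count = s$up_count, down_count = s$down_count,
               total = s$up_count + s$down_count,
               covered_genes = paste(c(s$covered_genes$up, s$covered_genes$down),
                                     collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[out$total >= 1L, , drop = FALSE]
  out <- out[order(-out$total, -out$up_count, out$family), , drop = FALSE]
  rownames(out) <- NULL
  out
}
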