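#' Simulation settings for synthetic stenosis-vs-control counts
#'
#' Defaults emulate the study design the pipeline targets: 11 specimen
#' biopsies drawn from 8 patients against a control group of 2 public
#' normal-trachea runs, with overdispersed negative-binomial counts
#' (variance \eqn{\mu + \phi\mu^2}), a log-normal baseline abundance
#' profile, a minority of genes carrying planted log2 fold changes in both
#' directions, and a further minority of "extreme" genes near-silenced in
#' one group, emulating the published table's fold decreases of 1e3-1e5.
#'
#' @param n_genes number of genes.
#' @param n_specimen,n_control group sizes.
#' @param n_patients specimen samples are assigned round-robin to this many
#'   patients (repeat biopsies are treated as independent samples).
#' @param library_size_mean expected total counts per sample; gene baseline
#'   means are rescaled so their sum equals this.
#' @param baseline_log_mean,baseline_log_sd log-normal parameters shaping
#'   relative gene abundance before rescaling.
#' @param dispersion negative-binomial dispersion \eqn{\phi} (variance
#'   \eqn{\mu + \phi\mu^2}).
#' @param de_fraction fraction of genes with a planted fold change.
#' @param lfc_range length-2 positive range of planted |log2 fold change|.
#' @param extreme_fraction fraction of the planted genes additionally
#'   near-silenced (mean multiplied by `extreme_factor`) in one group:
#'   the specimen group for planted-down genes, the control group for
#'   planted-up genes.
#' @param extreme_factor silencing multiplier, must be <= 1e-4.
#' @param seed master integer seed; independent substreams are derived for
#'   truth assignment and count drawing.
#' @return a validated list of class `sim_config`.
#' @export
simulation_config <- function(n_genes = 2000, n_specimen = 11, n_control = 2,
                              n_patients = 8,
                              library_size_mean = 1e6,
                              baseline_log_mean = log(200),
                              baseline_log_sd = 1.5,
                              dispersion = 0.1,
                              de_fraction = 0.05,
                              lfc_range = c(2, 3),
                              extreme_fraction = 0.1,
                              extreme_factor = 1e-4,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_specimen = as.integer(n_specimen),
              n_control = as.integer(n_control), n_patients = as.integer(n_patients),
              library_size_mean = library_size_mean,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd,
              dispersion = dispersion, de_fraction = de_fraction,
              lfc_range = as.numeric(lfc_range),
              extreme_fraction = extreme_fraction,
              extreme_factor = extreme_factor, seed = as.integer(seed))
  with(cfg, {
    if (n_genes < 1L) stop_data("n_genes must be positive")
    if (n_specimen < 1L || n_control < 1L) stop_data("group sizes must be positive")
    if (library_size_mean <= 0 || dispersion <= 0 || baseline_log_sd < 0)
      stop_data("library_size_mean and dispersion must be positive")
    if (de_fraction < 0 || de_fraction > 1) stop_data("de_fraction must be in [0,1]")
    if (extreme_fraction < 0 || extreme_fraction > 1)
      stop_data("extreme_fraction must be in [0,1]")
    if (length(lfc_range) != 2L || any(lfc_range <= 0) || lfc_range[1] > lfc_range[2])
      stop_data("lfc_range must be an increasing pair of positive values")
    if (extreme_factor <= 0 || extreme_factor > 1e-4)
      stop_data("extreme_factor must be in (0, 1e-4]")
  })
  structure(cfg, class = "sim_config")
}

# one master seed -> named substream seeds, so adding a consumer does not
# perturb the draws of another
substream_seeds <- function(seed, streams) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  setNames(sample.int(.Machine$integer.max - 1L, length(streams)), streams)
}

#' Simulate a stenosis-vs-control count matrix with known truth
#'
#' Draws negative-binomial counts around log-normally distributed gene
#' baselines; specimen-group means of planted genes are scaled by
#' `2^lfc`; extreme genes additionally have one group's mean multiplied
#' by `extreme_factor` (near-silencing without exact zeros, so that
#' pseudocount handling is exercised). Per-sample library sizes vary by a
#' log-normal factor (sdlog 0.15). Deterministic given the config seed.
#'
#' @param config a [simulation_config()].
#' @return list with `counts` (a [count_matrix()] with metadata) and
#'   `truth` (data.frame: gene, planted_lfc — 0 for null genes, is_de,
#'   direction in up/down/none, is_extreme).
#' @export
simulate_counts <- function(config = simulation_config()) {
  stopifnot(inherits(config, "sim_config"))
  ss <- substream_seeds(config$seed, c("truth", "counts"))

  # truth substream: baselines, DE assignment, planted effects
  set.seed(ss[["truth"]])
  mu <- rlnorm(config$n_genes, config$baseline_log_mean, config$baseline_log_sd)
  mu <- mu / sum(mu) * config$library_size_mean
  n_de <- round(config$de_fraction * config$n_genes)
  de_idx <- if (n_de > 0) sort(sample.int(config$n_genes, n_de)) else integer()
  lfc <- numeric(config$n_genes)
  if (n_de > 0) {
    sgn <- sample(c(-1, 1), n_de, replace = TRUE)
    lfc[de_idx] <- sgn * runif(n_de, config$lfc_range[1], config$lfc_range[2])
  }
  n_extreme <- round(config$extreme_fraction * n_de)
  extreme_idx <- if (n_extreme > 0) sort(sample(de_idx, n_extreme)) else integer()
  is_extreme <- seq_len(config$n_genes) %in% extreme_idx

  mean_specimen <- mu * 2^lfc
  mean_control <- mu
  sil_dn <- extreme_idx[lfc[extreme_idx] < 0]
  sil_up <- extreme_idx[lfc[extreme_idx] > 0]
  mean_specimen[sil_dn] <- mean_specimen[sil_dn] * config$extreme_factor
  mean_control[sil_up] <- mean_control[sil_up] * config$extreme_factor

  # counts substream: library-size factors then NB draws
  set.seed(ss[["counts"]])
  n_samp <- config$n_specimen + config$n_control
  size_factor <- rlnorm(n_samp, 0, 0.15)
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))
  sample_ids <- c(sprintf("SPEC%02d", seq_len(config$n_specimen)),
                  sprintf("CTRL%02d", seq_len(config$n_control)))
  group <- rep(c("specimen", "control"), c(config$n_specimen, config$n_control))
  cts <- matrix(0L, config$n_genes, n_samp, dimnames = list(gene_ids, sample_ids))
  for (j in seq_len(n_samp)) {
    m <- if (group[j] == "specimen") mean_specimen else mean_control
    cts[, j] <- rnbinom(config$n_genes, mu = size_factor[j] * m,
                        size = 1 / config$dispersion)
  }

  patient <- rep(NA_character_, n_samp)
  npat <- max(1L, min(config$n_patients, config$n_specimen))
  patient[group == "specimen"] <-
    sprintf("P%02d", ((seq_len(config$n_specimen) - 1L) %% npat) + 1L)
  md <- data.frame(sample_id = sample_ids, group = group, patient_id = patient,
                   stringsAsFactors = FALSE)

  truth <- data.frame(
    gene = gene_ids,
    baseline_mean = mu,
    planted_lfc = lfc,
    is_de = seq_len(config$n_genes) %in% de_idx,
    direction = ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "none")),
    is_extreme = is_extreme,
    stringsAsFactors = FALSE)

  list(counts = count_matrix(cts, md), truth = truth)
}

#' Simulate a drug-gene interaction table with a planted best agent
#'
#' One designated agent favorably regulates `cover_k` of the planted
#' dysregulated genes (it downregulates planted-up genes and upregulates
#' planted-down genes); every other agent receives `noise_edges` random
#' interactions with random genes and directions. Deterministic given
#' `seed`.
#'
#' @param truth truth data.frame from [simulate_counts()].
#' @param n_agents total number of agents (>= 1; the first is designated).
#' @param cover_k number of planted genes the designated agent covers;
#'   must not exceed the number of planted DE genes.
#' @param noise_edges random interactions per non-designated agent.
#' @param seed integer seed.
#' @return interaction data.frame (agent, gene, direction) with attribute
#'   `designated_agent` naming the planted best agent.
#' @export
simulate_drug_table <- function(truth, n_agents = 20, cover_k = 7,
                                noise_edges = 3, seed = 1L) {
  stopifnot(is.data.frame(truth), all(c("gene", "is_de", "direction") %in% names(truth)))
  de <- truth[truth$is_de, , drop = FALSE]
  if (cover_k > nrow(de))
    stop_data("cover_k (", cover_k, ") exceeds number of planted DE genes (",
              nrow(de), ")")
  if (n_agents < 1L) stop_data("n_agents must be >= 1")
  set.seed(substream_seeds(seed, "drugs")[[1L]])
  designated <- "agent01"
  rows <- list()
  if (cover_k > 0) {
    pick <- de[sample.int(nrow(de), cover_k), , drop = FALSE]
    rows[[1L]] <- data.frame(
      agent = designated, gene = pick$gene,
      direction = ifelse(pick$direction == "up", "downregulates", "upregulates"),
      stringsAsFactors = FALSE)
  }
  if (n_agents > 1L && noise_edges > 0) {
    noise_agents <- sprintf("agent%02d", 2:n_agents)
    for (a in noise_agents) {
      g <- sample(truth$gene, noise_edges, replace = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        agent = a, gene = g,
        direction = sample(c("downregulates", "upregulates"), noise_edges,
                           replace = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(agent = character(), gene = character(), direction = character(),
               stringsAsFactors = FALSE)
  df <- drug_gene_interactions(df$agent, df$gene, df$direction)
  attr(df, "designated_agent") <- designated
  df
}
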