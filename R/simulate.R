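# Synthetic dual-stimulus time-course generator with planted ground truth.
#
# Mean profiles on the log2 scale follow two archetypes: an immediate-early
# response that peaks at the first post-stimulation time and decays
# exponentially, and a delayed response that rises logistically after ~2 h.
# Replicate noise is Gaussian on the log2 scale (log-normal on TPM), matching
# the additive-error linear models the downstream analysis fits.

#' Simulation configuration
#'
#' @param n_generic number of promoters whose mean time profile is identical
#'   under both stimuli (the null class for the stimulus effect).
#' @param n_specific number of promoters whose HRG-arm mean is shifted by
#'   `delta` log2 units (random sign) at every post-stimulation time point.
#' @param n_unresponsive number of promoters with constant mean expression
#'   (removed by the time-effect filter).
#' @param design an [experiment_design()]; default [mcf7_design()].
#' @param frac_immediate_early fraction of responsive promoters following
#'   the immediate-early (decaying) archetype; the rest follow the delayed
#'   (increasing) archetype.
#' @param delta log2 shift between the stimulus arms for specific promoters
#'   (effect size); `delta = 0` yields an all-null dataset.
#' @param sigma replicate-level standard deviation on the log2 scale.
#' @param promoters_per_gene named numeric vector of probabilities over
#'   promoters-per-gene counts 1..7 (must sum to 1).
#' @param tf_prob probability that a gene is flagged as a transcription
#'   factor.
#' @param seed integer seed; the whole dataset is reproducible from
#'   (config, seed).
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_generic = 200, n_specific = 200,
                              n_unresponsive = 100,
                              design = mcf7_design(),
                              frac_immediate_early = 0.5,
                              delta = 2, sigma = 0.25,
                              promoters_per_gene = c(`1` = 0.85, `2` = 0.08,
                                                     `3` = 0.03, `4` = 0.015,
                                                     `5` = 0.01, `6` = 0.01,
                                                     `7` = 0.005),
                              tf_prob = 0.1, seed = 1L) {
  stopifnot(inherits(design, "experiment_design"))
  counts <- c(n_generic, n_specific, n_unresponsive)
  if (any(counts < 0)) stop("promoter counts must be non-negative")
  if (sum(counts) == 0) stop("configuration contains zero promoters")
  if (!is.numeric(sigma) || sigma <= 0) stop("'sigma' must be positive")
  if (!is.numeric(delta) || delta < 0) stop("'delta' must be non-negative")
  if (frac_immediate_early < 0 || frac_immediate_early > 1)
    stop("'frac_immediate_early' must be in [0, 1]")
  if (length(promoters_per_gene) != 7L ||
      abs(sum(promoters_per_gene) - 1) > 1e-8 ||
      any(promoters_per_gene < 0))
    stop("'promoters_per_gene' must be 7 probabilities (counts 1..7) summing to 1")
  if (tf_prob < 0 || tf_prob > 1) stop("'tf_prob' must be in [0, 1]")
  structure(
    list(n_generic = as.integer(n_generic),
         n_specific = as.integer(n_specific),
         n_unresponsive = as.integer(n_unresponsive),
         design = design, frac_immediate_early = frac_immediate_early,
         delta = delta, sigma = sigma,
         promoters_per_gene = promoters_per_gene,
         tf_prob = tf_prob, seed = as.integer(seed)),
    class = "simulation_config"
  )
}

# mean log2 profile archetypes; t in hours
.profile_immediate_early <- function(t, baseline, amplitude, tau = 1) {
  t1 <- min(t[t > 0])
  ifelse(t < t1, baseline, baseline + amplitude * exp(-(t - t1) / tau))
}

.profile_delayed <- function(t, baseline, amplitude, midpoint = 4,
                             scale = 0.7) {
  baseline + amplitude / (1 + exp(-(t - midpoint) / scale))
}

#' Generate a synthetic dataset with planted ground truth
#'
#' Produces a TPM-scale expression tensor, a promoter-gene map and a truth
#' table. Generic promoters share one mean time profile across both stimuli
#' (exact equality before noise); stimulus-specific promoters have their
#' second-arm mean shifted by `delta` log2 units at every post-stimulation
#' time point (shared unstimulated 0 h mean); unresponsive promoters have
#' constant means. Replicate values are `2^(log2 mean + Normal(0, sigma))`.
#'
#' Random draws use a single seed stream in a fixed order (baselines,
#' amplitudes, archetypes, shift signs, gene sizes, TF flags, noise), so the
#' same configuration always yields bit-identical output.
#'
#' @param config a [simulation_config()].
#' @return list with elements `tensor` (TPM [expression_tensor()]),
#'   `gene_map` ([gene_map()]), `truth` (data frame with columns `promoter`,
#'   `label`, `archetype`, `trend_sign`, `gene`) and `config`.
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  d <- config$design
  t <- d$time_points
  nt <- length(t)
  nk <- d$n_replicates
  labels <- rep(c("generic", "stimulus_specific", "unresponsive"),
                c(config$n_generic, config$n_specific, config$n_unresponsive))
  np <- length(labels)

  # promoter IDs: unique synthetic genomic coordinates
  chrom <- paste0("chr", sample(c(1:22, "X"), np, replace = TRUE))
  start <- sample.int(1e8L, np)
  width <- sample(10:80, np, replace = TRUE)
  strand <- sample(c("+", "-"), np, replace = TRUE)
  promoters <- sprintf("%s:%d..%d,%s", chrom, start, start + width, strand)

  baseline <- stats::runif(np, 3, 8)
  amplitude <- stats::runif(np, 1, 3)
  archetype <- sample(c("immediate_early", "delayed"), np, replace = TRUE,
                      prob = c(config$frac_immediate_early,
                               1 - config$frac_immediate_early))
  shift_sign <- sample(c(-1, 1), np, replace = TRUE)

  means <- array(0, dim = c(np, 2L, nt))
  for (i in seq_len(np)) {
    m <- if (labels[i] == "unresponsive") rep(baseline[i], nt)
         else if (archetype[i] == "immediate_early")
           .profile_immediate_early(t, baseline[i], amplitude[i])
         else .profile_delayed(t, baseline[i], amplitude[i])
    means[i, 1L, ] <- m
    means[i, 2L, ] <- m
    if (labels[i] == "stimulus_specific")
      means[i, 2L, t > 0] <- m[t > 0] + shift_sign[i] * config$delta
  }

  # promoter-gene assignment: chunk a random promoter order into genes whose
  # sizes follow the promoters-per-gene distribution
  ord <- sample.int(np)
  sizes <- integer(0)
  while (sum(sizes) < np)
    sizes <- c(sizes, sample(1:7, 1L, prob = config$promoters_per_gene))
  sizes[length(sizes)] <- sizes[length(sizes)] - (sum(sizes) - np)
  sizes <- sizes[sizes > 0]
  gene_of <- character(np)
  gene_ids <- sprintf("G%05d", seq_along(sizes))
  gene_of[ord] <- rep(gene_ids, sizes)
  tf_gene <- stats::rbinom(length(sizes), 1L, config$tf_prob) == 1L
  names(tf_gene) <- gene_ids

  noise <- array(stats::rnorm(np * 2L * nt * nk, 0, config$sigma),
                 dim = c(np, 2L, nt, nk))
  values <- 2 ^ (array(rep(means, nk), dim = c(np, 2L, nt, nk)) + noise)
  tensor <- expression_tensor(values, promoters, d, log_transformed = FALSE)

  gmap <- gene_map(promoters, gene_of, is_tf = tf_gene[gene_of])
  truth <- data.frame(
    promoter = promoters, label = labels, archetype = archetype,
    trend_sign = ifelse(labels == "unresponsive", 0L,
                        ifelse(archetype == "delayed", 1L, -1L)),
    gene = gene_of, stringsAsFactors = FALSE
  )
  list(tensor = tensor, gene_map = gmap, truth = truth, config = config)
}

#' Generate a random protein-protein interaction graph
#'
#' Erdos-Renyi G(n, p) graph with labelled nodes, for exercising the
#' shortest-path subnetwork extraction.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edge_prob edge probability in (0, 1].
#' @param seed integer seed.
#' @return An undirected simple [igraph::igraph] graph with node names
#'   `N001`, `N002`, ...
#' @export
generate_ppi <- function(n_nodes, edge_prob, seed = 1L) {
  if (n_nodes < 2) stop("'n_nodes' must be at least 2")
  if (edge_prob <= 0 || edge_prob > 1) stop("'edge_prob' must be in (0, 1]")
  set.seed(seed)
  g <- igraph::sample_gnp(n_nodes, edge_prob)
  igraph::V(g)$name <- sprintf("N%03d", seq_len(n_nodes))
  g
}
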