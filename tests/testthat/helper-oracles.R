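# Independent reference implementations used to cross-check the package:
# direct sum-of-squares ANOVA decompositions, the BH step-up formula, and
# exhaustive fixed-margin enumeration of Fisher's exact test.

# one-way ANOVA of a time x replicate matrix by explicit sums of squares
oracle_oneway <- function(mat) {
  grand <- mean(mat)
  group_means <- rowMeans(mat)
  ssb <- ncol(mat) * sum((group_means - grand)^2)
  ssw <- sum((mat - group_means)^2)
  df1 <- nrow(mat) - 1L
  df2 <- length(mat) - nrow(mat)
  f <- (ssb / df1) / (ssw / df2)
  list(statistic = f, p.value = stats::pf(f, df1, df2, lower.tail = FALSE))
}

# additive two-factor (stimulus + time) balanced decomposition for a
# 2 x times x replicates array; returns the stimulus-effect F test
oracle_twoway_stimulus <- function(arr) {
  grand <- mean(arr)
  nt <- dim(arr)[2L]
  nk <- dim(arr)[3L]
  n <- length(arr)
  stim_means <- apply(arr, 1L, mean)
  time_means <- apply(arr, 2L, mean)
  ss_stim <- nt * nk * sum((stim_means - grand)^2)
  ss_time <- 2 * nk * sum((time_means - grand)^2)
  ss_tot <- sum((arr - grand)^2)
  ss_res <- ss_tot - ss_stim - ss_time
  df2 <- n - nt - 1L
  f <- ss_stim / (ss_res / df2)
  list(statistic = f, p.value = stats::pf(f, 1, df2, lower.tail = FALSE))
}

# Benjamini-Hochberg step-up: adj_(i) = min_{j >= i} p_(j) * m / j, capped
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  running <- Inf
  for (i in m:1) {
    running <- min(running, sorted[i] * m / i)
    adj[i] <- min(running, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# exhaustive fixed-margin enumeration of the 2x2 Fisher test; the observed
# table is (k, K-k / n-k, N-K-n+k): k study genes in the term, K study size,
# n background genes in the term, N background size
oracle_fisher <- function(k, K, n, N, alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  lo <- max(0L, K + n - N)
  hi <- min(K, n)
  j <- lo:hi
  mass <- choose(n, j) * choose(N - n, K - j) / choose(N, K)
  if (alternative == "greater") return(sum(mass[j >= k]))
  sum(mass[mass <= mass[j == k] * (1 + 1e-7)])
}

# nodes on any hop-count-shortest path between any seed pair, by the
# distance characterization d(s,v) + d(v,t) == d(s,t)
oracle_sp_nodes <- function(g, seeds) {
  d <- igraph::distances(g, weights = NA)
  nodes <- igraph::V(g)$name
  on_path <- logical(length(nodes))
  for (i in seq_len(length(seeds) - 1L)) {
    for (jj in (i + 1L):length(seeds)) {
      s <- seeds[i]
      t <- seeds[jj]
      if (!is.finite(d[s, t])) next
      on_path <- on_path | (d[s, nodes] + d[nodes, t] == d[s, t])
    }
  }
  sort(nodes[on_path])
}

# small dual-stimulus tensor from an explicit value array
toy_design <- function(times = c(0, 1, 2, 4), reps = 2) {
  experiment_design(c("EGF", "HRG"), times, reps)
}

toy_tensor <- function(values, design = toy_design(), log2scale = FALSE) {
  np <- dim(values)[1L]
  expression_tensor(values, sprintf("chr1:%d..%d,+", 100 * seq_len(np),
                                    100 * seq_len(np) + 10),
                    design, log_transformed = log2scale)
}

# swap the two stimulus arms of a tensor (and the design labels)
swap_stimuli <- function(x) {
  d <- experiment_design(rev(x$design$stimuli), x$design$time_points,
                         x$design$n_replicates)
  expression_tensor(x$values[, 2:1, , , drop = FALSE], x$promoters, d,
                    x$log_transformed)
}
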