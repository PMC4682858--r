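# Core trajectory statistics: per-promoter ANOVA filtering and
# classification into generic vs stimulus-specific sets, linear trend
# estimation, and HRG:EGF fold-change divergence testing.

# shared guard for ANOVA tables with (numerically) zero residual variance
.anova_row <- function(a, row) {
  fstat <- a$`F value`[row]
  p <- a$`Pr(>F)`[row]
  ms_res <- a$`Mean Sq`[nrow(a)]
  ss_row <- a$`Sum Sq`[row]
  ss_tot <- sum(a$`Sum Sq`)
  if (ms_res <= 1e-300 || (ss_tot > 0 && ms_res / ss_tot < 1e-14)) {
    if (ss_row / max(ss_tot, 1e-300) > 1e-12) {
      warning("zero residual variance with non-zero effect; p-value set to 0")
      fstat <- Inf
      p <- 0
    } else {
      fstat <- 0
      p <- 1
    }
  }
  list(statistic = fstat, p.value = p)
}

#' One-way ANOVA of expression on time
#'
#' Fits `Y = mean(time) + error` with time as a categorical factor to a
#' single promoter's log2 time-by-replicate matrix and returns the F-test of
#' the time effect with (T-1, N-T) degrees of freedom. This is the
#' responsiveness test used by the unresponsive-promoter filter.
#'
#' @param mat numeric matrix of log2 values, time points in rows, replicates
#'   in columns.
#' @return list with `statistic` (F), `p.value` and `df`.
#' @export
time_anova <- function(mat) {
  mat <- as.matrix(mat)
  nt <- nrow(mat)
  n <- length(mat)
  if (nt < 2L) stop("time ANOVA requires at least 2 time levels")
  if (n - nt < 1L) stop("zero residual degrees of freedom")
  d <- data.frame(y = as.vector(mat),
                  time = factor(rep(seq_len(nt), times = ncol(mat))))
  # anova.lm warns on its own for near-perfect fits; .anova_row handles them
  a <- suppressWarnings(stats::anova(stats::lm(y ~ time, data = d)))
  c(.anova_row(a, 1L), list(df = c(nt - 1L, n - nt)))
}

#' Additive two-factor ANOVA stimulus test
#'
#' Fits `Y = mean + time + stimulus + error` (time categorical, no
#' interaction) to one promoter's stimulus-by-time-by-replicate slice and
#' returns the F-test of the stimulus main effect with (1, N-T-1) residual
#' degrees of freedom. A significant stimulus term marks the promoter's
#' trajectory as differing between the two arms.
#'
#' @param arr numeric array of log2 values, dimension
#'   `c(2, n_times, n_replicates)`.
#' @return list with `statistic` (F), `p.value` and `df`.
#' @export
stimulus_anova <- function(arr) {
  if (length(dim(arr)) != 3L || dim(arr)[1L] != 2L)
    stop("'arr' must be a 2 x times x replicates array")
  for (s in 1:2)
    if (all(is.na(arr[s, , ]))) stop("a stimulus arm is entirely missing")
  nt <- dim(arr)[2L]
  nk <- dim(arr)[3L]
  n <- 2L * nt * nk
  if (n - nt - 1L < 1L) stop("zero residual degrees of freedom")
  d <- data.frame(
    y = as.vector(arr),
    stimulus = factor(rep(1:2, times = nt * nk)),
    time = factor(rep(rep(seq_len(nt), each = 2L), times = nk))
  )
  a <- suppressWarnings(stats::anova(stats::lm(y ~ time + stimulus,
                                               data = d)))
  c(.anova_row(a, 2L), list(df = c(1L, n - nt - 1L)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: sorted p-values are scaled by `m/rank` and made
#' monotone from the largest down, capped at 1, and returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Remove promoters with no time response in either arm
#'
#' A promoter is flagged `filtered_unresponsive` if and only if its
#' BH-adjusted time-ANOVA p-value exceeds `alpha` in BOTH stimulus arms;
#' a significant change under either stimulus retains it.
#'
#' @param padj_a,padj_b adjusted time-ANOVA p-values per promoter for the
#'   two stimuli (same length, same promoter order).
#' @param alpha significance level, default 0.01.
#' @return character vector of labels, `"retained"` or
#'   `"filtered_unresponsive"`.
#' @export
filter_unresponsive <- function(padj_a, padj_b, alpha = 0.01) {
  if (length(padj_a) != length(padj_b))
    stop("adjusted p-value vectors must have equal length")
  ifelse(padj_a > alpha & padj_b > alpha, "filtered_unresponsive", "retained")
}

#' Label promoters from the adjusted stimulus-term p-value
#'
#' Strict inequality at the threshold: adjusted p below `alpha` is
#' stimulus-specific, at or above `alpha` (including exactly `alpha`) is
#' generic.
#'
#' @param padj_stimulus adjusted stimulus-effect p-values.
#' @param alpha classification level, default 0.01.
#' @return character vector, `"stimulus_specific"` or `"generic"`.
#' @export
classify_labels <- function(padj_stimulus, alpha = 0.01) {
  ifelse(padj_stimulus < alpha, "stimulus_specific", "generic")
}

#' Linear trend and stimulus-offset regression
#'
#' Ordinary least squares fit of `Y = a0 + alpha * time + lambda * stimulus`
#' with time numeric (hours) and stimulus coded 0 for the first design arm
#' and 1 for the second. `alpha_hat` measures the direction and degree of
#' change of expression over the time course; its sign maps to
#' `"increase"` / `"decrease"` (exact zero reported as `"flat"`).
#'
#' @param arr numeric array of log2 values, `c(2, n_times, n_replicates)`.
#' @param times numeric time points in hours (length `n_times`).
#' @return list with `alpha_hat`, `lambda_hat`, `direction`.
#' @export
linear_trend <- function(arr, times) {
  if (length(dim(arr)) != 3L || dim(arr)[1L] != 2L)
    stop("'arr' must be a 2 x times x replicates array")
  if (length(unique(times)) < 3L)
    stop("linear trend requires at least 3 distinct time points")
  nt <- dim(arr)[2L]
  nk <- dim(arr)[3L]
  d <- data.frame(
    y = as.vector(arr),
    time = rep(rep(times, each = 2L), times = nk),
    stim = rep(c(0, 1), times = nt * nk)
  )
  cf <- stats::coef(stats::lm(y ~ time + stim, data = d))
  alpha_hat <- unname(cf["time"])
  lambda_hat <- unname(cf["stim"])
  direction <- if (abs(alpha_hat) < 1e-12) "flat"
               else if (alpha_hat > 0) "increase" else "decrease"
  list(alpha_hat = alpha_hat, lambda_hat = lambda_hat, direction = direction)
}

#' Replicate-paired log2 fold-change profile
#'
#' For one promoter, the profile `FC[t, k] = Y[arm2, t, k] - Y[arm1, t, k]`
#' on the log2 scale (i.e. log2 of the HRG:EGF expression ratio when the
#' design arms are EGF then HRG). Replicates are paired by index.
#'
#' @param arr numeric array of log2 values `c(2, n_times, n_replicates)`,
#'   or a list of two equally-shaped time-by-replicate matrices.
#' @return numeric matrix, times in rows, replicates in columns.
#' @export
fold_change_profile <- function(arr) {
  if (is.list(arr)) {
    if (length(arr) != 2L || !all(dim(arr[[1L]]) == dim(arr[[2L]])))
      stop("unpaired replicate structure between the two arms")
    return(arr[[2L]] - arr[[1L]])
  }
  if (length(dim(arr)) != 3L || dim(arr)[1L] != 2L)
    stop("'arr' must be a 2 x times x replicates array")
  matrix(arr[2L, , ] - arr[1L, , ], nrow = dim(arr)[2L],
         dimnames = dimnames(arr)[2:3])
}

#' Full trajectory classification pipeline
#'
#' Runs the whole per-promoter classification on a TPM-scale tensor:
#' \enumerate{
#'   \item drop promoters below `tpm_min` TPM everywhere (`filtered_low`);
#'   \item log2-transform with `pseudocount`;
#'   \item per-arm one-way time ANOVA, BH-adjusted per stimulus across all
#'     TPM-passing promoters, and removal of promoters unresponsive in both
#'     arms (`filtered_unresponsive`);
#'   \item additive two-factor ANOVA stimulus test on the retained
#'     promoters, BH-adjusted across them, with adjusted p < `alpha_class`
#'     labelling a promoter `stimulus_specific` and all other retained
#'     promoters `generic`;
#'   \item linear trend regression giving `alpha_hat` (log2 units/hour),
#'     `lambda_hat` (log2 units) and the trend direction.
#' }
#'
#' @param x an `expr_tensor` on the TPM scale.
#' @param tpm_min minimum-expression threshold (TPM), default 1.
#' @param alpha_filter level of the unresponsiveness filter, default 0.01.
#' @param alpha_class level of the stimulus-term classification, default
#'   0.01.
#' @param pseudocount log2 pseudocount, default 1.
#' @return data frame with one row per input promoter: raw and adjusted
#'   time-ANOVA p-values per stimulus, raw and adjusted stimulus p-values,
#'   `label` in filtered_low / filtered_unresponsive / generic /
#'   stimulus_specific, `alpha_hat`, `lambda_hat`, `direction`.
#' @export
classify_promoters <- function(x, tpm_min = 1, alpha_filter = 0.01,
                               alpha_class = 0.01, pseudocount = 1) {
  stopifnot(inherits(x, "expr_tensor"))
  if (x$log_transformed)
    stop("classify_promoters expects a TPM-scale tensor")
  s1 <- tolower(x$design$stimuli[1L])
  s2 <- tolower(x$design$stimuli[2L])
  out <- data.frame(promoter = x$promoters, stringsAsFactors = FALSE)
  for (nm in c(paste0(c("p_time_", "padj_time_"), rep(c(s1, s2), each = 2)),
               "p_stimulus", "padj_stimulus"))
    out[[nm]] <- NA_real_
  out$label <- "filtered_low"
  out$alpha_hat <- out$lambda_hat <- NA_real_
  out$direction <- NA_character_

  flt <- filter_min_expression(x, tpm_min)
  if (length(flt$retained) == 0L) return(out)
  lt <- log_transform(subset_tensor(x, flt$retained), pseudocount)
  nt <- length(lt$design$time_points)
  nk <- lt$design$n_replicates

  p1 <- p2 <- numeric(length(lt$promoters))
  for (i in seq_along(lt$promoters)) {
    sl <- lt$values[i, , , ]
    p1[i] <- time_anova(matrix(sl[1L, , ], nt, nk))$p.value
    p2[i] <- time_anova(matrix(sl[2L, , ], nt, nk))$p.value
  }
  adj1 <- bh_adjust(p1)
  adj2 <- bh_adjust(p2)
  idx <- match(lt$promoters, out$promoter)
  out[[paste0("p_time_", s1)]][idx] <- p1
  out[[paste0("padj_time_", s1)]][idx] <- adj1
  out[[paste0("p_time_", s2)]][idx] <- p2
  out[[paste0("padj_time_", s2)]][idx] <- adj2

  status <- filter_unresponsive(adj1, adj2, alpha_filter)
  out$label[idx] <- status
  keep <- which(status == "retained")
  if (length(keep) == 0L) return(out)

  ps <- numeric(length(keep))
  ah <- lh <- numeric(length(keep))
  dir <- character(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    sl <- array(lt$values[i, , , ], dim = c(2L, nt, nk))
    ps[j] <- stimulus_anova(sl)$p.value
    tr <- linear_trend(sl, lt$design$time_points)
    ah[j] <- tr$alpha_hat
    lh[j] <- tr$lambda_hat
    dir[j] <- tr$direction
  }
  adj_s <- bh_adjust(ps)
  ridx <- idx[keep]
  out$p_stimulus[ridx] <- ps
  out$padj_stimulus[ridx] <- adj_s
  out$label[ridx] <- classify_labels(adj_s, alpha_class)
  out$alpha_hat[ridx] <- ah
  out$lambda_hat[ridx] <- lh
  out$direction[ridx] <- dir
  out
}

#' Fold-change divergence test
#'
#' Computes the replicate-paired log2 fold-change profile (second arm minus
#' first arm) for each requested promoter, tests for a change of the fold
#' change across time with a one-way ANOVA (time categorical), adjusts with
#' BH across all tested promoters, and reports the fold-change trend as the
#' OLS slope of the fold change on numeric time. A constant (even large)
#' offset between the arms is not divergence; only time-varying fold change
#' is.
#'
#' @param x an `expr_tensor`; TPM-scale input is log2-transformed
#'   internally with `pseudocount`.
#' @param promoters promoter IDs to test; default all promoters in `x`.
#' @param alpha level for the divergence call, default 0.01.
#' @param pseudocount log2 pseudocount used when `x` is on the TPM scale.
#' @return data frame with columns `promoter`, `p_fc`, `padj_fc`,
#'   `divergent` (adjusted p < `alpha`), `fc_trend`.
#' @export
divergence_test <- function(x, promoters = NULL, alpha = 0.01,
                            pseudocount = 1) {
  stopifnot(inherits(x, "expr_tensor"))
  if (!x$log_transformed) x <- log_transform(x, pseudocount)
  if (is.null(promoters)) promoters <- x$promoters
  nt <- length(x$design$time_points)
  nk <- x$design$n_replicates
  times <- x$design$time_points
  p <- tr <- numeric(length(promoters))
  for (i in seq_along(promoters)) {
    fc <- fold_change_profile(promoter_slice(x, promoters[i]))
    p[i] <- time_anova(fc)$p.value
    tr[i] <- unname(stats::coef(stats::lm(as.vector(fc) ~ rep(times, nk)))[2L])
  }
  padj <- bh_adjust(p)
  data.frame(promoter = promoters, p_fc = p, padj_fc = padj,
             divergent = padj < alpha, fc_trend = tr,
             stringsAsFactors = FALSE)
}
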