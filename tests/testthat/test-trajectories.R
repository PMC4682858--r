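# Filtering, ANOVA classification, trend and fold-change operations.

test_that("log2 transform applies the pseudocount and refuses to run twice", {
  x <- toy_tensor(array(rep(c(1, 0, 3), length.out = 16), c(1, 2, 4, 2)))
  y <- log_transform(x, pseudocount = 1)
  expect_true(y$log_transformed)
  expect_equal(sort(unique(as.vector(y$values))), c(0, 1, 2))
  expect_error(log_transform(y), "already")
})

test_that("minimum-expression filter drops a promoter only when all values are below threshold", {
  vals <- array(0, dim = c(3, 2, 4, 2))
  vals[1, , , ] <- 0.5                 # everywhere below 1 -> dropped
  vals[2, , , ] <- 0
  vals[2, 1, 1, 1] <- 1.0              # exactly at threshold -> retained
  vals[3, , , ] <- 5
  x <- toy_tensor(vals)
  flt <- filter_min_expression(x, 1)
  expect_equal(flt$dropped, x$promoters[1])
  expect_equal(flt$retained, x$promoters[2:3])
  expect_error(filter_min_expression(log_transform(x), 1), "TPM")
})

test_that("filter partition matches an exhaustive per-value scan on random data", {
  withr::with_seed(8, {
    vals <- array(stats::rexp(100 * 2 * 4 * 2, rate = 1),
                  dim = c(100, 2, 4, 2))
  })
  x <- toy_tensor(vals)
  flt <- filter_min_expression(x, 1)
  oracle_drop <- vapply(seq_len(100), function(i) all(vals[i, , , ] < 1),
                        logical(1))
  expect_setequal(flt$dropped, x$promoters[oracle_drop])
  expect_setequal(flt$retained, x$promoters[!oracle_drop])
})

test_that("time ANOVA F equals the sum-of-squares decomposition", {
  withr::with_seed(31, {
    for (rep in 1:25) {
      nt <- sample(3:6, 1)
      nk <- sample(2:4, 1)
      mat <- matrix(stats::rnorm(nt * nk), nt, nk)
      got <- time_anova(mat)
      want <- oracle_oneway(mat)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
      expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
      expect_equal(got$df, c(nt - 1, nt * nk - nt))
    }
  })
})

test_that("time ANOVA handles null and degenerate inputs", {
  # equal sample means at every time with residual noise: F is exactly 0
  mat <- rbind(c(-1, 1), c(-2, 2), c(-3, 3))
  out <- time_anova(mat)
  expect_equal(out$statistic, 0)
  expect_gt(out$p.value, 0.5)
  # between-group signal with zero residual variance: p -> 0 with a warning
  expect_warning(deg <- time_anova(rbind(c(0, 0), c(1, 1))), "zero residual")
  expect_equal(deg$p.value, 0)
  expect_error(time_anova(matrix(1:3, 3, 1)), "residual degrees")
  expect_error(time_anova(matrix(1:2, 1, 2)), "2 time levels")
})

test_that("stimulus ANOVA matches the two-factor decomposition and its symmetries", {
  withr::with_seed(32, {
    for (rep in 1:25) {
      nt <- sample(3:5, 1)
      nk <- sample(2:3, 1)
      arr <- array(stats::rnorm(2 * nt * nk), c(2, nt, nk))
      got <- stimulus_anova(arr)
      want <- oracle_twoway_stimulus(arr)
      expect_equal(got$statistic, want$statistic, tolerance = 1e-9)
      expect_equal(got$p.value, want$p.value, tolerance = 1e-9)
    }
  })
  # identical arms: zero stimulus sum of squares, p = 1
  withr::with_seed(33, base <- matrix(rep(stats::rnorm(4), 2), 4, 2))
  sym <- array(NA_real_, c(2, 4, 2))
  sym[1, , ] <- base
  sym[2, , ] <- base
  expect_equal(stimulus_anova(sym)$p.value, 1)
  # constant offset of 1 log2 unit with tiny noise separates the arms
  withr::with_seed(34, {
    off <- sym
    off[2, , ] <- base + 1 + stats::rnorm(8, 0, 1e-3)
  })
  expect_lt(stimulus_anova(off)$p.value, 1e-6)
})

test_that("BH adjustment reproduces the step-up formula", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(35, {
    for (rep in 1:20) {
      p <- stats::runif(sample(1:50, 1))
      adj <- bh_adjust(p)
      expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
      expect_true(all(adj >= p))
      o <- order(p)
      expect_true(all(diff(adj[o]) >= -1e-15))
    }
  })
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("the unresponsiveness filter removes only promoters null in both arms", {
  lab <- filter_unresponsive(c(0.5, 0.001, 0.9), c(0.5, 0.9, 0.005), 0.01)
  expect_equal(lab, c("filtered_unresponsive", "retained", "retained"))
  withr::with_seed(36, {
    a <- stats::runif(200)
    b <- stats::runif(200)
  })
  expect_equal(filter_unresponsive(a, b, 0.01),
               ifelse(a > 0.01 & b > 0.01, "filtered_unresponsive",
                      "retained"))
  expect_error(filter_unresponsive(a, b[-1]), "length")
})

test_that("classification uses strict inequality at the threshold", {
  expect_equal(classify_labels(c(0.005, 0.5, 0.01), 0.01),
               c("stimulus_specific", "generic", "generic"))
})

test_that("linear trend recovers exact coefficients and flags flat profiles", {
  d <- toy_design(times = c(0, 1, 2, 4), reps = 2)
  times <- d$time_points
  arr <- array(NA_real_, c(2, 4, 2))
  for (k in 1:2) for (s in 1:2) arr[s, , k] <- 2 * times  # exact line
  tr <- linear_trend(arr, times)
  expect_equal(tr$alpha_hat, 2, tolerance = 1e-12)
  expect_equal(tr$lambda_hat, 0, tolerance = 1e-12)
  expect_equal(tr$direction, "increase")
  flat <- array(3, c(2, 4, 2))
  expect_equal(linear_trend(flat, times)$direction, "flat")
  expect_error(linear_trend(arr[, 1:2, , drop = FALSE], times[1:2]),
               "3 distinct")
  # normal-equations oracle on random data
  withr::with_seed(37, {
    for (rep in 1:10) {
      arr <- array(stats::rnorm(16), c(2, 4, 2))
      tr <- linear_trend(arr, times)
      X <- cbind(1, rep(rep(times, each = 2), 2), rep(c(0, 1), 8))
      beta <- solve(t(X) %*% X, t(X) %*% as.vector(arr))
      expect_equal(tr$alpha_hat, beta[2], tolerance = 1e-9)
      expect_equal(tr$lambda_hat, beta[3], tolerance = 1e-9)
    }
  })
})

test_that("fold-change profiles subtract the arms replicate-by-replicate", {
  withr::with_seed(38, arr <- array(stats::rnorm(16), c(2, 4, 2)))
  same <- arr
  same[2, , ] <- arr[1, , ]
  expect_true(all(fold_change_profile(same) == 0))
  plus1 <- arr
  plus1[2, , ] <- arr[1, , ] + 1
  expect_true(all(fold_change_profile(plus1) == 1))
  fc <- fold_change_profile(arr)
  for (t in 1:4) for (k in 1:2)
    expect_equal(fc[t, k], arr[2, t, k] - arr[1, t, k])
  expect_error(fold_change_profile(list(matrix(0, 4, 2), matrix(0, 4, 3))),
               "unpaired")
})

test_that("divergence requires time-varying fold change, not a constant offset", {
  d <- toy_design(times = c(0, 1, 2, 4), reps = 3)
  nt <- 4; nk <- 3
  withr::with_seed(39, {
    vals <- array(NA_real_, c(2, 2, nt, nk))
    base <- matrix(stats::rnorm(nt * nk, 6, 0.05), nt, nk)
    # promoter 1: constant offset of 1 between arms
    vals[1, 1, , ] <- base
    vals[1, 2, , ] <- base + 1
    # promoter 2: ramp 0 -> 2 over the time course
    vals[2, 1, , ] <- base
    vals[2, 2, , ] <- base + seq(0, 2, length.out = nt) +
      stats::rnorm(nt * nk, 0, 0.05)
  })
  x <- toy_tensor(2^vals, d)
  div <- divergence_test(x, alpha = 0.01)
  expect_false(div$divergent[1])
  expect_true(div$divergent[2])
  expect_gt(div$fc_trend[2], 0)
})

test_that("full classification separates planted classes and reports exclusive labels", {
  cfg <- simulation_config(40, 40, 20, delta = 2, sigma = 0.1, seed = 44)
  sim <- generate_dataset(cfg)
  cls <- classify_promoters(sim$tensor)
  expect_setequal(cls$promoter, sim$truth$promoter)
  expect_true(all(cls$label %in% c("filtered_low", "filtered_unresponsive",
                                   "generic", "stimulus_specific")))
  truth <- sim$truth$label[match(cls$promoter, sim$truth$promoter)]
  expect_true(all(cls$label[truth == "unresponsive"] ==
                    "filtered_unresponsive"))
  expect_gte(mean(cls$label[truth == "stimulus_specific"] ==
                    "stimulus_specific"), 0.95)
  expect_gte(mean(cls$label[truth == "generic"] == "generic"), 0.9)
  # adjusted p-values never fall below raw ones
  ok <- !is.na(cls$p_stimulus)
  expect_true(all(cls$padj_stimulus[ok] >= cls$p_stimulus[ok]))
  # trend direction agrees with the planted archetype for specific promoters
  spec <- cls$label == "stimulus_specific"
  sign_truth <- sim$truth$trend_sign[match(cls$promoter, sim$truth$promoter)]
  agree <- sign(cls$alpha_hat[spec]) == sign_truth[spec]
  expect_gte(mean(agree), 0.9)
})

test_that("promoter order permutation permutes the classification output identically", {
  cfg <- simulation_config(15, 15, 5, seed = 46)
  sim <- generate_dataset(cfg)
  cls1 <- classify_promoters(sim$tensor)
  withr::with_seed(47, perm <- sample(length(sim$tensor$promoters)))
  x2 <- subset_tensor(sim$tensor, sim$tensor$promoters[perm])
  cls2 <- classify_promoters(x2)
  reord <- cls2[match(cls1$promoter, cls2$promoter), ]
  rownames(reord) <- NULL
  expect_equal(reord, cls1)
})
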