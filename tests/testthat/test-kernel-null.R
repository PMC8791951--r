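test_that("kernel bandwidth follows the normal-reference rule", {
  set.seed(1)
  x <- rnorm(132, 0.5, 0.1)
  model <- fit_kernel_density(x)
  expect_equal(model$bandwidth, sd(x) * (4 / (3 * 132))^(1 / 5),
               tolerance = 1e-14)
  # approximately 1.06 * sigma-hat * n^(-1/5)
  expect_equal(model$bandwidth, 1.06 * sd(x) * 132^(-1 / 5), tolerance = 0.01)

  expect_error(fit_kernel_density(rep(0.3, 20)), "identical")
  expect_error(fit_kernel_density(rnorm(5)), "at least 8")
})

test_that("fitted density integrates to one and sampling reflects the support", {
  x <- c(rep(0, 5), rep(1, 5))
  model <- fit_kernel_density(x)
  expect_gt(model$bandwidth, 0)
  total <- integrate(function(u) kde_density(model, u), -5, 6,
                     rel.tol = 1e-9)$value
  expect_equal(total, 1, tolerance = 1e-6)
  # bimodal spread around 0 and 1: modes at the support, dip between
  expect_gt(kde_density(model, 0), kde_density(model, 0.5))
  expect_gt(kde_density(model, 1), kde_density(model, 0.5))
  set.seed(2)
  s <- kde_sample(model, 5000)
  expect_gt(mean(s < 0.5), 0.4)
  expect_lt(mean(s < 0.5), 0.6)
})

test_that("null differences are symmetric, reproducible and correctly scaled", {
  set.seed(3)
  x <- rnorm(132, 2, 0.5)
  model <- fit_kernel_density(x)
  null <- generate_null_differences(model, m = 50000, seed = 11)
  expect_length(null$differences, 50000)
  # mean near 0 within 4 sd / sqrt(m)
  expect_lt(abs(mean(null$differences)),
            4 * sd(null$differences) / sqrt(null$m))
  # variance of X1 - X2 with X ~ KDE: 2 * (sigma-hat^2 + h^2)
  vhat <- stats::var(x) * (131 / 132) + model$bandwidth^2
  expect_equal(var(null$differences), 2 * vhat, tolerance = 0.05)
  # determinism
  null2 <- generate_null_differences(model, m = 50000, seed = 11)
  expect_identical(null$differences, null2$differences)
  expect_error(generate_null_differences(model, m = 10), "m >= 1000")
})

test_that("empirical p-values count the two-sided tail with a 1/m floor", {
  null <- structure(list(differences = c(-2, -1, 0, 1, 2), m = 5L,
                         seed = NULL, metric_name = "toy"),
                    class = "null_distribution")
  expect_equal(empirical_p_value(1.5, null)$p, 2 / 5)
  expect_equal(empirical_p_value(0, null)$p, 1)
  out <- empirical_p_value(9, null)
  expect_equal(out$p, 1 / 5)
  expect_true(out$p_floored)
  # monotone non-increasing in |observed|
  obs <- seq(0, 3, by = 0.25)
  ps <- empirical_p_value(obs, null)$p
  expect_true(all(diff(ps) <= 0))
  expect_equal(ps, empirical_p_value(-obs, null)$p)
})

test_that("BH adjustment matches the hand computation", {
  out <- bh_fdr(c(0.01, 0.02, 0.03, 0.5), q_threshold = 0.1)
  expect_equal(out$q, c(0.04, 0.04, 0.04, 0.5))
  expect_equal(out$significant, c(TRUE, TRUE, TRUE, FALSE))

  all1 <- bh_fdr(rep(1, 6))
  expect_equal(all1$q, rep(1, 6))
  expect_false(any(all1$significant))

  expect_equal(bh_fdr(0.05)$q, 0.05)
  expect_error(bh_fdr(numeric(0)), "empty")
  expect_error(bh_fdr(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("q >= p and BH flags contain the Bonferroni flags", {
  set.seed(4)
  p <- runif(40)^2
  out <- bh_fdr(p, q_threshold = 0.1)
  expect_true(all(out$q >= p))
  bonf <- p * length(p) < 0.1
  expect_true(all(out$significant[bonf]))
})

test_that("identical scans give p = 1 everywhere and no discoveries", {
  pair <- small_test_pair(seed = 21)
  net <- threshold_network(correlation_matrix(pair$baseline))
  mets <- compute_metrics(net, "same")
  res <- suppressMessages(test_metric_changes(mets, mets, m = 2000, seed = 5))
  expect_true(all(res$diff == 0))
  expect_true(all(res$p == 1))
  expect_false(any(res$significant))
  expect_true(all(res$q >= res$p))
})

test_that("the change test is deterministic and detects a planted shift", {
  pair <- small_test_pair(seed = 31)
  base <- compute_metrics(threshold_network(correlation_matrix(pair$baseline)),
                          "base")
  post <- base
  post$scan_id <- "post"
  # plant a GE shift of 5 baseline SDs at one ROI
  shift <- 5 * sd(base$GE)
  post$GE[7] <- post$GE[7] + shift
  res <- suppressMessages(test_metric_changes(base, post, m = 20000, seed = 9))
  ge <- res[res$metric == "GE", ]
  expect_true(ge$significant[ge$index == 6])
  res2 <- suppressMessages(test_metric_changes(base, post, m = 20000, seed = 9))
  expect_identical(res$p, res2$p)
  expect_identical(res$q, res2$q)

  mismatch <- base
  mismatch$name[1] <- "other"
  expect_error(suppressMessages(test_metric_changes(base, mismatch)),
               "share ROI set")
})

test_that("undefined APL rows are dropped from the APL family only", {
  pair <- small_test_pair(seed = 41)
  base <- compute_metrics(threshold_network(correlation_matrix(pair$baseline)),
                          "base")
  post <- compute_metrics(threshold_network(correlation_matrix(pair$post)),
                          "post")
  base$APL[3] <- NA
  base$apl_defined[3] <- FALSE
  expect_message(
    res <- test_metric_changes(base, post, m = 2000, seed = 2),
    "dropped from the APL"
  )
  expect_equal(sum(res$metric == "APL"), nrow(base) - 1L)
  expect_equal(sum(res$metric == "GE"), nrow(base))
})

test_that("per-ROI nulls agree statistically with the shared null", {
  pair <- small_test_pair(seed = 51)
  base <- compute_metrics(threshold_network(correlation_matrix(pair$baseline)),
                          "base")
  post <- compute_metrics(threshold_network(correlation_matrix(pair$post)),
                          "post")
  shared <- suppressMessages(test_metric_changes(base, post, m = 5000, seed = 3))
  fresh <- suppressMessages(test_metric_changes(base, post, m = 5000, seed = 3,
                                                fresh_null_per_roi = TRUE))
  ge_s <- shared$p[shared$metric == "GE"]
  ge_f <- fresh$p[fresh$metric == "GE"]
  expect_gt(cor(ge_s, ge_f), 0.95)
})
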