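test_that("a separable single informative feature is found and fit", {
  withr::local_seed(3)
  x <- cbind(signal = rep(c(3, -3), each = 10) + rnorm(20, sd = 0.1),
             noise = rnorm(20))
  y <- factor(rep(c("pos", "neg"), each = 10), levels = c("pos", "neg"))
  m <- fit_sparse_hinge(x, y, cost = 5, epsilon = 1)
  expect_true(1 %in% m$selected)
  pred <- predict(m, x)
  expect_equal(as.character(pred), as.character(y))
})

test_that("solutions satisfy the KKT conditions on well-conditioned data", {
  withr::local_seed(12)
  x <- matrix(rnorm(30 * 8), 30)
  y <- rep(c(1, -1), 15)
  xs <- scale(x)
  for (pars in list(c(1, 0.5), c(9, 1), c(17, 4))) {
    r <- divprof:::.sparse_hinge_fit(xs, y, pars[1], pars[2],
                                     max_sweeps = 20000, tol = 1e-12)
    w <- r$weights
    v <- 1 - y * (xs %*% w + r$intercept)
    u <- ifelse(y > 0, 0.5 * length(y) / sum(y > 0),
                0.5 * length(y) / sum(y < 0))
    grad <- vapply(seq_along(w), function(j) {
      -2 * pars[1] * sum(ifelse(v > 0, u * y * xs[, j] * v, 0))
    }, numeric(1))
    # nonzero weights: gradient balances the penalty subgradient exactly;
    # zero weights: gradient within the penalty band
    if (any(w != 0)) {
      expect_lt(max(abs(grad[w != 0] + pars[2] * sign(w[w != 0]))), 1e-4)
    }
    if (any(w == 0)) {
      expect_lt(max(abs(grad[w == 0])), pars[2] + 1e-4)
    }
  }
})

test_that("sparsity grows with the regularization parameter", {
  withr::local_seed(4)
  x <- matrix(rnorm(24 * 12), 24)
  y <- factor(rep(c("a", "b"), 12))
  nsel <- vapply(2^(0:7), function(e) {
    length(fit_sparse_hinge(x, y, cost = 9, epsilon = e)$selected)
  }, numeric(1))
  expect_lt(nsel[length(nsel)], nsel[1])
  expect_true(all(diff(nsel) <= 1))  # close to monotone along the path
  # extreme regularization removes every feature
  none <- fit_sparse_hinge(x, y, cost = 1, epsilon = 1e4)
  expect_length(none$selected, 0)
})

test_that("duplicated feature columns do not enlarge the selected set", {
  withr::local_seed(9)
  x1 <- cbind(rep(c(2, -2), each = 8) + rnorm(16, sd = 0.3), rnorm(16))
  y <- factor(rep(c("a", "b"), each = 8))
  base <- fit_sparse_hinge(x1, y, cost = 5, epsilon = 1)
  dup <- fit_sparse_hinge(cbind(x1, x1), y, cost = 5, epsilon = 1)
  expect_equal(length(dup$selected), length(base$selected))
})

test_that("fits reject degenerate inputs and are deterministic", {
  x <- matrix(rnorm(20), 10)
  expect_error(fit_sparse_hinge(x, rep("a", 10), 1, 1), "two classes")
  y <- factor(rep(c("a", "b"), 5))
  m1 <- fit_sparse_hinge(x, y, 5, 0.5)
  m2 <- fit_sparse_hinge(x, y, 5, 0.5)
  expect_identical(m1$weights, m2$weights)
})

test_that("hyperparameter grid carries the published defaults", {
  g <- hyperparameter_grid()
  expect_equal(g$cost, c(1, 5, 9, 13, 17))
  expect_equal(g$epsilon, 2^(-3:4))
  expect_equal(g$max_selected_features, 20)
  expect_equal(g$max_violations, 3)
})

test_that("nested LOOCV recovers a strong single-feature signal", {
  withr::local_seed(6)
  x <- cbind(matrix(rnorm(16 * 10), 16),
             rep(c(5, -5), each = 8) + rnorm(16, sd = 0.2))
  colnames(x) <- seq(0, 2, length.out = 11)
  y <- factor(rep(c("hi", "lo"), each = 8), levels = c("hi", "lo"))
  res <- nested_loocv(x, y)
  expect_equal(res$bacc, 100)
  expect_equal(res$bacc, (res$sensitivity + res$specificity) / 2)
  expect_equal(nrow(tidy(res)), 16)
  expect_true(all(tidy(res)$n_selected <= 20))
  expect_error(nested_loocv(x[1:5, ], y[1:5]), ">= 6")
  expect_error(nested_loocv(x, factor(rep("hi", 16))), "two classes")
  expect_error(nested_loocv(x[1:8, ], factor(c(rep("a", 6), "b", "b"))),
               ">= 3")
})

test_that("the BACC identity holds on every classification result", {
  pred <- factor(c(rep("p", 10), rep("n", 2), rep("n", 11), "p"),
                 levels = c("p", "n"))
  truth <- factor(rep(c("p", "n"), c(12, 12)), levels = c("p", "n"))
  m <- divprof:::bacc_percent(pred, truth, "p")
  expect_equal(m$sensitivity, 100 * 10 / 12, tolerance = 1e-9)
  expect_equal(m$specificity, 100 * 11 / 12, tolerance = 1e-9)
  expect_equal(m$bacc, (m$sensitivity + m$specificity) / 2)
})

test_that("inner-loop choices are blind to the held-out sample", {
  withr::local_seed(15)
  d <- two_regime_features(61, n_per_class = 5, n_reads = 5e3)
  res <- nested_loocv(d$x, d$y)
  # corrupt the features of one held-out sample: its fold's hyperparameter
  # choice must not change (its inner models never saw it)
  x2 <- d$x
  x2[3, ] <- x2[3, ] * 10 + 100
  res2 <- nested_loocv(x2, d$y)
  t1 <- tidy(res); t2 <- tidy(res2)
  expect_equal(t1$cost[3], t2$cost[3])
  expect_equal(t1$epsilon[3], t2$epsilon[3])
  expect_equal(t1$inner_bacc[3], t2$inner_bacc[3])
})

test_that("permutation testing flags real signal and respects its contracts", {
  d <- two_regime_features(71, n_per_class = 5, n_reads = 5e3)
  res <- nested_loocv(d$x, d$y)
  expect_gte(res$bacc, 80)
  expect_warning(
    pt <- permutation_test(d$x, d$y, n_permutations = 30, seed = 7,
                           result = res),
    "resolution")
  expect_gte(pt$permutation_p, 0)
  expect_lte(pt$permutation_p, 1)
  expect_equal(pt$permutation_p, pt$n_exceeding / 30)
  expect_equal(pt$significant, pt$n_exceeding < 0.01 * 30)
  # permutation p-values are seed-reproducible
  pt2 <- suppressWarnings(permutation_test(d$x, d$y, n_permutations = 30,
                                           seed = 7, result = res))
  expect_equal(pt$permuted_baccs, pt2$permuted_baccs)
})

test_that("single-index baselines restrict the feature space", {
  d <- two_regime_features(81, n_per_class = 5, n_reads = 5e3)
  base <- single_index_baseline(d$x, d$y, alphas_keep = 1)
  expect_lte(base$median_n_alphas, 1)
  expect_true(all(unlist(base$selected_alphas_per_fold) == 1))
  both <- single_index_baseline(d$x, d$y, alphas_keep = c(1, 2))
  expect_lte(both$median_n_alphas, 2)
  expect_error(single_index_baseline(d$x, d$y, alphas_keep = 99), "column")
})

test_that("profile features join metadata with explicit positive label", {
  coh <- simulate_cohort(6, n_reads = 5e3, seed = 19)
  prof <- repertoire_profiles(coh, alpha_grid(0, 4, 1))
  meta <- tibble::tibble(
    sample_id = unique(coh$sample_id),
    status_label = rep(c("Baseline", "Month 2"), 3))
  feats <- profile_features(prof, meta, positive_label = "Month 2")
  expect_equal(levels(feats$y)[1], "Month 2")
  expect_equal(dim(feats$x), c(6, 5))
  expect_equal(feats$alphas, 0:4)
})
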