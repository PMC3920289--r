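test_that("Euclidean distances have the stated closed forms", {
  pm <- make_pm(rbind(a = c(100, 0), b = c(0, 100)))
  d <- euclidean_distances(pm)
  expect_equal(as.numeric(d), sqrt(2) * 100, tolerance = 1e-12)

  pm3 <- make_pm(rbind(a = c(50, 50), b = c(50, 50), c = c(60, 40)))
  D <- as.matrix(euclidean_distances(pm3))
  expect_equal(unname(D["a", "b"]), 0)
  expect_equal(D, t(D))
  expect_equal(unname(diag(D)), rep(0, 3))
})

test_that("NMDS recovers exact low-dimensional embeddings with ~zero stress", {
  set.seed(42)
  X <- matrix(stats::rnorm(48), 24, 2)
  fit <- nmds(stats::dist(X), k = 2, n_restarts = 8, seed = 1)
  expect_lt(fit$stress, 1e-4)
  expect_equal(colMeans(fit$points), c(axis1 = 0, axis2 = 0), tolerance = 1e-8)

  # collinear points embed exactly in 1-D
  fit1 <- nmds(stats::dist(matrix(c(0, 1, 2.5, 7), 4, 1)), k = 1,
               n_restarts = 5, seed = 1)
  expect_lt(fit1$stress, 1e-4)

  expect_error(nmds(stats::dist(X[1:4, ]), k = 3),
               class = "trflpr_parameter_error")
})

test_that("planted configurations are recovered up to rotation and scale", {
  set.seed(7)
  X <- matrix(stats::rnorm(60), 30, 2)
  fit <- nmds(stats::dist(X), k = 2, n_restarts = 8, seed = 2)
  pro <- vegan::procrustes(X, fit$points)
  rmse <- sqrt(mean(stats::residuals(pro)^2))
  scale_X <- sqrt(mean(rowSums(scale(X, scale = FALSE)^2)))
  expect_lt(rmse / scale_X, 0.01)
})

test_that("stress is invariant under similarity transforms of the input", {
  set.seed(5)
  X <- matrix(stats::rnorm(30), 15, 2)
  d <- stats::dist(X)
  f1 <- nmds(d, k = 2, n_restarts = 6, seed = 3)
  # uniform scaling of dissimilarities must not change the optimum stress
  f2 <- nmds(d * 3.7, k = 2, n_restarts = 6, seed = 3)
  expect_equal(f1$stress, f2$stress, tolerance = 1e-6)
})

test_that("final disparities are monotone in dissimilarity rank", {
  set.seed(12)
  m <- matrix(stats::rlnorm(80), 8, 10)
  fit <- nmds(stats::dist(m), k = 2, n_restarts = 6, seed = 4)
  expect_true(all(diff(fit$shepard$disparity) >= -1e-12))
  expect_true(!is.unsorted(fit$shepard$dissimilarity))
})

test_that("stress agrees with an independent NMDS implementation", {
  # structured community data: both optimizers find the same optimum.
  # (structureless tiny matrices are avoided here: the reference optimizer
  # can collapse them into degenerate near-zero-stress configurations)
  st <- simulate_study(study_design(seed = 7))
  pm <- process_peaks(st$peaks, st$meta)
  d <- euclidean_distances(pm)
  mine <- nmds(d, k = 2, n_restarts = 20, seed = 5)
  ref <- vegan::monoMDS(d, k = 2, model = "global", smin = 1e-7,
                        maxit = 500)
  expect_lt(abs(mine$stress - 100 * ref$stress), 0.5)
})

test_that("dimensionality selection applies the stress-gain rule", {
  set.seed(33)
  X2 <- matrix(stats::rnorm(40), 20, 2)
  scan2 <- select_dimensionality(stats::dist(X2), k_range = 1:4,
                                 n_restarts = 6, seed = 6)
  expect_equal(scan2$k, 2)
  expect_lt(scan2$stress$stress[scan2$stress$k == 2], 1e-3)

  X1 <- matrix(seq(0, 10, length.out = 18), 18, 1)
  scan1 <- select_dimensionality(stats::dist(X1), k_range = 1:3,
                                 n_restarts = 6, seed = 7)
  expect_equal(scan1$k, 1)

  # best stress is non-increasing in k (warm-started with padded solutions)
  m <- matrix(stats::rlnorm(140), 14, 10)
  scan <- select_dimensionality(stats::dist(m), k_range = 1:5,
                                n_restarts = 6, seed = 8)
  expect_true(all(diff(scan$stress$stress) <= 1e-6))
})

test_that("the Monte Carlo stress test separates structure from noise", {
  # strongly clustered data: real stress far below randomized stress
  set.seed(9)
  centers <- rbind(c(0, 0), c(30, 0), c(0, 30))
  m <- centers[rep(1:3, each = 5), ] + matrix(stats::rnorm(30, 0, 0.5), 15, 2)
  m <- cbind(m + 40, 100 - rowSums(m + 40) / 2, rowSums(m + 40) / 2)
  pm <- make_pm(m)
  mc <- monte_carlo_stress_test(pm, k = 2, n_randomizations = 19,
                                n_restarts = 5, seed = 10)
  expect_lte(mc$p_value, 0.05)

  expect_error(monte_carlo_stress_test(pm, k = 2, n_randomizations = 0),
               class = "trflpr_parameter_error")
})

test_that("ordination results have tidy, glance and plot methods", {
  set.seed(2)
  st <- simulate_study(quick_design(2))
  pm <- process_peaks(st$peaks, st$meta)
  fit <- nmds(euclidean_distances(pm), k = 2, n_restarts = 5, seed = 11)
  td <- tidy(fit)
  expect_named(td, c("sample_id", "axis1", "axis2"))
  expect_equal(nrow(td), nrow(pm))
  gl <- glance(fit)
  expect_equal(gl$k, 2)
  p <- autoplot(fit, meta = pm_meta(pm), colour = "season",
                shape = "treatment")
  expect_s3_class(p, "ggplot")
})
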