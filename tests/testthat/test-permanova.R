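test_that("one-way pseudo-F on univariate Euclidean data equals classical F", {
  set.seed(101)
  for (i in 1:10) {
    k <- sample(2:4, 1)
    n_per <- sample(3:6, 1)
    y <- stats::rnorm(k * n_per)
    g <- rep(letters[1:k], each = n_per)
    meta <- tibble::tibble(sample_id = as.character(seq_along(y)), g = g)
    d <- stats::dist(matrix(y))
    attr(d, "Labels") <- meta$sample_id
    fit <- permanova(d, meta, ~ g, n_perm = 0)
    F_classic <- stats::anova(stats::lm(y ~ g))$`F value`[1]
    expect_equal(fit$table$pseudo_F[1], F_classic, tolerance = 1e-10)
  }
})

test_that("the SS partition is exact and matches an independent implementation", {
  st <- simulate_study(quick_design(17, planted = default_planted_effects()))
  pm <- process_peaks(st$peaks, st$meta)
  d <- euclidean_distances(pm)
  fit <- permanova(d, pm_meta(pm), ~ season * treatment, n_perm = 99, seed = 1)
  tab <- fit$table
  ss_total <- tab$SS[tab$term == "total"]
  expect_equal(sum(tab$SS[tab$term != "total"]), ss_total,
               tolerance = 1e-8)

  ad <- vegan::adonis2(pm_values(pm) ~ season * treatment,
                       data = pm_meta(pm), method = "euclidean",
                       permutations = 19, by = "terms")
  expect_equal(tab$SS[1:3], ad$SumOfSqs[1:3], tolerance = 1e-8)
  expect_equal(tab$pseudo_F[1:3], ad$F[1:3], tolerance = 1e-8)
  expect_equal(tab$df[1:3], ad$Df[1:3])
})

test_that("with Euclidean distance, term SS equals the summed univariate ANOVA SS", {
  set.seed(55)
  n <- 18
  meta <- tibble::tibble(
    sample_id = as.character(1:n),
    season = rep(c("sp", "su", "au"), each = 6),
    treatment = rep(c("amb", "oz"), 9)
  )
  m <- matrix(stats::rnorm(n * 5), n)
  fit <- permanova(stats::dist(m), meta, ~ season * treatment, n_perm = 0)
  # brute-force oracle: per-column classical sequential ANOVA
  ss_by_col <- sapply(seq_len(ncol(m)), function(j) {
    a <- stats::anova(stats::lm(m[, j] ~ season * treatment, data = meta))
    a$`Sum Sq`
  })
  expect_equal(fit$table$SS[1:4], unname(rowSums(ss_by_col)),
               tolerance = 1e-10)
})

test_that("permutation p-values are invariant to factor level relabeling", {
  st <- simulate_study(quick_design(23, planted = default_planted_effects()))
  pm <- process_peaks(st$peaks, st$meta)
  d <- euclidean_distances(pm)
  meta <- pm_meta(pm)
  f1 <- permanova(d, meta, ~ season * treatment, n_perm = 199, seed = 4)
  meta2 <- dplyr::mutate(meta,
    season = c(spring = "Z1", summer = "Z2", autumn = "Z3")[season])
  f2 <- permanova(d, meta2, ~ season * treatment, n_perm = 199, seed = 4)
  expect_equal(f1$table$p_value, f2$table$p_value)
  expect_equal(f1$table$SS, f2$table$SS, tolerance = 1e-12)
})

test_that("degenerate and invalid designs are rejected", {
  meta <- tibble::tibble(sample_id = as.character(1:6),
                         g = rep("a", 6), h = rep(c("x", "y"), 3))
  same <- make_pm(matrix(50, 6, 2))
  expect_error(permanova(euclidean_distances(same), pm_meta(same), ~ season),
               class = "trflpr_degenerate_error")
  d <- stats::dist(matrix(stats::rnorm(6), 6, 1))
  attr(d, "Labels") <- meta$sample_id
  expect_error(permanova(d, meta, ~ g), class = "trflpr_design_error")
})

test_that("pairwise comparisons report t = sqrt(F) per level pair", {
  st <- simulate_study(quick_design(29, planted = default_planted_effects()))
  pm <- process_peaks(st$peaks, st$meta)
  d <- euclidean_distances(pm)
  pw <- pairwise_permanova(d, pm_meta(pm), "season", n_perm = 199, seed = 5)
  expect_equal(nrow(pw), 3)
  expect_true(all(pw$t >= 0))

  # two identical groups: t ~ 0 and p near 1
  m <- rbind(matrix(rep(c(60, 40), 6), 6, 2, byrow = TRUE) +
               stats::rnorm(12, 0, 0.01))
  pm2 <- make_pm(m, season = rep(c("sp", "su"), each = 3))
  pw2 <- pairwise_permanova(euclidean_distances(pm2), pm_meta(pm2), "season",
                            n_perm = 199, seed = 6)
  expect_gt(pw2$p_value, 0.2)

  # monte carlo column present on request
  pw3 <- pairwise_permanova(d, pm_meta(pm), "treatment", n_perm = 99,
                            seed = 7, monte_carlo = TRUE)
  expect_true("p_mc" %in% names(pw3))
})

test_that("the gamma asymptotic fallback behaves at the center and in the tail", {
  set.seed(77)
  perm_F <- stats::rgamma(2000, shape = 5, rate = 4)
  p_center <- asymptotic_p(mean(perm_F), perm_F)
  expect_true(abs(p_center - 0.5) < 0.1)
  expect_lt(asymptotic_p(1e4, perm_F), 1 / 2001)
  expect_error(asymptotic_p(2, rep(1.3, 100)),
               class = "trflpr_degenerate_error")
  expect_error(asymptotic_p(2, stats::rf(10, 3, 20)),
               class = "trflpr_parameter_error")
})
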