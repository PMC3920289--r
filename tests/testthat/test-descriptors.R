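test_that("Pareto-Lorenz curves accumulate ranked abundances from (0,0)", {
  cv <- pareto_lorenz(c(`100` = 50, `200` = 30, `300` = 10, `400` = 5,
                        `500` = 5))
  expect_equal(cv$band_fraction, c(0, 0.2, 0.4, 0.6, 0.8, 1))
  expect_equal(cv$abundance_fraction, c(0, 0.5, 0.8, 0.9, 0.95, 1))
  # monotone and concave (sorted descending) hence on/above the diagonal
  expect_true(all(diff(cv$abundance_fraction) >= 0))
  expect_true(all(cv$abundance_fraction >= cv$band_fraction - 1e-12))

  eq <- pareto_lorenz(rep(20, 5))
  expect_equal(eq$abundance_fraction, eq$band_fraction)

  expect_error(pareto_lorenz(numeric(0)), class = "trflpr_empty_error")
  expect_error(pareto_lorenz(c(0, 0)), class = "trflpr_empty_error")
})

test_that("PL20 interpolates at the 20% band line with the stated conventions", {
  expect_equal(pl20(rep(20, 5)), 20)
  expect_equal(pl20(c(50, 30, 10, 5, 5)), 50)
  # single band: maximal dominance under the step convention
  expect_equal(pl20(100), 100)
  expect_equal(pl20(100, single_band = "linear"), 20)
  # scale invariance: PL20 is a property of the composition only
  set.seed(4)
  v <- stats::rlnorm(25, 0, 1.5)
  expect_equal(pl20(v), pl20(7.3 * v))
  # bounds for any >= 5 band profile; equality at 20 iff evenness
  for (i in 1:20) {
    x <- stats::rlnorm(sample(5:40, 1), 0, stats::runif(1, 0.1, 2))
    p <- pl20(x)
    expect_gte(p, 20 - 1e-9)
    expect_lte(p, 100)
  }
})

test_that("matrix rows are scored on the common band axis of the matrix", {
  # explicit zero T-RFs rank last: they add bands but no abundance
  m <- rbind(a = c(60, 40, 0, 0, 0), b = c(20, 20, 20, 20, 20))
  pm <- make_pm(m)
  pl <- pl20_profiles(pm)
  expect_equal(pl$pl20[pl$sample_id == "a"], 60)   # top 1 of 5 bands = 60%
  expect_equal(pl$pl20[pl$sample_id == "b"], 20)
  expect_equal(pl$n_bands, c(2, 5))
})

test_that("percent change is 100 * (1 - Pearson r) with its closed-form extremes", {
  pm <- make_pm(rbind(a = c(10, 20, 70), b = c(10, 20, 70)))
  pc <- percent_change_matrix(pm)
  expect_equal(unname(pc["a", "b"]), 0)
  expect_equal(diag(pc), c(a = 0, b = 0))

  pm2 <- make_pm(rbind(a = c(1, 2, 3), b = c(3, 2, 1)))
  expect_equal(unname(percent_change_matrix(pm2)["a", "b"]), 200)

  pm3 <- make_pm(rbind(a = c(2, 0), b = c(0, 2)))
  expect_equal(unname(percent_change_matrix(pm3)["a", "b"]), 200)

  # symmetric, bounded, zero-diagonal on arbitrary data
  set.seed(21)
  pm4 <- make_pm(matrix(stats::rlnorm(60), 6, 10))
  pc4 <- percent_change_matrix(pm4)
  expect_equal(pc4, t(pc4))
  expect_true(all(pc4 >= 0 & pc4 <= 200))

  pm5 <- make_pm(rbind(a = c(5, 5, 5), b = c(1, 2, 3)))
  expect_error(percent_change_matrix(pm5), class = "trflpr_degenerate_error",
               regexp = "a")
})

test_that("moving-window Delta_t averages all cross-group pairs per window", {
  # identical profiles everywhere: zero change
  m <- matrix(rep(c(30, 60, 10), 4), 4, 3, byrow = TRUE)
  rownames(m) <- paste0("s", 1:4)
  pm <- make_pm(m + matrix(c(0, 0, 0, 1, -1, 0, 0, 0, 0, 1, -1, 0), 4, 3,
                           byrow = TRUE),
                season = c("spring", "spring", "summer", "summer"))
  d <- moving_window_delta(pm, c("spring", "summer"), within = NULL)
  expect_equal(nrow(d), 1)
  expect_equal(d$n_pairs, 4)

  pm_id <- make_pm(rbind(s1 = c(30, 60, 10), s2 = c(30, 60, 10)),
                   season = c("spring", "summer"))
  d_id <- moving_window_delta(pm_id, c("spring", "summer"), within = NULL)
  expect_equal(d_id$mean_pct_change, 0)
  expect_equal(d_id$sd_pct_change, 0)

  pm_anti <- make_pm(rbind(s1 = c(1, 2, 3), s2 = c(3, 2, 1)),
                     season = c("spring", "summer"))
  d_anti <- moving_window_delta(pm_anti, c("spring", "summer"), within = NULL)
  expect_equal(d_anti$mean_pct_change, 200)
  expect_equal(d_anti$sd_pct_change, 0)

  # three ordered groups -> exactly two windows per stratum
  st <- simulate_study(quick_design(13))
  pm_st <- process_peaks(st$peaks, st$meta)
  d3 <- moving_window_delta(pm_st, c("spring", "summer", "autumn"))
  expect_equal(nrow(d3), 4)  # 2 windows x 2 treatments
  expect_equal(unique(d3$n_pairs), 9)  # 3 pots x 3 pots

  expect_error(moving_window_delta(pm_st, c("spring", "winter")), "winter")
})

test_that("within-group percent change on duplicates tracks the replicate CV", {
  # extraction duplicates of the same pots are highly correlated, so the
  # degenerate window of a group against itself stays near zero
  st <- simulate_study(study_design(seed = 31, planted_effects = list()))
  pm_e <- process_peaks(st$peaks, st$meta, average = FALSE)
  pc <- percent_change_matrix(pm_e)
  meta <- pm_meta(pm_e)
  within_pot <- vapply(unique(meta$pot_id), function(p) {
    idx <- which(meta$pot_id == p)
    pc[idx[1], idx[2]]
  }, 0)
  expect_lt(mean(within_pot), 5)
})

test_that("the replicate CV estimator recovers the generator target", {
  st <- simulate_study(study_design(seed = 8))
  pm_e <- process_peaks(st$peaks, st$meta, average = FALSE)
  cv <- replicate_cv(pm_e)
  expect_true(abs(attr(cv, "mean_cv") - 6.5) < 2)
})
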