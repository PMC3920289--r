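# Dufrene-Legendre indicator value analysis on T-RFs, the label-permutation
# test, and the univariate permutation ANOVA with pairwise comparisons used
# to follow up significant indicators.

# Core IndVal computation on an abundance matrix (samples x T-RFs).
# A_ig = mean abundance of T-RF i in group g / sum over groups of means;
# B_ig = fraction of group-g samples where i is present (> 0);
# IndVal_ig = 100 * A * B. Returns the per-group IndVal matrix.
indval_matrix <- function(m, groups) {
  cnt <- as.vector(table(groups)[levels(groups)])
  M <- rowsum(m, groups)[levels(groups), , drop = FALSE] / cnt
  P <- rowsum((m > 0) + 0, groups)[levels(groups), , drop = FALSE] / cnt
  tot <- colSums(M)
  A <- sweep(M, 2, ifelse(tot > 0, tot, 1), "/")
  100 * A * P
}

resolve_groups <- function(pm, groups) {
  meta <- pm_meta(pm)
  if (is.character(groups) && length(groups) == 1 && groups %in% names(meta)) {
    groups <- meta[[groups]]
  }
  groups <- as.factor(groups)
  if (length(groups) != nrow(pm)) {
    abort("`groups` must label every sample of the matrix.")
  }
  if (nlevels(droplevels(groups)) < 2) {
    abort("Need at least 2 groups.", class = "trflpr_design_error")
  }
  droplevels(groups)
}

#' Dufrene-Legendre indicator values of T-RFs
#'
#' For every T-RF and group, combines specificity (A: the group's share of
#' the T-RF's mean abundance) and fidelity (B: the fraction of the group's
#' samples containing the T-RF) into IndVal = 100 * A * B; each T-RF is
#' assigned the group maximizing its IndVal (ties broken by the first group
#' in level order and flagged).
#'
#' @param pm A `profile_matrix` (or numeric samples x T-RFs matrix).
#' @param groups Group labels: a vector over samples or the name of a
#'   metadata column (e.g. `"season"`).
#' @return Tibble: `trf`, `indicator_group`, `indval`, `tied`.
#' @export
indval <- function(pm, groups) {
  m <- if (inherits(pm, "profile_matrix")) pm_values(pm) else as.matrix(pm)
  groups <- if (inherits(pm, "profile_matrix")) resolve_groups(pm, groups)
            else droplevels(as.factor(groups))
  absent <- colSums(m) == 0
  if (any(absent)) {
    warn(sprintf("Excluding %d T-RF(s) absent from every sample.", sum(absent)))
    m <- m[, !absent, drop = FALSE]
  }
  iv <- indval_matrix(m, groups)
  best <- apply(iv, 2, which.max)
  tied <- apply(iv, 2, function(col) sum(col == max(col)) > 1)
  tibble::tibble(
    trf = colnames(m) %||% as.character(seq_len(ncol(m))),
    indicator_group = levels(groups)[best],
    indval = apply(iv, 2, max),
    tied = tied
  )
}

#' Indicator value analysis with a permutation test
#'
#' Tests each T-RF's maximal IndVal against the null distribution obtained
#' by randomly permuting group labels across samples; the same label
#' permutations are shared by all T-RFs within a run.
#' `p = (1 + #(IndVal_perm >= IndVal_obs)) / (1 + n_perm)`.
#'
#' @inheritParams indval
#' @param n_perm Number of label permutations (default 4999).
#' @param seed Optional integer seed.
#' @return The [indval()] tibble with `p_value`, plus attributes `n_perm`
#'   and `seed`.
#' @export
indval_test <- function(pm, groups, n_perm = 4999, seed = NULL) {
  if (n_perm < 1) abort("`n_perm` must be at least 1.",
                        class = "trflpr_parameter_error")
  m <- if (inherits(pm, "profile_matrix")) pm_values(pm) else as.matrix(pm)
  groups <- if (inherits(pm, "profile_matrix")) resolve_groups(pm, groups)
            else droplevels(as.factor(groups))
  obs <- indval(m, groups)
  keep <- colSums(m) > 0
  m <- m[, keep, drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  exceed <- rep(0L, ncol(m))
  obs_max <- obs$indval
  # shared label permutations, vectorized: IndVal_max = 100 * max_g(M*B) / tot
  gi <- as.integer(groups)
  k <- nlevels(groups)
  cnt <- tabulate(gi, k)
  comb <- cbind(m, (m > 0) + 0)
  tt <- ncol(m)
  n <- length(gi)
  for (b in seq_len(n_perm)) {
    rs <- rowsum(comb, gi[sample.int(n)]) / cnt
    E <- rs[, seq_len(tt), drop = FALSE] * rs[, tt + seq_len(tt), drop = FALSE]
    tot <- .colSums(rs[, seq_len(tt), drop = FALSE], k, tt)
    mx <- E[1, ]
    for (g in seq_len(k)[-1]) mx <- pmax(mx, E[g, ])
    exceed <- exceed + (100 * mx / tot >= obs_max - 1e-12)
  }
  obs$p_value <- (1 + exceed) / (1 + n_perm)
  attr(obs, "n_perm") <- n_perm
  attr(obs, "seed") <- seed
  obs
}

one_way_F <- function(values, groups) {
  n <- length(values)
  k <- nlevels(groups)
  gm <- tapply(values, groups, mean)
  cnt <- tapply(values, groups, length)
  ss_between <- sum(cnt * (gm - mean(values))^2)
  ss_within <- sum((values - gm[as.integer(groups)])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_within <= 1e-12 && ss_between <= 1e-12) {
    abort("ANOVA statistic undefined: no variation within or between groups.",
          class = "trflpr_degenerate_error")
  }
  (ss_between / df1) / (ss_within / df2)
}

two_sample_t <- function(values, g2) {
  # classical pooled-variance two-sample t
  n1 <- sum(g2 == levels(g2)[1]); n2 <- sum(g2 == levels(g2)[2])
  m1 <- mean(values[g2 == levels(g2)[1]])
  m2 <- mean(values[g2 == levels(g2)[2]])
  sp2 <- (sum((values[g2 == levels(g2)[1]] - m1)^2) +
            sum((values[g2 == levels(g2)[2]] - m2)^2)) / (n1 + n2 - 2)
  (m1 - m2) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

#' Univariate permutation ANOVA with pairwise comparisons
#'
#' Analyzes the per-sample abundances of a single T-RF: the overall
#' statistic is the classical one-way F, tested by permutation of group
#' labels; each level pair is additionally compared by a permutation test of
#' the pooled two-sample t statistic (two-sided). Raw permutation p-values
#' are reported (no multiplicity adjustment unless requested).
#'
#' @param values Numeric vector: one T-RF's abundance per sample.
#' @param groups Group labels (>= 2 groups with >= 2 samples each).
#' @param n_perm Number of permutations (default 4999).
#' @param seed Optional integer seed.
#' @param p_adjust Adjustment for the pairwise p-values (default `"none"`).
#' @return List of class `trflp_perm_anova`: `F_statistic`, `df`, `p_value`,
#'   and `pairwise` (tibble `level_1`, `level_2`, `t`, `p_value`).
#' @export
univariate_permutation_anova <- function(values, groups, n_perm = 4999,
                                         seed = NULL, p_adjust = "none") {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2 || any(table(groups) < 2)) {
    abort("Need >= 2 groups with >= 2 samples each.",
          class = "trflpr_design_error")
  }
  if (!is.null(seed)) set.seed(seed)
  F_obs <- one_way_F(values, groups)
  n <- length(values)
  perm_idx <- replicate(n_perm, sample.int(n))
  F_perm <- apply(perm_idx, 2, function(p) one_way_F(values[p], groups))
  p_overall <- (1 + sum(F_perm >= F_obs)) / (1 + n_perm)

  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    keep <- groups %in% pr
    v <- values[keep]
    g2 <- droplevels(groups[keep])
    t_obs <- two_sample_t(v, g2)
    m <- length(v)
    t_perm <- vapply(seq_len(n_perm), function(b) {
      two_sample_t(v[sample.int(m)], g2)
    }, 0)
    tibble::tibble(
      level_1 = pr[1], level_2 = pr[2], t = t_obs,
      p_value = (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
    )
  })
  pairwise$p_value <- stats::p.adjust(pairwise$p_value, method = p_adjust)
  structure(
    list(F_statistic = F_obs,
         df = c(nlevels(groups) - 1, n - nlevels(groups)),
         p_value = p_overall, pairwise = pairwise,
         n_perm = n_perm, seed = seed),
    class = "trflp_perm_anova"
  )
}

#' @export
print.trflp_perm_anova <- function(x, ...) {
  cat(sprintf("<trflp_perm_anova> F(%d, %d) = %.3f, permutation p = %.4g\n",
              x$df[1], x$df[2], x$F_statistic, x$p_value))
  print(x$pairwise)
  invisible(x)
}

#' @export
tidy.trflp_perm_anova <- function(x, ...) x$pairwise

#' @export
glance.trflp_perm_anova <- function(x, ...) {
  tibble::tibble(F_statistic = x$F_statistic, df1 = x$df[1], df2 = x$df[2],
                 p_value = x$p_value, n_perm = x$n_perm)
}

#' Indicator table: significant T-RFs with group means and pairwise tests
#'
#' The full responder workflow: indicator value analysis with a permutation
#' test; T-RFs significant at `alpha` are then analyzed by the univariate
#' permutation ANOVA with a posteriori pairwise comparisons. Per-group mean
#' relative abundances and standard deviations accompany each reported
#' T-RF.
#'
#' @inheritParams indval_test
#' @param alpha Significance cutoff for carrying a T-RF forward
#'   (default 0.05).
#' @return Tibble with one row per significant T-RF: `trf`,
#'   `indicator_group`, `indval`, `p_indval`, `mean_<group>`, `sd_<group>`
#'   columns, `p_anova`, and `p_<level1>_vs_<level2>` pairwise columns.
#' @export
indicator_table <- function(pm, groups, n_perm = 4999, seed = NULL,
                            alpha = 0.05) {
  m <- pm_values(pm)
  grp <- resolve_groups(pm, groups)
  iv <- indval_test(pm, groups, n_perm = n_perm, seed = seed)
  sig <- iv[iv$p_value <= alpha, , drop = FALSE]
  if (nrow(sig) == 0) {
    inform("No significant indicator T-RFs at the chosen alpha.")
    return(tibble::tibble())
  }
  purrr::map_dfr(sig$trf, function(tr) {
    v <- m[, tr]
    stats_wide <- purrr::map_dfc(levels(grp), function(l) {
      out <- tibble::tibble(mean(v[grp == l]), stats::sd(v[grp == l]))
      stats::setNames(out, paste0(c("mean_", "sd_"), l))
    })
    ua <- univariate_permutation_anova(v, grp, n_perm = n_perm)
    pw <- ua$pairwise
    pw_wide <- stats::setNames(
      as.list(pw$p_value),
      paste0("p_", pw$level_1, "_vs_", pw$level_2)
    )
    dplyr::bind_cols(
      sig[sig$trf == tr, c("trf", "indicator_group", "indval", "p_value")] |>
        dplyr::rename(p_indval = "p_value"),
      stats_wide,
      tibble::tibble(p_anova = ua$p_value),
      tibble::as_tibble(pw_wide)
    )
  })
}
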