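# Permutational multivariate analysis of variance on a distance matrix:
# sequential (Type I) partitioning via Gower-centered inner products and
# hat-matrix projections, permutation of raw sample units, pairwise
# comparisons, and a two-moment gamma asymptotic fallback.

gower_center <- function(D) {
  A <- -0.5 * D^2
  n <- nrow(A)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  tcrossprod(Q)
}

align_dist_meta <- function(d, data) {
  D <- as.matrix(stats::as.dist(d))
  lab <- rownames(D)
  if (!is.null(lab) && "sample_id" %in% names(data)) {
    idx <- match(lab, data$sample_id)
    if (anyNA(idx)) {
      abort("Distance labels missing from `data$sample_id`.",
            class = "trflpr_consistency_error")
    }
    data <- data[idx, , drop = FALSE]
  } else if (nrow(data) != nrow(D)) {
    abort("`data` rows must match the distance matrix.",
          class = "trflpr_consistency_error")
  }
  list(D = D, data = tibble::as_tibble(data))
}

#' PerMANOVA: permutational multivariate ANOVA on distances
#'
#' Partitions the total sum of squared interpoint distances among the terms
#' of `formula` (sequentially, in the order given; for the crossed seasonal
#' design use `~ season * treatment`). Pseudo-F for each term is the term
#' mean square over the residual mean square; p-values come from
#' unrestricted permutation of raw sample units (whole rows), with
#' `p = (1 + #(F_perm >= F_obs)) / (1 + n_perm)`.
#'
#' @param d A `dist` object or symmetric distance matrix.
#' @param data Sample metadata tibble; matched to the distance labels via a
#'   `sample_id` column when present, otherwise by row order.
#' @param formula Right-hand-side model formula over columns of `data`
#'   (default `~ season * treatment`).
#' @param n_perm Number of permutations (default 4999).
#' @param seed Optional integer seed for the permutations.
#' @return An object of class `trflp_permanova`: `table` (tibble with term,
#'   df, SS, pseudo-F, p), `n_perm`, `seed`, and `perm_F` (the permutation
#'   null statistics, terms x permutations).
#' @export
permanova <- function(d, data, formula = ~ season * treatment,
                      n_perm = 4999, seed = NULL) {
  al <- align_dist_meta(d, data)
  D <- al$D
  data <- al$data
  n <- nrow(D)
  G <- gower_center(D)
  ss_total <- sum(diag(G))
  if (ss_total <= 1e-12) {
    abort("All samples are identical: total sum of squares is zero.",
          class = "trflpr_degenerate_error")
  }

  trm <- stats::terms(formula)
  term_labels <- attr(trm, "term.labels")
  if (length(term_labels) == 0) abort("Formula has no terms.")
  for (v in all.vars(formula)) {
    if (!v %in% names(data)) abort(sprintf("No metadata column '%s'.", v))
    data[[v]] <- as.factor(data[[v]])
    if (nlevels(droplevels(data[[v]])) < 2) {
      abort(sprintf("Factor '%s' has fewer than 2 levels.", v),
            class = "trflpr_design_error")
    }
  }
  if (lfactorial(n) < log(20)) {
    warn("Fewer than 20 distinct permutations; consider asymptotic_p().")
  }

  # cumulative hat matrices for sequential (Type I) SS
  H_prev <- matrix(1 / n, n, n)
  df <- numeric(length(term_labels))
  Hd <- vector("list", length(term_labels))
  for (j in seq_along(term_labels)) {
    f <- stats::reformulate(term_labels[seq_len(j)])
    X <- stats::model.matrix(f, data = data)
    H <- hat_matrix(X)
    Hd[[j]] <- H - H_prev
    df[j] <- qr(X)$rank - qr(H_prev)$rank
    H_prev <- H
  }
  H_res <- diag(n) - H_prev
  df_res <- n - qr(H_prev)$rank
  if (df_res < 1) abort("No residual degrees of freedom.",
                        class = "trflpr_design_error")

  proj <- cbind(vapply(Hd, as.vector, numeric(n * n)), as.vector(H_res))
  ss_fun <- function(Gm) as.vector(crossprod(proj, as.vector(Gm)))
  ss_obs <- ss_fun(G)
  ss_terms <- ss_obs[seq_along(term_labels)]
  ss_res <- ss_obs[length(ss_obs)]
  F_obs <- (ss_terms / df) / (ss_res / df_res)

  if (n_perm < 0) abort("`n_perm` must be non-negative.")
  if (!is.null(seed)) set.seed(seed)
  perm_F <- matrix(NA_real_, length(term_labels), n_perm)
  for (b in seq_len(n_perm)) {
    p <- sample.int(n)
    ss_p <- ss_fun(G[p, p])
    perm_F[, b] <- (ss_p[seq_along(term_labels)] / df) /
      (ss_p[length(ss_p)] / df_res)
  }
  p_val <- if (n_perm > 0) {
    (1 + rowSums(perm_F >= F_obs)) / (1 + n_perm)
  } else {
    rep(NA_real_, length(term_labels))
  }

  tab <- tibble::tibble(
    term = c(term_labels, "residual", "total"),
    df = c(df, df_res, n - 1),
    SS = c(ss_terms, ss_res, ss_total),
    pseudo_F = c(F_obs, NA, NA),
    p_value = c(p_val, NA, NA)
  )
  rownames(perm_F) <- term_labels
  structure(list(table = tab, n_perm = n_perm, seed = seed, perm_F = perm_F),
            class = "trflp_permanova")
}

#' @export
print.trflp_permanova <- function(x, ...) {
  cat(sprintf("<trflp_permanova> %d permutations of raw data units\n", x$n_perm))
  print(x$table)
  invisible(x)
}

#' @export
tidy.trflp_permanova <- function(x, ...) x$table

#' @export
glance.trflp_permanova <- function(x, ...) {
  tibble::tibble(n_perm = x$n_perm,
                 n_terms = nrow(x$table) - 2,
                 ss_total = x$table$SS[x$table$term == "total"])
}

#' Pairwise PerMANOVA comparisons for one factor
#'
#' For each pair of factor levels, runs a one-way PerMANOVA restricted to
#' the samples of those levels and reports t = sqrt(pseudo-F) with its
#' permutation p-value (and optionally a Monte Carlo p from the gamma
#' asymptotic fallback, useful when few distinct permutations exist). No
#' multiplicity adjustment is applied by default.
#'
#' @inheritParams permanova
#' @param factor_name Metadata column to compare.
#' @param monte_carlo Also report the asymptotic (gamma-fit) p-value.
#' @param p_adjust Multiplicity adjustment method passed to
#'   [stats::p.adjust()] (default `"none"`).
#' @return Tibble: `level_1`, `level_2`, `t`, `df`, `p_value` (and `p_mc`).
#' @export
pairwise_permanova <- function(d, data, factor_name, n_perm = 4999,
                               seed = NULL, monte_carlo = FALSE,
                               p_adjust = "none") {
  al <- align_dist_meta(d, data)
  D <- al$D
  data <- al$data
  lev <- unique(as.character(data[[factor_name]]))
  if (length(lev) < 2) abort("Factor must have at least 2 levels.",
                             class = "trflpr_design_error")
  counts <- table(as.character(data[[factor_name]]))
  usable <- lev[counts[lev] >= 2]
  if (length(usable) < length(lev)) {
    warn(sprintf("Skipping level(s) with < 2 samples: %s",
                 paste(setdiff(lev, usable), collapse = ", ")))
  }
  if (!is.null(seed)) set.seed(seed)
  pairs <- utils::combn(usable, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    keep <- data[[factor_name]] %in% pr
    sub <- data[keep, , drop = FALSE]
    sub$grp <- factor(as.character(sub[[factor_name]]))
    fit <- permanova(D[keep, keep, drop = FALSE], sub, ~ grp,
                     n_perm = n_perm)
    row <- fit$table[1, ]
    res <- tibble::tibble(
      level_1 = pr[1], level_2 = pr[2],
      t = sqrt(row$pseudo_F), df = row$df, p_value = row$p_value
    )
    if (monte_carlo) {
      res$p_mc <- asymptotic_p(row$pseudo_F, fit$perm_F[1, ])
    }
    res
  })
  out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  out
}

#' Asymptotic p-value from a fitted permutation distribution
#'
#' When too few distinct permutations exist for a reasonable permutation
#' test, a two-moment gamma distribution is fitted to the available permuted
#' pseudo-F statistics and the upper-tail probability at the observed value
#' is reported. This is a documented stand-in for drawing Monte Carlo
#' samples from a theoretical asymptotic permutation distribution.
#'
#' @param F_obs Observed pseudo-F.
#' @param permuted_F Numeric vector of permuted pseudo-F values (>= 30).
#' @return The asymptotic p-value.
#' @export
asymptotic_p <- function(F_obs, permuted_F) {
  permuted_F <- permuted_F[is.finite(permuted_F)]
  if (length(permuted_F) < 30) {
    abort("Need at least 30 permuted statistics to fit moments.",
          class = "trflpr_parameter_error")
  }
  m <- mean(permuted_F)
  v <- stats::var(permuted_F)
  if (!is.finite(m) || !is.finite(v) || v <= 0) {
    abort("Degenerate permutation distribution: non-positive variance.",
          class = "trflpr_degenerate_error")
  }
  shape <- m^2 / v
  rate <- m / v
  stats::pgamma(F_obs, shape = shape, rate = rate, lower.tail = FALSE)
}
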