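# Non-metric multidimensional scaling (Kruskal stress formula 1) by
# majorization with isotonic disparities, plus the stress-gain rule for
# choosing the dimensionality and a Monte Carlo stress randomization test.

#' Euclidean distances between fingerprint profiles
#'
#' @param pm A `profile_matrix` (or numeric matrix) with at least 2 rows.
#' @return A `dist` object with sample labels.
#' @export
euclidean_distances <- function(pm) {
  m <- if (inherits(pm, "profile_matrix")) pm_values(pm) else as.matrix(pm)
  if (nrow(m) < 2) abort("Need at least two samples.")
  stats::dist(m)
}

lower_tri_vec <- function(M) M[lower.tri(M)]

# One majorized NMDS fit from a given start configuration. Disparities are
# fitted by isotonic regression of configuration distances on the
# dissimilarity order (primary tie approach: tied dissimilarities may get
# unequal disparities) and rescaled so sum(dhat^2) = sum(d^2); the
# configuration is updated by the Guttman transform. Raw stress-1 is
# tracked; iteration stops when its decrease over the last 10 iterations
# falls below `tol` or at `max_iter`.
nmds_engine <- function(D, X, max_iter = 500, tol = 1e-7) {
  n <- nrow(D)
  dvec <- lower_tri_vec(D)
  ord <- order(dvec)
  stress_hist <- rep(NA_real_, max_iter)
  stress <- Inf
  converged <- FALSE
  Dhat_full <- matrix(0, n, n)
  lower <- lower.tri(Dhat_full)

  for (it in seq_len(max_iter)) {
    CD <- as.matrix(stats::dist(X))
    cd <- lower_tri_vec(CD)
    ss_cd <- sum(cd^2)
    if (ss_cd == 0) { stress <- 0; converged <- TRUE; break }
    dhat <- numeric(length(cd))
    dhat[ord] <- stats::isoreg(cd[ord])$yf
    stress <- sqrt(sum((cd - dhat)^2) / ss_cd)
    stress_hist[it] <- stress
    if (stress < 1e-12) { converged <- TRUE; break }
    if (it > 10 && (stress_hist[it - 10] - stress) < tol) {
      converged <- TRUE
      break
    }
    # fixed disparity norm keeps the Guttman map from drifting in scale
    ss_dhat <- sum(dhat^2)
    if (ss_dhat == 0) break
    dhat <- dhat * sqrt(length(dhat) / ss_dhat)
    Dhat_full[lower] <- dhat
    Dhat_full <- Dhat_full + t(Dhat_full) - diag(diag(Dhat_full))
    B <- ifelse(CD > 0, -Dhat_full / CD, 0)
    diag(B) <- 0
    diag(B) <- -rowSums(B)
    X <- B %*% X / n
  }
  X <- sweep(X, 2, colMeans(X))
  list(points = X, stress = stress, iterations = it, converged = converged)
}

#' Non-metric multidimensional scaling
#'
#' Embeds samples in `k` dimensions so that the rank order of configuration
#' distances matches the rank order of the input dissimilarities, minimizing
#' Kruskal's stress formula 1 (reported multiplied by 100). The best of
#' `n_restarts` random starts plus one deterministic metric-scaling
#' (principal coordinates) start is returned; each fit runs at most
#' `max_iter` majorization iterations and stops early when stress decreases
#' by less than `stability_tol` over the last 10 iterations.
#'
#' @param d A `dist` object (e.g. from [euclidean_distances()]).
#' @param k Number of dimensions (must be < n samples - 1).
#' @param n_restarts Number of random starts (default 250).
#' @param max_iter Iteration cap per fit (default 500).
#' @param stability_tol Stress-stability stopping criterion (default 1e-7).
#' @param seed Optional integer seed for the random starts.
#' @param extra_starts Optional list of configuration matrices used as
#'   additional starts (used internally to warm-start higher dimensions).
#' @return An object of class `trflp_nmds`: `points` (centered n x k
#'   coordinates), `stress` (stress-1 x 100), `k`, `n_restarts`,
#'   `converged`, `iterations`, `seed`.
#' @export
nmds <- function(d, k = 2, n_restarts = 250, max_iter = 500,
                 stability_tol = 1e-7, seed = NULL, extra_starts = NULL) {
  D <- as.matrix(d)
  n <- nrow(D)
  if (k < 1) abort("`k` must be at least 1.")
  if (k >= n - 1) {
    abort("`k` must be smaller than the number of samples minus one.",
          class = "trflpr_parameter_error")
  }
  if (!is.null(seed)) set.seed(seed)

  starts <- list()
  pcoa <- suppressWarnings(stats::cmdscale(D, k = k))
  if (ncol(pcoa) < k) {
    pcoa <- cbind(pcoa, matrix(0, n, k - ncol(pcoa)))
  }
  starts[[1]] <- pcoa
  for (i in seq_len(n_restarts)) {
    X0 <- matrix(stats::runif(n * k, -1, 1), n, k)
    starts[[i + 1]] <- sweep(X0, 2, colMeans(X0))
  }
  starts <- c(starts, extra_starts)

  best <- NULL
  for (X0 in starts) {
    fit <- nmds_engine(D, X0, max_iter = max_iter, tol = stability_tol)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  rownames(best$points) <- rownames(D)
  colnames(best$points) <- paste0("axis", seq_len(k))
  # Shepard diagram data: dissimilarities, configuration distances, and the
  # monotone disparities of the final solution
  dvec <- lower_tri_vec(D)
  ord <- order(dvec)
  cd <- lower_tri_vec(as.matrix(stats::dist(best$points)))
  dhat <- numeric(length(cd))
  dhat[ord] <- stats::isoreg(cd[ord])$yf
  shepard <- tibble::tibble(dissimilarity = dvec[ord], distance = cd[ord],
                            disparity = dhat[ord])
  structure(
    list(points = best$points, stress = 100 * best$stress, k = k,
         n_restarts = n_restarts, converged = best$converged,
         iterations = best$iterations, seed = seed, shepard = shepard),
    class = "trflp_nmds"
  )
}

#' @export
print.trflp_nmds <- function(x, ...) {
  cat(sprintf("<trflp_nmds> %d samples, k = %d, stress = %.4g%s\n",
              nrow(x$points), x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
tidy.trflp_nmds <- function(x, ...) {
  tibble::as_tibble(x$points) |>
    dplyr::mutate(sample_id = rownames(x$points), .before = 1)
}

#' @export
glance.trflp_nmds <- function(x, ...) {
  tibble::tibble(stress = x$stress, k = x$k, n_restarts = x$n_restarts,
                 converged = x$converged, iterations = x$iterations)
}

#' @export
autoplot.trflp_nmds <- function(object, meta = NULL, colour = NULL,
                                shape = NULL, ...) {
  df <- tidy(object)
  if (object$k == 1) df$axis2 <- 0
  if (!is.null(meta)) df <- dplyr::left_join(df, meta, by = "sample_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$axis1, .data$axis2))
  pt_aes <- ggplot2::aes()
  if (!is.null(colour)) {
    pt_aes <- utils::modifyList(pt_aes, ggplot2::aes(colour = .data[[colour]]))
  }
  if (!is.null(shape)) {
    pt_aes <- utils::modifyList(pt_aes, ggplot2::aes(shape = .data[[shape]]))
  }
  p <- p + ggplot2::geom_point(pt_aes, size = 2)
  p + ggplot2::labs(
    x = "NMS axis 1", y = if (object$k > 1) "NMS axis 2" else NULL,
    colour = colour, shape = shape,
    caption = sprintf("Stress (Kruskal formula 1 x 100): %.2f", object$stress)
  ) + ggplot2::theme_minimal()
}

#' Choose the NMDS dimensionality by the stress-gain rule
#'
#' Fits NMDS for each dimensionality in `k_range` (each warm-started with
#' the previous solution padded by a zero axis, which makes the best stress
#' non-increasing in k) and selects the smallest k for which adding one more
#' dimension reduces the final stress by less than `stress_gain` (on the
#' x100 scale).
#'
#' @inheritParams nmds
#' @param k_range Candidate dimensionalities (default `1:6`).
#' @param stress_gain Minimum useful stress reduction (default 5).
#' @return A list of class `trflp_nmds_scan`: `k` (chosen), `stress`
#'   (tibble k/stress), `fits` (the per-k `trflp_nmds` objects).
#' @export
select_dimensionality <- function(d, k_range = 1:6, n_restarts = 250,
                                  max_iter = 500, stability_tol = 1e-7,
                                  stress_gain = 5, seed = NULL) {
  n <- attr(stats::as.dist(d), "Size")
  k_range <- sort(unique(k_range))
  k_range <- k_range[k_range >= 1 & k_range < n - 1]
  if (length(k_range) == 0) abort("No valid dimensionality in `k_range`.")
  if (!is.null(seed)) set.seed(seed)
  fits <- list()
  prev <- NULL
  for (k in k_range) {
    extra <- if (!is.null(prev)) {
      list(cbind(prev$points, matrix(0, nrow(prev$points), k - prev$k)))
    }
    fits[[as.character(k)]] <- nmds(
      d, k = k, n_restarts = n_restarts, max_iter = max_iter,
      stability_tol = stability_tol, extra_starts = extra
    )
    prev <- fits[[as.character(k)]]
  }
  stress <- vapply(fits, `[[`, 0, "stress")
  chosen <- k_range[length(k_range)]
  for (i in seq_len(length(k_range) - 1)) {
    if (stress[i] - stress[i + 1] < stress_gain) { chosen <- k_range[i]; break }
  }
  structure(
    list(k = chosen,
         stress = tibble::tibble(k = k_range, stress = unname(stress)),
         fits = fits),
    class = "trflp_nmds_scan"
  )
}

#' @export
print.trflp_nmds_scan <- function(x, ...) {
  cat(sprintf("<trflp_nmds_scan> chosen k = %d\n", x$k))
  print(x$stress)
  invisible(x)
}

#' @export
tidy.trflp_nmds_scan <- function(x, ...) x$stress

#' Monte Carlo randomization test of NMDS stress
#'
#' Tests whether the ordination extracts stronger structure than expected by
#' chance: each randomization independently permutes the values within every
#' T-RF column of the abundance matrix, the NMDS is refitted at the same
#' dimensionality, and the p-value is
#' `(1 + #(stress_random <= stress_real)) / (1 + n_randomizations)`.
#'
#' @param pm A `profile_matrix`.
#' @param k Dimensionality of the solutions compared.
#' @param n_randomizations Number of randomized datasets (default 50).
#' @param n_restarts Random starts per fit (default 20; the real and the
#'   randomized data get equal search effort).
#' @param seed Optional integer seed.
#' @return A list of class `trflp_mc_stress`: `p_value`, `stress_real`,
#'   `stress_random`, `n_randomizations`, `seed`.
#' @export
monte_carlo_stress_test <- function(pm, k = 2, n_randomizations = 50,
                                    n_restarts = 20, seed = NULL) {
  if (n_randomizations < 1) abort("`n_randomizations` must be at least 1.",
                                  class = "trflpr_parameter_error")
  if (!is.null(seed)) set.seed(seed)
  m <- pm_values(pm)
  real <- nmds(stats::dist(m), k = k, n_restarts = n_restarts)
  rand <- vapply(seq_len(n_randomizations), function(i) {
    mr <- apply(m, 2, sample)
    nmds(stats::dist(mr), k = k, n_restarts = n_restarts)$stress
  }, 0)
  structure(
    list(p_value = (1 + sum(rand <= real$stress)) / (1 + n_randomizations),
         stress_real = real$stress, stress_random = rand,
         n_randomizations = n_randomizations, seed = seed),
    class = "trflp_mc_stress"
  )
}

#' @export
print.trflp_mc_stress <- function(x, ...) {
  cat(sprintf(
    "<trflp_mc_stress> real stress %.3f vs %d randomizations; p = %.4f\n",
    x$stress_real, x$n_randomizations, x$p_value
  ))
  invisible(x)
}

#' Write ordination coordinates to delimited text
#'
#' @param fit A `trflp_nmds` object.
#' @param path Output path; the stress is recorded in a `#` header comment.
#' @export
write_ordination <- function(fit, path) {
  writeLines(sprintf("# stress_formula1_x100: %.6f (k = %d)", fit$stress, fit$k),
             path)
  readr::write_csv(tidy(fit), path, append = TRUE, col_names = TRUE)
  invisible(fit)
}
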