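# Fingerprint descriptors: Pareto-Lorenz evenness (PL20) and the
# moving-window rate of change (Delta_t) from a Pearson percent-change
# matrix.

as_abundances <- function(x) {
  if (inherits(x, "profile_matrix")) {
    if (nrow(x) != 1) abort("Supply a single profile (one-row matrix) or a vector.")
    v <- pm_values(x)[1, ]
  } else {
    v <- x
  }
  v <- v[is.finite(v) & v >= 0]
  if (sum(v > 0) == 0) abort("Profile has no positive abundances.",
                             class = "trflpr_empty_error")
  v
}

#' Pareto-Lorenz curve of a fingerprint profile
#'
#' Ranks the T-RFs of one profile from high to low abundance (ties broken by
#' ascending fragment size, for determinism) and accumulates both the
#' normalized number of bands (x) and their normalized abundances (y),
#' starting from (0, 0). The further the curve rises above the 45-degree
#' diagonal, the more the community is dominated by few T-RFs.
#'
#' When the profile comes from a binned community matrix, T-RFs of the
#' matrix that are absent from this sample (explicit zeros) still count as
#' bands: they rank last and extend the band axis without adding abundance,
#' so all samples of one matrix are scored on a common axis.
#'
#' @param x A one-row `profile_matrix` or a (optionally named by T-RF size)
#'   numeric vector of abundances; explicit zeros are kept as bands.
#' @return A tibble of class `pareto_lorenz` with columns `band_fraction`
#'   and `abundance_fraction`.
#' @examples
#' pareto_lorenz(c(`100` = 50, `200` = 30, `300` = 10, `400` = 5, `500` = 5))
#' @export
pareto_lorenz <- function(x) {
  v <- as_abundances(x)
  size <- suppressWarnings(as.numeric(names(v)))
  if (length(size) != length(v) || anyNA(size)) size <- seq_along(v)
  ord <- order(-v, size)
  v <- v[ord]
  out <- tibble::tibble(
    band_fraction = c(0, seq_along(v) / length(v)),
    abundance_fraction = unname(c(0, cumsum(v) / sum(v)))
  )
  class(out) <- c("pareto_lorenz", class(out))
  out
}

#' PL20: Lorenz-curve intercept at the 20% band line
#'
#' Linear interpolation of the Pareto-Lorenz curve at x = 0.20, reported on
#' the 0-100 scale. 20 indicates perfect evenness; values near 100 indicate
#' dominance by few T-RFs. A single-band profile is maximal dominance; under
#' the default step convention the curve is taken to jump to 1 at the first
#' band so PL20 = 100, while `single_band = "linear"` interpolates the
#' (0,0)-(1,1) segment and returns 20.
#'
#' @param x A `pareto_lorenz` curve, one-row `profile_matrix`, or abundance
#'   vector.
#' @param single_band Convention for one-band profiles: `"step"` (default)
#'   or `"linear"`.
#' @return PL20 in percent.
#' @export
pl20 <- function(x, single_band = c("step", "linear")) {
  single_band <- match.arg(single_band)
  curve <- if (inherits(x, "pareto_lorenz")) x else pareto_lorenz(x)
  n_bands <- nrow(curve) - 1
  if (n_bands == 1 && single_band == "step") return(100)
  100 * stats::approx(curve$band_fraction, curve$abundance_fraction,
                      xout = 0.2, ties = "ordered")$y
}

#' PL20 per sample of a profile matrix
#'
#' @param pm A `profile_matrix`.
#' @param single_band See [pl20()].
#' @return Tibble `sample_id`, `n_bands`, `pl20`, joined with the sample
#'   metadata.
#' @export
pl20_profiles <- function(pm, single_band = "step") {
  m <- pm_values(pm)
  out <- tibble::tibble(
    sample_id = rownames(m),
    n_bands = unname(apply(m, 1, function(r) sum(r > 0))),
    pl20 = unname(apply(m, 1, pl20, single_band = single_band))
  )
  dplyr::left_join(out, pm_meta(pm), by = "sample_id")
}

#' @export
autoplot.pareto_lorenz <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$band_fraction,
                                       .data$abundance_fraction)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_vline(xintercept = 0.2, linetype = "dotted") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::labs(x = "Cumulative fraction of T-RFs",
                  y = "Cumulative fraction of abundance") +
    ggplot2::theme_minimal()
}

#' Pearson percent-change matrix between profiles
#'
#' Similarity between two fingerprints is measured by the Pearson
#' product-moment correlation r of their abundance vectors over the union
#' of T-RF bins (absent T-RFs count as zero); dissimilarity is expressed as
#' the percent change 100 * (1 - r), ranging from 0 (identical shape) to
#' 200 (perfect anticorrelation).
#'
#' @param pm A `profile_matrix` with at least two samples.
#' @return Symmetric samples x samples matrix of percent change, zero
#'   diagonal.
#' @export
percent_change_matrix <- function(pm) {
  m <- pm_values(pm)
  if (nrow(m) < 2) abort("Need at least two samples.")
  rv <- apply(m, 1, stats::var)
  if (any(rv == 0)) {
    abort(sprintf("Zero-variance profile(s): %s",
                  paste(rownames(m)[rv == 0], collapse = ", ")),
          class = "trflpr_degenerate_error")
  }
  pc <- 100 * (1 - stats::cor(t(m)))
  pc[pc < 0] <- 0  # numerical guard at r = 1
  diag(pc) <- 0
  pc
}

#' Moving-window rate of change between consecutive groups
#'
#' For an ordered sequence of groups (typically harvests: spring, summer,
#' autumn), computes Delta_t for each consecutive pair as the mean and
#' standard deviation of the percent change over all cross-group sample
#' pairs, optionally stratified (e.g. within each treatment).
#'
#' @param pm A `profile_matrix` (pot-averaged profiles recommended).
#' @param ordering Character vector of group labels in temporal order.
#' @param group Metadata column holding the group labels (default
#'   `"season"`).
#' @param within Optional metadata column defining strata (e.g.
#'   `"treatment"`); `NULL` for none.
#' @return Tibble with columns `within` (if stratified), `from`, `to`,
#'   `mean_pct_change`, `sd_pct_change`, `n_pairs`.
#' @export
moving_window_delta <- function(pm, ordering, group = "season",
                                within = "treatment") {
  meta <- pm_meta(pm)
  if (!group %in% names(meta)) abort(sprintf("No metadata column '%s'.", group))
  labels <- as.character(meta[[group]])
  unknown <- setdiff(ordering, labels)
  if (length(unknown) > 0) {
    abort(sprintf("Ordering label(s) not present in metadata: %s",
                  paste(unknown, collapse = ", ")))
  }
  pc <- percent_change_matrix(pm)
  strata <- if (is.null(within)) {
    list(`all` = rep(TRUE, nrow(meta)))
  } else {
    lv <- unique(as.character(meta[[within]]))
    setNames(lapply(lv, function(l) meta[[within]] == l), lv)
  }
  out <- purrr::imap_dfr(strata, function(in_stratum, stratum_name) {
    purrr::map_dfr(seq_len(length(ordering) - 1), function(i) {
      a <- which(in_stratum & labels == ordering[i])
      b <- which(in_stratum & labels == ordering[i + 1])
      if (length(a) == 0 || length(b) == 0) {
        abort(sprintf("No samples for window %s -> %s in stratum %s.",
                      ordering[i], ordering[i + 1], stratum_name))
      }
      vals <- as.vector(pc[a, b, drop = FALSE])
      tibble::tibble(
        within = stratum_name, from = ordering[i], to = ordering[i + 1],
        mean_pct_change = mean(vals),
        sd_pct_change = if (length(vals) > 1) stats::sd(vals) else 0,
        n_pairs = length(vals)
      )
    })
  })
  if (is.null(within)) out$within <- NULL
  out
}

#' Replicate reproducibility as a coefficient of variation
#'
#' Measures the coefficient of variation of major peaks across the
#' extraction replicates of each pot. Per (pot, T-RF) the CV is the
#' within-pot standard deviation over the pot mean (for duplicates,
#' sd = |x1 - x2| / sqrt(2)); the overall figure pools these as a
#' root-mean-square, which (unlike averaging the raw CVs) is not biased
#' downward by the small replicate number.
#'
#' @param pm An extraction-level `profile_matrix` (before averaging).
#' @param major_threshold_pct Minimum pot-mean abundance (%) for a T-RF to
#'   count as a major peak (default 5).
#' @return Tibble `pot_id`, `trf`, `mean_abundance`, `cv_pct`; the pooled
#'   (root-mean-square) CV is attached as attribute `mean_cv`.
#' @export
replicate_cv <- function(pm, major_threshold_pct = 5) {
  meta <- pm_meta(pm)
  long <- tibble::as_tibble(pm) |>
    tidyr::pivot_longer(-"sample_id", names_to = "trf",
                        values_to = "abundance") |>
    dplyr::left_join(meta[c("sample_id", "pot_id")], by = "sample_id") |>
    dplyr::group_by(.data$pot_id, .data$trf) |>
    dplyr::summarise(
      mean_abundance = mean(.data$abundance),
      cv_pct = 100 * stats::sd(.data$abundance) / mean(.data$abundance),
      .groups = "drop"
    ) |>
    dplyr::filter(.data$mean_abundance >= major_threshold_pct)
  attr(long, "mean_cv") <- sqrt(mean(long$cv_pct^2, na.rm = TRUE))
  long
}
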