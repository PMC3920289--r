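# Peak-table ingestion and construction of the sample x T-RF analysis matrix.
#
# The working currency is a `profile_matrix`: a wide tibble whose first
# column is `sample_id` and whose remaining columns are binned T-RF sizes
# (bp, ascending), holding relative abundances that sum to 100 per row; the
# matching sample metadata travels along as an attribute.

REQUIRED_PEAK_COLS <- c("sample_id", "size", "height")
REQUIRED_META_COLS <- c("sample_id", "pot_id", "season", "treatment",
                        "extraction_replicate")

read_delim_auto <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "trflpr_io_error")
  }
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    progress = FALSE)
}

check_columns <- function(tbl, required, what) {
  missing <- setdiff(required, names(tbl))
  if (length(missing) > 0) {
    abort(sprintf("%s is missing required column(s): %s",
                  what, paste(missing, collapse = ", ")),
          class = "trflpr_format_error")
  }
  invisible(tbl)
}

#' Read a peak table and its sample metadata
#'
#' Reads fragment-analysis peak calls (one row per detected peak:
#' `sample_id`, `size` in bp, `height` in fluorescence units) and the sample
#' metadata table (`sample_id`, `pot_id`, `season`, `treatment`,
#' `extraction_replicate`) from delimiter-separated text (comma for `.csv`,
#' tab otherwise). Rows with non-positive size or height are rejected with a
#' warning; peaks from samples absent from the metadata are a consistency
#' error.
#'
#' @param path Peak table file.
#' @param meta_path Metadata file.
#' @return A list with tibbles `peaks` and `meta`.
#' @export
read_peak_table <- function(path, meta_path) {
  peaks <- check_columns(read_delim_auto(path), REQUIRED_PEAK_COLS, "Peak table")
  meta <- check_columns(read_delim_auto(meta_path), REQUIRED_META_COLS, "Metadata")
  validate_peaks(peaks, meta)
}

#' Validate peak and metadata tibbles
#'
#' The in-memory counterpart of [read_peak_table()]: drops non-positive
#' peaks with a warning and checks that every sampled profile has metadata.
#'
#' @param peaks Tibble with `sample_id`, `size`, `height`.
#' @param meta Tibble with `sample_id`, `pot_id`, `season`, `treatment`,
#'   `extraction_replicate`.
#' @return A list with validated `peaks` and `meta`.
#' @export
validate_peaks <- function(peaks, meta) {
  check_columns(peaks, REQUIRED_PEAK_COLS, "Peak table")
  check_columns(meta, REQUIRED_META_COLS, "Metadata")
  bad <- !is.finite(peaks$size) | !is.finite(peaks$height) |
    peaks$size <= 0 | peaks$height <= 0
  if (any(bad)) {
    warn(sprintf("Rejected %d peak row(s) with non-positive size or height.",
                 sum(bad)))
    peaks <- peaks[!bad, , drop = FALSE]
  }
  orphan <- setdiff(unique(peaks$sample_id), meta$sample_id)
  if (length(orphan) > 0) {
    abort(sprintf("Sample(s) present in peaks but not in metadata: %s",
                  paste(orphan, collapse = ", ")),
          class = "trflpr_consistency_error")
  }
  if (anyDuplicated(meta[c("pot_id", "extraction_replicate")]) > 0) {
    abort("Metadata rows must be unique in (pot_id, extraction_replicate).",
          class = "trflpr_consistency_error")
  }
  list(peaks = tibble::as_tibble(peaks), meta = tibble::as_tibble(meta))
}

#' Relativize peak heights and drop background peaks
#'
#' Within each sample, peak heights are expressed relative to the total
#' height of all detected peaks; peaks below `threshold_pct` of that total
#' are excluded and the survivors re-normalized to sum to 100.
#'
#' @param peaks Tibble with `sample_id`, `size`, `height`.
#' @param threshold_pct Exclusion threshold in percent of total peak height
#'   (default 0.5).
#' @return Tibble with `sample_id`, `size`, `abundance` (%, summing to 100
#'   per sample).
#' @export
relativize_and_filter <- function(peaks, threshold_pct = 0.5) {
  if (nrow(peaks) == 0) abort("No peaks supplied.", class = "trflpr_empty_error")
  if (threshold_pct < 0 || threshold_pct >= 100) {
    abort("`threshold_pct` must lie in [0, 100).")
  }
  out <- peaks |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(abundance = 100 * .data$height / sum(.data$height)) |>
    dplyr::filter(.data$abundance >= threshold_pct) |>
    dplyr::mutate(abundance = 100 * .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup() |>
    dplyr::select("sample_id", "size", "abundance")
  empty <- setdiff(unique(peaks$sample_id), unique(out$sample_id))
  if (length(empty) > 0) {
    abort(sprintf("All peaks below threshold for sample(s): %s",
                  paste(empty, collapse = ", ")),
          class = "trflpr_empty_error")
  }
  out
}

# Single-linkage 1-d clustering: a gap > tol between consecutive sorted
# sizes starts a new bin. Returns per-input bin ids (in size order).
single_linkage_bins <- function(sizes, tol) {
  ord <- order(sizes)
  s <- sizes[ord]
  new_bin <- c(TRUE, diff(s) > tol)
  ids <- cumsum(new_bin)
  out <- integer(length(sizes))
  out[ord] <- ids
  out
}

#' Bin fragment sizes across samples into common T-RFs
#'
#' Clusters all fragment sizes across samples by single linkage (a gap
#' larger than `bin_tolerance_bp` starts a new bin) so that sub-bp
#' size-calling jitter collapses into one T-RF per bin. Each bin is labeled
#' with the rounded mean of its member sizes; within a sample, peaks falling
#' into the same bin are summed, and rows are re-normalized to 100.
#'
#' @param profiles Tibble with `sample_id`, `size`, `abundance` (output of
#'   [relativize_and_filter()]).
#' @param meta Sample metadata tibble.
#' @param bin_tolerance_bp Single-linkage gap tolerance in bp (default 0.5).
#' @return A `profile_matrix`: wide tibble (`sample_id` + one column per
#'   binned T-RF, ascending) with metadata attached.
#' @export
bin_trfs <- function(profiles, meta, bin_tolerance_bp = 0.5) {
  if (nrow(profiles) == 0) abort("No profiles supplied.", class = "trflpr_empty_error")
  bins <- single_linkage_bins(profiles$size, bin_tolerance_bp)
  labels <- round(tapply(profiles$size, bins, mean))
  # rounding can collide labels of adjacent bins; merge those (sub-bp apart)
  profiles$trf <- as.integer(labels[as.character(bins)])
  wide <- profiles |>
    dplyr::group_by(.data$sample_id, .data$trf) |>
    dplyr::summarise(abundance = sum(.data$abundance), .groups = "drop") |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::mutate(abundance = 100 * .data$abundance / sum(.data$abundance)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$trf) |>
    tidyr::pivot_wider(names_from = "trf", values_from = "abundance",
                       values_fill = 0) |>
    dplyr::arrange(.data$sample_id)
  profile_matrix(wide, meta)
}

#' Construct a profile matrix
#'
#' @param wide Wide tibble: `sample_id` first, then numeric T-RF columns
#'   (names coercible to numbers, strictly increasing).
#' @param meta Metadata tibble covering every `sample_id`.
#' @return A `profile_matrix` object.
#' @export
profile_matrix <- function(wide, meta) {
  stopifnot(names(wide)[1] == "sample_id")
  trfs <- as.numeric(names(wide)[-1])
  if (anyNA(trfs)) abort("T-RF column names must be numeric sizes.")
  wide <- wide[, c(1L, 1L + order(trfs)), drop = FALSE]
  meta <- meta[match(wide$sample_id, meta$sample_id), , drop = FALSE]
  if (anyNA(meta$sample_id)) {
    abort("Every sample in the matrix needs a metadata row.",
          class = "trflpr_consistency_error")
  }
  structure(tibble::as_tibble(wide),
            meta = tibble::as_tibble(meta),
            class = c("profile_matrix", class(tibble::tibble())))
}

#' Extract the numeric abundance matrix of a profile matrix
#' @param pm A `profile_matrix`.
#' @return Numeric matrix, samples x T-RFs, with dimnames.
#' @export
pm_values <- function(pm) {
  m <- as.matrix(pm[, -1, drop = FALSE])
  rownames(m) <- pm$sample_id
  storage.mode(m) <- "double"
  m
}

#' Metadata of a profile matrix
#' @param pm A `profile_matrix`.
#' @return The sample metadata tibble, aligned with the matrix rows.
#' @export
pm_meta <- function(pm) attr(pm, "meta")

#' T-RF sizes of a profile matrix
#' @param pm A `profile_matrix`.
#' @return Numeric vector of binned T-RF sizes (bp).
#' @export
pm_trfs <- function(pm) as.numeric(names(pm)[-1])

#' @export
print.profile_matrix <- function(x, ...) {
  cat(sprintf("<profile_matrix> %d samples x %d T-RFs (%s..%s bp)\n",
              nrow(x), ncol(x) - 1,
              names(x)[2], names(x)[ncol(x)]))
  NextMethod()
}

#' Check profile-matrix invariants
#'
#' Asserts that rows sum to 100, no T-RF column is all zero, and column
#' labels are strictly increasing; errors otherwise.
#'
#' @param pm A `profile_matrix`.
#' @return `pm`, invisibly.
#' @export
validate_profile_matrix <- function(pm) {
  m <- pm_values(pm)
  if (any(abs(rowSums(m) - 100) > 1e-6)) {
    abort("Profile matrix rows must sum to 100.", class = "trflpr_invariant_error")
  }
  if (any(colSums(m) == 0)) {
    abort("Profile matrix must not contain all-zero T-RF columns.",
          class = "trflpr_invariant_error")
  }
  if (is.unsorted(pm_trfs(pm), strictly = TRUE)) {
    abort("T-RF columns must be strictly increasing.",
          class = "trflpr_invariant_error")
  }
  invisible(pm)
}

#' Average duplicate DNA extractions per pot
#'
#' Collapses extraction replicates of the same pot by the per-T-RF
#' arithmetic mean of relative abundances (a T-RF absent in one replicate
#' contributes zero there) and re-normalizes each pot profile to 100. The
#' resulting rows are labeled by `pot_id`.
#'
#' @param pm A `profile_matrix` of extraction-level samples.
#' @return A pot-level `profile_matrix`.
#' @export
average_replicates <- function(pm) {
  meta <- pm_meta(pm)
  m <- pm_values(pm)
  consistent <- meta |>
    dplyr::distinct(.data$pot_id, .data$season, .data$treatment)
  if (anyDuplicated(consistent$pot_id) > 0) {
    abort("Replicates of one pot disagree on season/treatment.",
          class = "trflpr_consistency_error")
  }
  pot <- as.character(meta$pot_id)
  avg <- rowsum(m, pot)
  avg <- avg / as.vector(table(pot)[rownames(avg)])
  avg <- 100 * avg / rowSums(avg)
  keep <- colSums(avg) > 0
  wide <- tibble::as_tibble(avg[, keep, drop = FALSE]) |>
    dplyr::mutate(sample_id = rownames(avg), .before = 1)
  pot_meta <- consistent |>
    dplyr::mutate(sample_id = .data$pot_id, .before = 1)
  profile_matrix(wide, pot_meta)
}

#' Run the full profile-processing pipeline
#'
#' Convenience wrapper: relativize and filter each sample at
#' `threshold_pct`, bin fragment sizes across samples, and (optionally)
#' average extraction replicates per pot.
#'
#' @param peaks,meta Peak and metadata tibbles (see [read_peak_table()]).
#' @param threshold_pct Background-exclusion threshold (% of total height).
#' @param bin_tolerance_bp Binning tolerance (bp).
#' @param average Average extraction replicates per pot (default `TRUE`).
#' @return A `profile_matrix`.
#' @export
process_peaks <- function(peaks, meta, threshold_pct = 0.5,
                          bin_tolerance_bp = 0.5, average = TRUE) {
  v <- validate_peaks(peaks, meta)
  prof <- relativize_and_filter(v$peaks, threshold_pct)
  pm <- bin_trfs(prof, v$meta, bin_tolerance_bp)
  if (average) pm <- average_replicates(pm)
  validate_profile_matrix(pm)
}

#' Write / read a profile matrix as delimited text
#'
#' Round-trips the wide sample x T-RF table (first column `sample_id`) and a
#' sibling metadata file.
#'
#' @param pm A `profile_matrix`.
#' @param path Output file for the matrix (`.csv` for comma-separated).
#' @param meta_path Optional output file for the metadata.
#' @return `pm` (write) / a `profile_matrix` (read).
#' @export
write_profile_matrix <- function(pm, path, meta_path = NULL) {
  readr::write_csv(tibble::as_tibble(pm), path)
  if (!is.null(meta_path)) readr::write_csv(pm_meta(pm), meta_path)
  invisible(pm)
}

#' @rdname write_profile_matrix
#' @export
read_profile_matrix <- function(path, meta_path) {
  wide <- read_delim_auto(path)
  meta <- read_delim_auto(meta_path)
  profile_matrix(wide, meta)
}
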