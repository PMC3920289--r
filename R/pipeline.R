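# End-to-end orchestration: ingest -> filter -> bin -> average ->
# descriptors -> ordination -> PerMANOVA (+ pairwise) -> indicator analysis
# (-> optional digest matching), with every parameter and seed recorded.

#' Assemble a pipeline configuration
#'
#' Defaults reproduce the analysis settings of the emulated study where
#' stated: 0.5% background threshold, 4999 permutations, 250 NMDS restarts
#' over 1-6 dimensions with a stress gain of 5. The remaining knobs
#' (binning tolerance, Monte Carlo randomizations, match tolerance) are
#' package defaults.
#'
#' @param peaks_path,meta_path Input peak table and metadata files.
#' @param out_dir Output directory.
#' @param threshold_pct Background-exclusion threshold (default 0.5).
#' @param bin_tolerance_bp Binning tolerance in bp (default 0.5).
#' @param n_perm Permutations for all permutation tests (default 4999).
#' @param nmds_restarts NMDS random starts per dimensionality (default 250).
#' @param k_range NMDS dimensionalities compared (default 1:6).
#' @param stress_gain Minimum useful stress reduction (default 5).
#' @param mc_randomizations Monte Carlo stress randomizations (default 50).
#' @param season_order Temporal ordering of the season labels.
#' @param fasta_path,primer,enzymes,match_tolerance_bp Optional digest
#'   stage: clone/isolate FASTA, labeled forward primer, enzyme set and
#'   observed-size match tolerance.
#' @param seed Integer seed governing every stochastic stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(peaks_path, meta_path, out_dir,
                       threshold_pct = 0.5, bin_tolerance_bp = 0.5,
                       n_perm = 4999, nmds_restarts = 250, k_range = 1:6,
                       stress_gain = 5, mc_randomizations = 50,
                       season_order = c("spring", "summer", "autumn"),
                       fasta_path = NULL, primer = NULL,
                       enzymes = c("MboI", "FauI"), match_tolerance_bp = 5,
                       seed = 1L) {
  cfg <- list(
    peaks_path = peaks_path, meta_path = meta_path, out_dir = out_dir,
    threshold_pct = threshold_pct, bin_tolerance_bp = bin_tolerance_bp,
    n_perm = n_perm, nmds_restarts = nmds_restarts, k_range = k_range,
    stress_gain = stress_gain, mc_randomizations = mc_randomizations,
    season_order = season_order, fasta_path = fasta_path, primer = primer,
    enzymes = enzymes, match_tolerance_bp = match_tolerance_bp,
    seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a pipeline configuration from a flat key-value file
#'
#' One `key = value` (or `key: value`) pair per line; `#` comments and blank
#' lines ignored. Multi-valued keys (`k_range`, `season_order`, `enzymes`)
#' take comma-separated values.
#'
#' @param path Configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config file not found: %s", path),
          class = "trflpr_config_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) {
    abort(sprintf("Malformed config line: '%s'", lines[bad][1]),
          class = "trflpr_config_error")
  }
  vals <- stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
  numeric_keys <- c("threshold_pct", "bin_tolerance_bp", "n_perm",
                    "nmds_restarts", "stress_gain", "mc_randomizations",
                    "match_tolerance_bp", "seed")
  multi_keys <- c("k_range", "season_order", "enzymes")
  args <- lapply(stats::setNames(names(vals), names(vals)), function(k) {
    v <- vals[[k]]
    if (k %in% numeric_keys) as.numeric(v)
    else if (k %in% multi_keys) {
      parts <- trimws(strsplit(v, ",")[[1]])
      if (k == "k_range") as.numeric(parts) else parts
    } else v
  })
  unknown <- setdiff(names(args), names(formals(run_config)))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")),
          class = "trflpr_config_error")
  }
  do.call(run_config, args)
}

validate_config <- function(config) {
  if (!inherits(config, "run_config")) {
    abort("Supply a run_config().", class = "trflpr_config_error")
  }
  for (p in c("peaks_path", "meta_path")) {
    if (is.null(config[[p]]) || !file.exists(config[[p]])) {
      abort(sprintf("Input file for '%s' is missing or unreadable.", p),
            class = "trflpr_config_error")
    }
  }
  if (!is.null(config$fasta_path) && !file.exists(config$fasta_path)) {
    abort("Configured FASTA file does not exist.",
          class = "trflpr_config_error")
  }
  invisible(config)
}

stage <- function(name, log) {
  log(sprintf("[%s] start", name))
  name
}

#' Run the full fingerprint analysis pipeline
#'
#' Executes every stage on the configured inputs and writes delimited
#' result tables plus a machine-readable JSON summary to
#' `config$out_dir`. All stochastic stages derive their seeds from
#' `config$seed`, so a fixed configuration reproduces byte-identical
#' outputs.
#'
#' @param config A [run_config()] or the path to a flat key-value config
#'   file.
#' @param quiet Suppress progress logging (default `FALSE`).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_config(config)
  log <- if (quiet) function(...) invisible() else function(msg) {
    message(sprintf("trflpr | %s", msg))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)

  stage("ingest", log)
  raw <- read_peak_table(config$peaks_path, config$meta_path)

  stage("process", log)
  pm_samples <- process_peaks(raw$peaks, raw$meta,
                              threshold_pct = config$threshold_pct,
                              bin_tolerance_bp = config$bin_tolerance_bp,
                              average = FALSE)
  pm <- average_replicates(pm_samples)
  validate_profile_matrix(pm)
  write_profile_matrix(pm, out("profile_matrix.csv"), out("profile_meta.csv"))

  stage("descriptors", log)
  pl <- pl20_profiles(pm)
  readr::write_csv(pl, out("pl20.csv"))
  seasons <- intersect(config$season_order, unique(pm_meta(pm)$season))
  delta <- moving_window_delta(pm, ordering = seasons,
                               group = "season", within = "treatment")
  readr::write_csv(delta, out("delta_t.csv"))

  stage("ordination", log)
  d <- euclidean_distances(pm)
  scan <- select_dimensionality(d, k_range = config$k_range,
                                n_restarts = config$nmds_restarts,
                                stress_gain = config$stress_gain,
                                seed = config$seed)
  fit <- scan$fits[[as.character(scan$k)]]
  write_ordination(fit, out("nmds_coordinates.csv"))
  readr::write_csv(scan$stress, out("nmds_stress_by_k.csv"))
  mc <- monte_carlo_stress_test(pm, k = scan$k,
                                n_randomizations = config$mc_randomizations,
                                seed = config$seed + 1L)

  stage("permanova", log)
  fit_pmv <- permanova(d, pm_meta(pm), ~ season * treatment,
                       n_perm = config$n_perm, seed = config$seed + 2L)
  readr::write_csv(tidy(fit_pmv), out("permanova.csv"))
  pw_season <- pairwise_permanova(d, pm_meta(pm), "season",
                                  n_perm = config$n_perm,
                                  seed = config$seed + 3L)
  readr::write_csv(pw_season, out("pairwise_season.csv"))

  stage("indval", log)
  ind <- indicator_table(pm, "season", n_perm = config$n_perm,
                         seed = config$seed + 4L)
  readr::write_csv(ind, out("indicator_table.csv"))

  digest_tbl <- NULL
  if (!is.null(config$fasta_path)) {
    stage("digest", log)
    preds <- predict_trfs(config$fasta_path, enzymes = config$enzymes,
                          primer = config$primer)
    digest_tbl <- match_trfs(pm_trfs(pm), preds,
                             tolerance_bp = config$match_tolerance_bp)
    readr::write_csv(digest_tbl, out("digest_matches.csv"))
  }

  stage("summary", log)
  summary <- list(
    parameters = unclass(config),
    n_samples = nrow(pm), n_trfs = length(pm_trfs(pm)),
    mean_pl20 = mean(pl$pl20),
    delta_t = delta,
    nmds = list(k = scan$k, stress = fit$stress,
                stress_by_k = scan$stress,
                monte_carlo_p = mc$p_value),
    permanova = tidy(fit_pmv),
    pairwise_season = pw_season,
    n_significant_indicators = nrow(ind)
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = 10, pretty = TRUE, force = TRUE)
  log("done")
  invisible(list(profile_matrix = pm, pl20 = pl, delta_t = delta,
                 nmds_scan = scan, nmds = fit, monte_carlo = mc,
                 permanova = fit_pmv, pairwise_season = pw_season,
                 indicators = ind, digest = digest_tbl, summary = summary))
}
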