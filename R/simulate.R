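# Synthetic data: a fingerprint-study generator emulating a two-treatment x
# three-season pot experiment with duplicate DNA extractions, and a
# sequence generator with planted restriction sites for digest tests.

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Specify a synthetic fingerprint study
#'
#' Describes the generative world of the emulated pot experiment: a crossed
#' treatment x season design with `pots_per_cell` independent pots per cell
#' and duplicate DNA extractions per pot; a community of `n_trfs` terminal
#' restriction fragments whose base composition is drawn once from a
#' Dirichlet distribution shaped by `dominance`; multiplicative log-normal
#' pot-to-pot and extraction noise (the latter calibrated to the target
#' replicate coefficient of variation on major peaks); sub-threshold
#' nuisance peaks; and optional planted seasonal/treatment effects.
#'
#' The default dominance preset places 6 dominant T-RFs (about 85% of the
#' community, shares echoing a strongly uneven actinobacterial profile) over
#' 33 minor T-RFs that hover around the 0.5% detection threshold, which
#' reproduces both a Pareto-Lorenz PL20 near 87 on pot-averaged profiles and
#' a cross-study union of about 39 retained T-RFs. The default planted
#' effects mirror the two responders of the emulated study: a dominant T-RF
#' (102 bp) nearly doubling from spring to summer (and staying elevated in
#' autumn), and a second dominant T-RF (579 bp) reduced under ozone in
#' summer only.
#'
#' @param n_treatments,n_seasons,pots_per_cell,extractions_per_pot Design
#'   dimensions (defaults 2, 3, 6, 2).
#' @param n_trfs Number of true T-RFs (default 39).
#' @param dominance Dirichlet concentration vector of length `n_trfs`
#'   (default: the calibrated dominance preset).
#' @param replicate_cv Target coefficient of variation (%) of major peak
#'   heights across extraction duplicates (default 6.5).
#' @param pot_cv Pot-to-pot compositional coefficient of variation (%)
#'   (default 15).
#' @param mid_trfs Number of mid-abundance minor T-RFs (default 10).
#' @param minor_level,minor_floor Community shares (%) of the largest and
#'   smallest mid-abundance minor T-RF; mid shares decay geometrically
#'   between them (defaults 2.0 and 0.9, calibrated together with the rare
#'   tier so the dominance preset yields pot-mean PL20 near 87).
#' @param rare_share Community share (%) of each rare T-RF (default 0.24:
#'   below the 0.5% threshold on average, surfacing only in occasional
#'   extractions, so the cross-study union still reaches ~39 T-RFs).
#' @param minor_noise_sd,rare_noise_sd Log-scale extraction noise of mid
#'   and rare minor peaks (defaults 0.3 and 0.5; peaks near the detection
#'   limit fluctuate far more than major peaks).
#' @param planted_effects List of [planted_effect()] entries;
#'   `list()` for a null study. Default: the two study-like responders.
#' @param noise_floor Expected number of spurious sub-threshold peaks per
#'   electropherogram (default 4).
#' @param total_signal Mean total fluorescence per sample (default 5e4).
#' @param size_jitter_sd Size-calling jitter of fragment sizes in bp
#'   (default 0.12).
#' @param seed Integer seed; fixing it makes [simulate_study()] fully
#'   reproducible.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_treatments = 2, n_seasons = 3, pots_per_cell = 6,
                         extractions_per_pot = 2, n_trfs = 39,
                         dominance = NULL, replicate_cv = 6.5, pot_cv = 12,
                         mid_trfs = 10, minor_level = 2.0, minor_floor = 0.9,
                         rare_share = 0.24, minor_noise_sd = 0.3,
                         rare_noise_sd = 0.5,
                         planted_effects = default_planted_effects(),
                         noise_floor = 4, total_signal = 5e4,
                         size_jitter_sd = 0.12, seed = 1L) {
  stopifnot(n_treatments >= 1, n_seasons >= 1, pots_per_cell >= 1,
            extractions_per_pot >= 1, n_trfs >= 1, replicate_cv >= 0,
            noise_floor >= 0)
  n_major <- min(6L, n_trfs)
  major_weights <- c(24, 20, 16, 12, 9, 6)[seq_len(n_major)]
  n_minor <- n_trfs - n_major
  # bimodal minor tail: mid-abundance T-RFs (geometric between minor_level
  # and minor_floor, reliably above the 0.5% detection threshold) and a set
  # of genuinely rare T-RFs that surface only in occasional extractions
  n_mid <- min(mid_trfs, n_minor)
  n_rare <- n_minor - n_mid
  minor_shares <- c(
    if (n_mid > 0) exp(seq(log(minor_level), log(minor_floor),
                           length.out = n_mid)),
    rep(rare_share, n_rare)
  )
  target <- c(major_weights / sum(major_weights) * (100 - sum(minor_shares)),
              minor_shares) / 100
  # high concentration: the preset IS the community, the Dirichlet draw
  # only perturbs it slightly (one fixed soil community per study)
  if (is.null(dominance)) dominance <- 5e4 * target
  if (length(dominance) != n_trfs) {
    abort("`dominance` must have one concentration per T-RF.",
          class = "trflpr_spec_error")
  }
  folds <- vapply(planted_effects, `[[`, 0, "fold")
  if (length(folds) > 0 && any(folds <= 0)) {
    abort("Planted folds must be positive.", class = "trflpr_spec_error")
  }
  treatments <- if (n_treatments <= 2) c("ambient", "ozone")[seq_len(n_treatments)]
                else paste0("treat", seq_len(n_treatments))
  seasons <- if (n_seasons <= 3) c("spring", "summer", "autumn")[seq_len(n_seasons)]
             else paste0("season", seq_len(n_seasons))
  structure(
    list(
      n_treatments = n_treatments, n_seasons = n_seasons,
      pots_per_cell = pots_per_cell, extractions_per_pot = extractions_per_pot,
      n_trfs = n_trfs, n_major = n_major, dominance = dominance,
      replicate_cv = replicate_cv, pot_cv = pot_cv,
      mid_trfs = mid_trfs, minor_level = minor_level,
      minor_floor = minor_floor, rare_share = rare_share,
      rare_noise_sd = rare_noise_sd, target_shares = target,
      minor_noise_sd = minor_noise_sd, planted_effects = planted_effects,
      noise_floor = noise_floor, total_signal = total_signal,
      size_jitter_sd = size_jitter_sd, treatments = treatments,
      seasons = seasons, seed = as.integer(seed)
    ),
    class = "study_design"
  )
}

#' Declare a planted (ground-truth) effect
#'
#' A multiplicative fold change applied to one T-RF's share of the
#' community in every design cell matching the given `season` and/or
#' `treatment` (a `NULL` field matches all levels), followed by
#' re-normalization of the cell composition.
#'
#' @param trf T-RF size (bp) the effect acts on (must exist in the design).
#' @param fold Multiplicative fold (> 0).
#' @param season,treatment Optional level restrictions.
#' @export
planted_effect <- function(trf, fold, season = NULL, treatment = NULL) {
  list(trf = trf, fold = fold, season = season, treatment = treatment)
}

#' @rdname planted_effect
#' @export
default_planted_effects <- function() {
  list(
    planted_effect(102, 1.82, season = "summer"),
    planted_effect(102, 1.47, season = "autumn"),
    planted_effect(579, 0.60, season = "summer", treatment = "ozone")
  )
}

MAJOR_TRF_SIZES <- c(162, 69, 579, 102, 380, 226)

#' Generate a synthetic fingerprint study
#'
#' Draws one study from the generative world of a [study_design()]: raw
#' peak tables (one electropherogram per extraction, with size-calling
#' jitter and sub-threshold nuisance peaks), the sample metadata, and the
#' ground truth (true compositions and planted effects) for recovery tests.
#' The output feeds directly into [process_peaks()].
#'
#' @param design A [study_design()].
#' @return List of class `trflp_study` with `peaks`, `meta` and `truth`.
#' @export
simulate_study <- function(design = study_design()) {
  stopifnot(inherits(design, "study_design"))
  set.seed(design$seed)
  n_major <- design$n_major
  n_minor <- design$n_trfs - n_major

  major_sizes <- MAJOR_TRF_SIZES[seq_len(n_major)]
  candidates <- seq(61, 599, by = 2)
  candidates <- candidates[!candidates %in% c(major_sizes - 1, major_sizes,
                                              major_sizes + 1)]
  if (n_minor > length(candidates)) {
    abort("Too many T-RFs for the available size range.",
          class = "trflpr_spec_error")
  }
  minor_sizes <- sort(sample(candidates, n_minor))
  trf_sizes <- c(major_sizes, minor_sizes)

  base <- rdirichlet1(design$dominance)
  sigma_major <- sqrt(log(1 + (design$replicate_cv / 100)^2))
  sigma_pot <- sqrt(log(1 + (design$pot_cv / 100)^2))
  n_mid <- min(design$mid_trfs, n_minor)
  sigma_trf <- c(rep(sigma_major, n_major),
                 rep(design$minor_noise_sd, n_mid),
                 rep(design$rare_noise_sd, n_minor - n_mid))

  cells <- expand.grid(treatment = design$treatments, season = design$seasons,
                       stringsAsFactors = FALSE)
  cell_comp <- lapply(seq_len(nrow(cells)), function(i) {
    comp <- base
    for (ef in design$planted_effects) {
      hit <- (is.null(ef$season) || ef$season == cells$season[i]) &&
        (is.null(ef$treatment) || ef$treatment == cells$treatment[i])
      if (hit) {
        idx <- match(ef$trf, trf_sizes)
        if (is.na(idx)) {
          abort(sprintf("Planted effect targets unknown T-RF %s.", ef$trf),
                class = "trflpr_spec_error")
        }
        comp[idx] <- comp[idx] * ef$fold
      }
    }
    comp / sum(comp)
  })

  id_acc <- list(); size_acc <- list(); height_acc <- list()
  meta <- list()
  row <- 0
  for (i in seq_len(nrow(cells))) {
    for (pot in seq_len(design$pots_per_cell)) {
      pot_id <- sprintf("%s_%s_p%02d", substr(cells$treatment[i], 1, 2),
                        substr(cells$season[i], 1, 2), pot)
      pot_comp <- cell_comp[[i]] * exp(stats::rnorm(design$n_trfs, 0, sigma_pot))
      pot_comp <- pot_comp / sum(pot_comp)
      for (ex in seq_len(design$extractions_per_pot)) {
        row <- row + 1
        sample_id <- sprintf("%s_e%d", pot_id, ex)
        heights <- pot_comp *
          exp(stats::rnorm(design$n_trfs, 0, sigma_trf)) *
          design$total_signal * exp(stats::rnorm(1, 0, 0.1))
        sizes <- trf_sizes + stats::rnorm(design$n_trfs, 0, design$size_jitter_sd)
        n_noise <- stats::rpois(1, design$noise_floor)
        if (n_noise > 0) {
          heights <- c(heights,
                       stats::runif(n_noise, 0.0005, 0.004) * sum(heights))
          sizes <- c(sizes, stats::runif(n_noise, 60, 600))
        }
        id_acc[[row]] <- rep(sample_id, length(sizes))
        size_acc[[row]] <- sizes
        height_acc[[row]] <- heights
        meta[[row]] <- list(
          sample_id = sample_id, pot_id = pot_id,
          season = cells$season[i], treatment = cells$treatment[i],
          extraction_replicate = ex
        )
      }
    }
  }
  structure(
    list(
      peaks = tibble::tibble(
        sample_id = unlist(id_acc, use.names = FALSE),
        size = unlist(size_acc, use.names = FALSE),
        height = unlist(height_acc, use.names = FALSE)
      ),
      meta = dplyr::bind_rows(meta),
      truth = list(
        design = design,
        trf_sizes = trf_sizes,
        is_major = c(rep(TRUE, n_major), rep(FALSE, n_minor)),
        base_composition = stats::setNames(base, trf_sizes),
        cell_compositions = stats::setNames(
          cell_comp, paste(cells$treatment, cells$season, sep = ".")
        ),
        planted_effects = design$planted_effects
      )
    ),
    class = "trflp_study"
  )
}

#' @export
print.trflp_study <- function(x, ...) {
  cat(sprintf("<trflp_study> %d peaks, %d samples, %d true T-RFs\n",
              nrow(x$peaks), nrow(x$meta), length(x$truth$trf_sizes)))
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the peak table and metadata in the formats [read_peak_table()]
#' reads, plus the ground truth as JSON.
#'
#' @param study A `trflp_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    peaks = file.path(dir, "peaks.csv"),
    meta = file.path(dir, "metadata.csv"),
    truth = file.path(dir, "truth.json")
  )
  readr::write_csv(study$peaks, paths["peaks"])
  readr::write_csv(study$meta, paths["meta"])
  truth <- study$truth
  truth$design <- unclass(truth$design)
  jsonlite::write_json(truth, paths["truth"], auto_unbox = TRUE, digits = 10,
                       force = TRUE)
  invisible(paths)
}

# ---- sequence fixtures with planted restriction sites ----------------------

random_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

instantiate_iupac <- function(x) {
  chars <- strsplit(x, "")[[1]]
  paste(vapply(chars, function(ch) {
    s <- IUPAC_SETS[[ch]]
    s[sample.int(length(s), 1)]
  }, ""), collapse = "")
}

#' Generate sequences with planted restriction sites
#'
#' Builds random background sequences that contain the given enzymes'
#' recognition sites exactly at the planted cut positions and nowhere else
#' (accidental sites are re-drawn until clean), optionally prepended with a
#' labeled forward primer. The returned truth table lists the expected
#' labeled terminal fragment per enzyme, for use as ground truth in digest
#' tests.
#'
#' @param n Number of sequences.
#' @param length_range Total sequence length range in bp (default
#'   `c(200, 1500)`).
#' @param enzymes Enzymes kept free of accidental sites (and available for
#'   planting).
#' @param planted_sites Tibble or data frame with columns `enzyme`,
#'   `position` (desired labeled-strand cut position, 0-based, in final
#'   coordinates) and optionally `strand` (`"top"` default, or `"bottom"`);
#'   applied to every sequence. `NULL` plants nothing.
#' @param primer Optional primer sequence prepended to every sequence
#'   (IUPAC codes instantiated randomly).
#' @param seed Optional integer seed.
#' @param max_fix_iter Resampling budget for removing accidental sites.
#' @return List of class `trflp_seqsim`: `sequences` (named character
#'   vector) and `truth` (tibble `sequence_id`, `enzyme`, `expected_trf`,
#'   `no_cut`).
#' @export
simulate_digest_sequences <- function(n, length_range = c(200, 1500),
                                      enzymes = c("MboI", "FauI"),
                                      planted_sites = NULL, primer = NULL,
                                      seed = NULL, max_fix_iter = 2000) {
  if (!is.null(seed)) set.seed(seed)
  enzymes <- resolve_enzymes(enzymes)
  primer_seq <- if (is.null(primer)) "" else {
    instantiate_iupac(normalize_nucleotides(primer, "primer"))
  }
  P <- nchar(primer_seq)
  planted <- if (is.null(planted_sites)) {
    tibble::tibble(enzyme = character(), position = integer(),
                   strand = character())
  } else {
    ps <- tibble::as_tibble(planted_sites)
    if (!"strand" %in% names(ps)) ps$strand <- "top"
    ps
  }

  seqs <- character(n)
  truths <- vector("list", n)
  for (s in seq_len(n)) {
    len <- length_range[1] +
      sample.int(length_range[2] - length_range[1] + 1, 1) - 1L
    if (len <= P + 10) abort("Sequence length too short for the primer.")
    chars <- c(strsplit(primer_seq, "")[[1]], random_bases(len - P))
    frozen <- rep(FALSE, len)
    if (P > 0) frozen[seq_len(P)] <- TRUE

    # write planted sites and freeze their bases
    for (j in seq_len(nrow(planted))) {
      enz <- resolve_enzymes(list(planted$enzyme[j]))[[1]]
      L <- nchar(enz$recognition)
      site <- instantiate_iupac(enz$recognition)
      if (planted$strand[j] == "bottom") {
        start0 <- planted$position[j] - L + enz$cut_offset_bottom
        site <- reverse_complement(site)
      } else {
        start0 <- planted$position[j] - enz$cut_offset_top
      }
      idx <- seq(start0 + 1, start0 + L)
      if (start0 < P || (start0 + L) > len) {
        abort("Planted site does not fit inside the sequence.",
              class = "trflpr_generation_error")
      }
      if (any(frozen[idx])) {
        abort("Planted sites overlap each other or the primer.",
              class = "trflpr_generation_error")
      }
      chars[idx] <- strsplit(site, "")[[1]]
      frozen[idx] <- TRUE
    }

    expected <- purrr::map_dfr(names(enzymes), function(nm) {
      pos <- planted$position[planted$enzyme == nm]
      tibble::tibble(
        sequence_id = sprintf("seq%03d", s), enzyme = nm,
        expected_trf = if (length(pos)) as.integer(min(pos)) else NA_integer_,
        no_cut = length(pos) == 0
      )
    })

    # remove accidental sites by redrawing their unfrozen bases
    planted_keys <- character(nrow(planted))
    for (j in seq_len(nrow(planted))) {
      enz <- resolve_enzymes(list(planted$enzyme[j]))[[1]]
      L <- nchar(enz$recognition)
      start0 <- if (planted$strand[j] == "bottom") {
        planted$position[j] - L + enz$cut_offset_bottom
      } else {
        planted$position[j] - enz$cut_offset_top
      }
      planted_keys[j] <- paste(planted$enzyme[j], start0, planted$strand[j])
    }
    for (iter in seq_len(max_fix_iter)) {
      sq <- paste(chars, collapse = "")
      accidental <- NULL
      for (nm in names(enzymes)) {
        enz <- enzymes[[nm]]
        L <- nchar(enz$recognition)
        tops <- match_sites(sq, enz$recognition) - 1L
        bots <- if (enz$palindromic) integer(0) else {
          match_sites(sq, reverse_complement(enz$recognition)) - 1L
        }
        for (st in tops) {
          if (!paste(nm, st, "top") %in% planted_keys &&
              !(enz$palindromic && paste(nm, st, "bottom") %in% planted_keys)) {
            accidental <- rbind(accidental, c(st, L))
          }
        }
        for (st in bots) {
          if (!paste(nm, st, "bottom") %in% planted_keys) {
            accidental <- rbind(accidental, c(st, L))
          }
        }
      }
      if (is.null(accidental)) break
      for (r in seq_len(nrow(accidental))) {
        idx <- seq(accidental[r, 1] + 1, accidental[r, 1] + accidental[r, 2])
        idx <- idx[!frozen[idx]]
        if (length(idx) == 0) {
          abort("Accidental site inside frozen bases cannot be removed.",
                class = "trflpr_generation_error")
        }
        chars[idx] <- random_bases(length(idx))
      }
      if (iter == max_fix_iter) {
        abort("Could not generate a clean background within the retry budget.",
              class = "trflpr_generation_error")
      }
    }
    seqs[s] <- paste(chars, collapse = "")
    truths[[s]] <- expected
  }
  names(seqs) <- sprintf("seq%03d", seq_len(n))
  structure(list(sequences = seqs, truth = dplyr::bind_rows(truths)),
            class = "trflp_seqsim")
}

#' Write sequences as wrapped FASTA
#'
#' @param sequences Named character vector.
#' @param path Output FASTA path.
#' @param width Line width (default 70).
#' @export
write_fasta <- function(sequences, path, width = 70) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}
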