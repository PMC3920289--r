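# In-silico restriction digestion of 5'-end-labeled amplicons.
#
# Coordinates: the labeled strand is the given (top) strand and position 0 is
# its 5' terminus. A cut position c means the phosphodiester bond between
# bases c-1 and c is cleaved, so c equals the length in nt of the labeled
# terminal fragment produced by that cut.

match_sites <- function(sequence, pattern) {
  subj <- Biostrings::DNAString(sequence)
  pat <- Biostrings::DNAString(pattern)
  if (length(subj) < length(pat)) return(integer(0))
  Biostrings::start(Biostrings::matchPattern(pat, subj, fixed = FALSE))
}

#' Find restriction cut positions on the labeled strand
#'
#' Scans both strands of `sequence` for the enzyme's recognition site
#' (IUPAC-aware: two codes match when their expansion sets intersect) and
#' maps every scission onto the labeled (given) strand. For a top-strand
#' site starting at 0-based position `s` the labeled-strand cut is
#' `s + cut_offset_top`; for a bottom-strand site (reverse complement of the
#' recognition found at `s`) it is `s + L - cut_offset_bottom`, with `L` the
#' recognition length. Cuts falling outside the molecule are discarded.
#'
#' @param sequence A nucleotide string (IUPAC codes allowed), 5'->3' on the
#'   labeled strand.
#' @param enzyme A [restriction_enzyme()] or built-in enzyme name.
#' @return Sorted integer vector of 0-based cut positions (each equal to the
#'   labeled fragment length it would produce).
#' @examples
#' find_cut_positions("AAAGATCAAA", "MboI")  # 3
#' @export
find_cut_positions <- function(sequence, enzyme) {
  enzyme <- resolve_enzymes(list(enzyme))[[1]]
  sequence <- normalize_nucleotides(sequence)
  n <- nchar(sequence)
  L <- nchar(enzyme$recognition)

  top <- match_sites(sequence, enzyme$recognition) - 1L
  cuts <- top + enzyme$cut_offset_top
  if (!enzyme$palindromic) {
    bottom <- match_sites(sequence, reverse_complement(enzyme$recognition)) - 1L
    cuts <- c(cuts, bottom + L - enzyme$cut_offset_bottom)
  }
  cuts <- cuts[cuts > 0L & cuts < n]
  sort(unique(as.integer(cuts)))
}

#' Predict the labeled terminal fragment of a digest
#'
#' For a single or combined (double) digest, the observed terminal
#' restriction fragment corresponds to the cut closest to the labeled 5'
#' end, i.e. the minimum cut position over all enzymes. A sequential double
#' digestion is equivalent to the combined digest for this purpose.
#'
#' @param sequence Labeled-strand nucleotide sequence.
#' @param enzymes One or more enzymes ([restriction_enzyme()] objects or
#'   built-in names), e.g. `c("MboI", "FauI")`.
#' @param sequence_id Optional identifier carried into the result.
#' @return One-row tibble: `sequence_id`, `enzymes` (comma-separated),
#'   `cutting_enzyme` (the enzyme producing the nearest cut, `NA` if none),
#'   `expected_trf` (fragment length in bp, `NA` when no enzyme cuts), and
#'   `no_cut` flag.
#' @export
terminal_fragment <- function(sequence, enzymes, sequence_id = NA_character_) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be a single non-empty string.",
          class = "trflpr_sequence_error")
  }
  enzymes <- resolve_enzymes(enzymes)
  cuts <- purrr::map(enzymes, ~ find_cut_positions(sequence, .x))
  firsts <- vapply(cuts, function(cc) if (length(cc)) min(cc) else NA_integer_, 1L)
  no_cut <- all(is.na(firsts))
  tibble::tibble(
    sequence_id = sequence_id,
    enzymes = paste(names(enzymes), collapse = ","),
    cutting_enzyme = if (no_cut) NA_character_ else names(which.min(firsts)),
    expected_trf = if (no_cut) NA_integer_ else as.integer(min(firsts, na.rm = TRUE)),
    no_cut = no_cut
  )
}

read_sequences <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x) && is.null(names(x))) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) == 0) {
      warn("FASTA file contains no sequences.")
      return(character(0))
    }
    out <- as.character(set)
    names(out) <- sub("\\s.*$", "", names(set))
    return(out)
  }
  if (!is.character(x)) abort("Supply a FASTA path or a character vector of sequences.")
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  x
}

anchor_at_primer <- function(sequence, primer) {
  hits <- match_sites(sequence, primer)
  if (length(hits) > 0) {
    return(list(sequence = substr(sequence, hits[1], nchar(sequence)),
                anchoring = "primer"))
  }
  rc <- reverse_complement(sequence)
  hits <- match_sites(rc, primer)
  if (length(hits) > 0) {
    return(list(sequence = substr(rc, hits[1], nchar(rc)),
                anchoring = "reverse_complement"))
  }
  list(sequence = sequence, anchoring = "assumed_start")
}

#' Predict terminal fragments for a set of sequences
#'
#' Reads amplicon or clone sequences (FASTA path or named character vector),
#' re-anchors each so that position 0 is the first base of the labeled
#' forward primer, and predicts the terminal restriction fragment of the
#' given digest. Primer matching is IUPAC-aware and inosine (`I`/`X`)
#' matches any base. When the primer is not found on the given strand the
#' reverse complement is tried (recorded as `"reverse_complement"`); when it
#' is found on neither, the sequence is assumed to start at the primer and
#' flagged `"assumed_start"`.
#'
#' @param x FASTA file path or (named) character vector of sequences.
#' @param enzymes Enzymes of the digest, as in [terminal_fragment()].
#' @param primer Labeled forward primer (optional). IUPAC and inosine codes
#'   allowed.
#' @return Tibble with one row per sequence: `sequence_id`, `anchoring`,
#'   `enzymes`, `cutting_enzyme`, `expected_trf`, `no_cut`.
#' @examples
#' predict_trfs(c(a = "AAAGATCAAAA"), enzymes = "MboI")
#' @export
predict_trfs <- function(x, enzymes, primer = NULL) {
  seqs <- read_sequences(x)
  if (length(seqs) == 0) {
    return(tibble::tibble(
      sequence_id = character(), anchoring = character(), enzymes = character(),
      cutting_enzyme = character(), expected_trf = integer(), no_cut = logical()
    ))
  }
  if (!is.null(primer)) primer <- normalize_nucleotides(primer, what = "primer")
  purrr::imap_dfr(seqs, function(s, id) {
    s <- normalize_nucleotides(s, what = id)
    anchoring <- "assumed_start"
    if (!is.null(primer)) {
      anc <- anchor_at_primer(s, primer)
      s <- anc$sequence
      anchoring <- anc$anchoring
    }
    res <- terminal_fragment(s, enzymes, sequence_id = id)
    dplyr::mutate(res, anchoring = anchoring, .after = "sequence_id")
  })
}

#' Match predicted to observed terminal fragment sizes
#'
#' Observed T-RF sizes from capillary electrophoresis drift systematically
#' from sequence-predicted sizes (typically a few bp short). Each prediction
#' is matched to the nearest observed size, either within a fixed window or
#' after a linear recalibration (`observed ~ a + b * expected` fitted on the
#' provisional fixed-window matches, then re-matched on residuals).
#'
#' @param observed Numeric vector of observed T-RF sizes (bp).
#' @param predictions Tibble from [predict_trfs()] (or any tibble with an
#'   `expected_trf` column).
#' @param mode `"fixed"` (default) or `"calibrated"`.
#' @param tolerance_bp Maximum |drift| for a match (default 5 bp).
#' @return `predictions` with columns `observed_trf`, `drift`
#'   (observed - expected, on the calibrated scale in calibrated mode) and
#'   `matched` appended.
#' @export
match_trfs <- function(observed, predictions, mode = c("fixed", "calibrated"),
                       tolerance_bp = 5) {
  mode <- match.arg(mode)
  if (length(observed) == 0 || nrow(predictions) == 0) {
    abort("Both observed sizes and predictions must be non-empty.")
  }
  observed <- sort(unique(observed))

  nearest <- function(expected, target = expected) {
    # match each prediction to the observed size nearest its target value
    purrr::map_dfr(seq_along(expected), function(i) {
      if (is.na(expected[i])) {
        return(tibble::tibble(observed_trf = NA_real_, drift = NA_real_, matched = FALSE))
      }
      dd <- abs(observed - target[i])
      j <- which.min(dd)
      if (dd[j] <= tolerance_bp) {
        tibble::tibble(observed_trf = observed[j],
                       drift = observed[j] - expected[i], matched = TRUE)
      } else {
        tibble::tibble(observed_trf = NA_real_, drift = NA_real_, matched = FALSE)
      }
    })
  }

  res <- nearest(predictions$expected_trf)
  if (mode == "calibrated") {
    # two passes: fit on the provisional matches, re-match on residuals,
    # then refit on the richer matched set
    for (pass in 1:2) {
      prov <- dplyr::bind_cols(predictions["expected_trf"], res)
      prov <- prov[prov$matched, , drop = FALSE]
      if (nrow(prov) < 2 || stats::sd(prov$expected_trf) == 0) {
        warn("Too few provisional matches to calibrate; fixed-window result returned.")
        break
      }
      fit <- stats::lm(observed_trf ~ expected_trf, data = prov)
      target <- as.numeric(stats::predict(fit,
        newdata = predictions["expected_trf"]))
      res <- nearest(predictions$expected_trf, target)
      res$drift <- res$observed_trf - target
      res$drift[!res$matched] <- NA_real_
    }
  }
  dplyr::bind_cols(predictions, res)
}
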