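# IUPAC nucleotide expansion sets; inosine (I/X in primer notation) matches
# any base and is normalised to N before matching.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S", W = "W",
  K = "M", M = "K", B = "V", D = "H", H = "D", V = "B", N = "N"
)

normalize_nucleotides <- function(x, what = "sequence") {
  x <- toupper(x)
  x <- gsub("U", "T", x, fixed = TRUE)
  # inosine: written I (or X in some primer notations), matches any base
  x <- gsub("[IX]", "N", x)
  chars <- strsplit(x, "")[[1]]
  bad <- which(!chars %in% names(IUPAC_SETS))
  if (length(bad) > 0) {
    abort(sprintf(
      "Invalid nucleotide code '%s' in %s at position %d.",
      chars[bad[1]], what, bad[1]
    ), class = "trflpr_sequence_error")
  }
  x
}

#' Reverse complement of a nucleotide sequence
#'
#' IUPAC-aware reverse complementation (vectorized over sequences).
#'
#' @param x Character vector of nucleotide sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement_seq <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    paste(rev(unname(IUPAC_COMPLEMENT[chars])), collapse = "")
  }, "", USE.NAMES = FALSE)
}

reverse_complement <- function(x) reverse_complement_seq(x)

#' Define a restriction enzyme
#'
#' Models a (possibly offset-cutting) type II restriction enzyme by its
#' recognition sequence and the positions of the two strand scissions,
#' both measured in nucleotides from the first base of the recognition
#' site on the strand that carries it.
#'
#' @param name Enzyme name, e.g. `"MboI"`.
#' @param recognition Recognition sequence, 5'->3', IUPAC codes allowed.
#' @param cut_offset_top Cut position on the recognition-carrying strand:
#'   the enzyme cleaves immediately 5' of the base at
#'   `recognition_start + cut_offset_top` (0-based). `0` means a cut right
#'   before the site (as for MboI, ^GATC); values beyond the recognition
#'   length describe downstream offset cutters (FauI, CCCGC(4/6)).
#' @param cut_offset_bottom The analogous offset on the complementary
#'   strand, measured from the base pairing with the recognition start.
#'
#' @return An object of class `trflp_enzyme`.
#' @examples
#' restriction_enzyme("MboI", "GATC", 0, 4)
#' @export
restriction_enzyme <- function(name, recognition, cut_offset_top, cut_offset_bottom) {
  recognition <- normalize_nucleotides(recognition, what = paste0(name, " recognition"))
  if (nchar(recognition) < 4) {
    abort("Recognition sequence must be at least 4 nt long.",
          class = "trflpr_enzyme_error")
  }
  stopifnot(is.finite(cut_offset_top), is.finite(cut_offset_bottom))
  structure(
    list(
      name = name,
      recognition = recognition,
      cut_offset_top = as.integer(cut_offset_top),
      cut_offset_bottom = as.integer(cut_offset_bottom),
      palindromic = identical(recognition, reverse_complement(recognition))
    ),
    class = "trflp_enzyme"
  )
}

#' @export
print.trflp_enzyme <- function(x, ...) {
  cat(sprintf(
    "<trflp_enzyme> %s  %s (%d/%d)%s\n",
    x$name, x$recognition, x$cut_offset_top, x$cut_offset_bottom,
    if (x$palindromic) "  [palindromic]" else ""
  ))
  invisible(x)
}

#' Built-in enzymes used for actinobacterial T-RFLP assays
#'
#' Standard catalogue definitions for the three enzymes of the two assays:
#' MboI (^GATC) and FauI (CCCGC(4/6)) for the 16S rRNA gene double digest,
#' and HhaI (GCG^C) for the PKS type II digest.
#'
#' @return A named list of [restriction_enzyme()] objects.
#' @export
trflp_enzymes <- function() {
  list(
    MboI = restriction_enzyme("MboI", "GATC", 0L, 4L),
    FauI = restriction_enzyme("FauI", "CCCGC", 9L, 11L),
    HhaI = restriction_enzyme("HhaI", "GCGC", 3L, 1L)
  )
}

resolve_enzymes <- function(enzymes) {
  if (inherits(enzymes, "trflp_enzyme")) enzymes <- list(enzymes)
  builtin <- trflp_enzymes()
  out <- lapply(enzymes, function(e) {
    if (inherits(e, "trflp_enzyme")) return(e)
    if (is.character(e) && length(e) == 1) {
      if (!e %in% names(builtin)) {
        abort(sprintf("Unknown enzyme '%s'; supply a restriction_enzyme().", e),
              class = "trflpr_enzyme_error")
      }
      return(builtin[[e]])
    }
    abort("Enzymes must be trflp_enzyme objects or built-in names.",
          class = "trflpr_enzyme_error")
  })
  names(out) <- vapply(out, `[[`, "", "name")
  out
}
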