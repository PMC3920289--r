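# Shared fixtures and independent oracles.

# Minimal profile_matrix from a plain abundance matrix.
make_pm <- function(mat, season = NULL, treatment = NULL, pot_id = NULL) {
  n <- nrow(mat)
  ids <- rownames(mat) %||% paste0("s", seq_len(n))
  rownames(mat) <- ids
  if (is.null(colnames(mat))) colnames(mat) <- seq_len(ncol(mat)) * 100
  wide <- tibble::as_tibble(mat)
  wide <- dplyr::mutate(wide, sample_id = ids, .before = 1)
  meta <- tibble::tibble(
    sample_id = ids,
    pot_id = pot_id %||% ids,
    season = season %||% rep("spring", n),
    treatment = treatment %||% rep("ambient", n),
    extraction_replicate = 1L
  )
  profile_matrix(wide, meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- independent restriction-scan oracle -----------------------------------
# Literal per-position, per-strand scanner with its own IUPAC machinery,
# sharing no code with the package's Biostrings-based matcher.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)
ORACLE_COMP <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R",
                 S = "S", W = "W", K = "M", M = "K", B = "V", D = "H",
                 H = "D", V = "B", N = "N")

# IUPAC compatibility lookup: codes match when their expansion sets share
# a base.
ORACLE_COMPAT <- outer(names(ORACLE_IUPAC), names(ORACLE_IUPAC),
                       Vectorize(function(a, b) {
                         length(intersect(ORACLE_IUPAC[[a]],
                                          ORACLE_IUPAC[[b]])) > 0
                       }))
dimnames(ORACLE_COMPAT) <- list(names(ORACLE_IUPAC), names(ORACLE_IUPAC))

# Exhaustive scan: tests the recognition (and its reverse complement, for
# bottom-strand sites) against every position of the sequence.
oracle_match_starts <- function(chars, site_chars) {
  n <- length(chars)
  L <- length(site_chars)
  if (n < L) return(integer(0))
  ok <- rep(TRUE, n - L + 1)
  for (k in seq_len(L)) {
    ok <- ok & ORACLE_COMPAT[cbind(chars[seq_len(n - L + 1) + k - 1],
                                   site_chars[k])]
  }
  which(ok)
}

# All labeled-strand cut positions (0-based) of `enzyme` in `sequence`,
# by exhaustive per-position, per-strand scan.
oracle_cuts <- function(sequence, enzyme) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  rec <- strsplit(enzyme$recognition, "")[[1]]
  L <- length(rec)
  rec_rc <- rev(unname(ORACLE_COMP[rec]))
  cuts <- c(
    (oracle_match_starts(chars, rec) - 1) + enzyme$cut_offset_top,
    (oracle_match_starts(chars, rec_rc) - 1) + L - enzyme$cut_offset_bottom
  )
  sort(unique(as.integer(cuts[cuts > 0 & cuts < n])))
}

random_dna <- function(n, ambiguity = 0) {
  base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (ambiguity > 0) {
    idx <- which(stats::runif(n) < ambiguity)
    base[idx] <- sample(c("R", "Y", "S", "W", "N"), length(idx), replace = TRUE)
  }
  paste(base, collapse = "")
}

# Small default study variants used across tests
quick_design <- function(seed, planted = list()) {
  study_design(seed = seed, planted_effects = planted,
               pots_per_cell = 3)
}
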