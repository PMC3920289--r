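test_that("cut positions honor each enzyme's offsets on both strands", {
  # MboI cuts immediately before its GATC site
  expect_equal(find_cut_positions("AAAGATCAAA", "MboI"), 3)
  # HhaI: GCG^C
  expect_equal(find_cut_positions("TTGCGCTT", "HhaI"), 5)
  # FauI: CCCGC(4/6), top-strand cut 4 nt past the recognition end
  expect_equal(find_cut_positions("AACCCGCAAAAAA", "FauI"), 11)
  # FauI site on the bottom strand: GCGGG on the given strand, cut 6 nt
  # upstream of the match under the bottom-strand offset
  seqb <- paste0(strrep("A", 20), "GCGGG", strrep("A", 10))
  expect_equal(find_cut_positions(seqb, "FauI"), 20 - 6)

  # cuts falling outside the molecule are dropped
  expect_equal(find_cut_positions("CCCGCAA", "FauI"), integer(0))
  expect_error(find_cut_positions("ACGZT", "MboI"),
               class = "trflpr_sequence_error")
})

test_that("site finding matches the exhaustive per-position scanner", {
  set.seed(14)
  enzymes <- trflp_enzymes()
  for (i in 1:40) {
    s <- random_dna(sample(200:800, 1),
                    ambiguity = sample(c(0, 0.01), 1))
    for (e in enzymes) {
      expect_identical(find_cut_positions(s, e), oracle_cuts(s, e))
    }
  }
})

test_that("reverse complementation mirrors palindromic cut positions", {
  set.seed(15)
  enz <- trflp_enzymes()
  for (e in c("MboI", "HhaI")) {
    s <- random_dna(500)
    cuts <- find_cut_positions(s, e)
    cuts_rc <- find_cut_positions(reverse_complement_seq(s), e)
    # a site starting at s maps to 500 - s - L; its cut follows the offset
    L <- nchar(enz[[e]]$recognition)
    off <- enz[[e]]$cut_offset_top
    expect_identical(cuts_rc,
                     sort(as.integer(500L - rev(cuts) - L + 2L * off)))
  }
})

test_that("terminal fragments take the cut nearest the labeled end", {
  sim <- simulate_digest_sequences(
    1, length_range = c(700, 700),
    planted_sites = data.frame(enzyme = c("MboI", "FauI"),
                               position = c(149, 471)),
    seed = 3
  )
  tf <- terminal_fragment(sim$sequences[[1]], c("MboI", "FauI"))
  expect_equal(tf$expected_trf, 149)
  expect_equal(tf$cutting_enzyme, "MboI")

  # no site for either enzyme: the no-cut sentinel
  sim0 <- simulate_digest_sequences(1, length_range = c(300, 300), seed = 4)
  tf0 <- terminal_fragment(sim0$sequences[[1]], c("MboI", "FauI"))
  expect_true(tf0$no_cut)
  expect_true(is.na(tf0$expected_trf))

  # single digest equals double digest when the second enzyme has no site
  simM <- simulate_digest_sequences(
    1, length_range = c(400, 400),
    planted_sites = data.frame(enzyme = "MboI", position = 220), seed = 5
  )
  one <- terminal_fragment(simM$sequences[[1]], "MboI")
  two <- terminal_fragment(simM$sequences[[1]], c("MboI", "FauI"))
  expect_equal(one$expected_trf, two$expected_trf)

  expect_error(terminal_fragment("", "MboI"), class = "trflpr_sequence_error")
})

test_that("double-digest terminal fragments equal the min of single digests", {
  set.seed(16)
  for (i in 1:25) {
    s <- random_dna(sample(300:900, 1))
    singles <- vapply(c("MboI", "FauI"), function(e) {
      terminal_fragment(s, e)$expected_trf
    }, 1L)
    both <- terminal_fragment(s, c("MboI", "FauI"))$expected_trf
    expect_equal(both,
                 if (all(is.na(singles))) NA_integer_
                 else as.integer(min(singles, na.rm = TRUE)))
  }
})

test_that("FASTA prediction anchors at the labeled primer", {
  primer <- "CGCGGCCTATCAGCTTGTTG"
  sim <- simulate_digest_sequences(
    3, length_range = c(500, 600),
    planted_sites = data.frame(enzyme = "MboI", position = 149),
    primer = primer, seed = 6
  )
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$sequences, f)
  preds <- predict_trfs(f, enzymes = c("MboI", "FauI"), primer = primer)
  expect_equal(nrow(preds), 3)
  expect_true(all(preds$anchoring == "primer"))
  expect_true(all(preds$expected_trf == 149))

  # leading vector bases upstream of the primer are trimmed by re-anchoring
  shifted <- stats::setNames(paste0("TTTTTTT", sim$sequences), names(sim$sequences))
  p2 <- predict_trfs(shifted, enzymes = "MboI", primer = primer)
  expect_true(all(p2$expected_trf == 149))

  # a sequence deposited in reverse orientation is flipped and flagged
  rc <- stats::setNames(reverse_complement_seq(sim$sequences[[1]]), "rc1")
  p3 <- predict_trfs(rc, enzymes = "MboI", primer = primer)
  expect_equal(p3$anchoring, "reverse_complement")
  expect_equal(p3$expected_trf, 149L)

  # primer absent: assume the sequence starts at the primer, flagged
  p4 <- predict_trfs(c(x = "AAAAGATCAAAAAA"), enzymes = "MboI",
                     primer = primer)
  expect_equal(p4$anchoring, "assumed_start")
  expect_equal(p4$expected_trf, 4L)
})

test_that("predictions are invariant to case and FASTA line wrapping", {
  sim <- simulate_digest_sequences(
    2, length_range = c(400, 450),
    planted_sites = data.frame(enzyme = "FauI", position = 230), seed = 7
  )
  p_ref <- predict_trfs(sim$sequences, enzymes = c("MboI", "FauI"))
  p_low <- predict_trfs(stats::setNames(tolower(sim$sequences),
                                        names(sim$sequences)),
                        enzymes = c("MboI", "FauI"))
  expect_equal(p_low$expected_trf, p_ref$expected_trf)

  f10 <- withr::local_tempfile(fileext = ".fa")
  f_nowrap <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$sequences, f10, width = 10)
  write_fasta(sim$sequences, f_nowrap, width = 1e6)
  expect_equal(predict_trfs(f10, enzymes = "FauI")$expected_trf,
               predict_trfs(f_nowrap, enzymes = "FauI")$expected_trf)
})

test_that("observed sizes match predictions within drift tolerance", {
  preds <- tibble::tibble(
    sequence_id = c("A15", "A39", "far"),
    expected_trf = c(106L, 596L, 106L)
  )
  # capillary sizes run a few bp short of sequence-predicted sizes
  m <- match_trfs(c(102, 596), preds[1:2, ], tolerance_bp = 5)
  expect_equal(m$observed_trf, c(102, 596))
  expect_equal(m$drift, c(-4, 0))
  expect_true(all(m$matched))

  m2 <- match_trfs(500, preds[3, ], tolerance_bp = 5)
  expect_false(m2$matched)
  expect_true(is.na(m2$observed_trf))

  # linear calibration recovers a systematic shrinkage
  expected <- c(106, 154, 230, 375, 476, 596)
  observed <- round(expected * 0.985 - 2.5)
  predc <- tibble::tibble(sequence_id = letters[1:6],
                          expected_trf = as.integer(expected))
  mc <- match_trfs(observed, predc, mode = "calibrated", tolerance_bp = 5)
  expect_true(all(mc$matched))
  expect_lt(max(abs(mc$drift)), 1.5)
})

test_that("sequence generation plants sites exactly where requested", {
  sim <- simulate_digest_sequences(
    4, length_range = c(300, 500),
    planted_sites = data.frame(enzyme = c("MboI", "FauI"),
                               position = c(149, 260)),
    seed = 8
  )
  for (s in sim$sequences) {
    expect_identical(find_cut_positions(s, "MboI"), 149L)
    expect_identical(find_cut_positions(s, "FauI"), 260L)
  }
  # bottom-strand planting honors the bottom offset (checked by the oracle)
  simb <- simulate_digest_sequences(
    2, length_range = c(400, 400),
    planted_sites = data.frame(enzyme = "FauI", position = 200,
                               strand = "bottom"),
    seed = 9
  )
  for (s in simb$sequences) {
    expect_identical(oracle_cuts(s, trflp_enzymes()$FauI), 200L)
  }
  # byte-identical reproduction under a fixed seed
  a <- simulate_digest_sequences(2, length_range = c(250, 300), seed = 10)
  b <- simulate_digest_sequences(2, length_range = c(250, 300), seed = 10)
  expect_identical(a$sequences, b$sequences)
})
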