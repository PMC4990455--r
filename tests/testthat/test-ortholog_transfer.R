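params <- alignment_params()

test_that("self-alignment is gapless with the diagonal score", {
  al <- global_align("PAWHEAE", "PAWHEAE", params)
  expect_equal(al$aligned_a, "PAWHEAE")
  expect_equal(al$aligned_b, "PAWHEAE")
  expect_equal(al$score, 44)  # 7+4+11+8+5+4+5 on the BLOSUM62 diagonal
  set.seed(5)
  for (i in 1:5) {
    s <- random_sequence(sample(10:40, 1))
    al <- global_align(s, s, params)
    expect_false(grepl("-", al$aligned_a))
    expect_equal(al$score,
                 sum(diag(params$matrix)[match(strsplit(s, "")[[1]],
                                               rownames(params$matrix))]))
  }
})

test_that("affine gap costs follow the open + (k-1) * extend model", {
  al <- global_align("AW", "W", params)
  expect_equal(al$score, 1)  # -10 gap + W:W 11
  expect_equal(al$aligned_a, "AW")
  expect_equal(al$aligned_b, "-W")
  al2 <- global_align("ACD", "", params)
  expect_equal(al2$score, -11)  # -10 - 2 * 0.5
  expect_equal(al2$aligned_b, "---")
})

test_that("alignment invariants hold: equal lengths, gap removal, no double gaps", {
  set.seed(21)
  for (i in 1:20) {
    a <- random_sequence(sample(5:30, 1))
    b <- random_sequence(sample(5:30, 1))
    al <- global_align(a, b, params)
    expect_equal(nchar(al$aligned_a), nchar(al$aligned_b))
    expect_equal(gsub("-", "", al$aligned_a), a)
    expect_equal(gsub("-", "", al$aligned_b), b)
    cols <- paste0(strsplit(al$aligned_a, "")[[1]],
                   strsplit(al$aligned_b, "")[[1]])
    expect_false("--" %in% cols)
  }
})

test_that("optimal score equals the exhaustive-enumeration oracle", {
  set.seed(77)
  alphabet <- c("A", "C", "D", "W")
  for (i in 1:120) {
    a <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    b <- paste(sample(alphabet, sample(0:6, 1), replace = TRUE), collapse = "")
    p <- alignment_params(gap_open = sample(c(-10, -5, -2), 1),
                          gap_extend = sample(c(-0.5, -1), 1),
                          penalize_end_gaps = sample(c(TRUE, FALSE), 1))
    expect_equal(global_align(a, b, p)$score,
                 align_score_bruteforce(a, b, p),
                 tolerance = 1e-9,
                 label = paste(a, b, p$gap_open, p$gap_extend,
                               p$penalize_end_gaps))
  }
})

test_that("residues absent from the matrix raise an error", {
  small <- params$matrix[c("A", "C"), c("A", "C")]
  p <- alignment_params(matrix = rbind(small))
  expect_error(global_align("AW", "AC", p), "absent")
})

test_that("coordinate maps read off alignment columns", {
  id <- structure(list(aligned_a = "MAWKE", aligned_b = "MAWKE", score = 0),
                  class = "pairwise_alignment")
  expect_equal(coordinate_map(id), 1:5)
  al <- structure(list(aligned_a = "A-W", aligned_b = "AVW", score = 0),
                  class = "pairwise_alignment")
  expect_equal(coordinate_map(al), c(1L, 3L))
  al2 <- structure(list(aligned_a = "AW", aligned_b = "A-", score = 0),
                   class = "pairwise_alignment")
  expect_equal(coordinate_map(al2), c(1L, NA_integer_))
})

test_that("coordinate maps are strictly increasing over non-gap entries", {
  set.seed(31)
  for (i in 1:10) {
    a <- random_sequence(sample(10:40, 1))
    b <- random_sequence(sample(10:40, 1))
    map <- coordinate_map(global_align(a, b, params))
    expect_length(map, nchar(a))
    mapped <- map[!is.na(map)]
    if (length(mapped) > 1) expect_true(all(diff(mapped) > 0))
  }
})

test_that("variant transfer applies the gap and synonymous drop rules", {
  # position aligned against a gap
  r1 <- transfer_variant(parse_variant("A2V"), c(1L, NA_integer_), "MK")
  expect_equal(r1$status, "dropped_gap")
  # target native equals the mutant: would be a synonymous variant
  r2 <- transfer_variant(parse_variant("A2V"), c(1L, 2L), "MVK")
  expect_equal(r2$status, "dropped_synonymous")
  expect_equal(r2$target_native, "V")
  # plain transfer with position lifted, letters kept
  r3 <- transfer_variant(parse_variant("A2V"), c(1L, 3L), "MKAW")
  expect_equal(r3$status, "transferred")
  expect_equal(format_variant(r3$variant), "A3V")
  expect_equal(r3$target_native, "A")
})

test_that("transfer outcomes partition the input variant set", {
  set.seed(91)
  for (i in 1:5) {
    a <- random_sequence(40)
    b <- random_sequence(38)
    map <- coordinate_map(global_align(a, b, params))
    recs <- do.call(rbind, lapply(sample.int(40, 10), function(p)
      random_snv_variant(a, p)))
    tr <- transfer_variants(recs, map, b)
    expect_equal(nrow(tr), 10L)
    expect_true(all(tr$status %in% c("transferred", "dropped_gap",
                                     "dropped_synonymous")))
  }
})

test_that("transfer through a gapless alignment inverts cleanly", {
  a <- "MAWKEDLI"
  map <- coordinate_map(global_align(a, a, params))
  inv <- order(map)  # identity here
  v <- parse_variant("W3C")
  fwd <- transfer_variant(v, map, a)
  back <- transfer_variant(fwd$variant, inv, a)
  expect_equal(format_variant(back$variant), "W3C")
})

test_that("native identity fraction counts agreeing mapped positions", {
  a <- "MAWK"
  expect_equal(native_identity_fraction(data.frame(position = 1:4),
                                        1:4, a, a), 1.0)
  expect_equal(native_identity_fraction(data.frame(position = 1:4),
                                        rep(NA_integer_, 4), a, a), 0.0)
  # 3 of 4 agree: target differs at position 2
  b <- "MCWK"
  expect_equal(native_identity_fraction(data.frame(position = 1:4),
                                        1:4, a, b), 0.75)
})

test_that("aligned pairs export as 2-record gapped FASTA", {
  al <- global_align("AW", "W", params)
  f <- tempfile(fileext = ".fasta")
  write_alignment_fasta(al, c("src", "tgt"), f)
  lines <- readLines(f)
  expect_equal(lines, c(">src", "AW", ">tgt", "-W"))
})
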