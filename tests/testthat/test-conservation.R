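test_that("information content matches closed forms", {
  # fully conserved column, uniform background, pseudocount 0
  pr <- conservation_profile(rep("A", 10), pseudocount = 0)
  expect_equal(pr$values, log2(20), tolerance = 1e-12)
  # column uniform over all 20 residues
  pr2 <- conservation_profile(AAS, pseudocount = 0)
  expect_equal(pr2$values, 0, tolerance = 1e-12)
  # half A half C: 2 * 0.5 * log2(0.5 / 0.05)
  pr3 <- conservation_profile(c(rep("A", 5), rep("C", 5)), pseudocount = 0)
  expect_equal(pr3$values, log2(10), tolerance = 1e-12)
})

test_that("information is non-negative and zero only at the background", {
  set.seed(14)
  for (i in 1:20) {
    col <- sample(AAS, 60, replace = TRUE)
    pr <- conservation_profile(col, pseudocount = 0)
    expect_gte(pr$values, 0)
  }
})

test_that("reference gaps are skipped and ragged alignments rejected", {
  msa <- c("MA-W", "MACW", "MGCW")
  pr <- conservation_profile(msa, reference_index = 1)
  expect_length(pr$values, 3L)  # reference has 3 residues
  expect_error(conservation_profile(c("MAW", "MA")), "ragged")
})

spec_vals <- {
  v <- rep(1.0, 30)
  v[12] <- 2.5; v[15] <- 2.0; v[18] <- 2.0
  v
}
spec_profile <- structure(list(values = spec_vals, depth = 10,
                               protein_ref = "p"),
                          class = "conservation_profile")

test_that("eligible positions honor conservation mode and edge exclusion", {
  seqn <- strrep("A", 30)
  dv <- parse_variant("A15L")
  cons <- eligible_positions(seqn, spec_profile, dv,
                             known_disease_positions = 15L,
                             sampling_spec("conserved",
                                           require_native_match = FALSE))
  expect_equal(cons, c(12L, 18L))
  ncons <- eligible_positions(seqn, spec_profile, dv,
                              known_disease_positions = 15L,
                              sampling_spec("not_conserved",
                                            require_native_match = FALSE))
  expect_equal(ncons, c(11L, 13L, 14L, 16L, 17L, 19L, 20L))
})

test_that("the skip rule: strictly most conserved disease position has no nulls", {
  v <- rep(1.0, 30); v[15] <- 3.0
  prof <- structure(list(values = v, depth = 10, protein_ref = "p"),
                    class = "conservation_profile")
  out <- eligible_positions(strrep("A", 30), prof, parse_variant("A15L"),
                            15L, sampling_spec("conserved",
                                               require_native_match = FALSE))
  expect_length(out, 0L)
})

test_that("conserved/not-conserved eligibility partitions the interior", {
  set.seed(8)
  for (i in 1:5) {
    L <- 40
    seqn <- random_sequence(L)
    prof <- structure(list(values = runif(L, 0, 4), depth = 10,
                           protein_ref = "p"),
                      class = "conservation_profile")
    dpos <- sample(11:(L - 10), 1)
    dv <- parse_variant(paste0(substr(seqn, dpos, dpos), dpos, "A"))
    dv$mut_aa <- "L"  # ensure non-synonymous object irrelevant here
    cons <- eligible_positions(seqn, prof, dv, dpos,
                               sampling_spec("conserved", FALSE))
    ncons <- eligible_positions(seqn, prof, dv, dpos,
                                sampling_spec("not_conserved", FALSE))
    interior <- setdiff(11:(L - 10), dpos)
    expect_equal(sort(c(cons, ncons)), interior)
    expect_length(intersect(cons, ncons), 0L)
  }
})

test_that("native-residue matching restricts eligibility", {
  seqn <- paste0(strrep("A", 14), "I", strrep("A", 2), "I", strrep("A", 12))
  dv <- parse_variant("I15L")  # I at 15; other I at 18
  out <- eligible_positions(seqn, spec_profile, dv, 15L,
                            sampling_spec("conserved",
                                          require_native_match = TRUE))
  expect_equal(out, 18L)  # position 12 is conserved enough but carries A
})

test_that("exhaustive null sets enumerate exactly the eligible set", {
  seqn <- paste0(strrep("I", 30))
  records <- toy_records("I15L", "p1")
  proteins <- toy_proteins("p1", seqn)
  profs <- list(p1 = spec_profile)
  out <- build_null_set(records, proteins, profs,
                        sampling_spec("conserved", TRUE, exhaustive = TRUE),
                        "same_target")
  expect_equal(out$variants$position, c(12L, 18L))
  expect_true(all(out$variants$mut_aa == "L"))
  expect_true(all(out$variants$wild_aa == "I"))
  expect_equal(out$skip_count, 0L)
})

test_that("empty eligibility is counted as a skip", {
  v <- rep(1.0, 30); v[15] <- 3.0
  prof <- list(p1 = structure(list(values = v, depth = 10, protein_ref = "p1"),
                              class = "conservation_profile"))
  records <- toy_records("I15L", "p1")
  proteins <- toy_proteins("p1", strrep("I", 30))
  out <- build_null_set(records, proteins, prof,
                        sampling_spec("conserved", TRUE), "same_target")
  expect_equal(nrow(out$variants), 0L)
  expect_equal(out$skip_count, 1L)
})

test_that("sampled null sets are seed-reproducible and satisfy predicates", {
  set.seed(4)
  L <- 60
  seqn <- random_sequence(L)
  vals <- runif(L, 0, 4)
  prof <- list(p1 = structure(list(values = vals, depth = 10,
                                   protein_ref = "p1"),
                              class = "conservation_profile"))
  dpos <- 30L
  dv_txt <- paste0(substr(seqn, dpos, dpos), dpos, "A")
  if (substr(seqn, dpos, dpos) == "A") dv_txt <- paste0("A", dpos, "L")
  records <- toy_records(dv_txt, "p1")
  proteins <- toy_proteins("p1", seqn)
  for (mode in c("conserved", "not_conserved")) {
    sp <- sampling_spec(mode, require_native_match = TRUE)
    s1 <- build_null_set(records, proteins, prof, sp, "random_snv", seed = 42)
    s2 <- build_null_set(records, proteins, prof, sp, "random_snv", seed = 42)
    expect_identical(s1$variants, s2$variants)
    vr <- round(vals, 4)
    for (k in seq_len(nrow(s1$variants))) {
      m <- s1$variants$position[k]
      expect_true(m > 10 && m <= L - 10)
      expect_false(m == dpos)
      expect_equal(s1$variants$wild_aa[k], records$wild_aa[1])
      if (mode == "conserved") expect_gte(vr[m], vr[dpos])
      else expect_lt(vr[m], vr[dpos])
      expect_true(s1$variants$mut_aa[k] %in%
                    snv_reachable(s1$variants$wild_aa[k]))
    }
  }
})

test_that("the conservation-threshold baseline covers the SNV-possible space", {
  seqn <- "MWKDEFGHIKLMNPQRSTVW"
  vals <- rep(1, 20); vals[2] <- 3; vals[9] <- 3  # natives W and I above tau
  prof <- structure(list(values = vals, depth = 10, protein_ref = "p"),
                    class = "conservation_profile")
  calls <- conservation_threshold_baseline(seqn, prof, tau = 2)
  expect_equal(sum(calls$call == "effect"), 5L + 9L)  # |reach(W)| + |reach(I)|
  none <- conservation_threshold_baseline(seqn, prof, tau = 10)
  expect_equal(sum(none$call == "effect"), 0L)
  all_eff <- conservation_threshold_baseline(seqn, prof, tau = 0.5)
  expect_equal(sum(all_eff$call == "neutral"), 0L)
  expect_equal(nrow(all_eff),
               sum(lengths(reachability_map()[strsplit(seqn, "")[[1]]])))
})

test_that("profiles round-trip through TSV and PSI-BLAST PSSM text parses", {
  seqn <- "MAWK"
  pr <- conservation_profile(c("MAWK", "MAWK", "MCWK"), protein_ref = "p1")
  f <- tempfile()
  write_profile_tsv(pr, seqn, f)
  back <- read_profile_tsv(f, protein_ref = "p1")
  expect_equal(back$values, pr$values, tolerance = 1e-9)
  # minimal ASCII PSSM: position, residue, 40 numeric columns,
  # information-per-position, relative weight
  pssm <- tempfile()
  rows <- vapply(1:3, function(i) {
    paste(c(i, "A", rep(0, 40), i * 0.5, 0.1), collapse = " ")
  }, "")
  writeLines(c("", "Last position-specific scoring matrix computed",
               paste(c("   ", rep(LETTERS[1:20], 2)), collapse = " "),
               rows), pssm)
  pp <- read_psiblast_pssm(pssm)
  expect_equal(pp$values, c(0.5, 1.0, 1.5))
})
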