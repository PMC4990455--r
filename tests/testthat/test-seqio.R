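test_that("FASTA reading parses, uppercases and preserves order", {
  f <- tmp_fasta(c(">p1 first protein", "mal", ">p2", "WKDE", "HI"))
  ps <- read_fasta(f)
  expect_equal(ps$id, c("p1", "p2"))
  expect_equal(ps$description, c("first protein", ""))
  expect_equal(ps$sequence, c("MAL", "WKDEHI"))
})

test_that("FASTA round trip reproduces ids and sequences exactly", {
  set.seed(42)
  ps <- toy_proteins(sprintf("seq%02d", 1:8),
                     vapply(sample(30:120, 8), random_sequence, ""))
  f <- tempfile(fileext = ".fasta")
  write_fasta(ps, f)
  back <- read_fasta(f)
  expect_equal(back$id, ps$id)
  expect_equal(back$sequence, ps$sequence)
})

test_that("malformed FASTA input is rejected with the offending entry named", {
  expect_error(read_fasta(tmp_fasta(c(">ok", "MAL", ">bad", "MA1L"))), "bad")
  expect_error(read_fasta(tempfile()), "not found")
})

test_that("variant strings parse to wild/position/mutant", {
  v <- parse_variant("A11W")
  expect_equal(v$wild_aa, "A")
  expect_equal(v$position, 11L)
  expect_equal(v$mut_aa, "W")
  expect_false(v$synonymous)
})

test_that("synonymous variant strings parse but are flagged", {
  v <- parse_variant("Y2Y")
  expect_equal(v$wild_aa, "Y")
  expect_equal(v$position, 2L)
  expect_true(v$synonymous)
})

test_that("invalid variant strings are rejected", {
  expect_error(parse_variant("A0W"), "position")
  expect_error(parse_variant("B5W"), "wild-type")
  expect_error(parse_variant("A5U"), "mutant")
  expect_error(parse_variant("AW"), "malformed")
  expect_error(parse_variant("A5"), "malformed")
})

test_that("parse and format are inverse over random variants", {
  set.seed(11)
  for (i in 1:200) {
    wild <- sample(AAS, 1)
    mut <- sample(AAS, 1)
    pos <- sample.int(5000, 1)
    txt <- paste0(wild, pos, mut)
    v <- parse_variant(txt)
    expect_identical(format_variant(v), txt)
    expect_identical(v$synonymous, wild == mut)
  }
})

test_that("variant table reading is order-preserving and total", {
  df <- data.frame(gene_symbol = c("g1", "g2", "g3"),
                   taxon_id = c(9615L, 9913L, 9615L),
                   protein_ref = c("p1", "p2", "p3"),
                   variant = c("A11W", "I10L", "Y2F"),
                   label = "d", source = "s")
  vt <- read_variant_table(tmp_tsv(df))
  expect_equal(nrow(vt), 3L)
  expect_equal(vt$variant, df$variant)
  expect_equal(vt$position, c(11L, 10L, 2L))
  expect_equal(vt$variant_type, rep("sav", 3))
})

test_that("bad variant rows and missing columns are located", {
  df <- data.frame(gene_symbol = "g", taxon_id = 9615L, protein_ref = "p",
                   variant = c("A11W", "A0W"), label = "d", source = "s")
  expect_error(read_variant_table(tmp_tsv(df)), "row 2")
  expect_error(read_variant_table(tmp_tsv(df[, -3])), "protein_ref")
})

test_that("packaged BLOSUM62 parses with correct entries and symmetry", {
  m <- read_matrix(fixture("BLOSUM62.txt"))
  expect_equal(m["W", "W"], 11)
  expect_equal(m["A", "W"], m["W", "A"])
  # dual route: the parsed file must agree with the Biostrings copy of the
  # same standard matrix over all residue pairs
  data(BLOSUM62, package = "Biostrings", envir = environment())
  expect_equal(m[AAS, AAS], BLOSUM62[AAS, AAS])
})

test_that("matrices missing residues or asymmetric are rejected", {
  m <- read_matrix(fixture("BLOSUM62.txt"))
  keep <- setdiff(rownames(m), "C")
  f <- tempfile()
  writeLines(c(paste(" ", paste(keep, collapse = " ")),
               vapply(keep, function(r)
                 paste(r, paste(m[r, keep], collapse = " ")), "")), f)
  expect_error(read_matrix(f), "missing standard residue")
  m2 <- m
  m2["A", "W"] <- m2["A", "W"] + 1
  f2 <- tempfile()
  writeLines(c(paste(" ", paste(rownames(m2), collapse = " ")),
               vapply(rownames(m2), function(r)
                 paste(r, paste(m2[r, ], collapse = " ")), "")), f2)
  expect_error(read_matrix(f2), "not symmetric")
})

test_that("score tables reject duplicate (protein, variant, method) rows", {
  df <- data.frame(protein_ref = "p1", variant = c("A1W", "A1W"),
                   method = "m", score = c(0.2, 0.4))
  expect_error(read_score_table(tmp_tsv(df)), "duplicate")
  vt <- read_score_table(tmp_tsv(df[1, ]))
  expect_equal(vt$score, 0.2)
})
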