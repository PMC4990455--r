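test_that("dominance solver inverts the column information closed form", {
  targets <- c(0, 0.5, 1, 2, 3, 4, log2(20))
  q <- savlink:::solve_dominance(targets)
  realized <- savlink:::dominance_information(q)
  expect_equal(realized, targets, tolerance = 1e-6)
  expect_equal(q[1], 1 / 20, tolerance = 1e-9)
  expect_equal(q[length(q)], 1)
})

test_that("maximally conserved families realize full information", {
  spec <- family_spec(n_sequences = 50, length = 40,
                      conservation_shape = list(target_bits = rep(log2(20), 40)),
                      seed = 5)
  fam <- generate_family(spec, pseudocount = 0)
  expect_equal(fam$profile$values, rep(log2(20), 40), tolerance = 1e-9)
})

test_that("uniform-target families realize near-zero information at depth 500", {
  spec <- family_spec(n_sequences = 500, length = 30,
                      conservation_shape = list(target_bits = rep(0, 30)),
                      seed = 6)
  fam <- generate_family(spec, pseudocount = 0)
  expect_true(all(fam$profile$values < 0.1))
})

test_that("family generation is seed-reproducible", {
  spec <- family_spec(n_sequences = 20, length = 25, seed = 99)
  f1 <- generate_family(spec)
  f2 <- generate_family(spec)
  expect_identical(f1$msa, f2$msa)
  expect_identical(f1$profile$values, f2$profile$values)
})

test_that("realized information tracks the conservation targets", {
  spec <- family_spec(n_sequences = 300, length = 60, seed = 13)
  fam <- generate_family(spec, pseudocount = 0)
  expect_lt(mean(abs(fam$profile$values - fam$target_bits)), 0.25)
})

test_that("planted variants sit at conserved interior positions and validate", {
  spec <- family_spec(n_sequences = 100, length = 120, seed = 17)
  fam <- generate_family(spec)
  set.seed(17)
  planted <- plant_disease_variants(fam, 5, conservation_quantile = 0.9)
  expect_equal(nrow(planted), 5L)
  cut <- quantile(fam$profile$values, 0.9, names = FALSE)
  expect_true(all(fam$profile$values[planted$position] >= cut))
  expect_true(all(planted$position > 10 & planted$position <= 110))
  expect_equal(anyDuplicated(planted$position), 0L)
  for (i in 1:5) {
    v <- parse_variant(planted$variant[i])
    expect_equal(validate_variant(v, fam$reference$sequence[1])$status,
                 "match")
  }
  expect_equal(nrow(plant_disease_variants(fam, 0)), 0L)
  expect_error(plant_disease_variants(fam, 1000), "eligible")
})

test_that("zero divergence yields an identical ortholog", {
  fam <- generate_family(family_spec(30, 50, seed = 3))
  ort <- generate_ortholog(fam, divergence = 0)
  expect_identical(ort$sequence$sequence[1], fam$reference$sequence[1])
  expect_length(ort$substituted, 0L)
})

test_that("substitution counts track the divergence rate", {
  spec <- family_spec(n_sequences = 50, length = 300,
                      conservation_shape = list(shape1 = 1.5, shape2 = 3),
                      seed = 1)
  counts <- vapply(1:30, function(s) {
    fam <- generate_family(family_spec(50, 300, seed = s))
    set.seed(1000 + s)
    length(generate_ortholog(fam, divergence = 0.1)$substituted)
  }, numeric(1))
  expect_gt(mean(counts), 20)
  expect_lt(mean(counts), 40)
  expect_true(all(counts > 10 & counts < 55))
})

test_that("conserved positions are substituted less often than unconserved", {
  sub_high <- 0; n_high <- 0; sub_low <- 0; n_low <- 0
  for (s in 1:25) {
    fam <- generate_family(family_spec(40, 150, seed = 100 + s))
    set.seed(200 + s)
    ort <- generate_ortholog(fam, divergence = 0.15)
    q <- quantile(fam$profile$values, c(0.25, 0.75), names = FALSE)
    high <- which(fam$profile$values >= q[2])
    low <- which(fam$profile$values <= q[1])
    sub_high <- sub_high + sum(ort$substituted %in% high)
    n_high <- n_high + length(high)
    sub_low <- sub_low + sum(ort$substituted %in% low)
    n_low <- n_low + length(low)
  }
  expect_lt(sub_high / n_high, sub_low / n_low)
})

test_that("indel restriction keeps deletions off conserved positions", {
  fam <- generate_family(family_spec(40, 200, seed = 8))
  set.seed(8)
  ort <- generate_ortholog(fam, divergence = 0.05, del_rate = 0.2,
                           restrict_indels = TRUE)
  med <- median(fam$profile$values)
  expect_true(all(fam$profile$values[ort$deleted] < med))
})

test_that("predictor scores separate planted variants and respect seeds", {
  fam <- generate_family(family_spec(60, 200, seed = 21))
  set.seed(21)
  planted <- plant_disease_variants(fam, 3)
  interior <- setdiff(11:190, planted$position)
  others <- do.call(rbind, lapply(sample(interior, 40), function(p)
    random_snv_variant(fam$reference$sequence[1], p)))
  others$protein_ref <- fam$reference$id[1]
  pspec <- predictor_spec(intercept = -2, conservation_weight = 0,
                          planted_effect_weight = 4, noise_sd = 0.3)
  set.seed(5)
  sc_planted <- generate_scores(planted, fam$profile, pspec)
  sc_others <- generate_scores(others, fam$profile, pspec, planted = FALSE)
  expect_gt(mean(sc_planted$score), mean(sc_others$score))
  set.seed(5)
  sc_again <- generate_scores(planted, fam$profile, pspec)
  expect_identical(sc_planted, sc_again)
})

test_that("with zero weights the mean score approaches the intercept logistic", {
  fam <- generate_family(family_spec(30, 120, seed = 30))
  vs <- do.call(rbind, lapply(rep(11:110, length.out = 1000), function(p)
    enumerate_snv_possible(fam$reference$sequence[1], p)[1, ]))
  vs$protein_ref <- fam$reference$id[1]
  pspec <- predictor_spec(intercept = -1, conservation_weight = 0,
                          planted_effect_weight = 0, noise_sd = 0.5)
  set.seed(77)
  sc <- generate_scores(vs, fam$profile, pspec, planted = FALSE)
  expect_lt(abs(mean(sc$score) - plogis(-1)), 0.035)
})
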