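#' Default synthetic study scenario
#'
#' The study conditions under which the full pipeline is exercised end to
#' end: 50 families of length 300 at alignment depth 200, two disease SAVs
#' planted per family at positions in the top conservation decile, ortholog
#' divergence 0.1, and the logistic predictor of [predictor_spec()] with
#' conservation weight 2 per bit and planted-effect weight 2.
#'
#' @param seed Scenario seed; per-family seeds are derived from it.
#' @return A list of class `scenario`.
#' @export
default_scenario <- function(seed = 1L) {
  structure(list(
    n_families = 50L,
    n_sequences = 200L,
    length = 300L,
    conservation_shape = list(shape1 = 1.5, shape2 = 3),
    k_planted = 2L,
    conservation_quantile = 0.9,
    edge_exclusion = 10L,
    divergence = 0.1,
    del_rate = 0.02,
    ins_rate = 0.01,
    predictor = predictor_spec(),
    cutoff = 0.5,
    seed = as.integer(seed)
  ), class = "scenario")
}

#' Read / write a scenario as YAML
#'
#' @param path File path.
#' @return A `scenario` (reader); `path` invisibly (writer).
#' @export
read_scenario <- function(path) {
  cfg <- yaml::read_yaml(path)
  sc <- default_scenario()
  for (nm in setdiff(names(cfg), "predictor")) sc[[nm]] <- cfg[[nm]]
  if (!is.null(cfg$predictor)) {
    sc$predictor <- do.call(predictor_spec, cfg$predictor)
  }
  sc$n_families <- as.integer(sc$n_families)
  sc$seed <- as.integer(sc$seed)
  sc
}

#' @rdname read_scenario
#' @param scenario A `scenario`.
#' @export
write_scenario <- function(scenario, path) {
  out <- unclass(scenario)
  out$predictor <- unclass(out$predictor)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Simulate one family bundle under a scenario
#'
#' @param scenario A `scenario`.
#' @param index Family index (1-based), used for naming and seed
#'   derivation.
#' @return List: `family` (`synthetic_family`), `planted`
#'   (`variant_table` with `planted` flags), `ortholog`
#'   (`synthetic_ortholog`).
#' @export
simulate_family <- function(scenario, index = 1L) {
  fam_seed <- (scenario$seed * 1000003L + index) %% .Machine$integer.max
  ref <- sprintf("synfam%03d", index)
  fam <- generate_family(
    family_spec(scenario$n_sequences, scenario$length,
                scenario$conservation_shape, seed = fam_seed),
    protein_ref = ref)
  planted <- plant_disease_variants(
    fam, scenario$k_planted, scenario$conservation_quantile,
    scenario$edge_exclusion, gene_symbol = ref)
  ortholog <- generate_ortholog(fam, scenario$divergence,
                                scenario$del_rate, scenario$ins_rate)
  list(family = fam, planted = planted, ortholog = ortholog)
}

#' Run the disease-vs-null effect-pattern analysis on a synthetic scenario
#'
#' The end-to-end parameter-recovery run: for every simulated family, plant
#' disease SAVs at conserved positions, sample one conservation-matched
#' ("conserved") and one less-conserved ("not conserved") null variant per
#' disease SAV (case i: same mutant residue, native-matched positions),
#' score all three sets with the synthetic predictor, binarize at the
#' scenario cutoff, and summarize effect fractions. Also runs the
#' conservation-threshold baseline with each family's threshold set at its
#' least-conserved planted position, counting its effect calls.
#'
#' @param scenario A `scenario`.
#' @param seed Optional override of the scenario seed.
#' @param bootstrap_reps Bootstrap replicates for the summaries.
#' @return A list of class `scenario_analysis`: `report`
#'   (`comparison_report` over the sets `disease`, `null conserved`,
#'   `null not conserved`), `summaries`, `baseline_effect_calls`,
#'   `n_planted`, `baseline_ratio`, `skip_counts`.
#' @export
run_scenario_analysis <- function(scenario = default_scenario(), seed = NULL,
                                  bootstrap_reps = 500L) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  set.seed(scenario$seed)
  rules <- list(synpred = cutoff_rule(scenario$predictor$method,
                                      scenario$cutoff, "greater_is_effect"))
  names(rules) <- scenario$predictor$method
  spec_cons <- sampling_spec("conserved", require_native_match = TRUE,
                             edge_exclusion = scenario$edge_exclusion)
  spec_ncons <- sampling_spec("not_conserved", require_native_match = TRUE,
                              edge_exclusion = scenario$edge_exclusion)
  scores <- list(disease = list(), cons = list(), ncons = list())
  skips <- c(conserved = 0L, not_conserved = 0L)
  baseline_effect <- 0L
  n_planted <- 0L
  for (f in seq_len(scenario$n_families)) {
    sim <- simulate_family(scenario, f)
    fam <- sim$family
    planted <- sim$planted
    n_planted <- n_planted + nrow(planted)
    profiles <- stats::setNames(list(fam$profile), fam$reference$id[1])
    cons <- build_null_set(planted, fam$reference, profiles, spec_cons,
                           "same_target", label = "null conserved")
    ncons <- build_null_set(planted, fam$reference, profiles, spec_ncons,
                            "same_target", label = "null not conserved")
    skips["conserved"] <- skips["conserved"] + cons$skip_count
    skips["not_conserved"] <- skips["not_conserved"] + ncons$skip_count
    scores$disease[[f]] <- generate_scores(planted, fam$profile,
                                           scenario$predictor)
    scores$cons[[f]] <- generate_scores(cons$variants, fam$profile,
                                        scenario$predictor, planted = FALSE)
    scores$ncons[[f]] <- generate_scores(ncons$variants, fam$profile,
                                         scenario$predictor, planted = FALSE)
    tau <- min(fam$profile$values[planted$position]) - 1e-9
    base <- conservation_threshold_baseline(fam$reference$sequence[1],
                                            fam$profile, tau)
    baseline_effect <- baseline_effect + sum(base$call == "effect")
  }
  call_sets <- lapply(scores, function(s) binarize(do.call(rbind, s), rules))
  summaries <- list(
    effect_fraction(call_sets$disease, "disease", bootstrap_reps),
    effect_fraction(call_sets$cons, "null conserved", bootstrap_reps,
                    skip_count = skips[["conserved"]]),
    effect_fraction(call_sets$ncons, "null not conserved", bootstrap_reps,
                    skip_count = skips[["not_conserved"]]))
  report <- comparison_report(summaries,
                              differences = list(
                                c("disease", "null conserved"),
                                c("disease", "null not conserved"),
                                c("null conserved", "null not conserved")))
  structure(list(report = report, summaries = summaries,
                 baseline_effect_calls = baseline_effect,
                 n_planted = n_planted,
                 baseline_ratio = baseline_effect / max(n_planted, 1L),
                 skip_counts = skips),
            class = "scenario_analysis")
}

#' @export
print.scenario_analysis <- function(x, ...) {
  print(x$report)
  cat("conservation-threshold baseline:", x$baseline_effect_calls,
      "effect calls for", x$n_planted, "planted variants (ratio",
      round(x$baseline_ratio, 1), ")\n")
  invisible(x)
}

#' Transfer attrition on simulated ortholog pairs
#'
#' Aligns each simulated reference to its ortholog, transfers per-position
#' test variants, and tallies transfer outcomes — the synthetic analogue of
#' lifting human disease variants into a model organism.
#'
#' @param scenario A `scenario`.
#' @param n_families Number of families to simulate (default from the
#'   scenario).
#' @param variants_per_family Number of random test SAVs per family.
#' @param params Alignment parameters.
#' @param seed Optional scenario-seed override.
#' @return A list with `counts` (named: transferred, dropped_gap,
#'   dropped_synonymous), `n`, `dropped_gap_fraction`,
#'   `deleted_position_fraction` (realized single-residue deletion coverage
#'   of the simulated orthologs), `native_identity_fraction` (mean over
#'   families).
#' @export
run_transfer_attrition <- function(scenario = default_scenario(),
                                   n_families = scenario$n_families,
                                   variants_per_family = 20L,
                                   params = NULL, seed = NULL) {
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  if (is.null(params)) params <- alignment_params()
  set.seed(scenario$seed)
  counts <- c(transferred = 0L, dropped_gap = 0L, dropped_synonymous = 0L)
  nif <- numeric(0)
  n_deleted <- 0L
  n_positions <- 0L
  for (f in seq_len(n_families)) {
    sim <- simulate_family(scenario, f)
    src <- sim$family$reference$sequence[1]
    tgt <- sim$ortholog$sequence$sequence[1]
    n_deleted <- n_deleted + length(sim$ortholog$deleted)
    n_positions <- n_positions + nchar(src)
    al <- global_align(src, tgt, params)
    map <- coordinate_map(al)
    pos <- sample.int(nchar(src), variants_per_family)
    recs <- do.call(rbind, lapply(pos, function(p) random_snv_variant(src, p)))
    tr <- transfer_variants(recs, map, tgt)
    tab <- table(factor(tr$status, levels = names(counts)))
    counts <- counts + as.integer(tab)
    nif <- c(nif, native_identity_fraction(recs, map, src, tgt))
  }
  n <- sum(counts)
  list(counts = counts, n = n,
       dropped_gap_fraction = counts[["dropped_gap"]] / n,
       deleted_position_fraction = n_deleted / n_positions,
       native_identity_fraction = mean(nif))
}
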