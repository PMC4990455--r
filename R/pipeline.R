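#' Multi-protein conservation profile TSV
#'
#' Columns: `protein_ref`, `position`, `residue`, `information_bits`.
#'
#' @param profiles Named list of `conservation_profile`s.
#' @param proteins Matching `protein_set` (for the residue column).
#' @param path File path.
#' @return `path` invisibly (writer); named list of profiles (reader).
#' @export
write_profiles_tsv <- function(profiles, proteins, path) {
  rows <- lapply(names(profiles), function(ref) {
    seq <- get_sequence(proteins, ref)
    data.frame(protein_ref = ref, position = seq_along(profiles[[ref]]$values),
               residue = strsplit(seq, "")[[1]],
               information_bits = profiles[[ref]]$values,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_tsv
#' @export
read_profiles_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("protein_ref", "position", "information_bits") %in% names(df)))
  out <- lapply(split(df, df$protein_ref), function(d) {
    d <- d[order(d$position), ]
    structure(list(values = d$information_bits, depth = NA_integer_,
                   protein_ref = d$protein_ref[1]),
              class = "conservation_profile")
  })
  out
}

#' Pipeline stage: validate a curated variant table against sequences
#'
#' @param variant_table Path to a variant TSV (see [read_variant_table()]).
#' @param fasta Path to the sequence FASTA.
#' @param out_dir Output directory (created if needed); writes
#'   `attrition.tsv`, `attrition.json` and `retained_variants.tsv`.
#' @return The `attrition_report`, invisibly.
#' @export
pipeline_validate <- function(variant_table, fasta, out_dir) {
  records <- read_variant_table(variant_table)
  proteins <- read_fasta(fasta)
  report <- build_attrition_report(records, proteins)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_attrition_report(report,
                         tsv = file.path(out_dir, "attrition.tsv"),
                         json = file.path(out_dir, "attrition.json"),
                         retained_tsv = file.path(out_dir,
                                                  "retained_variants.tsv"))
  invisible(report)
}

#' Pipeline stage: transfer variants into aligned ortholog sequences
#'
#' @param variant_table Path to the source variant TSV.
#' @param fasta Path to a FASTA holding source and target sequences.
#' @param pairs Path to a TSV with columns `source_id`, `target_id`.
#' @param out_dir Output directory; writes `transfer.tsv` and
#'   `transfer_summary.json`.
#' @param params Alignment parameters.
#' @return Data frame of per-variant transfer outcomes, invisibly.
#' @export
pipeline_transfer <- function(variant_table, fasta, pairs, out_dir,
                              params = NULL) {
  if (is.null(params)) params <- alignment_params()
  records <- read_variant_table(variant_table)
  proteins <- read_fasta(fasta)
  pair_df <- utils::read.delim(pairs, comment.char = "#",
                               stringsAsFactors = FALSE)
  stopifnot(all(c("source_id", "target_id") %in% names(pair_df)))
  out <- list()
  identity <- numeric(0)
  for (i in seq_len(nrow(pair_df))) {
    src_id <- pair_df$source_id[i]; tgt_id <- pair_df$target_id[i]
    src <- get_sequence(proteins, src_id)
    tgt <- get_sequence(proteins, tgt_id)
    if (is.na(src) || is.na(tgt)) {
      stop("pair row ", i, ": sequence missing for ",
           if (is.na(src)) src_id else tgt_id)
    }
    recs <- records[records$protein_ref == src_id, , drop = FALSE]
    if (nrow(recs) == 0L) next
    al <- global_align(src, tgt, params)
    map <- coordinate_map(al)
    tr <- transfer_variants(recs, map, tgt)
    tr <- cbind(source_id = src_id, target_id = tgt_id, tr,
                stringsAsFactors = FALSE)
    identity <- c(identity, native_identity_fraction(recs, map, src, tgt))
    out[[length(out) + 1L]] <- tr
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(source_id = character(0), target_id = character(0),
               source_variant = character(0), status = character(0),
               target_variant = character(0), target_native = character(0))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(res, file.path(out_dir, "transfer.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(n = nrow(res), counts = as.list(table(res$status)),
         mean_native_identity = if (length(identity)) mean(identity) else NA),
    file.path(out_dir, "transfer_summary.json"), auto_unbox = TRUE,
    pretty = TRUE)
  invisible(res)
}

#' Pipeline stage: build labeled null-variant sets
#'
#' Builds the four standard contrasts for a disease variant table: case-i
#' nulls (same mutant residue, native-matched positions) at conserved and
#' not-conserved positions, in sampled or exhaustive ("all @") mode.
#'
#' @param variant_table Path to the disease variant TSV.
#' @param fasta Path to the sequence FASTA.
#' @param profiles Path to a multi-protein profile TSV
#'   (see [read_profiles_tsv()]).
#' @param out_dir Output directory; one TSV per set plus `sampling.json`
#'   with skip counts.
#' @param exhaustive Emit all eligible positions instead of one draw each.
#' @param seed RNG seed.
#' @param edge_exclusion Terminal residues excluded from sampling.
#' @return Named list of `sampled_set`s, invisibly.
#' @export
pipeline_sample <- function(variant_table, fasta, profiles, out_dir,
                            exhaustive = FALSE, seed = 1L,
                            edge_exclusion = 10L) {
  records <- read_variant_table(variant_table)
  proteins <- read_fasta(fasta)
  profs <- read_profiles_tsv(profiles)
  prefix <- if (exhaustive) "all @ " else ""
  sets <- list()
  set.seed(seed)
  for (mode in c("conserved", "not_conserved")) {
    label <- paste0(prefix, "NotDisease ",
                    if (mode == "conserved") "conserved" else "not conserved")
    spec <- sampling_spec(mode, require_native_match = TRUE,
                          edge_exclusion = edge_exclusion,
                          exhaustive = exhaustive)
    sets[[label]] <- build_null_set(records, proteins, profs, spec,
                                    "same_target", label = label)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (label in names(sets)) {
    fn <- paste0(gsub("[^A-Za-z0-9]+", "_", label), ".tsv")
    write_variant_table(sets[[label]]$variants, file.path(out_dir, fn))
  }
  jsonlite::write_json(
    lapply(sets, function(s) list(n = nrow(s$variants),
                                  skipped = s$skip_count,
                                  n_input = s$n_input)),
    file.path(out_dir, "sampling.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(sets)
}

#' Pipeline stage: binarize score tables into effect calls
#'
#' @param score_table Path to a score TSV (see [read_score_table()]).
#' @param out Path of the output call TSV.
#' @param rules_yaml Optional path to a cutoff-rule YAML (defaults to the
#'   packaged rules).
#' @return The call data frame, invisibly.
#' @export
pipeline_call <- function(score_table, out, rules_yaml = NULL) {
  scores <- read_score_table(score_table)
  calls <- binarize(scores, default_cutoff_rules(rules_yaml))
  utils::write.table(calls, out, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(calls)
}

#' Pipeline stage: summarize labeled call sets
#'
#' @param call_tables Named character vector of call-TSV paths; names are
#'   set labels.
#' @param out_dir Output directory; writes `summary.json`, `summary.tsv`
#'   (bar data) and `agreement.tsv`.
#' @param bootstrap_reps Bootstrap replicates per set.
#' @param seed RNG seed for the bootstrap.
#' @return The `comparison_report`, invisibly.
#' @export
pipeline_summarize <- function(call_tables, out_dir, bootstrap_reps = 2000L,
                               seed = 1L) {
  set.seed(seed)
  call_sets <- lapply(call_tables, function(p)
    utils::read.delim(p, comment.char = "#", stringsAsFactors = FALSE))
  summaries <- lapply(names(call_sets), function(label)
    effect_fraction(call_sets[[label]], label, bootstrap_reps))
  report <- comparison_report(summaries)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_comparison_report(report,
                          json = file.path(out_dir, "summary.json"),
                          tsv = file.path(out_dir, "summary.tsv"))
  agreement <- pairwise_agreement(join_calls(call_sets), dataset = "all")
  utils::write.table(agreement, file.path(out_dir, "agreement.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(report)
}

#' Pipeline stage: write a full synthetic input bundle
#'
#' Simulates every family of a scenario and writes the same file formats
#' the real pipeline consumes: `sequences.fasta` (references + orthologs),
#' `pairs.tsv`, `variants.tsv` (planted disease SAVs), `profiles.tsv`,
#' `scores.tsv` (predictor scores for the planted SAVs) and
#' `scenario.yaml`.
#'
#' @param out_dir Output directory.
#' @param scenario A `scenario` or path to a scenario YAML (default:
#'   [default_scenario()]).
#' @param seed Optional scenario-seed override.
#' @return Invisibly, the list of per-family simulation objects.
#' @export
pipeline_simulate <- function(out_dir, scenario = NULL, seed = NULL) {
  if (is.null(scenario)) scenario <- default_scenario()
  if (is.character(scenario)) scenario <- read_scenario(scenario)
  if (!is.null(seed)) scenario$seed <- as.integer(seed)
  set.seed(scenario$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sims <- lapply(seq_len(scenario$n_families), function(f)
    simulate_family(scenario, f))
  proteins <- do.call(rbind, lapply(sims, function(s)
    rbind(s$family$reference, s$ortholog$sequence)))
  write_fasta(proteins, file.path(out_dir, "sequences.fasta"))
  pairs <- do.call(rbind, lapply(sims, function(s)
    data.frame(source_id = s$family$reference$id[1],
               target_id = s$ortholog$sequence$id[1])))
  utils::write.table(pairs, file.path(out_dir, "pairs.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  variants <- do.call(rbind, lapply(sims, function(s) s$planted))
  write_variant_table(variants, file.path(out_dir, "variants.tsv"))
  profiles <- stats::setNames(lapply(sims, function(s) s$family$profile),
                              vapply(sims, function(s)
                                s$family$reference$id[1], ""))
  write_profiles_tsv(profiles, proteins, file.path(out_dir, "profiles.tsv"))
  scores <- do.call(rbind, lapply(sims, function(s)
    generate_scores(s$planted, s$family$profile, scenario$predictor)))
  utils::write.table(scores[, c("protein_ref", "variant", "method", "score")],
                     file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_scenario(scenario, file.path(out_dir, "scenario.yaml"))
  invisible(sims)
}

#' Run every pipeline stage on a synthetic bundle
#'
#' Chains simulate -> validate -> transfer -> sample -> call -> summarize
#' inside one output directory.
#'
#' @param out_dir Output directory.
#' @param scenario Scenario object or YAML path (default scenario if
#'   `NULL`).
#' @param seed Optional seed override.
#' @return Invisibly, the final `comparison_report`.
#' @export
pipeline_run_all <- function(out_dir, scenario = NULL, seed = NULL) {
  pipeline_simulate(out_dir, scenario, seed)
  vt <- file.path(out_dir, "variants.tsv")
  fa <- file.path(out_dir, "sequences.fasta")
  pipeline_validate(vt, fa, file.path(out_dir, "validate"))
  pipeline_transfer(vt, fa, file.path(out_dir, "pairs.tsv"),
                    file.path(out_dir, "transfer"))
  pipeline_sample(vt, fa, file.path(out_dir, "profiles.tsv"),
                  file.path(out_dir, "sample"),
                  seed = if (is.null(seed)) 1L else seed)
  pipeline_call(file.path(out_dir, "scores.tsv"),
                file.path(out_dir, "calls.tsv"))
  report <- pipeline_summarize(
    c(disease = file.path(out_dir, "calls.tsv")),
    file.path(out_dir, "summary"),
    seed = if (is.null(seed)) 1L else seed)
  invisible(report)
}
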