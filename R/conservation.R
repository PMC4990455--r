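#' Per-position conservation profile from a multiple sequence alignment
#'
#' Conservation is measured as information content per position: the
#' relative entropy (in bits) of the column residue distribution versus a
#' background distribution,
#' \deqn{I_j = \sum_a p_{aj} \log_2 (p_{aj} / b_a),}
#' with column frequencies estimated from gap-excluded counts plus an
#' additive pseudocount. Columns where the reference row carries a gap are
#' skipped, so the profile is indexed by reference residue positions.
#'
#' @param msa Character vector of equal-length gapped sequences (`-` gaps).
#' @param reference_index Row of the reference sequence (default 1).
#' @param pseudocount Additive pseudocount per residue; default `1/depth`.
#'   Use 0 for raw column frequencies.
#' @param background Background residue distribution: named numeric vector
#'   over the 20 standard residues (default uniform).
#' @param protein_ref Identifier stored with the profile.
#' @return Object of class `conservation_profile`: list with `values`
#'   (bits, one per reference position), `depth`, `protein_ref`.
#' @export
conservation_profile <- function(msa, reference_index = 1L,
                                 pseudocount = NULL,
                                 background = NULL,
                                 protein_ref = "") {
  stopifnot(length(msa) >= 1L)
  widths <- nchar(msa)
  if (length(unique(widths)) != 1L) stop("ragged MSA: unequal sequence lengths")
  if (is.null(background)) {
    background <- stats::setNames(rep(1 / 20, 20), AA_STANDARD)
  }
  background <- background[AA_STANDARD]
  if (anyNA(background)) stop("background must cover all 20 standard residues")
  depth <- length(msa)
  if (is.null(pseudocount)) pseudocount <- 1 / depth
  chars <- do.call(rbind, strsplit(msa, ""))
  ref <- chars[reference_index, ]
  cols <- which(ref != "-")
  # integer residue codes; gaps / non-standard letters are dropped per column
  codes <- matrix(match(chars, AA_STANDARD), nrow = depth)
  values <- numeric(length(cols))
  bg <- as.numeric(background)
  for (k in seq_along(cols)) {
    col <- codes[, cols[k]]
    cnt <- tabulate(col[!is.na(col)], nbins = 20L)
    p <- cnt + pseudocount
    p <- p / sum(p)
    nz <- p > 0
    values[k] <- sum(p[nz] * log2(p[nz] / bg[nz]))
  }
  structure(list(values = values, depth = depth, protein_ref = protein_ref),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  cat("Conservation profile", if (nzchar(x$protein_ref)) x$protein_ref else "",
      ": ", length(x$values), " positions, depth ", x$depth,
      ", mean ", round(mean(x$values), 2), " bits\n", sep = "")
  invisible(x)
}

#' Sampling specification for null-position construction
#'
#' @param mode `"conserved"` (positions at least as conserved as the disease
#'   position), `"not_conserved"` (strictly less conserved) or
#'   `"unconstrained"`.
#' @param require_native_match Restrict to positions carrying the disease
#'   variant's wild-type residue (the `XmY` construction).
#' @param edge_exclusion Number of residues excluded at each sequence end
#'   (default 10, matching a 21-residue predictor input window).
#' @param exhaustive If `TRUE`, enumerate every eligible position ("all @"
#'   sets) instead of drawing one at random per variant.
#' @return A list of class `sampling_spec`.
#' @export
sampling_spec <- function(mode = c("conserved", "not_conserved", "unconstrained"),
                          require_native_match = TRUE,
                          edge_exclusion = 10L,
                          exhaustive = FALSE) {
  mode <- match.arg(mode)
  stopifnot(edge_exclusion >= 0L)
  structure(list(mode = mode, require_native_match = require_native_match,
                 edge_exclusion = as.integer(edge_exclusion),
                 exhaustive = exhaustive),
            class = "sampling_spec")
}

# conservation values are compared after rounding to 4 decimals so that the
# >= / < split (and the skip rule) is not decided by float noise
round_cons <- function(x) round(x, 4)

#' Eligible null positions for one disease variant
#'
#' Positions of the protein that (a) carry no known disease variant, (b) lie
#' outside the terminal `edge_exclusion` residues, (c) satisfy the
#' conservation constraint relative to the disease position (`conserved`:
#' at least as conserved; `not_conserved`: strictly less), and (d) if
#' requested, carry the disease variant's wild-type residue.
#'
#' @param sequence Protein sequence string.
#' @param profile Matching `conservation_profile`.
#' @param disease_variant A `variant` located on this protein.
#' @param known_disease_positions Integer positions of all known disease
#'   variants in this protein (excluded from sampling).
#' @param spec A `sampling_spec`.
#' @return Sorted integer vector of eligible positions (possibly empty — the
#'   "skip" case when a disease position is the most conserved of its
#'   protein and no other position ties it).
#' @export
eligible_positions <- function(sequence, profile, disease_variant,
                               known_disease_positions = integer(0),
                               spec = sampling_spec()) {
  L <- nchar(sequence)
  if (length(profile$values) != L) {
    stop("profile length ", length(profile$values),
         " does not match sequence length ", L)
  }
  n <- disease_variant$position
  if (n < 1L || n > L) stop("disease position ", n, " outside sequence")
  pos <- setdiff(seq_len(L), known_disease_positions)
  pos <- pos[pos > spec$edge_exclusion & pos <= L - spec$edge_exclusion]
  vals <- round_cons(profile$values)
  v_n <- vals[n]
  if (spec$mode == "conserved") pos <- pos[vals[pos] >= v_n]
  if (spec$mode == "not_conserved") pos <- pos[vals[pos] < v_n]
  if (spec$require_native_match && length(pos)) {
    pos <- pos[substring(sequence, pos, pos) == disease_variant$wild_aa]
  }
  sort(pos)
}

#' Build a conservation-matched null variant set
#'
#' For every disease variant, null variants are placed at eligible
#' non-disease positions of the same protein (see [eligible_positions()]).
#' Case (i), `substitution_rule = "same_target"`: the null position is
#' mutated to the disease variant's mutant residue (an `I10L` disease
#' variant yields `ImL` nulls). Case (ii), `"random_snv"`: one random
#' SNV-possible substitution of the null position's native residue.
#' Variants whose eligible set is empty are skipped and counted.
#'
#' @param records A `variant_table` of disease variants.
#' @param proteins `protein_set` with every `protein_ref` present.
#' @param profiles Named list of `conservation_profile`s keyed by
#'   `protein_ref`.
#' @param spec A `sampling_spec`; with `exhaustive = TRUE` every eligible
#'   position is emitted ("all @" sets), otherwise one uniform draw per
#'   variant.
#' @param substitution_rule `"same_target"` (case i) or `"random_snv"`
#'   (case ii).
#' @param label Set label stored on the output (e.g. `"NotOMIM conserved"`).
#' @param seed Optional RNG seed for reproducible draws.
#' @return Object of class `sampled_set`: list with `label`, `variants`
#'   (variant-table data frame), `skip_count`, `n_input`.
#' @export
build_null_set <- function(records, proteins, profiles,
                           spec = sampling_spec(),
                           substitution_rule = c("same_target", "random_snv"),
                           label = spec$mode, seed = NULL) {
  substitution_rule <- match.arg(substitution_rule)
  if (!is.null(seed)) set.seed(seed)
  disease_by_protein <- split(records$position, records$protein_ref)
  out <- list()
  skip <- 0L
  for (i in seq_len(nrow(records))) {
    ref <- records$protein_ref[i]
    sequence <- get_sequence(proteins, ref)
    if (is.na(sequence)) stop("no sequence for protein '", ref, "'")
    profile <- profiles[[ref]]
    if (is.null(profile)) stop("no conservation profile for protein '", ref, "'")
    v <- new_variant(records$wild_aa[i], records$position[i], records$mut_aa[i])
    pos <- eligible_positions(sequence, profile, v,
                              known_disease_positions =
                                disease_by_protein[[ref]],
                              spec = spec)
    if (!length(pos)) {
      skip <- skip + 1L
      next
    }
    if (!spec$exhaustive) pos <- pos[sample.int(length(pos), 1L)]
    for (m in pos) {
      native <- substr(sequence, m, m)
      mut <- if (substitution_rule == "same_target") v$mut_aa
             else random_snv_variant(sequence, m)$mut_aa
      if (native == mut) next  # would be synonymous at the null position
      out[[length(out) + 1L]] <- data.frame(
        gene_symbol = records$gene_symbol[i], taxon_id = records$taxon_id[i],
        protein_ref = ref, variant = paste0(native, m, mut),
        label = label, source = paste0("null:", records$variant[i]),
        wild_aa = native, position = as.integer(m), mut_aa = mut,
        synonymous = FALSE, variant_type = "sav", stringsAsFactors = FALSE)
    }
  }
  variants <- if (length(out)) do.call(rbind, out) else
    data.frame(gene_symbol = character(0), taxon_id = integer(0),
               protein_ref = character(0), variant = character(0),
               label = character(0), source = character(0),
               wild_aa = character(0), position = integer(0),
               mut_aa = character(0), synonymous = logical(0),
               variant_type = character(0), stringsAsFactors = FALSE)
  class(variants) <- c("variant_table", "data.frame")
  structure(list(label = label, variants = variants, skip_count = skip,
                 n_input = nrow(records)),
            class = "sampled_set")
}

#' @export
print.sampled_set <- function(x, ...) {
  cat("Sampled set '", x$label, "': ", nrow(x$variants), " variants from ",
      x$n_input, " inputs (", x$skip_count, " skipped)\n", sep = "")
  invisible(x)
}

#' Conservation-threshold baseline predictor
#'
#' The trivial predictor: call every SNV-possible SAV at positions with
#' conservation above `tau` an effect, everything else neutral. Used to show
#' that a single conservation threshold over-predicts effect relative to a
#' curated disease set.
#'
#' @param sequence Protein sequence string.
#' @param profile Matching `conservation_profile`.
#' @param tau Conservation threshold in bits.
#' @param protein_ref Identifier for the output rows.
#' @return Data frame of effect calls: `protein_ref`, `variant`, `wild_aa`,
#'   `position`, `mut_aa`, `method`, `score` (the position's conservation)
#'   and `call`.
#' @export
conservation_threshold_baseline <- function(sequence, profile, tau,
                                            protein_ref = profile$protein_ref) {
  L <- nchar(sequence)
  stopifnot(length(profile$values) == L)
  rmap <- reachability_map()
  residues <- strsplit(sequence, "")[[1]]
  keep <- which(residues %in% AA_STANDARD)
  reach <- rmap[residues[keep]]
  k <- lengths(reach)
  pos <- rep(keep, k)
  wild <- rep(residues[keep], k)
  mut <- unlist(reach, use.names = FALSE)
  score <- profile$values[pos]
  data.frame(protein_ref = protein_ref,
             variant = paste0(wild, pos, mut),
             wild_aa = wild, position = pos, mut_aa = mut,
             method = "conservation_threshold", score = score,
             call = ifelse(score > tau, "effect", "neutral"),
             stringsAsFactors = FALSE)
}

#' Write / read a conservation profile as TSV
#'
#' Columns: `position`, `residue`, `information_bits`.
#'
#' @param profile A `conservation_profile`.
#' @param sequence Matching sequence string (for the residue column).
#' @param path File path.
#' @return `path` invisibly (writer); a `conservation_profile` (reader).
#' @export
write_profile_tsv <- function(profile, sequence, path) {
  df <- data.frame(position = seq_along(profile$values),
                   residue = strsplit(sequence, "")[[1]],
                   information_bits = profile$values)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_tsv
#' @param depth Alignment depth to record on the profile read back.
#' @param protein_ref Identifier stored with the profile.
#' @export
read_profile_tsv <- function(path, depth = NA_integer_, protein_ref = "") {
  df <- utils::read.delim(path, comment.char = "#")
  stopifnot(all(c("position", "information_bits") %in% names(df)))
  df <- df[order(df$position), ]
  structure(list(values = df$information_bits, depth = depth,
                 protein_ref = protein_ref),
            class = "conservation_profile")
}

#' Read information-per-position from a PSI-BLAST ASCII PSSM
#'
#' Parses the ASCII PSSM layout written by PSI-BLAST (`-out_ascii_pssm`):
#' after the header, each data row carries the position, the residue, 20
#' log-odds columns, 20 percentage columns, then the information per
#' position and the relative-weight column. Only the information column is
#' retained.
#'
#' @param path Path to the ASCII PSSM file.
#' @param protein_ref Identifier stored with the profile.
#' @return A `conservation_profile` (depth unknown, recorded as `NA`).
#' @export
read_psiblast_pssm <- function(path, protein_ref = "") {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  lines <- readLines(path)
  data_rows <- grep("^\\s*[0-9]+\\s+[A-Z]\\s", lines, value = TRUE)
  if (!length(data_rows)) stop("no PSSM data rows found in ", path)
  vals <- numeric(length(data_rows))
  pos <- integer(length(data_rows))
  for (i in seq_along(data_rows)) {
    parts <- strsplit(trimws(data_rows[i]), "\\s+")[[1]]
    if (length(parts) < 44L) {
      stop("PSSM row ", i, " has ", length(parts),
           " fields, expected >= 44 (position, residue, 2x20 columns, ",
           "information, weight)")
    }
    pos[i] <- as.integer(parts[1])
    vals[i] <- as.numeric(parts[43])
  }
  structure(list(values = vals[order(pos)], depth = NA_integer_,
                 protein_ref = protein_ref),
            class = "conservation_profile")
}
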