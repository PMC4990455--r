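MAX_BITS <- log2(20)

#' Specification of a synthetic protein family
#'
#' Families are simulated column-wise: each alignment column has a dominant
#' residue occurring with probability `q`, the remaining mass spread
#' uniformly over the other 19 residues. `q` is solved numerically per
#' position so that the column's expected information content (relative
#' entropy vs the uniform background) hits a target drawn from a scaled Beta
#' distribution — giving direct control of the quantity the sampling logic
#' consumes.
#'
#' @param n_sequences Alignment depth (>= 2; default 200).
#' @param length Protein length in residues (default 300; must exceed twice
#'   the edge exclusion used downstream).
#' @param conservation_shape List with Beta parameters `shape1`, `shape2`
#'   of the per-position target information distribution (scaled to
#'   `[0, log2(20)]` bits), or an explicit numeric vector `target_bits` of
#'   length `length`.
#' @param seed RNG seed for the family.
#' @return A list of class `family_spec`.
#' @export
family_spec <- function(n_sequences = 200L, length = 300L,
                        conservation_shape = list(shape1 = 1.5, shape2 = 3),
                        seed = 1L) {
  stopifnot(n_sequences >= 2L, length > 20L)
  structure(list(n_sequences = as.integer(n_sequences),
                 length = as.integer(length),
                 conservation_shape = conservation_shape,
                 seed = as.integer(seed)),
            class = "family_spec")
}

# expected information (bits, uniform background) of a dominant-residue
# column with dominance q: q*log2(20q) + (1-q)*log2(20(1-q)/19)
dominance_information <- function(q) {
  i1 <- ifelse(q > 0, q * log2(20 * q), 0)
  i2 <- ifelse(q < 1, (1 - q) * log2(20 * (1 - q) / 19), 0)
  i1 + i2
}

# invert dominance_information on [1/20, 1]
solve_dominance <- function(target_bits) {
  vapply(target_bits, function(tb) {
    if (tb <= 0) return(1 / 20)
    if (tb >= MAX_BITS - 1e-9) return(1)
    stats::uniroot(function(q) dominance_information(q) - tb,
                   lower = 1 / 20, upper = 1 - 1e-12,
                   tol = 1e-10)$root
  }, numeric(1))
}

#' Generate a synthetic protein family
#'
#' Draws an ungapped MSA from per-position dominant-residue distributions
#' (see [family_spec()]), takes the first row as the reference protein, and
#' computes its conservation profile.
#'
#' @param spec A `family_spec`.
#' @param protein_ref Identifier for the reference protein.
#' @param pseudocount Pseudocount for the realized profile (default
#'   `1/depth`; use 0 for the raw closed-form checks).
#' @return List of class `synthetic_family`: `reference` (a one-row
#'   `protein_set`), `msa` (character vector), `profile`
#'   (`conservation_profile`), `target_bits`, `dominant` (residue per
#'   position).
#' @export
generate_family <- function(spec, protein_ref = "synfam1", pseudocount = NULL) {
  stopifnot(inherits(spec, "family_spec"))
  set.seed(spec$seed)
  L <- spec$length; n <- spec$n_sequences
  cs <- spec$conservation_shape
  if (!is.null(cs$target_bits)) {
    target <- cs$target_bits
    if (length(target) != L) stop("target_bits must have length ", L)
  } else {
    if (is.null(cs$shape1) || is.null(cs$shape2)) {
      stop("conservation_shape needs shape1/shape2 or target_bits")
    }
    target <- MAX_BITS * stats::rbeta(L, cs$shape1, cs$shape2)
  }
  q <- solve_dominance(target)
  dominant <- sample(AA_STANDARD, L, replace = TRUE)
  cols <- matrix("", nrow = n, ncol = L)
  for (p in seq_len(L)) {
    others <- AA_STANDARD[AA_STANDARD != dominant[p]]
    take_dom <- stats::runif(n) < q[p]
    cols[, p] <- ifelse(take_dom, dominant[p],
                        sample(others, n, replace = TRUE))
  }
  msa <- apply(cols, 1, paste, collapse = "")
  profile <- conservation_profile(msa, 1L, pseudocount = pseudocount,
                                  protein_ref = protein_ref)
  reference <- structure(
    data.frame(id = protein_ref, description = "synthetic family reference",
               sequence = msa[1], stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame"))
  structure(list(reference = reference, msa = msa, profile = profile,
                 target_bits = target, dominant = dominant),
            class = "synthetic_family")
}

#' Plant disease variants at conserved positions
#'
#' Places `k` SAVs at distinct positions whose conservation reaches at least
#' the requested profile quantile, outside the terminal exclusion zone —
#' emulating the observation that curated disease SAVs sit at well-conserved
#' positions. Mutant residues are drawn from the SNV-possible set of the
#' native residue.
#'
#' @param family A `synthetic_family`.
#' @param k Number of variants to plant.
#' @param conservation_quantile Profile quantile the planted positions must
#'   reach (default 0.9).
#' @param edge_exclusion Terminal residues excluded (default 10).
#' @param taxon_id,gene_symbol,label Provenance fields for the records.
#' @return A `variant_table` data frame with an extra logical `planted`
#'   column (all `TRUE`).
#' @export
plant_disease_variants <- function(family, k, conservation_quantile = 0.9,
                                   edge_exclusion = 10L,
                                   taxon_id = 9606L,
                                   gene_symbol = family$profile$protein_ref,
                                   label = "disease") {
  vals <- family$profile$values
  L <- length(vals)
  cut <- stats::quantile(vals, conservation_quantile, names = FALSE)
  pos <- which(vals >= cut)
  pos <- pos[pos > edge_exclusion & pos <= L - edge_exclusion]
  if (k > length(pos)) {
    stop("cannot plant ", k, " variants: only ", length(pos),
         " eligible conserved positions")
  }
  if (k == 0L) {
    out <- data.frame(gene_symbol = character(0), taxon_id = integer(0),
                      protein_ref = character(0), variant = character(0),
                      label = character(0), source = character(0),
                      wild_aa = character(0), position = integer(0),
                      mut_aa = character(0), synonymous = logical(0),
                      variant_type = character(0), planted = logical(0))
    class(out) <- c("variant_table", "data.frame")
    return(out)
  }
  chosen <- sort(pos[sample.int(length(pos), k)])
  seqs <- family$reference$sequence[1]
  rows <- lapply(chosen, function(p) {
    v <- random_snv_variant(seqs, p)
    data.frame(gene_symbol = gene_symbol, taxon_id = taxon_id,
               protein_ref = family$reference$id[1],
               variant = v$variant, label = label, source = "planted",
               wild_aa = v$wild_aa, position = v$position, mut_aa = v$mut_aa,
               synonymous = FALSE, variant_type = "sav", planted = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Simulate an ortholog of a reference protein
#'
#' Substitutions occur with per-position probability decreasing in
#' conservation (normalized so the expected substituted fraction equals
#' `divergence`), drawn from the SNV-possible set. Single-residue deletions
#' and insertions occur at per-position rates `del_rate` / `ins_rate`; by
#' default indels are restricted to below-median-conservation positions so
#' conserved (disease-carrying) positions exercise the transferred /
#' synonymous paths deterministically.
#'
#' @param family A `synthetic_family` (reference + profile).
#' @param divergence Expected substituted fraction of positions, in
#'   `[0, 1)`.
#' @param del_rate,ins_rate Per-position single-residue deletion /
#'   insertion probabilities.
#' @param restrict_indels If `TRUE` (default), indels only at positions
#'   with below-median conservation; if `FALSE`, anywhere.
#' @param id Identifier of the simulated ortholog.
#' @return List of class `synthetic_ortholog`: `sequence` (one-row
#'   `protein_set`), `substituted`, `deleted` (reference positions),
#'   `inserted_after` (reference positions followed by an insertion).
#' @export
generate_ortholog <- function(family, divergence = 0.1, del_rate = 0,
                              ins_rate = 0, restrict_indels = TRUE,
                              id = paste0(family$reference$id[1], "_ortholog")) {
  stopifnot(divergence >= 0, divergence < 1)
  ref <- family$reference$sequence[1]
  L <- nchar(ref)
  vals <- family$profile$values
  cn <- pmin(pmax(vals / MAX_BITS, 0), 1)
  w <- 1 - cn
  r <- if (divergence == 0 || mean(w) == 0) rep(0, L)
       else pmin(divergence * w / mean(w), 0.95)
  residues <- strsplit(ref, "")[[1]]
  sub_pos <- which(stats::runif(L) < r)
  for (p in sub_pos) {
    residues[p] <- sample(snv_reachable(residues[p]), 1L)
  }
  indel_ok <- if (restrict_indels) vals < stats::median(vals) else rep(TRUE, L)
  del_pos <- which(stats::runif(L) < del_rate & indel_ok)
  ins_pos <- which(stats::runif(L) < ins_rate & indel_ok)
  pieces <- residues
  pieces[del_pos] <- ""
  for (p in ins_pos) {
    pieces[p] <- paste0(pieces[p], sample(AA_STANDARD, 1L))
  }
  seq_out <- paste(pieces, collapse = "")
  sequence <- structure(
    data.frame(id = id, description = "synthetic ortholog",
               sequence = seq_out, stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame"))
  structure(list(sequence = sequence, substituted = sub_pos,
                 deleted = del_pos, inserted_after = ins_pos),
            class = "synthetic_ortholog")
}

#' Specification of the synthetic effect predictor
#'
#' Scores are drawn from a logistic model on the conservation (in bits) of
#' the variant position and a planted-effect indicator:
#' `score = plogis(intercept + w_c * bits + w_e * planted + noise)`.
#' Defaults make conservation the dominant signal (as for an alignment-based
#' predictor that never sees disease labels), with the planted-effect term a
#' smaller boost.
#'
#' @param intercept Logit intercept (default -6).
#' @param conservation_weight Logit units per bit of conservation
#'   (default 2).
#' @param planted_effect_weight Logit boost for planted disease variants
#'   (default 2).
#' @param noise_sd Gaussian noise on the logit scale (default 0.5).
#' @param method Method name stamped on the score records.
#' @return A list of class `predictor_spec`.
#' @export
predictor_spec <- function(intercept = -6, conservation_weight = 2,
                           planted_effect_weight = 2, noise_sd = 0.5,
                           method = "synpred") {
  structure(list(intercept = intercept,
                 conservation_weight = conservation_weight,
                 planted_effect_weight = planted_effect_weight,
                 noise_sd = noise_sd, method = method),
            class = "predictor_spec")
}

#' Generate predictor scores for a set of variants
#'
#' @param variants Variant data frame (needs `protein_ref`, `variant`,
#'   `position`; a logical `planted` column marks planted disease variants,
#'   otherwise the `planted` argument is used).
#' @param profile `conservation_profile` of the variants' protein.
#' @param pspec A `predictor_spec`.
#' @param planted Optional logical vector overriding the `planted` column.
#' @return Score-table data frame: `protein_ref`, `variant`, `method`,
#'   `score` plus the variant coordinate columns.
#' @export
generate_scores <- function(variants, profile, pspec = predictor_spec(),
                            planted = NULL) {
  n <- nrow(variants)
  if (is.null(planted)) {
    planted <- if ("planted" %in% names(variants)) variants$planted
               else rep(FALSE, n)
  }
  if (length(planted) == 1L) planted <- rep(planted, n)
  stopifnot(length(planted) == n)
  if (n == 0L) {
    return(data.frame(protein_ref = character(0), variant = character(0),
                      method = character(0), score = numeric(0)))
  }
  bits <- profile$values[variants$position]
  logit <- pspec$intercept + pspec$conservation_weight * bits +
    pspec$planted_effect_weight * as.numeric(planted) +
    stats::rnorm(n, 0, pspec$noise_sd)
  data.frame(protein_ref = variants$protein_ref, variant = variants$variant,
             method = pspec$method, score = stats::plogis(logit),
             wild_aa = variants$wild_aa, position = variants$position,
             mut_aa = variants$mut_aa, stringsAsFactors = FALSE)
}
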