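#' Alignment parameters for global affine-gap alignment
#'
#' Cost model: a gap run of length `k` costs `gap_open + (k - 1) * gap_extend`
#' (the first gap character is charged the opening cost, each further
#' character the extension cost). Terminal gaps are penalized by default.
#'
#' @param matrix Substitution matrix (see [read_matrix()]); defaults to the
#'   packaged BLOSUM62.
#' @param gap_open Score for the first character of a gap run (<= 0).
#' @param gap_extend Score for each further gap character (<= 0).
#' @param penalize_end_gaps If `FALSE`, terminal gap runs are free
#'   (ends-free global alignment).
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(matrix = NULL, gap_open = -10, gap_extend = -0.5,
                             penalize_end_gaps = TRUE) {
  if (is.null(matrix)) {
    matrix <- read_matrix(system.file("extdata", "BLOSUM62.txt",
                                      package = "savlink"))
  }
  stopifnot(gap_open <= 0, gap_extend <= 0)
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend,
                 penalize_end_gaps = penalize_end_gaps),
            class = "alignment_params")
}

#' Global pairwise alignment with affine gap costs
#'
#' Optimal global alignment of two protein sequences under the cost model of
#' [alignment_params()]. The dynamic programming is delegated to
#' [Biostrings::pairwiseAlignment()] with the gap penalties mapped onto its
#' convention; the score and aligned strings follow this package's cost
#' model (verified against exhaustive enumeration in the test suite).
#'
#' @param a,b Protein sequence strings (sequence A = source, B = target).
#' @param params An `alignment_params` object.
#' @return A list of class `pairwise_alignment` with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings) and `score`.
#' @export
global_align <- function(a, b, params = alignment_params()) {
  stopifnot(is.character(a), is.character(b), length(a) == 1L, length(b) == 1L)
  if (!nzchar(a) || !nzchar(b)) {
    # degenerate: one (or both) empty -> a single all-gap run
    k <- max(nchar(a), nchar(b))
    sc <- if (k == 0L || !params$penalize_end_gaps) 0
          else params$gap_open + (k - 1L) * params$gap_extend
    return(structure(list(aligned_a = paste0(a, strrep("-", nchar(b))),
                          aligned_b = paste0(strrep("-", nchar(a)), b),
                          score = sc),
                     class = "pairwise_alignment"))
  }
  letters_ab <- unique(strsplit(paste0(a, b), "")[[1]])
  missing <- setdiff(letters_ab, rownames(params$matrix))
  if (length(missing)) {
    stop("residue(s) absent from substitution matrix: ",
         paste(missing, collapse = ", "))
  }
  # Biostrings charges gapOpening + k * gapExtension for a length-k run;
  # shift the opening cost so a length-k run costs open + (k-1) * extend.
  pa <- Biostrings::pairwiseAlignment(
    a, b,
    substitutionMatrix = params$matrix,
    gapOpening = -(params$gap_open - params$gap_extend),
    gapExtension = -params$gap_extend,
    type = if (params$penalize_end_gaps) "global" else "overlap"
  )
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  if (!params$penalize_end_gaps) {
    # overlap alignments are clipped; restore unaligned terminal pieces,
    # stacking leading/trailing overhangs against gaps
    sp <- pa@pattern@range@start
    ep <- sp + pa@pattern@range@width - 1L
    ss <- pa@subject@range@start
    es <- ss + pa@subject@range@width - 1L
    pre_a <- substr(a, 1L, sp - 1L); pre_b <- substr(b, 1L, ss - 1L)
    post_a <- substr(a, ep + 1L, nchar(a)); post_b <- substr(b, es + 1L, nchar(b))
    al_a <- paste0(pre_a, strrep("-", nchar(pre_b)), al_a,
                   post_a, strrep("-", nchar(post_b)))
    al_b <- paste0(strrep("-", nchar(pre_a)), pre_b, al_b,
                   strrep("-", nchar(post_a)), post_b)
  }
  structure(list(aligned_a = al_a, aligned_b = al_b,
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("A:", x$aligned_a, "\nB:", x$aligned_b, "\nscore:", x$score, "\n")
  invisible(x)
}

#' Exhaustive-enumeration alignment score
#'
#' Brute-force reference: enumerates every global alignment of the two
#' sequences (no double-gap columns) and returns the maximal score under the
#' [alignment_params()] cost model. Exponential; intended for short
#' sequences and for cross-checking [global_align()].
#'
#' @inheritParams global_align
#' @return The optimal score (numeric scalar).
#' @export
align_score_bruteforce <- function(a, b, params = alignment_params()) {
  sm <- params$matrix
  ai <- match(strsplit(a, "")[[1]], rownames(sm)) - 1L
  bi <- match(strsplit(b, "")[[1]], colnames(sm)) - 1L
  if (anyNA(ai) || anyNA(bi)) stop("residue absent from substitution matrix")
  enumerate_align_score(ai, bi, sm, params$gap_open, params$gap_extend,
                        params$penalize_end_gaps)
}

#' Map each position of sequence A to its aligned position in B
#'
#' @param alignment A `pairwise_alignment`.
#' @return Integer vector of length `nchar(ungapped A)`: for each 1-based
#'   A-position, the 1-based B-position sharing its column, or `NA` where A
#'   is aligned against a gap.
#' @export
coordinate_map <- function(alignment) {
  ca <- strsplit(alignment$aligned_a, "")[[1]]
  cb <- strsplit(alignment$aligned_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  map <- integer(0)
  pb <- 0L
  for (i in seq_along(ca)) {
    if (cb[i] != "-") pb <- pb + 1L
    if (ca[i] != "-") map <- c(map, if (cb[i] == "-") NA_integer_ else pb)
  }
  map
}

#' Transfer one variant through a coordinate map
#'
#' Lifts the variant's position into the target sequence. Variants whose
#' position is aligned against a gap are dropped; variants whose target
#' native residue already equals the mutant are dropped as
#' synonymous-in-target (the "variant" would be a synonymous `Y2Y`). The
#' wild/mutant letters are never rewritten to the target's residues.
#'
#' @param variant A `variant` object.
#' @param map Output of [coordinate_map()] for the source->target alignment.
#' @param target Target protein sequence string.
#' @return A list with `status` (`transferred`, `dropped_gap` or
#'   `dropped_synonymous`), `variant` (the lifted `variant`, or `NULL`), and
#'   `target_native` (residue at the mapped position, or `NA`).
#' @export
transfer_variant <- function(variant, map, target) {
  stopifnot(inherits(variant, "variant"))
  if (variant$position < 1L || variant$position > length(map)) {
    stop("variant position ", variant$position,
         " outside source sequence of length ", length(map))
  }
  tp <- map[variant$position]
  if (is.na(tp)) {
    return(list(status = "dropped_gap", variant = NULL,
                target_native = NA_character_))
  }
  native <- substr(target, tp, tp)
  if (native == variant$mut_aa) {
    return(list(status = "dropped_synonymous", variant = NULL,
                target_native = native))
  }
  list(status = "transferred",
       variant = new_variant(variant$wild_aa, tp, variant$mut_aa),
       target_native = native)
}

#' Transfer a table of variants into an aligned target sequence
#'
#' @param records A `variant_table`-shaped data frame (needs `wild_aa`,
#'   `position`, `mut_aa`).
#' @param map Output of [coordinate_map()].
#' @param target Target protein sequence string.
#' @return Data frame with one row per input variant: `source_variant`,
#'   `status`, `target_variant`, `target_native`.
#' @export
transfer_variants <- function(records, map, target) {
  n <- nrow(records)
  status <- character(n); tv <- rep(NA_character_, n); tn <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    v <- new_variant(records$wild_aa[i], records$position[i], records$mut_aa[i])
    res <- transfer_variant(v, map, target)
    status[i] <- res$status
    tn[i] <- res$target_native
    if (res$status == "transferred") tv[i] <- format_variant(res$variant)
  }
  data.frame(source_variant = paste0(records$wild_aa, records$position,
                                     records$mut_aa),
             status = status, target_variant = tv, target_native = tn,
             stringsAsFactors = FALSE)
}

#' Fraction of variant positions with identical native residues
#'
#' Fraction of variant positions that map without a gap and whose native
#' residue agrees between source and target (the cross-species "native
#' identity" of disease positions).
#'
#' @param records Variant data frame with a `position` column.
#' @param map Output of [coordinate_map()].
#' @param source,target Source and target sequence strings.
#' @return A fraction in `[0, 1]` (0 for an empty table).
#' @export
native_identity_fraction <- function(records, map, source, target) {
  if (nrow(records) == 0L) return(0)
  ok <- vapply(records$position, function(p) {
    tp <- map[p]
    !is.na(tp) && substr(source, p, p) == substr(target, tp, tp)
  }, logical(1))
  mean(ok)
}

#' Write an aligned pair as gapped FASTA
#'
#' @param alignment A `pairwise_alignment`.
#' @param ids Character vector of two sequence identifiers.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_alignment_fasta <- function(alignment, ids, path) {
  writeLines(c(paste0(">", ids[1]), alignment$aligned_a,
               paste0(">", ids[2]), alignment$aligned_b), path)
  invisible(path)
}
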