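VALIDATION_STATUSES <- c("match", "match_shift1", "mismatch", "no_sequence",
                         "synonymous", "aa_deletion", "nonsense")

#' Validate a curated variant annotation against a sequence
#'
#' Reproduces the curation attrition protocol for annotated SAVs: a variant
#' `XnY` matches if the sequence carries `X` at position `n`; failing that, a
#' single `+1` shift is tried (`X` at `n + 1`), which accounts for database
#' sequences stored without the initiator methionine; anything else is a
#' mismatch. Synonymous annotations (`X == Y`) and absent sequences get their
#' own statuses. Only the literal `+1` shift is attempted, never other
#' offsets.
#'
#' @param variant A `variant` object (see [parse_variant()]).
#' @param sequence Protein sequence string, or `NA` if no sequence was found.
#' @param variant_type Annotation type: `"sav"` (default), `"aa_deletion"`
#'   or `"nonsense"`; the latter two are recorded and excluded from SAV
#'   analysis.
#' @return A list with `status` (one of `match`, `match_shift1`, `mismatch`,
#'   `no_sequence`, `synonymous`, `aa_deletion`, `nonsense`) and
#'   `corrected_position` (`n`, or `n + 1` for shift matches, else `NA`).
#' @examples
#' validate_variant(parse_variant("A2L"), "MALK")    # match
#' validate_variant(parse_variant("A2L"), "XGALK")   # match_shift1 at 3
#' @export
validate_variant <- function(variant, sequence, variant_type = "sav") {
  stopifnot(inherits(variant, "variant"))
  if (variant_type %in% c("aa_deletion", "nonsense")) {
    return(list(status = variant_type, corrected_position = NA_integer_))
  }
  if (length(sequence) != 1L || is.na(sequence)) {
    return(list(status = "no_sequence", corrected_position = NA_integer_))
  }
  if (variant$synonymous) {
    return(list(status = "synonymous", corrected_position = NA_integer_))
  }
  n <- variant$position
  at <- function(p) if (p >= 1L && p <= nchar(sequence)) substr(sequence, p, p) else ""
  if (at(n) == variant$wild_aa) {
    return(list(status = "match", corrected_position = n))
  }
  if (at(n + 1L) == variant$wild_aa) {
    return(list(status = "match_shift1", corrected_position = n + 1L))
  }
  list(status = "mismatch", corrected_position = NA_integer_)
}

#' Build an attrition report for a curated variant set
#'
#' Applies [validate_variant()] to every record and tallies the outcomes.
#' Retained records are the plain and `+1`-shift matches; shift matches carry
#' their corrected position in the output.
#'
#' @param records A `variant_table` data frame (see [read_variant_table()]).
#' @param proteins A `protein_set` data frame; records whose `protein_ref`
#'   is absent count as `no_sequence`.
#' @return An object of class `attrition_report`: list with `counts` (named
#'   integer vector over all statuses), `total`, and `retained` (the
#'   surviving records with corrected `position` and a `shifted` flag).
#' @export
build_attrition_report <- function(records, proteins) {
  counts <- stats::setNames(integer(length(VALIDATION_STATUSES)),
                            VALIDATION_STATUSES)
  n <- nrow(records)
  keep <- logical(n)
  shifted <- logical(n)
  corrected <- records$position
  for (i in seq_len(n)) {
    v <- new_variant(records$wild_aa[i], records$position[i], records$mut_aa[i])
    res <- validate_variant(v, get_sequence(proteins, records$protein_ref[i]),
                            records$variant_type[i])
    counts[res$status] <- counts[res$status] + 1L
    if (res$status %in% c("match", "match_shift1")) {
      keep[i] <- TRUE
      corrected[i] <- res$corrected_position
      shifted[i] <- res$status == "match_shift1"
    }
  }
  retained <- records[keep, , drop = FALSE]
  retained$position <- corrected[keep]
  retained$variant <- paste0(retained$wild_aa, retained$position, retained$mut_aa)
  retained$shifted <- shifted[keep]
  structure(list(counts = counts, total = n, retained = retained),
            class = "attrition_report")
}

#' @export
print.attrition_report <- function(x, ...) {
  cat("Attrition report:", x$total, "annotations,",
      nrow(x$retained), "retained\n")
  print(x$counts)
  invisible(x)
}

#' Write an attrition report to TSV and JSON
#'
#' @param report An `attrition_report`.
#' @param tsv,json,retained_tsv Optional output paths; `NULL` skips a file.
#' @return The report, invisibly.
#' @export
write_attrition_report <- function(report, tsv = NULL, json = NULL,
                                   retained_tsv = NULL) {
  if (!is.null(tsv)) {
    df <- data.frame(status = names(report$counts),
                     count = as.integer(report$counts))
    utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(total = report$total, retained = nrow(report$retained),
           counts = as.list(report$counts)),
      json, auto_unbox = TRUE, pretty = TRUE)
  }
  if (!is.null(retained_tsv)) write_variant_table(report$retained, retained_tsv)
  invisible(report)
}
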