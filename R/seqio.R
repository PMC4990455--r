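#' @useDynLib savlink, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# 20 standard residues, alphabetical; 'X' allowed in sequences as unknown
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALPHABET <- c(AA_STANDARD, "X")

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased on read and restricted to the 20 standard amino
#' acid one-letter codes plus `X` (unknown residue).
#'
#' @param path Path to a FASTA file.
#' @return A data frame of class `protein_set` with columns `id`,
#'   `description` and `sequence`, one row per FASTA entry, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "MALW"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  # validate the raw entries first: the AAStringSet reader silently drops
  # letters outside its alphabet, which would mask annotation errors
  lines <- readLines(path)
  headers <- grepl("^>", lines)
  if (!any(headers) || !headers[1]) stop("malformed FASTA header in ", path)
  entry <- cumsum(headers)
  raw_ids <- sub("^>(\\S*).*$", "\\1", lines[headers])
  for (e in unique(entry)) {
    body <- toupper(paste(lines[entry == e & !headers], collapse = ""))
    if (!nzchar(body)) {
      stop("empty sequence for FASTA entry '", raw_ids[e], "'")
    }
    bad <- setdiff(unique(strsplit(body, "")[[1]]), AA_ALPHABET)
    if (length(bad)) {
      stop("FASTA entry '", raw_ids[e], "' contains non amino-acid ",
           "characters: ", paste(bad, collapse = ", "))
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  full <- names(aa)
  id <- sub("\\s.*$", "", full)
  desc <- ifelse(grepl("\\s", full), sub("^\\S+\\s+", "", full), "")
  seqs <- toupper(as.character(aa))
  structure(
    data.frame(id = id, description = desc, sequence = unname(seqs),
               stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame")
  )
}

#' Write a protein set to FASTA
#'
#' @param proteins A `protein_set` data frame (or any data frame with `id`,
#'   `description`, `sequence` columns).
#' @param path Output file path.
#' @param width Line width for wrapping sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(proteins)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    desc <- if ("description" %in% names(proteins)) proteins$description[i] else ""
    header <- if (nzchar(desc)) paste(proteins$id[i], desc) else proteins$id[i]
    writeLines(paste0(">", header), con)
    s <- proteins$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Look up one sequence in a protein set
#'
#' @param proteins A `protein_set` data frame.
#' @param id Sequence identifier.
#' @return The sequence string, or `NA_character_` if absent.
#' @export
get_sequence <- function(proteins, id) {
  i <- match(id, proteins$id)
  if (is.na(i)) NA_character_ else proteins$sequence[i]
}

#' Parse a variant string in XnY notation
#'
#' A SAV is written `XnY`: wild-type residue `X` at 1-based position `n`
#' substituted by `Y`, e.g. `"A11W"`. Strings with identical wild-type and
#' mutant letters parse but are flagged synonymous.
#'
#' @param text A single variant string.
#' @return A list of class `variant` with elements `wild_aa`, `position`,
#'   `mut_aa` and `synonymous`.
#' @examples
#' parse_variant("A11W")
#' @export
parse_variant <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec("^([A-Za-z])([0-9]+)([A-Za-z])$", text))[[1]]
  if (length(m) != 4L) stop("malformed variant string: '", text, "'")
  wild <- toupper(m[2]); mut <- toupper(m[4])
  pos <- suppressWarnings(as.integer(m[3]))
  if (is.na(pos) || pos < 1L) stop("variant position must be >= 1 in '", text, "'")
  if (!(wild %in% AA_STANDARD)) stop("unknown wild-type residue '", wild, "' in '", text, "'")
  if (!(mut %in% AA_STANDARD)) stop("unknown mutant residue '", mut, "' in '", text, "'")
  new_variant(wild, pos, mut)
}

new_variant <- function(wild, pos, mut) {
  structure(list(wild_aa = wild, position = as.integer(pos), mut_aa = mut,
                 synonymous = identical(wild, mut)),
            class = "variant")
}

#' Format a variant back to XnY notation
#'
#' @param v A `variant` object.
#' @return The `XnY` string.
#' @export
format_variant <- function(v) {
  paste0(v$wild_aa, v$position, v$mut_aa)
}

#' @export
print.variant <- function(x, ...) {
  cat(format_variant(x), if (x$synonymous) "(synonymous)" else "", "\n")
  invisible(x)
}

#' Read a curated variant table
#'
#' Tab-separated, `#` comment lines allowed, header row with at least the
#' columns `gene_symbol`, `taxon_id`, `protein_ref`, `variant`, `label`,
#' `source`. Each variant string is parsed via [parse_variant()] into
#' `wild_aa` / `position` / `mut_aa` columns. An optional `variant_type`
#' column (values `sav`, `aa_deletion`, `nonsense`) is carried through for
#' attrition accounting.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `variant_table`, one row per input row, in
#'   file order.
#' @export
read_variant_table <- function(path) {
  if (!file.exists(path)) stop("variant table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  required <- c("gene_symbol", "taxon_id", "protein_ref", "variant",
                "label", "source")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("variant table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$taxon_id <- as.integer(df$taxon_id)
  if (any(is.na(df$taxon_id) | df$taxon_id <= 0L)) {
    stop("variant table ", path, ": taxon_id must be a positive integer (row ",
         which(is.na(df$taxon_id) | df$taxon_id <= 0L)[1], ")")
  }
  n <- nrow(df)
  wild <- character(n); pos <- integer(n); mut <- character(n); syn <- logical(n)
  for (i in seq_len(n)) {
    v <- tryCatch(parse_variant(df$variant[i]),
                  error = function(e) stop("row ", i, " of ", path, ": ",
                                           conditionMessage(e), call. = FALSE))
    wild[i] <- v$wild_aa; pos[i] <- v$position; mut[i] <- v$mut_aa
    syn[i] <- v$synonymous
  }
  df$wild_aa <- wild; df$position <- pos; df$mut_aa <- mut
  df$synonymous <- syn
  if (!"variant_type" %in% names(df)) df$variant_type <- "sav"
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Write a variant table to TSV
#'
#' @param records A `variant_table`-shaped data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(records, path) {
  cols <- intersect(c("gene_symbol", "taxon_id", "protein_ref", "variant",
                      "label", "source", "variant_type"), names(records))
  utils::write.table(records[, cols, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-variant prediction score table
#'
#' Tab-separated with header columns `protein_ref`, `variant`, `method`,
#' `score`. Missing scores (pre-binarized imports) may be given as `NA`.
#'
#' @param path Path to the TSV file.
#' @return A data frame with parsed variant columns added.
#' @export
read_score_table <- function(path) {
  if (!file.exists(path)) stop("score table not found: ", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  required <- c("protein_ref", "variant", "method", "score")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("score table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df$score <- as.numeric(df$score)
  key <- paste(df$protein_ref, df$variant, df$method)
  if (anyDuplicated(key)) {
    stop("score table ", path, ": duplicate (protein, variant, method) entries")
  }
  for (i in seq_len(nrow(df))) parse_variant(df$variant[i])  # validate
  df
}

#' Read a substitution matrix in NCBI text format
#'
#' Parses the standard NCBI matrix layout: `#` comment lines, a header row of
#' residue letters, then one row per residue. The matrix must be symmetric
#' and cover all 20 standard residues.
#'
#' @param path Path to the matrix file (e.g. the packaged BLOSUM62:
#'   `system.file("extdata", "BLOSUM62.txt", package = "savlink")`).
#' @return A symmetric numeric matrix with residue dimnames.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop("matrix file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("matrix file ", path, " has no data rows")
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  n <- length(header)
  m <- matrix(NA_real_, n, n, dimnames = list(header, header))
  for (ln in lines[-1]) {
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != n + 1L) {
      stop("matrix row for '", parts[1], "' has ", length(parts) - 1L,
           " entries, expected ", n)
    }
    m[parts[1], ] <- as.numeric(parts[-1])
  }
  missing <- setdiff(AA_STANDARD, header)
  if (length(missing)) {
    stop("matrix is missing standard residue(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(m)) stop("matrix file ", path, ": incomplete rows")
  if (!isTRUE(all.equal(m, t(m), tolerance = 0))) {
    stop("matrix file ", path, " is not symmetric")
  }
  m
}
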