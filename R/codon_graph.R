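#' The standard genetic code
#'
#' @return A named character vector mapping all 64 codons (DNA alphabet) to
#'   amino-acid one-letter codes, with `*` for stop codons.
#' @export
standard_genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

#' Read a codon translation table from text
#'
#' Accepts the NCBI-style compact layout, i.e. lines
#' `AAs = FFLL...`, `Base1 = TTTT...`, `Base2 = ...`, `Base3 = ...`
#' (a `Starts` line, if present, is ignored), or a plain two-column
#' `codon<TAB>aa` table.
#'
#' @param path Path to the codon-table file.
#' @return A named character vector in the shape of
#'   [standard_genetic_code()].
#' @export
read_codon_table <- function(path) {
  if (!file.exists(path)) stop("codon table not found: ", path)
  lines <- readLines(path)
  get_field <- function(key) {
    ln <- grep(paste0("^\\s*", key, "\\s*="), lines, value = TRUE)
    if (!length(ln)) return(NULL)
    gsub("\\s", "", sub("^[^=]*=", "", ln[1]))
  }
  aas <- get_field("AAs")
  if (!is.null(aas)) {
    b1 <- get_field("Base1"); b2 <- get_field("Base2"); b3 <- get_field("Base3")
    if (is.null(b1) || is.null(b2) || is.null(b3)) {
      stop("codon table ", path, ": AAs line present but Base1/2/3 missing")
    }
    codons <- paste0(strsplit(b1, "")[[1]], strsplit(b2, "")[[1]],
                     strsplit(b3, "")[[1]])
    code <- strsplit(aas, "")[[1]]
    names(code) <- codons
  } else {
    df <- utils::read.delim(path, comment.char = "#", header = FALSE,
                            stringsAsFactors = FALSE)
    code <- toupper(df[[2]]); names(code) <- toupper(df[[1]])
  }
  validate_genetic_code(code)
  code
}

validate_genetic_code <- function(code) {
  if (length(code) != 64L) stop("genetic code must have 64 codons, got ", length(code))
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  if (!setequal(names(code), all64)) stop("genetic code does not cover all 64 codons")
  coded <- setdiff(unique(code), "*")
  missing <- setdiff(AA_STANDARD, coded)
  if (length(missing)) {
    stop("genetic code encodes no codon for: ", paste(missing, collapse = ", "))
  }
  invisible(code)
}

#' Amino acids reachable from a residue by one nucleotide change
#'
#' For each codon of `aa`, every single-base edit is translated; the union of
#' products, excluding `aa` itself and stop codons, is the SNV-possible
#' substitution set of the residue.
#'
#' @param aa A standard amino-acid one-letter code.
#' @param code Genetic code (default: standard nuclear code).
#' @return Sorted character vector of reachable amino-acid letters.
#' @examples
#' snv_reachable("W")  # R, G, S, L, C
#' @export
snv_reachable <- function(aa, code = standard_genetic_code()) {
  stopifnot(is.character(aa), length(aa) == 1L)
  if (!(aa %in% AA_STANDARD)) stop("not a standard residue: '", aa, "'")
  codons <- names(code)[code == aa]
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (codon in codons) {
    cs <- strsplit(codon, "")[[1]]
    for (p in 1:3) {
      for (b in setdiff(bases, cs[p])) {
        edited <- cs
        edited[p] <- b
        out <- c(out, unname(code[paste(edited, collapse = "")]))
      }
    }
  }
  sort(setdiff(unique(out), c(aa, "*")))
}

#' Full SNV reachability map of a genetic code
#'
#' @param code Genetic code.
#' @return Named list: per standard residue, its [snv_reachable()] set.
#' @export
reachability_map <- function(code = standard_genetic_code()) {
  stats::setNames(lapply(AA_STANDARD, snv_reachable, code = code), AA_STANDARD)
}

#' Total number of directed SNV-possible substitution edges
#'
#' @param code Genetic code.
#' @return Integer count of (residue, reachable residue) pairs.
#' @export
snv_edge_count <- function(code = standard_genetic_code()) {
  sum(lengths(reachability_map(code)))
}

#' Write a reachability map as TSV
#'
#' @param map Output of [reachability_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_reachability_tsv <- function(map, path) {
  df <- data.frame(aa = names(map),
                   reachable_set = vapply(map, paste, "", collapse = ","))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

check_position <- function(sequence, position) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (position < 1L || position > nchar(sequence)) {
    stop("position ", position, " outside sequence of length ", nchar(sequence))
  }
  aa <- substr(sequence, position, position)
  if (!(aa %in% AA_STANDARD)) {
    stop("residue '", aa, "' at position ", position, " is not a standard residue")
  }
  aa
}

#' Enumerate SNV-possible variants at a position
#'
#' @param sequence Protein sequence string.
#' @param position 1-based residue position.
#' @param code Genetic code.
#' @return Data frame with columns `wild_aa`, `position`, `mut_aa`,
#'   `variant`, sorted alphabetically by mutant residue.
#' @export
enumerate_snv_possible <- function(sequence, position,
                                   code = standard_genetic_code()) {
  aa <- check_position(sequence, position)
  muts <- snv_reachable(aa, code)
  data.frame(wild_aa = aa, position = as.integer(position), mut_aa = muts,
             variant = paste0(aa, position, muts), stringsAsFactors = FALSE)
}

#' Enumerate all 19 non-native variants at a position
#'
#' @inheritParams enumerate_snv_possible
#' @return Data frame of the 19 substitutions to every other standard
#'   residue, sorted by mutant residue.
#' @export
enumerate_full <- function(sequence, position) {
  aa <- check_position(sequence, position)
  muts <- setdiff(AA_STANDARD, aa)
  data.frame(wild_aa = aa, position = as.integer(position), mut_aa = muts,
             variant = paste0(aa, position, muts), stringsAsFactors = FALSE)
}

#' Draw one random SNV-possible variant at a position
#'
#' Uniform over [enumerate_snv_possible()]; reproducible under `set.seed()`.
#'
#' @inheritParams enumerate_snv_possible
#' @return A single-row data frame as in [enumerate_snv_possible()].
#' @export
random_snv_variant <- function(sequence, position,
                               code = standard_genetic_code()) {
  cand <- enumerate_snv_possible(sequence, position, code)
  cand[sample.int(nrow(cand), 1L), , drop = FALSE]
}
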