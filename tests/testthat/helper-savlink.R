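AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

fixture <- function(name) {
  system.file("extdata", name, package = "savlink")
}

tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

tmp_tsv <- function(df) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

random_sequence <- function(n) {
  paste(sample(AAS, n, replace = TRUE), collapse = "")
}

# variant-table data frame in the shape read_variant_table() returns
toy_records <- function(variant, protein_ref, gene_symbol = "G1",
                        taxon_id = 9615L, label = "toy", source = "test",
                        variant_type = "sav") {
  n <- length(variant)
  parsed <- lapply(variant, parse_variant)
  df <- data.frame(
    gene_symbol = rep_len(gene_symbol, n), taxon_id = rep_len(taxon_id, n),
    protein_ref = rep_len(protein_ref, n), variant = variant,
    label = rep_len(label, n), source = rep_len(source, n),
    wild_aa = vapply(parsed, `[[`, "", "wild_aa"),
    position = vapply(parsed, `[[`, 1L, "position"),
    mut_aa = vapply(parsed, `[[`, "", "mut_aa"),
    synonymous = vapply(parsed, `[[`, TRUE, "synonymous"),
    variant_type = rep_len(variant_type, n),
    stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

toy_proteins <- function(ids, sequences) {
  structure(data.frame(id = ids, description = "", sequence = sequences,
                       stringsAsFactors = FALSE),
            class = c("protein_set", "data.frame"))
}

# independent brute-force SNV reachability: enumerate every
# (codon, position, base) triple directly from the Biostrings genetic code
oracle_snv_reachable <- function(aa) {
  code <- Biostrings::GENETIC_CODE
  out <- character(0)
  for (codon in names(code)[code == aa]) {
    for (p in 1:3) {
      for (b in c("A", "C", "G", "T")) {
        if (substr(codon, p, p) == b) next
        edited <- codon
        substr(edited, p, p) <- b
        out <- c(out, unname(code[edited]))
      }
    }
  }
  sort(setdiff(unique(out), c(aa, "*")))
}
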