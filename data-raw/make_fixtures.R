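# Regenerates the plain-text fixtures under inst/extdata/.
# Run from the package root: Rscript data-raw/make_fixtures.R

suppressMessages(library(Biostrings))
set.seed(20160818)

dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE)

## ---- BLOSUM62 in NCBI text format (standard public-domain table) ----
data(BLOSUM62)
m <- BLOSUM62
letters_keep <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F",
                  "P","S","T","W","Y","V","B","Z","X","*")
m <- m[letters_keep, letters_keep]
con <- file("inst/extdata/BLOSUM62.txt", "w")
writeLines(c("#  Matrix made by matblas from blosum62.iij",
             "#  BLOSUM Clustered Scoring Matrix in 1/2 Bit Units",
             paste("  ", paste(colnames(m), collapse = "  "))), con)
for (r in rownames(m)) {
  writeLines(paste(r, paste(sprintf("%2d", m[r, ]), collapse = " ")), con)
}
close(con)

## ---- cutoff rules configuration ----
writeLines(c(
  "# Binary effect/neutral cutoff rules, one per prediction method.",
  "# orientation: greater_is_effect (score above threshold = effect) or",
  "#              less_is_effect (score below threshold = effect).",
  "synpred:",
  "  threshold: 0.5",
  "  orientation: greater_is_effect",
  "snap2:",
  "  threshold: 0",
  "  orientation: greater_is_effect",
  "polyphen2:",
  "  threshold: 0.5",
  "  orientation: greater_is_effect",
  "sift:",
  "  threshold: 0.05",
  "  orientation: less_is_effect"
), "inst/extdata/cutoff_rules.yaml")

## ---- synthetic curated animal-disease SAV set (S2-shaped stand-in) ----
# 117 SAVs over 99 distinct sequences; taxon composition dog 46/117 (39%),
# cattle 25/117 (21%); 110 plain matches and 7 "+1"-shift matches.
AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")
code <- GENETIC_CODE
snv_set <- function(aa) {
  codons <- names(code)[code == aa]
  out <- character(0)
  for (codon in codons) {
    cs <- strsplit(codon, "")[[1]]
    for (p in 1:3) for (b in setdiff(c("A","C","G","T"), cs[p])) {
      e <- cs; e[p] <- b
      out <- c(out, unname(code[paste(e, collapse = "")]))
    }
  }
  sort(setdiff(unique(out), c(aa, "*")))
}

n_prot <- 99
ids <- sprintf("SYNP%03d", seq_len(n_prot))
genes <- sprintf("SYNG%03d", seq_len(n_prot))
lens <- sample(50:80, n_prot, replace = TRUE)
seqs <- vapply(lens, function(L) paste(sample(AA, L, replace = TRUE),
                                       collapse = ""), "")

# proteins 1..18 carry two variants, the rest one (36 + 81 = 117)
doubles <- 1:18
taxon_of_protein <- c(
  rep(9615L, 10), rep(9913L, 5), rep(9796L, 3),              # doubles
  rep(9615L, 26), rep(9913L, 15), rep(9796L, 6), rep(9685L, 10),
  rep(9940L, 9), rep(9823L, 8), rep(9031L, 7))               # singles
stopifnot(length(taxon_of_protein) == n_prot)

prot_idx <- c(rep(doubles, each = 2), 19:99)
stopifnot(length(prot_idx) == 117)
shift_rows <- sort(sample(which(prot_idx >= 19), 7))  # 7 "+1"-shift entries

rows <- list()
used_pos <- lapply(seq_len(n_prot), function(i) integer(0))
diseases <- sprintf("synthetic disorder %02d", seq_len(n_prot))
for (r in seq_along(prot_idx)) {
  i <- prot_idx[r]
  L <- lens[i]
  repeat {
    true_pos <- sample(3:(L - 2), 1)
    if (!(true_pos %in% used_pos[[i]])) break
  }
  used_pos[[i]] <- c(used_pos[[i]], true_pos)
  wild <- substr(seqs[i], true_pos, true_pos)
  mut <- sample(snv_set(wild), 1)
  ann_pos <- true_pos
  if (r %in% shift_rows) {
    # annotated one short of the true position; make sure the plain check
    # fails there so validation must use the +1 shift
    ann_pos <- true_pos - 1L
    if (substr(seqs[i], ann_pos, ann_pos) == wild) {
      repl <- sample(setdiff(AA, c(wild, substr(seqs[i], ann_pos, ann_pos))), 1)
      substr(seqs[i], ann_pos, ann_pos) <- repl
    }
  }
  rows[[r]] <- data.frame(
    gene_symbol = genes[i], taxon_id = taxon_of_protein[i],
    protein_ref = ids[i], variant = paste0(wild, ann_pos, mut),
    label = diseases[i], source = "synthetic", stringsAsFactors = FALSE)
}
tab <- do.call(rbind, rows)

# plain-match rows must not accidentally match one position to the right of
# an annotated +1 row elsewhere; re-verify the intended statuses
check_status <- function(v, s) {
  m <- regmatches(v, regexec("^([A-Z])([0-9]+)([A-Z])$", v))[[1]]
  n <- as.integer(m[3])
  if (substr(s, n, n) == m[2]) "match"
  else if (substr(s, n + 1, n + 1) == m[2]) "match_shift1"
  else "mismatch"
}
status <- mapply(check_status, tab$variant,
                 seqs[match(tab$protein_ref, ids)])
stopifnot(sum(status == "match") == 110, sum(status == "match_shift1") == 7)

writeLines(c(
  "# Synthetic stand-in for a curated animal-disease SAV table",
  "# (S2-shaped: 117 SAVs over 99 sequences, dog 39% / cattle 21%,",
  "#  110 plain + 7 '+1'-shift matches). Generated by",
  "# data-raw/make_fixtures.R; sequences in synthetic_s2_sequences.fasta.",
  paste(names(tab), collapse = "\t"),
  apply(tab, 1, paste, collapse = "\t")),
  "inst/extdata/synthetic_s2_variants.tsv")

fa <- file("inst/extdata/synthetic_s2_sequences.fasta", "w")
for (i in seq_len(n_prot)) {
  writeLines(c(paste0(">", ids[i], " synthetic curated-set sequence"),
               seqs[i]), fa)
}
close(fa)

cat("fixtures written\n")
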