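#' Effect fraction of a labeled call set, with bootstrap interval
#'
#' The headline statistic of the analysis: the fraction of calls in a set
#' that are effect calls (the "bar height"), with the number of SAVs in the
#' set (the "number above the bar") and a percentile bootstrap interval.
#' The underlying study reports no intervals; they are additional rigor.
#'
#' @param calls Data frame with a `call` column (`"effect"` / `"neutral"`;
#'   `NA` calls are dropped).
#' @param label Set label.
#' @param bootstrap_reps Number of bootstrap resamples (default 2000; 0
#'   skips the interval).
#' @param conf Interval coverage (default 0.95).
#' @param seed Optional RNG seed.
#' @param skip_count Number of skipped source variants to record.
#' @return Object of class `effect_summary`: list with `label`, `n`,
#'   `effect_fraction`, `ci_low`, `ci_high`, `skip_count`.
#' @export
effect_fraction <- function(calls, label = "", bootstrap_reps = 2000L,
                            conf = 0.95, seed = NULL, skip_count = 0L) {
  calls <- calls[!is.na(calls$call), , drop = FALSE]
  n <- nrow(calls)
  if (n == 0L) {
    return(structure(list(label = label, n = 0L, effect_fraction = NA_real_,
                          ci_low = NA_real_, ci_high = NA_real_,
                          skip_count = skip_count),
                     class = "effect_summary"))
  }
  eff <- calls$call == "effect"
  frac <- mean(eff)
  ci <- c(NA_real_, NA_real_)
  if (bootstrap_reps > 0L) {
    if (!is.null(seed)) set.seed(seed)
    reps <- vapply(seq_len(bootstrap_reps),
                   function(i) mean(eff[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
    alpha <- (1 - conf) / 2
    ci <- unname(stats::quantile(reps, c(alpha, 1 - alpha), type = 7))
  }
  structure(list(label = label, n = n, effect_fraction = frac,
                 ci_low = ci[1], ci_high = ci[2], skip_count = skip_count),
            class = "effect_summary")
}

#' @export
print.effect_summary <- function(x, ...) {
  cat(sprintf("%s: %.0f%% effect (n = %d%s)\n", x$label,
              100 * x$effect_fraction, x$n,
              if (x$skip_count > 0) paste0(", ", x$skip_count, " skipped") else ""))
  invisible(x)
}

#' Pairwise binary agreement between prediction methods
#'
#' For every method pair, the percentage of variants (present in both) with
#' identical binary calls, i.e. both effect or both neutral.
#'
#' @param matrix Per-variant call matrix from [join_calls()].
#' @param dataset Dataset label stored on the output rows.
#' @return Data frame with `method_a`, `method_b`, `dataset`,
#'   `percent_agree`, `n` (one row per unordered pair, plus self-agreement).
#' @export
pairwise_agreement <- function(matrix, dataset = "") {
  methods <- setdiff(names(matrix), c("protein_ref", "variant"))
  rows <- list()
  for (i in seq_along(methods)) {
    for (j in i:length(methods)) {
      a <- matrix[[methods[i]]]; b <- matrix[[methods[j]]]
      both <- !is.na(a) & !is.na(b)
      n <- sum(both)
      pct <- if (n > 0) 100 * mean(a[both] == b[both]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        method_a = methods[i], method_b = methods[j], dataset = dataset,
        percent_agree = pct, n = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Taxonomic composition of a variant set
#'
#' @param records A `variant_table` data frame.
#' @return Named numeric vector: per NCBI taxon id, the fraction of records
#'   (sums to 1; empty input gives an empty vector), sorted decreasing.
#' @export
composition_by_taxon <- function(records) {
  if (nrow(records) == 0L) return(stats::setNames(numeric(0), character(0)))
  tab <- table(records$taxon_id)
  sort(stats::setNames(as.numeric(tab) / nrow(records), names(tab)),
       decreasing = TRUE)
}

#' Assemble effect summaries into a comparison report
#'
#' Machine-readable analogue of a grouped bar panel: one row per labeled
#' set, in input order, with optional pairwise differences between named
#' sets (e.g. a disease set minus a neutral training set).
#'
#' @param summaries List of `effect_summary` objects.
#' @param differences Optional list of 2-element character vectors of
#'   labels; each yields a difference row `first - second`.
#' @return A list of class `comparison_report` with data frames `bars`
#'   (label, n, effect_fraction, percent, ci_low, ci_high, skip_count) and
#'   `differences` (label_a, label_b, difference).
#' @export
comparison_report <- function(summaries, differences = NULL) {
  bars <- do.call(rbind, lapply(summaries, function(s) {
    data.frame(label = s$label, n = s$n, effect_fraction = s$effect_fraction,
               percent = round(100 * s$effect_fraction),
               ci_low = s$ci_low, ci_high = s$ci_high,
               skip_count = s$skip_count, stringsAsFactors = FALSE)
  }))
  if (is.null(bars)) {
    bars <- data.frame(label = character(0), n = integer(0),
                       effect_fraction = numeric(0), percent = numeric(0),
                       ci_low = numeric(0), ci_high = numeric(0),
                       skip_count = integer(0))
  }
  diffs <- NULL
  if (!is.null(differences)) {
    diffs <- do.call(rbind, lapply(differences, function(pair) {
      ia <- match(pair[1], bars$label); ib <- match(pair[2], bars$label)
      if (is.na(ia) || is.na(ib)) stop("unknown label in difference: ",
                                       paste(pair, collapse = " - "))
      data.frame(label_a = pair[1], label_b = pair[2],
                 difference = bars$effect_fraction[ia] - bars$effect_fraction[ib],
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(bars = bars, differences = diffs),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  print(x$bars)
  if (!is.null(x$differences)) print(x$differences)
  invisible(x)
}

#' Write a comparison report as JSON and/or TSV
#'
#' @param report A `comparison_report`.
#' @param json,tsv Optional output paths.
#' @return The report, invisibly.
#' @export
write_comparison_report <- function(report, json = NULL, tsv = NULL) {
  if (!is.null(tsv)) {
    utils::write.table(report$bars, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(list(bars = report$bars,
                              differences = report$differences),
                         json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  invisible(report)
}
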