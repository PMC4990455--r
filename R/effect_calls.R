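#' Cutoff rule for binarizing a prediction method's scores
#'
#' @param method Method name as it appears in score tables.
#' @param threshold Decision threshold on the raw score.
#' @param orientation `"greater_is_effect"` (scores above the threshold are
#'   effect calls) or `"less_is_effect"` (mirrored, e.g. p-value-like
#'   scores).
#' @param tie_policy Call assigned when the score equals the threshold.
#' @return A list of class `cutoff_rule`.
#' @export
cutoff_rule <- function(method, threshold,
                        orientation = c("greater_is_effect", "less_is_effect"),
                        tie_policy = c("neutral", "effect")) {
  orientation <- match.arg(orientation)
  tie_policy <- match.arg(tie_policy)
  structure(list(method = method, threshold = threshold,
                 orientation = orientation, tie_policy = tie_policy),
            class = "cutoff_rule")
}

#' Default cutoff rules shipped with the package
#'
#' Reads `inst/extdata/cutoff_rules.yaml`: editable configuration giving one
#' rule per method name, documenting common conventions (score > 0 for
#' SNAP2-like scores, probability > 0.5 for PolyPhen-2-like classifiers,
#' p-value-like scores < 0.05 for SIFT-like methods, and the synthetic
#' predictor of this package).
#'
#' @param path Optional path to an alternative YAML rules file.
#' @return Named list of `cutoff_rule`s keyed by method.
#' @export
default_cutoff_rules <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "cutoff_rules.yaml", package = "savlink")
  }
  cfg <- yaml::read_yaml(path)
  rules <- lapply(names(cfg), function(m) {
    r <- cfg[[m]]
    cutoff_rule(m, r$threshold, r$orientation,
                if (is.null(r$tie_policy)) "neutral" else r$tie_policy)
  })
  stats::setNames(rules, names(cfg))
}

#' Binarize prediction scores into effect/neutral calls
#'
#' @param scores Score table data frame (see [read_score_table()]).
#' @param rules Named list of `cutoff_rule`s covering every method present.
#' @return The input with a `call` column (`"effect"` / `"neutral"`) added;
#'   rows with missing scores get `NA` calls.
#' @export
binarize <- function(scores, rules = default_cutoff_rules()) {
  methods <- unique(scores$method)
  missing <- setdiff(methods, names(rules))
  if (length(missing)) {
    stop("no cutoff rule for method(s): ", paste(missing, collapse = ", "))
  }
  call <- rep(NA_character_, nrow(scores))
  for (m in methods) {
    r <- rules[[m]]
    idx <- scores$method == m & !is.na(scores$score)
    s <- scores$score[idx]
    above <- if (r$orientation == "greater_is_effect") s > r$threshold
             else s < r$threshold
    tie <- s == r$threshold
    call[idx] <- ifelse(above, "effect",
                        ifelse(tie & r$tie_policy == "effect", "effect",
                               "neutral"))
  }
  scores$call <- call
  scores
}

#' Join call sets into a per-variant call matrix
#'
#' @param sets A single call data frame (with `protein_ref`, `variant`,
#'   `method`, `call`) or a list of them.
#' @return Data frame keyed by (`protein_ref`, `variant`) with one call
#'   column per method; missing entries are `NA`.
#' @export
join_calls <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  calls <- do.call(rbind, lapply(sets, function(s) {
    s[, c("protein_ref", "variant", "method", "call")]
  }))
  key <- paste(calls$protein_ref, calls$variant, calls$method, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    first <- match(key[dup], key)
    if (any(calls$call[dup] != calls$call[first])) {
      stop("conflicting duplicate calls for ",
           calls$variant[dup][calls$call[dup] != calls$call[first]][1])
    }
    calls <- calls[!dup, ]
  }
  methods <- sort(unique(calls$method))
  vk <- unique(calls[, c("protein_ref", "variant")])
  out <- vk
  for (m in methods) {
    sub <- calls[calls$method == m, ]
    out[[m]] <- sub$call[match(paste(vk$protein_ref, vk$variant),
                               paste(sub$protein_ref, sub$variant))]
  }
  out
}
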