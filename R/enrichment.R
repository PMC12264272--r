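#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum (Mann-Whitney) test with midranks for ties. The p-value is
#' exact (full enumeration of rank assignments) when both samples have at
#' most 12 observations and there are no ties; otherwise the normal
#' approximation with tie and continuity correction is used. The method
#' actually applied is recorded in the result.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return One-row tibble: `statistic` (Mann-Whitney U for `x`),
#'   `p_value`, `n_x`, `n_y`, `method` ("exact" or "normal_approx"),
#'   `direction` (sign of the median difference x - y).
#' @export
#'
#' @examples
#' wilcoxon_rank_sum(c(1, 2), c(3, 4))
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) {
    abort("Both samples must be non-empty.")
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- !has_ties && length(x) <= 12 && length(y) <= 12
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided",
                exact = use_exact, correct = TRUE)
  )
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_x = length(x), n_y = length(y),
    method = if (use_exact) "exact" else "normal_approx",
    direction = sign(median(x) - median(y))
  )
}

#' Compare signature scores across molecular subtypes
#'
#' Wilcoxon rank-sum comparisons of a per-sample score between a reference
#' subtype (CMS4 by default, the stroma-rich poor-prognosis class) and every
#' other subtype, plus reference-vs-rest. Samples whose label is missing,
#' `NA` or `"unlabeled"` are dropped with a warning. Raw p-values are the
#' primary report; Benjamini-Hochberg adjusted values are always included.
#'
#' @param scores Output of [score_signature] (columns `sample_id`, `score`).
#' @param clinical Clinical tibble with `sample_id` and the grouping column.
#' @param grouping Name of the label column, default `"cms"`.
#' @param reference Reference level, default `"CMS4"`.
#' @return Tibble with one row per comparison: `signature`, `grouping`,
#'   `comparison`, `n_ref`, `n_other`, `statistic`, `direction`,
#'   `p_value`, `p_adjusted`, `method`.
#' @export
compare_scores_by_subtype <- function(scores, clinical, grouping = "cms",
                                      reference = "CMS4") {
  if (!grouping %in% names(clinical)) {
    abort(sprintf("Column '%s' not found in `clinical`.", grouping))
  }
  d <- dplyr::inner_join(scores, clinical, by = "sample_id")
  lab <- d[[grouping]]
  keep <- !is.na(lab) & lab != "unlabeled"
  if (any(!keep)) {
    warn(sprintf("Dropping %d unlabeled sample(s) from '%s' comparisons.",
                 sum(!keep), grouping))
    d <- d[keep, , drop = FALSE]
    lab <- lab[keep]
  }
  sizes <- table(lab)
  if (sum(sizes >= 2) < 2) {
    abort("Need at least 2 groups with >= 2 samples each.")
  }
  if (!reference %in% names(sizes)) {
    abort(sprintf("Reference level '%s' has no samples.", reference))
  }
  ref_scores <- d$score[lab == reference]
  others <- setdiff(sort(names(sizes)), reference)

  rows <- purrr::map(others, function(g) {
    dplyr::mutate(wilcoxon_rank_sum(ref_scores, d$score[lab == g]),
                  comparison = paste0(reference, " vs ", g), .before = 1)
  })
  rows <- c(rows, list(
    dplyr::mutate(wilcoxon_rank_sum(ref_scores, d$score[lab != reference]),
                  comparison = paste0(reference, " vs rest"), .before = 1)
  ))
  out <- dplyr::bind_rows(rows) |>
    dplyr::rename(n_ref = "n_x", n_other = "n_y") |>
    dplyr::mutate(
      signature = attr(scores, "signature") %||% NA_character_,
      grouping = grouping, .before = 1) |>
    dplyr::mutate(p_adjusted = p.adjust(.data$p_value, method = "BH"))
  out
}

#' Fisher exact test for risk-group enrichment in a target subtype
#'
#' Formal version of the visual claim that signature-high patients cluster
#' in the CMS4/iCMS3-fibrotic corner of an annotated heatmap: cross-
#' tabulates the signature-defined risk group against membership in a
#' target subtype and applies the two-sided Fisher exact test
#' (hypergeometric enumeration), reporting the conditional
#' maximum-likelihood odds ratio (infinite when a zero cell makes the
#' enrichment one-sided).
#'
#' @param status Output of [assign_status] (a `risk` column is derived via
#'   [risk_groups] using the score polarity) or of [risk_groups].
#' @param clinical Clinical tibble with `sample_id` and the annotation
#'   columns named by `target`.
#' @param target Named character vector defining the target class as a
#'   conjunction of annotation equalities; default
#'   `c(cms = "CMS4", fibrosis = "fibrotic")`.
#' @return An `enrichment_result`: list with `table` (2x2: risk yes/no x
#'   target yes/no), `odds_ratio`, `p_value`, `target`, `n`; supports
#'   [tidy()] and [glance()].
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 200, seed = 11))
#' st <- assign_status(score_signature(cohort$expression,
#'                                     builtin_signatures()[["RESIST-M"]]))
#' enrichment_test(st, cohort$clinical)
enrichment_test <- function(status, clinical,
                            target = c(cms = "CMS4", fibrosis = "fibrotic")) {
  if (!"risk" %in% names(status)) status <- risk_groups(status)
  miss <- setdiff(names(target), names(clinical))
  if (length(miss) > 0) {
    abort(sprintf("Target annotation column(s) missing from clinical: %s",
                  paste(miss, collapse = ", ")))
  }
  d <- dplyr::inner_join(status, clinical, by = "sample_id")
  in_target <- rep(TRUE, nrow(d))
  for (col in names(target)) in_target <- in_target & d[[col]] == target[[col]]
  if (!any(in_target)) abort("Target class is empty.")

  tab <- table(
    risk = factor(d$risk, levels = c(1, 0), labels = c("risk-high", "risk-low")),
    target = factor(in_target, levels = c(TRUE, FALSE),
                    labels = c("in-target", "out"))
  )
  ft <- fisher.test(tab, alternative = "two.sided")
  structure(
    list(table = tab,
         odds_ratio = unname(ft$estimate),
         p_value = ft$p.value,
         target = target, n = nrow(d)),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat("<enrichment_result> target:",
      paste(names(x$target), x$target, sep = " = ", collapse = " & "), "\n")
  print(x$table)
  cat(sprintf("  odds ratio = %.3g, Fisher p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' @rdname enrichment_test
#' @param x An `enrichment_result`.
#' @param ... Unused.
#' @export
tidy.enrichment_result <- function(x, ...) {
  as.data.frame(x$table) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @rdname enrichment_test
#' @export
glance.enrichment_result <- function(x, ...) {
  tibble::tibble(
    odds_ratio = x$odds_ratio, p_value = x$p_value, n = x$n,
    n_risk_in_target = x$table["risk-high", "in-target"],
    n_target = sum(x$table[, "in-target"])
  )
}
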