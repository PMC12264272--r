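#' Min-max reflection of one gene's expression across a cohort
#'
#' Inverts a gene's ranking so that risk-up genes combine coherently with
#' protective-down genes: each value x maps to
#' `min + (max - min) * (max - x) / (max - min)`, which simplifies to
#' `min + max - x`. The cohort minimum maps to the maximum and vice versa;
#' applying the reflection twice recovers the input. A constant vector is
#' returned unchanged (the continuous limit of the formula, whose printed
#' form is 0/0 when max = min).
#'
#' @param values Numeric vector: one gene's expression across the cohort
#'   being scored. The min and max are taken over this vector, so reflected
#'   values are cohort-relative.
#'
#' @return Numeric vector of reflected values, same length and names.
#' @export
#'
#' @examples
#' reflect_gene(c(1, 3, 5))
#' reflect_gene(c(0.5, 2, 4, 10))
reflect_gene <- function(values) {
  if (length(values) == 0L) abort("Cannot reflect an empty vector.")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values))
    lab <- if (!is.null(names(values))) names(values)[bad] else as.character(bad)
    abort(sprintf("Non-finite expression values for: %s",
                  paste(head(lab, 5), collapse = ", ")))
  }
  min(values) + max(values) - values
}

#' Score samples with a gene signature
#'
#' Two scoring procedures are supported. `"reflected_median"` reflects each
#' risk-direction (`up`) gene across the cohort with [reflect_gene], keeps
#' protective (`down`) genes as-is, and takes the per-sample median over all
#' signature genes; after reflection a *lower* score means a *higher-risk*
#' expression pattern. `"mean"` is the per-sample arithmetic mean of the
#' listed genes on their original scale (higher score = higher expression).
#'
#' Signature genes missing from the matrix are dropped with a warning
#' (mirroring published practice of scoring available subsets); set
#' `strict = TRUE` to make missing genes an error.
#'
#' @param expr Expression table: tibble with a `gene` column and one numeric
#'   column per sample (log-scale normalized expression recommended, e.g.
#'   log2(TPM+1), since the median step mixes gene magnitudes).
#' @param signature A [gene_signature], or a character vector of gene
#'   symbols (treated as an unnamed all-up set, useful with `method = "mean"`).
#' @param method `"reflected_median"` or `"mean"`.
#' @param strict Error (rather than warn) when signature genes are missing.
#'
#' @return A tibble with columns `sample_id` and `score`, carrying
#'   attributes `signature`, `method` and `polarity`
#'   (`"lower = higher risk"` for reflected_median, `"higher = higher
#'   expression"` for mean).
#' @export
#'
#' @examples
#' expr <- tibble::tibble(gene = c("SERPINE1", "SMARCD3"),
#'                        s1 = c(5, 6), s2 = c(2, 3))
#' score_signature(expr, builtin_signatures()[["RESIST-M1"]], method = "mean")
score_signature <- function(expr, signature,
                            method = c("reflected_median", "mean"),
                            strict = FALSE) {
  method <- match.arg(method)
  if (is.character(signature)) {
    signature <- gene_signature("custom", up_genes = signature)
  }
  m <- expr_to_matrix(expr)
  wanted <- signature_genes(signature)
  present <- intersect(wanted, rownames(m))
  missing <- setdiff(wanted, rownames(m))
  if (length(present) == 0L) {
    abort(sprintf("None of the %d genes of signature '%s' are in the matrix.",
                  length(wanted), signature$name))
  }
  if (length(missing) > 0) {
    msg <- sprintf("Signature '%s': %d gene(s) not in matrix, scoring the remaining %d: missing %s",
                   signature$name, length(missing), length(present),
                   paste(missing, collapse = ", "))
    if (strict) abort(msg) else warn(msg)
  }

  if (method == "reflected_median") {
    sub <- m[present, , drop = FALSE]
    up <- intersect(signature$up_genes, present)
    for (g in up) sub[g, ] <- reflect_gene(sub[g, ])
    scores <- apply(sub, 2, median)
    polarity <- "lower = higher risk"
  } else {
    sub <- m[present, , drop = FALSE]
    scores <- colMeans(sub)
    polarity <- "higher = higher expression"
  }

  out <- tibble::tibble(sample_id = colnames(m), score = unname(scores))
  attr(out, "signature") <- signature$name
  attr(out, "method") <- method
  attr(out, "polarity") <- polarity
  attr(out, "genes_used") <- present
  out
}

#' Per-sample mean expression of a gene list
#'
#' Convenience wrapper around [score_signature] with `method = "mean"`.
#'
#' @inheritParams score_signature
#' @param genes Character vector of gene symbols.
#' @return Tibble `sample_id`, `score`.
#' @export
score_mean <- function(expr, genes, strict = FALSE) {
  score_signature(expr, genes, method = "mean", strict = strict)
}

#' Median-split risk status
#'
#' Dichotomizes a continuous per-sample score at the cohort median: a sample
#' is status 1 ("high") if its score is strictly above the median of all
#' samples' scores, 0 ("low") otherwise, so a sample sitting exactly at the
#' median is "low". If all scores are identical every sample is "low" and a
#' degenerate-split warning is raised.
#'
#' @param scores Output of [score_signature] (or any data frame with
#'   `sample_id` and `score` columns).
#'
#' @return The input tibble with an added integer `status` column and
#'   attributes `threshold` (the cohort median) and `rule`
#'   (`"strictly_greater"`). Score polarity attributes are carried through.
#' @export
#'
#' @examples
#' s <- tibble::tibble(sample_id = letters[1:4], score = 1:4)
#' assign_status(s)
assign_status <- function(scores) {
  if (!all(c("sample_id", "score") %in% names(scores))) {
    abort("`scores` needs `sample_id` and `score` columns.")
  }
  if (nrow(scores) < 2L) abort("Need at least 2 samples for a median split.")
  if (any(!is.finite(scores$score))) abort("Scores must be finite.")
  threshold <- median(scores$score)
  status <- as.integer(scores$score > threshold)
  if (all(scores$score == scores$score[1])) {
    warn("All scores identical: degenerate median split, every status is 0.")
  }
  out <- dplyr::mutate(scores, status = status)
  attr(out, "threshold") <- threshold
  attr(out, "rule") <- "strictly_greater"
  attr(out, "signature") <- attr(scores, "signature")
  attr(out, "method") <- attr(scores, "method")
  attr(out, "polarity") <- attr(scores, "polarity")
  out
}

#' Risk-group labels from a median-split status
#'
#' Translates a median-split `status` into a risk flag using the score's
#' polarity: for reflected-median scores ("lower = higher risk") the *low*
#' arm is the risk group, for mean scores the *high* arm is. The returned
#' tibble gains a `risk` column (1 = higher-risk group).
#'
#' @param status Output of [assign_status].
#' @param polarity Override the polarity attribute if it is absent.
#' @return Input tibble with an integer `risk` column.
#' @export
risk_groups <- function(status, polarity = NULL) {
  polarity <- polarity %||% attr(status, "polarity") %||%
    "higher = higher expression"
  if (!"status" %in% names(status)) abort("`status` must come from assign_status().")
  risk <- if (identical(polarity, "lower = higher risk")) {
    1L - status$status
  } else {
    status$status
  }
  out <- dplyr::mutate(status, risk = risk)
  for (a in c("threshold", "rule", "signature", "method", "polarity")) {
    attr(out, a) <- attr(status, a)
  }
  out
}

#' Row-wise z-scoring of an expression table
#'
#' Centers and scales each gene row to mean 0 and sample standard deviation
#' 1 (n-1 denominator). Constant rows are mapped to all-zero rows with a
#' warning rather than dividing by zero.
#'
#' @param expr Expression table (tibble with `gene` column).
#' @return Expression table of the same shape with z-scored rows.
#' @export
zscore_rows <- function(expr) {
  m <- expr_to_matrix(expr)
  if (ncol(m) < 2L) abort("Row z-scoring needs at least 2 samples.")
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  const <- s == 0
  if (any(const)) {
    warn(sprintf("%d constant row(s) z-scored to all zeros: %s",
                 sum(const), paste(head(rownames(m)[const], 5), collapse = ", ")))
    s[const] <- 1
  }
  z <- (m - mu) / s
  z[const, ] <- 0
  matrix_to_expr(z)
}
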