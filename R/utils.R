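# Internal helpers shared across modules.
#
# An expression table is a wide tibble: character column `gene` first, one
# numeric column per sample. Genes in rows matches the orientation of the
# public CRC matrices this package targets.

expr_to_matrix <- function(expr) {
  validate_expression(expr)
  m <- as.matrix(expr[, setdiff(names(expr), "gene"), drop = FALSE])
  rownames(m) <- expr$gene
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, rownames = "gene")
}

validate_expression <- function(expr, arg = "expr") {
  if (!is.data.frame(expr) || !"gene" %in% names(expr)) {
    abort(sprintf("`%s` must be a data frame with a `gene` column first.", arg))
  }
  sample_cols <- setdiff(names(expr), "gene")
  if (length(sample_cols) == 0L) {
    abort(sprintf("`%s` has no sample columns.", arg))
  }
  if (anyDuplicated(expr$gene)) {
    dups <- unique(expr$gene[duplicated(expr$gene)])
    abort(sprintf("Duplicate gene symbols in `%s`: %s", arg,
                  paste(dups, collapse = ", ")))
  }
  if (anyDuplicated(sample_cols)) {
    abort(sprintf("Duplicate sample ids in `%s`.", arg))
  }
  vals <- as.matrix(expr[, sample_cols, drop = FALSE])
  if (!is.numeric(vals)) {
    abort(sprintf("`%s` contains non-numeric expression values.", arg))
  }
  if (any(!is.finite(vals))) {
    abort(sprintf("`%s` contains non-finite expression values.", arg))
  }
  invisible(expr)
}

expr_sample_ids <- function(expr) setdiff(names(expr), "gene")

validate_clinical <- function(clinical, require_survival = TRUE) {
  if (!is.data.frame(clinical) || !"sample_id" %in% names(clinical)) {
    abort("`clinical` must be a data frame with a `sample_id` column.")
  }
  if (anyDuplicated(clinical$sample_id)) {
    abort("Duplicate sample ids in `clinical`.")
  }
  if (require_survival) {
    if (!all(c("time", "event") %in% names(clinical))) {
      abort("`clinical` must have `time` and `event` columns.")
    }
    if (any(!is.finite(clinical$time)) || any(clinical$time < 0)) {
      abort("Survival times must be finite and non-negative.")
    }
    if (!all(clinical$event %in% c(0, 1))) {
      abort("`event` must be 0 (censored) or 1 (event).")
    }
  }
  invisible(clinical)
}

# Align a per-sample table to the sample ids of an expression table.
check_matched_ids <- function(expr, clinical) {
  ids <- expr_sample_ids(expr)
  missing <- setdiff(ids, clinical$sample_id)
  if (length(missing) > 0) {
    abort(sprintf("Samples present in expression but not clinical: %s",
                  paste(head(missing, 5), collapse = ", ")))
  }
  invisible(TRUE)
}
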