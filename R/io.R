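# Readers and writers for the plain-text formats the pipeline exchanges:
# expression TSV/CSV (gene symbols in the first column, sample ids in the
# header), clinical TSV/CSV, and GMT gene-set files.

delim_for <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read an expression matrix from TSV/CSV
#'
#' Expects genes in rows: a first column of gene symbols (any header name)
#' and one numeric column per sample. A matrix that looks transposed
#' (sample-like row ids such as TCGA barcodes in the first column is not
#' detectable in general, but an all-numeric first column is) produces a
#' descriptive error rather than a silent mis-read.
#'
#' @param path File path; delimiter inferred from the extension
#'   (`.csv` = comma, otherwise tab) unless `delim` is given.
#' @param delim Optional explicit field delimiter.
#' @param duplicate_genes Policy for duplicated gene symbols: `"error"`
#'   (default), `"mean"` (collapse by averaging), or `"first"`.
#'
#' @return Wide expression tibble (`gene` + sample columns).
#' @export
read_expression <- function(path, delim = NULL,
                            duplicate_genes = c("error", "mean", "first")) {
  duplicate_genes <- match.arg(duplicate_genes)
  d <- readr::read_delim(path, delim = delim_for(path, delim),
                         show_col_types = FALSE, progress = FALSE)
  if (ncol(d) < 2L) abort(sprintf("'%s': expected a gene column plus sample columns.", path))
  names(d)[1] <- "gene"
  if (is.numeric(d$gene)) {
    abort(sprintf("'%s': first column is numeric; expected gene symbols (is the matrix transposed?).", path))
  }
  d$gene <- as.character(d$gene)
  if (anyDuplicated(d$gene)) {
    dups <- unique(d$gene[duplicated(d$gene)])
    if (duplicate_genes == "error") {
      abort(sprintf("'%s': duplicated gene symbol(s): %s", path,
                    paste(head(dups, 5), collapse = ", ")))
    } else if (duplicate_genes == "mean") {
      d <- dplyr::summarise(dplyr::group_by(d, .data$gene),
                            dplyr::across(dplyr::everything(), mean),
                            .groups = "drop")
    } else {
      d <- d[!duplicated(d$gene), , drop = FALSE]
    }
  }
  bad <- names(d)[-1][!vapply(d[-1], is.numeric, logical(1))]
  if (length(bad) > 0) {
    abort(sprintf("'%s': non-numeric expression column(s): %s", path,
                  paste(head(bad, 5), collapse = ", ")))
  }
  validate_expression(d, arg = path)
  d
}

#' Write an expression matrix as TSV/CSV
#'
#' @param expr Expression tibble.
#' @param path Output path; delimiter inferred from the extension.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, delim = NULL) {
  validate_expression(expr)
  readr::write_delim(expr, path, delim = delim_for(path, delim))
  invisible(path)
}

subtype_levels <- list(
  cms = c("CMS1", "CMS2", "CMS3", "CMS4"),
  icms = c("iCMS2", "iCMS3"),
  msi = c("MSI", "MSS"),
  fibrosis = c("fibrotic", "non-fibrotic")
)

#' Read a clinical annotation table from TSV/CSV
#'
#' Columns: `sample_id`, `time`, `event`, optionally `endpoint` and the
#' subtype annotations `cms`, `icms`, `msi`, `fibrosis`. Subtype labels are
#' matched case-insensitively against their known vocabularies; unknown
#' strings become `"unlabeled"` with a warning. The event column is coerced
#' strictly: any value outside \{0, 1\} is an error.
#'
#' @inheritParams read_expression
#' @return Clinical tibble.
#' @export
read_clinical <- function(path, delim = NULL) {
  d <- readr::read_delim(path, delim = delim_for(path, delim),
                         show_col_types = FALSE, progress = FALSE)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    abort(sprintf("'%s': missing required column(s): %s", path,
                  paste(miss, collapse = ", ")))
  }
  d$sample_id <- as.character(d$sample_id)
  if (!is.numeric(d$time)) abort(sprintf("'%s': `time` must be numeric.", path))
  if (!all(d$event %in% c(0, 1))) {
    abort(sprintf("'%s': `event` must contain only 0 and 1.", path))
  }
  d$event <- as.integer(d$event)
  for (col in names(subtype_levels)) {
    if (!col %in% names(d)) next
    raw <- as.character(d[[col]])
    lev <- subtype_levels[[col]]
    idx <- match(tolower(raw), tolower(lev))
    norm <- ifelse(is.na(raw) | raw == "NA", "unlabeled", lev[idx])
    unknown <- !is.na(raw) & raw != "NA" & is.na(idx)
    if (any(unknown)) {
      warn(sprintf("'%s': %d unrecognized %s label(s) mapped to 'unlabeled' (e.g. %s)",
                   path, sum(unknown), col,
                   paste(head(unique(raw[unknown]), 3), collapse = ", ")))
      norm[unknown] <- "unlabeled"
    }
    norm[is.na(norm)] <- "unlabeled"
    d[[col]] <- norm
  }
  validate_clinical(d)
  d
}

#' Write a clinical table as TSV/CSV
#'
#' @param clinical Clinical tibble.
#' @inheritParams write_expression
#' @return `path`, invisibly.
#' @export
write_clinical <- function(clinical, path, delim = NULL) {
  readr::write_delim(clinical, path, delim = delim_for(path, delim), na = "NA")
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member genes. Direction is reconstructed from a `_UP` / `_DN`
#' suffix convention: `NAME_UP` and `NAME_DN` lines are paired into one
#' two-arm [gene_signature] called `NAME`; a set without suffix is treated
#' as all-up.
#'
#' @param path GMT file path.
#' @return Named list of [gene_signature]s.
#' @export
read_gmt <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L) {
      abort(sprintf("'%s' line %d: GMT lines need name, description and >= 1 gene.",
                    path, i))
    }
    sets[[f[1]]] <- list(description = f[2], genes = f[-(1:2)])
  }
  base_of <- function(nm) sub("_(UP|DN)$", "", nm)
  bases <- unique(vapply(names(sets), base_of, character(1)))
  out <- lapply(bases, function(b) {
    up <- sets[[paste0(b, "_UP")]]
    dn <- sets[[paste0(b, "_DN")]]
    plain <- sets[[b]]
    desc <- (up %||% dn %||% plain)$description
    gene_signature(b,
                   up_genes = c(plain$genes, up$genes),
                   down_genes = dn$genes %||% character(),
                   provenance = desc %||% "")
  })
  setNames(out, bases)
}

#' Write gene signatures to a GMT file
#'
#' Each signature's arms are written as separate sets named `NAME_UP` and
#' `NAME_DN`; [read_gmt] reassembles them losslessly.
#'
#' @param registry Named list of [gene_signature]s.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(registry, path) {
  lines <- character()
  for (sig in registry) {
    if (length(sig$up_genes) > 0) {
      lines <- c(lines, paste(c(paste0(sig$name, "_UP"), sig$provenance,
                                sig$up_genes), collapse = "\t"))
    }
    if (length(sig$down_genes) > 0) {
      lines <- c(lines, paste(c(paste0(sig$name, "_DN"), sig$provenance,
                                sig$down_genes), collapse = "\t"))
    }
  }
  readr::write_lines(lines, path)
  invisible(path)
}
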