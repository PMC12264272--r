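#' Configuration for the end-to-end pipeline
#'
#' @param mode `"synthetic"` (simulate a cohort) or `"files"` (read
#'   expression/clinical from disk).
#' @param cohort A [cohort_config] used in synthetic mode; its seed is
#'   overridden by `seed`.
#' @param expression_path,clinical_path Input files for `"files"` mode.
#' @param gmt_path Optional GMT file whose signatures are merged over the
#'   built-in registry.
#' @param signatures Character vector of signature names to analyse;
#'   defaults to all registry entries.
#' @param endpoint Endpoint label recorded in the report ("OS" or "RFS").
#' @param conf_level Confidence level for all intervals.
#' @param seed Integer seed for any stochastic step.
#' @param out_dir Optional output directory for the JSON report and TSV
#'   artifacts.
#' @param strict Missing-gene policy for scoring.
#'
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "files"),
                            cohort = cohort_config(),
                            expression_path = NULL, clinical_path = NULL,
                            gmt_path = NULL,
                            signatures = NULL,
                            endpoint = "OS", conf_level = 0.95,
                            seed = 1L, out_dir = NULL, strict = FALSE) {
  mode <- match.arg(mode)
  if (mode == "files") {
    for (p in c(expression_path, clinical_path)) {
      if (is.null(p) || !file.exists(p)) {
        abort("`files` mode needs existing `expression_path` and `clinical_path`.")
      }
    }
  }
  if (!is.null(gmt_path) && !file.exists(gmt_path)) {
    abort(sprintf("GMT file not found: %s", gmt_path))
  }
  structure(
    list(mode = mode, cohort = cohort,
         expression_path = expression_path, clinical_path = clinical_path,
         gmt_path = gmt_path, signatures = signatures,
         endpoint = endpoint, conf_level = conf_level,
         seed = as.integer(seed), out_dir = out_dir, strict = strict),
    class = "pipeline_config"
  )
}

#' Run the full scoring / stratification / enrichment pipeline
#'
#' Executes, in order: simulate-or-load the cohort; score every selected
#' signature (reflected-median for the RESIST-M family, mean for the
#' comparators, and both variants for RESIST-M1 and RESIST-M2 singly);
#' median-split each score and compare risk-group survival
#' ([stratified_km_report]); Wilcoxon comparisons of each score across CMS
#' subtypes ([compare_scores_by_subtype]); Fisher enrichment of the
#' combined-signature risk group in the CMS4-and-fibrotic class
#' ([enrichment_test]); and the z-scored heatmap table
#' ([build_heatmap_table]). Re-running with the same config and seed
#' reproduces identical numeric content.
#'
#' @param config A [pipeline_config].
#' @return A `run_report` list: `provenance`, `survival` (one glance row
#'   per signature x method), `reports` (the full `stratification_report`s),
#'   `score_summaries`, `subtype_comparisons`, `enrichment`, `heatmap`,
#'   `warnings`.
#' @export
#'
#' @examples
#' \donttest{
#' report <- run_pipeline(pipeline_config(seed = 1))
#' report$survival
#' }
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    abort("`config` must come from pipeline_config().")
  }
  registry <- builtin_signatures()
  if (!is.null(config$gmt_path)) {
    extra <- read_gmt(config$gmt_path)
    registry[names(extra)] <- extra
  }
  selected <- config$signatures %||% names(registry)
  unknown <- setdiff(selected, names(registry))
  if (length(unknown) > 0) {
    abort(sprintf("[validate] Unknown signature(s): %s",
                  paste(unknown, collapse = ", ")))
  }

  warnings_log <- character()
  log_warning <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }

  withCallingHandlers(warning = log_warning, {
    if (config$mode == "synthetic") {
      cc <- config$cohort
      cc$seed <- config$seed
      cohort <- simulate_cohort(cc)
      expr <- cohort$expression
      clinical <- cohort$clinical
      truth <- cohort$truth
    } else {
      expr <- tryCatch(read_expression(config$expression_path),
                       error = function(e) abort(paste0("[load] ", conditionMessage(e))))
      clinical <- tryCatch(read_clinical(config$clinical_path),
                           error = function(e) abort(paste0("[load] ", conditionMessage(e))))
      truth <- NULL
    }
    clinical$endpoint <- config$endpoint

    # which methods apply to which signature
    methods_for <- function(nm) {
      if (nm %in% c("RESIST-M1", "RESIST-M2")) c("reflected_median", "mean")
      else if (nm == "RESIST-M") "reflected_median"
      else "mean"
    }

    reports <- list()
    for (nm in selected) {
      for (mth in methods_for(nm)) {
        key <- paste0(nm, ":", mth)
        reports[[key]] <- tryCatch(
          stratified_km_report(expr, clinical, registry[[nm]], method = mth,
                               conf_level = config$conf_level,
                               strict = config$strict),
          error = function(e) abort(paste0("[survival] ", key, ": ",
                                           conditionMessage(e))))
      }
    }
    survival_tbl <- dplyr::bind_rows(lapply(reports, glance))

    score_summaries <- dplyr::bind_rows(lapply(reports, function(r) {
      tibble::tibble(
        signature = r$signature, method = r$method,
        polarity = attr(r$scores, "polarity"),
        n = nrow(r$scores),
        threshold = attr(r$status, "threshold"),
        score_mean = mean(r$scores$score),
        score_sd = sd(r$scores$score),
        n_high_risk = unname(r$group_sizes[["high-risk"]]))
    }))

    comparisons <- dplyr::bind_rows(lapply(reports, function(r) {
      tryCatch(compare_scores_by_subtype(r$scores, clinical),
               error = function(e) {
                 abort(paste0("[subtypes] ", r$signature, ": ",
                              conditionMessage(e)))
               }) |>
        dplyr::mutate(method = r$method, .after = "signature")
    }))

    combined_key <- if ("RESIST-M" %in% selected) "RESIST-M:reflected_median"
                    else names(reports)[1]
    enr <- tryCatch(
      enrichment_test(reports[[combined_key]]$status, clinical),
      error = function(e) abort(paste0("[enrichment] ", conditionMessage(e))))

    heat <- tryCatch(
      build_heatmap_table(expr, clinical, registry,
                          scores = reports[[combined_key]]$scores),
      error = function(e) abort(paste0("[heatmap] ", conditionMessage(e))))

    report <- structure(
      list(
        provenance = list(
          package_version = as.character(utils::packageVersion("resistm")),
          seed = config$seed, mode = config$mode,
          endpoint = config$endpoint, conf_level = config$conf_level,
          signatures = selected,
          cohort_config = if (config$mode == "synthetic") {
            unclass(config$cohort)[!vapply(unclass(config$cohort), is.null, logical(1))]
          } else NULL),
        survival = survival_tbl,
        reports = reports,
        score_summaries = score_summaries,
        subtype_comparisons = comparisons,
        enrichment = enr,
        heatmap = heat,
        truth = truth,
        warnings = warnings_log
      ),
      class = "run_report"
    )
  })

  if (!is.null(config$out_dir)) write_run_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report> seed", x$provenance$seed, "|", x$provenance$mode,
      "mode |", length(x$reports), "signature fits\n")
  print(dplyr::select(x$survival, "signature", "method", "logrank_p",
                      "hr", "cox_p"))
  cat(sprintf("Enrichment in %s: OR = %.3g, Fisher p = %.3g\n",
              paste(x$enrichment$target, collapse = "/"),
              x$enrichment$odds_ratio, x$enrichment$p_value))
  invisible(x)
}

#' Write a run report to disk
#'
#' Emits `report.json` (provenance, survival table, comparisons, enrichment,
#' warnings; numbers at full double precision) plus TSV artifacts:
#' `survival.tsv`, `scores.tsv`, `subtype_comparisons.tsv`, `heatmap.tsv`.
#'
#' @param report A `run_report`.
#' @param out_dir Directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_run_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- dplyr::bind_rows(lapply(report$reports, function(r) {
    dplyr::mutate(r$status, signature = r$signature, method = r$method,
                  .before = 1)
  }))
  readr::write_tsv(report$survival, file.path(out_dir, "survival.tsv"))
  readr::write_tsv(scores, file.path(out_dir, "scores.tsv"))
  readr::write_tsv(report$subtype_comparisons,
                   file.path(out_dir, "subtype_comparisons.tsv"))
  readr::write_tsv(tibble::as_tibble(report$heatmap),
                   file.path(out_dir, "heatmap.tsv"))
  json <- list(
    provenance = report$provenance,
    survival = report$survival,
    score_summaries = report$score_summaries,
    subtype_comparisons = report$subtype_comparisons,
    enrichment = list(
      table = as.data.frame(report$enrichment$table),
      odds_ratio = report$enrichment$odds_ratio,
      p_value = report$enrichment$p_value,
      target = as.list(report$enrichment$target)),
    warnings = report$warnings
  )
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
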