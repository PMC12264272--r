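#' Configuration for the synthetic cohort generator
#'
#' Collects and validates the parameters of [simulate_cohort]. Defaults
#' describe a 400-patient colorectal cohort on a log2(TPM+1)-like scale with
#' a CMS4-and-fibrotic risk subpopulation (25% CMS4, 80% of them fibrotic,
#' so a 20% risk fraction), a 2-log2 shift up in the RESIST-M1 genes and
#' down in the RESIST-M2 genes for risk samples, and exponential
#' proportional-hazards survival with a planted hazard ratio of 2.5 under
#' independent exponential censoring.
#'
#' @param n_samples Number of patients.
#' @param subtype_proportions Named probabilities over CMS labels, summing
#'   to 1.
#' @param fibrotic_fraction_in_cms4 Probability that a CMS4 sample is
#'   fibrotic.
#' @param fibrotic_fraction_other Probability that a non-CMS4 sample is
#'   fibrotic.
#' @param n_filler_genes Unplanted background genes drawn from the same
#'   baseline law.
#' @param baseline_mean,baseline_sd Per-gene baseline means are drawn once
#'   from Normal(baseline_mean, baseline_sd), log2 units.
#' @param noise_sd Per-observation Gaussian noise, log2 units.
#' @param m1_shift Added to RESIST-M1 genes in risk samples (log2 units).
#' @param m2_shift Subtracted from RESIST-M2 genes in risk samples.
#' @param comparator_shifts Optional named numeric vector of per-gene log2
#'   shifts applied to risk samples (e.g. stromal genes up, cell-cycle genes
#'   down, mimicking the recurrence-score pattern).
#' @param baseline_hazard Event rate per time unit for non-risk samples.
#' @param planted_hr Hazard-ratio multiplier for risk samples.
#' @param censoring_rate Rate of the independent exponential censoring time;
#'   0 disables censoring.
#' @param seed Integer seed; the same config and seed give bit-identical
#'   cohorts.
#'
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_samples = 400,
                          subtype_proportions = c(CMS1 = 0.15, CMS2 = 0.35,
                                                  CMS3 = 0.25, CMS4 = 0.25),
                          fibrotic_fraction_in_cms4 = 0.8,
                          fibrotic_fraction_other = 0.1,
                          n_filler_genes = 200,
                          baseline_mean = 7, baseline_sd = 1.5, noise_sd = 1,
                          m1_shift = 2, m2_shift = 2,
                          comparator_shifts = NULL,
                          baseline_hazard = 0.02, planted_hr = 2.5,
                          censoring_rate = 0.015,
                          seed = 1L) {
  if (n_samples < 1) abort("`n_samples` must be positive.")
  if (abs(sum(subtype_proportions) - 1) > 1e-9) {
    abort("`subtype_proportions` must sum to 1.")
  }
  if (any(subtype_proportions < 0 | subtype_proportions > 1)) {
    abort("`subtype_proportions` must lie in [0, 1].")
  }
  for (p in c(fibrotic_fraction_in_cms4, fibrotic_fraction_other)) {
    if (p < 0 || p > 1) abort("Fibrotic fractions must lie in [0, 1].")
  }
  if (any(c(baseline_sd, noise_sd, m1_shift, m2_shift,
            baseline_hazard, censoring_rate) < 0)) {
    abort("Standard deviations, shifts and rates must be non-negative.")
  }
  if (planted_hr <= 0) abort("`planted_hr` must be positive.")
  if (!is.null(comparator_shifts) &&
      (is.null(names(comparator_shifts)) || any(!nzchar(names(comparator_shifts))))) {
    abort("`comparator_shifts` must be a named numeric vector (gene -> shift).")
  }
  structure(
    list(n_samples = as.integer(n_samples),
         subtype_proportions = subtype_proportions,
         fibrotic_fraction_in_cms4 = fibrotic_fraction_in_cms4,
         fibrotic_fraction_other = fibrotic_fraction_other,
         n_filler_genes = as.integer(n_filler_genes),
         baseline_mean = baseline_mean, baseline_sd = baseline_sd,
         noise_sd = noise_sd, m1_shift = m1_shift, m2_shift = m2_shift,
         comparator_shifts = comparator_shifts,
         baseline_hazard = baseline_hazard, planted_hr = planted_hr,
         censoring_rate = censoring_rate, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate an expression + survival cohort with a planted risk subgroup
#'
#' Generates a synthetic bulk-expression cohort with the structure the
#' signature analyses assume: expression is simulated directly in log2
#' space as `mu_g + effect(g, risk_s) + Normal(0, noise_sd)`, with per-gene
#' baselines `mu_g ~ Normal(baseline_mean, baseline_sd)` drawn once. Samples
#' labelled CMS4 *and* fibrotic carry the latent risk flag; in those samples
#' RESIST-M1 genes gain `m1_shift`, RESIST-M2 genes lose `m2_shift`, and any
#' `comparator_shifts` are added. Survival is exponential proportional
#' hazards: the event time has rate `baseline_hazard * planted_hr^risk`,
#' censoring is an independent exponential with rate `censoring_rate`, the
#' observed time is the minimum and `event = 1` iff failure precedes
#' censoring. All draws come from one seeded generator in a fixed order
#' (gene means, subtype labels, expression noise, event times, censoring
#' times), so the same config is bit-reproducible.
#'
#' The gene universe is the union of all built-in signature genes plus
#' `n_filler_genes` background genes named `FILLER_0001`, ...
#'
#' @param config A [cohort_config].
#'
#' @return A `synthetic_cohort` list with elements `expression` (wide
#'   tibble), `clinical` (tibble: sample_id, time, event, endpoint, cms,
#'   icms, msi, fibrosis), `truth` (tibble: sample_id, risk) and `config`.
#' @export
#'
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_samples = 50, seed = 7))
#' truth_summary(cohort)
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config")) {
    abort("`config` must come from cohort_config().")
  }
  registry <- builtin_signatures()
  sig_genes <- unique(unlist(lapply(registry, signature_genes)))
  filler <- if (config$n_filler_genes > 0) {
    sprintf("FILLER_%04d", seq_len(config$n_filler_genes))
  } else character()
  genes <- c(sig_genes, filler)
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    abort(sprintf("Duplicate gene symbols in the simulated universe: %s",
                  paste(dups, collapse = ", ")))
  }
  if (!is.null(config$comparator_shifts)) {
    unknown <- setdiff(names(config$comparator_shifts), genes)
    if (length(unknown) > 0) {
      abort(sprintf("comparator_shifts name genes outside the universe: %s",
                    paste(unknown, collapse = ", ")))
    }
  }
  n <- config$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))

  withr::with_seed(config$seed, {
    # 1. gene baselines
    mu <- rnorm(length(genes), config$baseline_mean, config$baseline_sd)
    names(mu) <- genes

    # 2. labels: cms, fibrosis, icms, msi
    cms <- sample(names(config$subtype_proportions), n, replace = TRUE,
                  prob = config$subtype_proportions)
    fib_p <- ifelse(cms == "CMS4", config$fibrotic_fraction_in_cms4,
                    config$fibrotic_fraction_other)
    fibrosis <- ifelse(runif(n) < fib_p, "fibrotic", "non-fibrotic")
    risk <- as.integer(cms == "CMS4" & fibrosis == "fibrotic")
    # iCMS3 is the stroma-associated epithelial class: all risk samples and
    # a minority of the rest
    icms <- ifelse(risk == 1L, "iCMS3",
                   ifelse(runif(n) < 0.35, "iCMS3", "iCMS2"))
    # MSI is enriched in CMS1
    msi <- ifelse(runif(n) < ifelse(cms == "CMS1", 0.7, 0.1), "MSI", "MSS")

    # 3. expression noise
    m1 <- registry[["RESIST-M1"]]$up_genes
    m2 <- registry[["RESIST-M2"]]$down_genes
    eff <- matrix(0, nrow = length(genes), ncol = n,
                  dimnames = list(genes, sample_ids))
    if (any(risk == 1L)) {
      eff[m1, risk == 1L] <- eff[m1, risk == 1L] + config$m1_shift
      eff[m2, risk == 1L] <- eff[m2, risk == 1L] - config$m2_shift
      if (!is.null(config$comparator_shifts)) {
        for (g in names(config$comparator_shifts)) {
          eff[g, risk == 1L] <- eff[g, risk == 1L] + config$comparator_shifts[[g]]
        }
      }
    }
    noise <- matrix(rnorm(length(genes) * n, 0, config$noise_sd),
                    nrow = length(genes))
    values <- mu + eff + noise
    dimnames(values) <- list(genes, sample_ids)

    # 4. survival, 5. censoring
    rate <- config$baseline_hazard * config$planted_hr^risk
    t_event <- rexp(n, rate)
    t_cens <- if (config$censoring_rate > 0) {
      rexp(n, config$censoring_rate)
    } else rep(Inf, n)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)

    strata_n <- table(factor(risk, levels = c(0, 1)))
    if (any(strata_n == 0)) {
      warn("A risk stratum is empty; downstream stratified analyses will fail.")
    }

    cohort <- structure(
      list(
        expression = matrix_to_expr(values),
        clinical = tibble::tibble(
          sample_id = sample_ids, time = time, event = event,
          endpoint = "OS", cms = cms, icms = icms, msi = msi,
          fibrosis = fibrosis),
        truth = tibble::tibble(sample_id = sample_ids, risk = risk),
        config = config
      ),
      class = "synthetic_cohort"
    )
    cohort
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$clinical), " samples, ",
      nrow(x$expression), " genes\n", sep = "")
  print(truth_summary(x))
  invisible(x)
}

#' Summarize the planted truth of a synthetic cohort
#'
#' One-row tibble with subtype counts, the observed event and censoring
#' fractions, and the planted generator parameters echoed back; used to
#' sanity-check simulations.
#'
#' @param cohort A `synthetic_cohort` from [simulate_cohort].
#' @return One-row tibble.
#' @export
truth_summary <- function(cohort) {
  if (!inherits(cohort, "synthetic_cohort")) {
    abort("`cohort` must come from simulate_cohort().")
  }
  cl <- cohort$clinical
  counts <- table(factor(cl$cms, levels = names(cohort$config$subtype_proportions)))
  out <- tibble::tibble(
    n = nrow(cl),
    event_rate = mean(cl$event),
    censoring_rate_observed = mean(1 - cl$event),
    n_risk = sum(cohort$truth$risk),
    planted_hr = cohort$config$planted_hr,
    m1_shift = cohort$config$m1_shift,
    m2_shift = cohort$config$m2_shift,
    baseline_hazard = cohort$config$baseline_hazard,
    censoring_rate = cohort$config$censoring_rate
  )
  for (lv in names(counts)) out[[paste0("n_", lv)]] <- as.integer(counts[[lv]])
  out
}
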