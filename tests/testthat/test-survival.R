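test_that("Kaplan-Meier equals the empirical survival without censoring", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 1, 1))
  km <- km_estimate(d)
  expect_equal(km$estimate, c(2 / 3, 1 / 3, 0))

  set.seed(31)
  times <- round(rexp(40, 0.2), 3)
  km2 <- km_estimate(tibble::tibble(time = times, event = 1))
  ecdf_surv <- vapply(km2$time, function(t) mean(times > t), numeric(1))
  expect_equal(km2$estimate, ecdf_surv, tolerance = 1e-12)
})

test_that("Kaplan-Meier handles censoring per the product-limit oracle", {
  d <- tibble::tibble(time = c(1, 2, 3), event = c(1, 0, 1))
  km <- km_estimate(d)
  # S(1) = 2/3; the subject censored at 2 leaves; S(3) = 2/3 * (1 - 1/1) = 0
  expect_equal(km$estimate[km$time == 1], 2 / 3)
  expect_equal(km$estimate[km$time == 3], 0)

  set.seed(17)
  t2 <- round(rexp(30, 0.1), 2)
  e2 <- rbinom(30, 1, 0.7)
  km3 <- km_estimate(tibble::tibble(time = t2, event = e2))
  orc <- oracle_km(t2, e2)
  expect_equal(km3$estimate[match(orc$time, km3$time)], orc$surv,
               tolerance = 1e-12)
})

test_that("all-censored data give S = 1 and log-log CIs stay in [0,1]", {
  km <- km_estimate(tibble::tibble(time = c(2, 4, 6), event = c(0, 0, 0)))
  expect_true(all(km$estimate == 1))
  expect_equal(sum(km$n_event), 0)

  set.seed(13)
  km2 <- km_estimate(tibble::tibble(time = rexp(80, 0.1),
                                    event = rbinom(80, 1, 0.6)))
  expect_true(all(diff(km2$estimate) <= 1e-12))
  ok <- !is.na(km2$conf_low)
  expect_true(all(km2$conf_low[ok] >= 0 & km2$conf_high[ok] <= 1))
  expect_true(all(km2$conf_low[ok] <= km2$estimate[ok] + 1e-12))
  expect_true(all(km2$conf_high[ok] >= km2$estimate[ok] - 1e-12))

  expect_error(km_estimate(tibble::tibble(time = -1, event = 1)), ">= 0")
})

test_that("log-rank chi-square matches hand-evaluated O/E/V sums", {
  d <- tibble::tibble(time = c(1, 2, 3, 4), event = 1,
                      group = c("A", "A", "B", "B"))
  lr <- logrank_test(d, group)
  # hand sums: t=1 (n=4,n_A=2): O-E = 1-1/2; t=2 (n=3,n_A=1): 1-1/3;
  # t=3 (n=2,n_A=0): 0-0; t=4: single subject, V=0
  # V = 1/4 + 2/9
  hand <- (1 / 2 + 2 / 3)^2 / (1 / 4 + 2 / 9)
  expect_equal(lr$statistic, hand, tolerance = 1e-10)
  expect_equal(lr$p_value, pchisq(hand, 1, lower.tail = FALSE))

  set.seed(23)
  t2 <- round(rexp(24, 0.1), 2); e2 <- rbinom(24, 1, 0.8)
  g2 <- rep(c("x", "y"), each = 12)
  lr2 <- logrank_test(tibble::tibble(time = t2, event = e2, group = g2), group)
  expect_equal(lr2$statistic, oracle_logrank_chisq(t2, e2, g2),
               tolerance = 1e-8)
})

test_that("log-rank is zero for identical groups and invariant to label swap", {
  base <- tibble::tibble(time = c(1, 3, 5, 7), event = c(1, 1, 0, 1))
  d <- dplyr::bind_rows(dplyr::mutate(base, group = "A"),
                        dplyr::mutate(base, group = "B"))
  lr <- logrank_test(d, group)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p_value, 1)

  set.seed(29)
  d2 <- tibble::tibble(time = rexp(30, 0.1), event = rbinom(30, 1, 0.7),
                       group = rep(0:1, 15))
  swapped <- dplyr::mutate(d2, group = 1 - group)
  expect_equal(logrank_test(d2, group)$statistic,
               logrank_test(swapped, group)$statistic, tolerance = 1e-12)

  expect_error(logrank_test(dplyr::mutate(base, group = "A"), group), "2 non-empty")
  expect_error(
    logrank_test(tibble::tibble(time = 1:4, event = 0, group = rep(0:1, 2)),
                 group), "No events")
})

test_that("log-rank p approximates the exact permutation oracle at small n", {
  time <- c(1.2, 2.5, 3.1, 4.8, 0.9, 2.2, 6.4, 5.5)
  event <- c(1, 1, 0, 1, 1, 1, 1, 0)
  group <- rep(c("A", "B"), each = 4)
  p_chisq <- logrank_test(tibble::tibble(time, event, group), group)$p_value
  p_perm <- oracle_logrank_permutation_p(time, event, group)
  # asymptotic chi-square vs exact enumeration at n = 8
  expect_lt(abs(p_chisq - p_perm), 0.1)
})

test_that("Cox log-HR matches grid-search maximization of the partial likelihood", {
  time <- c(0.8, 1.5, 2.3, 3.1, 4.2, 5.0, 6.7, 7.4)
  event <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(1, 0, 1, 1, 0, 1, 0, 0)
  fit <- cox_fit(tibble::tibble(time, event, status = x), status)
  expect_equal(fit$log_hr, oracle_cox_grid(time, event, x), tolerance = 1e-3)
  expect_true(fit$converged)
  expect_gt(fit$hr, 0)
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
})

test_that("Cox fit respects relabeling symmetry and mirrored data", {
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 1, 1, 1)
  d <- tibble::tibble(time, event, status = c(0, 1, 0, 1, 0, 1))
  f1 <- cox_fit(d, status)
  f2 <- cox_fit(dplyr::mutate(d, status = 1 - status), status)
  expect_equal(f1$log_hr, -f2$log_hr, tolerance = 1e-9)

  # perfectly mirrored groups: identical event patterns in both levels
  base <- tibble::tibble(time = c(1, 2, 3, 4), event = c(1, 1, 0, 1))
  sym <- dplyr::bind_rows(dplyr::mutate(base, status = 0),
                          dplyr::mutate(base, status = 1))
  expect_equal(cox_fit(sym, status)$log_hr, 0, tolerance = 1e-8)

  expect_error(cox_fit(dplyr::mutate(d, status = 1), status), "No variation")
  expect_error(cox_fit(dplyr::mutate(d, event = 0), status), "censored")
})

test_that("monotone likelihood is reported through the converged flag", {
  # all events in one group, perfectly separated times
  d <- tibble::tibble(time = c(1, 2, 3, 10, 11, 12),
                      event = c(1, 1, 1, 1, 1, 1),
                      status = c(1, 1, 1, 0, 0, 0))
  fit <- suppressWarnings(cox_fit(d, status))
  expect_false(fit$converged)
})

test_that("stratified report composes scoring, split, KM, log-rank and Cox", {
  cohort <- simulate_cohort(balanced_config(n_samples = 200, seed = 2))
  rep <- stratified_km_report(cohort$expression, cohort$clinical, "RESIST-M")
  g <- glance(rep)
  expect_equal(g$n_high + g$n_low, 200)
  expect_equal(sort(unique(rep$km$group)), c("high-risk", "low-risk"))
  # planted hazard ratio of 2.5 should show up as elevated risk-group HR
  expect_gt(g$hr, 1)
  expect_lt(g$logrank_p, 0.05)
  expect_s3_class(tidy(rep), "tbl_df")
  expect_s3_class(autoplot(rep), "ggplot")

  # duplicated cohort halves with separated scores: the split puts one copy
  # in each arm, so both groups carry identical survival data
  cl <- tibble::tibble(sample_id = c(paste0("a", 1:4), paste0("b", 1:4)),
                       time = rep(c(1, 2, 3, 4), 2),
                       event = rep(c(1, 1, 0, 1), 2))
  ex <- tibble::tibble(gene = "G1",
                       !!!setNames(as.list(rep(c(5, 1), each = 4)), cl$sample_id))
  rep2 <- stratified_km_report(ex, cl, gene_signature("G", up_genes = "G1"),
                               method = "mean")
  expect_equal(rep2$logrank$statistic, 0, tolerance = 1e-12)
})
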