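# Committed fixtures and cohort configurations shared across test files.

# 9-gene x 5-sample fixture on the RESIST-M gene set (values frozen).
resist_m_fixture <- function() {
  tibble::tibble(
    gene = c("SERPINE1", "SMARCD3", "SC5D", "FDPS", "MVD", "HMGCS1",
             "HMGCR", "CYP51A1", "ACAT2"),
    s1 = c(10.98, 11.24, 3.43, 9.97, 7.70, 6.23, 8.84, 1.62, 7.88),
    s2 = c(8.46, 5.49, 8.63, 11.22, 3.07, 5.55, 11.28, 11.74, 1.41),
    s3 = c(5.70, 6.72, 10.85, 1.66, 11.87, 11.36, 0.99, 6.17, 4.68),
    s4 = c(10.87, 5.36, 10.03, 8.85, 9.73, 4.66, 8.22, 0.05, 9.99),
    s5 = c(0.09, 2.49, 10.88, 7.34, 4.55, 5.23, 0.45, 11.68, 5.18)
  )
}

# 5-gene x 3-sample fixture on the Yin gene set (values frozen).
yin_fixture <- function() {
  tibble::tibble(
    gene = c("P4HA1", "ATF6", "PHLDB3", "IBTK", "COPE"),
    a = c(9.66, 9.10, 7.12, 9.77, 6.95),
    b = c(4.67, 4.77, 5.19, 8.28, 2.31),
    c = c(7.99, 7.42, 3.37, 4.09, 6.12)
  )
}

# Balanced-risk design: CMS4-and-fibrotic prevalence 0.5, so the median
# split can align with the planted flag (used for alignment / recovery /
# integration simulations).
balanced_config <- function(n_samples = 400, seed = 1L, ...) {
  cohort_config(
    n_samples = n_samples,
    subtype_proportions = c(CMS1 = 0.10, CMS2 = 0.25, CMS3 = 0.15, CMS4 = 0.50),
    fibrotic_fraction_in_cms4 = 1,
    seed = seed, ...)
}

# Null design: no expression effect, no survival effect.
null_config <- function(n_samples = 200, seed = 1L, ...) {
  cohort_config(n_samples = n_samples, m1_shift = 0, m2_shift = 0,
                planted_hr = 1, n_filler_genes = 10, seed = seed, ...)
}
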