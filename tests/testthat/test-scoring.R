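test_that("reflection swaps min and max and matches the printed formula", {
  expect_equal(reflect_gene(c(1, 3, 5)), c(5, 3, 1))
  expect_equal(reflect_gene(c(2, 2, 2)), c(2, 2, 2))
  expect_equal(reflect_gene(c(0.5, 2.0, 4.0, 10.0)), c(10.0, 8.5, 6.5, 0.5))

  set.seed(101)
  for (i in 1:50) {
    x <- rnorm(sample(2:40, 1), sd = runif(1, 0.1, 10))
    r <- reflect_gene(x)
    expect_equal(r, oracle_reflect(x), tolerance = 1e-12)
    # involution
    expect_equal(reflect_gene(r), x, tolerance = 1e-12)
    # order exactly reversed for distinct values
    if (!anyDuplicated(x)) expect_equal(rank(r), length(x) + 1 - rank(x))
  }

  expect_error(reflect_gene(numeric(0)), "empty")
  expect_error(reflect_gene(c(a = 1, b = NA)), "b")
})

test_that("reflected-median scores match the brute-force oracle on the frozen fixture", {
  expr <- resist_m_fixture()
  sig <- builtin_signatures()[["RESIST-M"]]
  sc <- score_signature(expr, sig, method = "reflected_median")
  expected <- oracle_reflected_median(expr, sig$up_genes, sig$down_genes)
  expect_equal(sc$score, unname(expected[sc$sample_id]), tolerance = 1e-12)
  expect_identical(attr(sc, "polarity"), "lower = higher risk")
})

test_that("reflected-median score has the documented polarity and shift invariance", {
  # sample A has strictly higher M1 and strictly lower M2 than B
  expr <- tibble::tibble(
    gene = c("SERPINE1", "SMARCD3", "SC5D", "FDPS", "MVD", "HMGCS1",
             "HMGCR", "CYP51A1", "ACAT2"),
    A = c(9, 9, 1, 1, 1, 1, 1, 1, 1),
    B = c(2, 2, 7, 7, 7, 7, 7, 7, 7),
    C = c(5, 5, 5, 5, 5, 5, 5, 5, 5)
  )
  sig <- builtin_signatures()[["RESIST-M"]]
  sc <- score_signature(expr, sig)
  scores <- setNames(sc$score, sc$sample_id)
  expect_lt(scores[["A"]], scores[["B"]])
  # a sample where every gene has the same value c scores exactly c
  expect_equal(scores[["C"]], 5)

  # adding a constant to the whole matrix shifts every score by that constant
  shifted <- dplyr::mutate(expr, dplyr::across(-gene, ~ .x + 3.7))
  expect_equal(score_signature(shifted, sig)$score, sc$score + 3.7,
               tolerance = 1e-12)
})

test_that("mean scores equal hand-computed means and degenerate cases behave", {
  expr <- yin_fixture()
  sc <- score_mean(expr, expr$gene)
  hand <- colMeans(as.matrix(expr[, -1]))
  expect_equal(sc$score, unname(hand), tolerance = 1e-12)

  one <- score_mean(expr, "ATF6")
  expect_equal(one$score, unname(unlist(expr[expr$gene == "ATF6", -1])),
               tolerance = 1e-12)
  expect_equal(score_mean(tibble::tibble(gene = c("g1", "g2"), s = c(1, 3)),
                          c("g1", "g2"))$score, 2)
  expect_error(score_mean(expr, c("NOPE1", "NOPE2")), "None of the")
})

test_that("missing signature genes warn and intersect, or error in strict mode", {
  expr <- yin_fixture()[1:3, ]
  expect_warning(sc <- score_mean(expr, yin_fixture()$gene), "IBTK")
  expect_length(attr(sc, "genes_used"), 3)
  expect_error(
    score_signature(yin_fixture()[1:3, ], builtin_signatures()[["Yin"]],
                    method = "mean", strict = TRUE),
    "IBTK")
})

test_that("median split follows the strictly-greater tie rule", {
  s4 <- assign_status(tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4)))
  expect_equal(s4$status, c(0L, 0L, 1L, 1L))
  expect_equal(attr(s4, "threshold"), 2.5)

  s3 <- assign_status(tibble::tibble(sample_id = letters[1:3], score = c(1, 2, 3)))
  expect_equal(s3$status, c(0L, 0L, 1L))

  expect_warning(
    sd <- assign_status(tibble::tibble(sample_id = letters[1:3], score = c(2, 2, 2))),
    "degenerate")
  expect_equal(sd$status, c(0L, 0L, 0L))
})

test_that("all-distinct scores split floor(n/2) high / ceiling(n/2) low", {
  set.seed(7)
  for (n in c(4, 5, 11, 20)) {
    st <- assign_status(tibble::tibble(sample_id = as.character(1:n),
                                       score = sample(rnorm(n))))
    expect_equal(sum(st$status == 1), floor(n / 2))
    expect_equal(sum(st$status == 0), ceiling(n / 2))
  }
})

test_that("risk groups flip with score polarity", {
  sc <- tibble::tibble(sample_id = letters[1:4], score = c(1, 2, 3, 4))
  st <- assign_status(sc)
  attr(st, "polarity") <- "lower = higher risk"
  expect_equal(risk_groups(st)$risk, c(1L, 1L, 0L, 0L))
  attr(st, "polarity") <- "higher = higher expression"
  expect_equal(risk_groups(st)$risk, c(0L, 0L, 1L, 1L))
})

test_that("row z-scoring gives mean 0 / sd 1 rows and zeroes constant rows", {
  expect_equal(
    zscore_rows(tibble::tibble(gene = "g", s1 = 1, s2 = 2, s3 = 3))[, -1] |>
      unlist() |> unname(),
    c(-1, 0, 1))
  expect_warning(
    zc <- zscore_rows(tibble::tibble(gene = "g", s1 = 2, s2 = 2, s3 = 2)),
    "constant")
  expect_equal(unname(unlist(zc[, -1])), c(0, 0, 0))
  expect_error(zscore_rows(tibble::tibble(gene = "g", s1 = 1)), "2 samples")

  set.seed(5)
  z <- zscore_rows(tibble::tibble(gene = "g", !!!setNames(as.list(rnorm(20, 5, 2)),
                                                          paste0("s", 1:20))))
  v <- unlist(z[, -1])
  expect_lt(abs(mean(v)), 1e-12)
  expect_equal(sd(v), 1, tolerance = 1e-12)
})
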