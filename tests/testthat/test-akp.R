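test_that("similarity sets enumerate exactly the within-group pairs", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3))
  s2 <- intraGroupSimilarity(m, c(TRUE, TRUE))
  expect_equal(cValues(s2), 1)
  set.seed(2)
  m5 <- randomCountMatrix(7, 10)
  s5 <- intraGroupSimilarity(m5, c(rep(TRUE, 5), FALSE, FALSE),
                             group = "exposed")
  expect_length(cValues(s5), 10)
  expect_equal(groupLabel(s5), "exposed")
  expect_equal(sort(cValues(s5)),
               sort(bruteCIndex(m5, c(rep(TRUE, 5), FALSE, FALSE))),
               tolerance = 1e-12)
  expect_error(intraGroupSimilarity(m5, c(TRUE, rep(FALSE, 6))),
               "insufficient group")
})

makeSet <- function(values, group = "g") {
  n <- ceiling((1 + sqrt(1 + 8 * length(values))) / 2)
  ids <- paste0("s", seq_len(n))
  pairs <- t(combn(ids, 2))[seq_along(values), , drop = FALSE]
  new("SimilaritySet", group = group, pairs = pairs, values = values,
      metric = "ruzicka")
}

test_that("akp verdicts follow the three-hypothesis rule", {
  set.seed(1)
  hi <- makeSet(runif(45, 0.7, 0.9), "exposed")
  lo <- makeSet(runif(45, 0.3, 0.5), "non_exposed")
  vAkp <- akpTest(hi, lo, convention = "paper")
  expect_equal(vAkp@verdict, "AKP")
  expect_lt(vAkp@pTwo, 0.05)
  expect_lt(vAkp@pGreater, 0.001)
  expect_gt(vAkp@pLess, 0.99)
  vAnti <- akpTest(lo, hi, convention = "paper")
  expect_equal(vAnti@verdict, "anti-AKP")
  expect_lt(vAnti@pLess, 0.001)
  same <- akpTest(makeSet(seq(0.2, 0.8, length.out = 10)),
                  makeSet(seq(0.2, 0.8, length.out = 10)))
  expect_gt(same@pTwo, 0.95)
  expect_equal(same@verdict, "none")
})

test_that("switching convention swaps the verdict labels exactly", {
  set.seed(8)
  for (i in 1:5) {
    a <- makeSet(runif(10, 0.2, 0.9))
    b <- makeSet(runif(10, 0.2, 0.9))
    vp <- akpTest(a, b, convention = "paper")@verdict
    ve <- akpTest(a, b, convention = "ecological")@verdict
    expected <- switch(vp, AKP = "anti-AKP", `anti-AKP` = "AKP",
                       none = "none")
    expect_equal(ve, expected)
  }
})

test_that("verdict medians and IQRs summarize the input collections", {
  v <- akpTest(makeSet(c(0.2, 0.4, 0.6)), makeSet(c(0.5, 0.7, 0.9)),
               factor = "smoking")
  expect_equal(v@medianE, 0.4)
  expect_equal(v@medianNE, 0.7)
  expect_equal(unname(v@iqrE), unname(quantile(c(0.2, 0.4, 0.6),
                                               c(0.25, 0.75))))
  df <- as.data.frame(v)
  expect_equal(df$factor, "smoking")
  expect_named(df, c("factor", "median_e", "q1_e", "q3_e", "median_ne",
                     "q1_ne", "q3_ne", "p_two", "p_greater", "p_less",
                     "verdict", "convention"))
})

test_that("the permutation test is exact for a perfect separation", {
  ## exposed: three identical communities (all pairwise C = 1);
  ## non-exposed: disjoint single-taxon communities (all pairwise C = 0).
  ## Any relabelling strictly lowers the median contrast, so the smallest
  ## attainable p is realized.
  n <- 50
  p <- 50
  m <- matrix(0, n, p, dimnames = list(paste0("s", 1:n), NULL))
  m[1:3, 1:3] <- 1
  for (i in 4:n) m[i, i] <- 1
  mask <- c(rep(TRUE, 3), rep(FALSE, n - 3))
  pt <- akpPermutationTest(m, mask, nPerm = 999, seed = 1)
  expect_equal(pt$statistic, 1)
  expect_equal(pt$pGreater, 1 / 1000)
  expect_error(akpPermutationTest(m, mask, nPerm = 50), "parameter error")
})

test_that("identical groups give a null permutation p-value", {
  set.seed(4)
  m <- randomCountMatrix(12, 20)
  pt <- akpPermutationTest(m, rep(c(TRUE, FALSE), 6), nPerm = 199, seed = 2)
  expect_gt(pt$pTwo, 0.1)
})

test_that("akpTable reproduces per-factor akpTest results", {
  cohort <- generateCohort(n = 30, marginals = list(smoking = 12,
                                                    obesity = 15),
                           seed = 6)
  se <- generateMicrobiome(cohort, nTaxa = 40, depth = 1000, seed = 6)
  tab <- akpTable(se, factors = c("smoking", "obesity"))
  expect_equal(nrow(tab), 2L)
  mask <- cohort$smoking == "ever"
  ref <- akpTest(intraGroupSimilarity(se, mask, group = "exposed"),
                 intraGroupSimilarity(se, !mask, group = "non_exposed"),
                 factor = "smoking")
  expect_equal(tab$median_e[1], ref@medianE)
  expect_equal(tab$p_two[1], ref@pTwo)
  expect_true(all(tab$median_e >= 0 & tab$median_e <= 1))
})
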