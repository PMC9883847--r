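test_that("procrustes m2 vanishes for a rotated, scaled copy", {
  set.seed(1)
  y <- matrix(rnorm(18 * 3), 18, 3)
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  y2 <- 2.5 * y %*% rot
  d1 <- as.matrix(dist(y))
  d2 <- as.matrix(dist(y2))
  dimnames(d1) <- dimnames(d2) <- list(paste0("s", 1:18), paste0("s", 1:18))
  pr <- procrustesProtest(d1, d2, nPerm = 99, seed = 1)
  expect_lte(pr@m2, 1e-10)
  expect_equal(pr@pPerm, 1 / 100)
})

test_that("procrustes m2 is invariant to isometries of either input", {
  set.seed(2)
  y1 <- matrix(rnorm(15 * 3), 15, 3)
  y2 <- matrix(rnorm(15 * 3), 15, 3)
  ids <- paste0("s", 1:15)
  dd <- function(y) {
    d <- as.matrix(dist(y))
    dimnames(d) <- list(ids, ids)
    d
  }
  base <- procrustesProtest(dd(y1), dd(y2), nPerm = 99, seed = 3)@m2
  rot <- qr.Q(qr(matrix(rnorm(9), 3)))
  m2rot <- procrustesProtest(dd(y1 %*% rot * 7), dd(y2), nPerm = 99,
                             seed = 3)@m2
  expect_equal(m2rot, base, tolerance = 1e-9)
  d3 <- dd(y2)
  rownames(d3)[1] <- colnames(d3)[1] <- "zz"
  expect_error(procrustesProtest(dd(y1), d3), "alignment error")
})

test_that("procrustes m2 agrees with the vegan protest statistic", {
  skip_if_not_installed("vegan")
  set.seed(3)
  d1 <- randomDistanceMatrix(16)
  d2 <- randomDistanceMatrix(16)
  pr <- procrustesProtest(d1, d2, nPerm = 99, seed = 1)
  o1 <- pcoaOrdination(d1)
  o2 <- pcoaOrdination(d2)
  k <- pr@k
  ref <- vegan::protest(o1$coordinates[, 1:k], o2$coordinates[, 1:k],
                        permutations = 99, symmetric = TRUE)
  expect_equal(pr@m2, ref$ss, tolerance = 1e-9)
})

test_that("permanova enumerates tiny designs exhaustively", {
  ## two separated 2-point clouds: observed split and its complement tie
  y <- rbind(c(0, 0), c(0, 0.1), c(10, 0), c(10, 0.1))
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", 1:4), paste0("s", 1:4))
  pm <- permanova(d, c("a", "a", "b", "b"))
  expect_true(pm@exhaustive)
  expect_equal(pm@nPerm, 6)
  expect_equal(pm@pPerm, 1 / 3)
  expect_equal(pm@R2 + (1 - pm@R2), 1)
  expect_error(permanova(d, rep("a", 4)), "degenerate design")
})

test_that("permanova pseudo-F and R2 agree with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(8:14, 1)
    d <- randomDistanceMatrix(n)
    n1 <- sample(3:(n - 3), 1)
    lab <- sample(rep(c("a", "b"), c(n1, n - n1)))
    pm <- permanova(d, lab, nPerm = 19, seed = 1, maxExhaustive = 5)
    ref <- vegan::adonis2(as.dist(d) ~ lab, permutations = 19)
    expect_equal(pm@pseudoF, ref$F[1], tolerance = 1e-9)
    expect_equal(pm@R2, ref$R2[1], tolerance = 1e-9)
  }
})

test_that("a null permanova is calibrated near its nominal level", {
  set.seed(6)
  rej <- 0
  for (i in 1:60) {
    d <- randomDistanceMatrix(20)
    lab <- rep(c("a", "b"), each = 10)
    if (permanova(d, lab, nPerm = 99, seed = i)@pPerm <= 0.05) {
      rej <- rej + 1
    }
  }
  expect_lte(rej / 60, 0.12)
})

test_that("the alpha-diversity linear model matches the pooled t-test", {
  set.seed(5)
  for (i in 1:5) {
    a <- rnorm(30)
    f <- rep(c("x", "y"), 15)
    fit <- alphaGlm(a, f)
    ref <- t.test(a ~ f, var.equal = TRUE)
    expect_equal(fit$p, ref$p.value, tolerance = 1e-10)
  }
  expect_error(alphaGlm(rnorm(10), rep("x", 10)), "design error")
  f <- rep(c("x", "y"), 10)
  collinear <- data.frame(z = as.integer(f == "y"))
  expect_error(alphaGlm(rnorm(20), f, collinear), "design error")
})

test_that("clade abundances sum descendants on the ppm scale", {
  cohort <- generateCohort(n = 8, seed = 1)
  se <- generateMicrobiome(cohort, nTaxa = 20, depth = 500, seed = 1)
  feat <- cladeAbundance(se)
  ## every kingdom-level row is 1e6 (all leaves descend from Bacteria)
  expect_equal(unname(feat["Bacteria", ]), rep(1e6, 8), tolerance = 1e-9)
  ## phylum rows sum to the kingdom row
  phyla <- rownames(feat)[grepl("^Bacteria\\|[^|]+$", rownames(feat))]
  expect_equal(unname(colSums(feat[phyla, , drop = FALSE])),
               rep(1e6, 8), tolerance = 1e-6)
})

test_that("lefse hits are symmetric in the class labels and nested in the screen", {
  cohort <- generateCohort(n = 40, marginals = list(smoking = 20), seed = 9)
  se <- generateMicrobiome(cohort, nTaxa = 30, depth = 5000, seed = 9)
  cm <- SummarizedExperiment::assay(se)
  tax <- as.data.frame(SummarizedExperiment::rowData(se))
  mask <- cohort$smoking == "ever"
  cm[1:3, mask] <- cm[1:3, mask] * 8
  se2 <- AbundanceExperiment(cm, tax, cohort)
  cls <- ifelse(mask, "exposed", "non_exposed")
  h1 <- lefseTwoClass(se2, cls, seed = 1)
  h2 <- lefseTwoClass(se2, ifelse(mask, "non_exposed", "exposed"),
                      seed = 1)
  expect_setequal(h1$lineage, h2$lineage)
  flip <- ifelse(h2$enriched_class == "exposed", "non_exposed", "exposed")
  expect_equal(h1$enriched_class[match(h2$lineage, h1$lineage)], flip)
  ## stage-1 survivors are a superset of the final hits
  screen <- attr(h1, "screen")
  expect_true(all(h1$lineage %in% screen$lineage[screen$kw_p < 0.05]))
  expect_true(all(h1$lda_score >= 2))
  expect_error(lefseTwoClass(se2, rep("one", ncol(se2))), "design error")
})

test_that("a planted clade shift is the top-ranked lefse hit", {
  found <- 0
  for (seed in 1:5) {
    cohort <- generateCohort(n = 60, marginals = list(smoking = 30),
                             seed = seed)
    se <- generateMicrobiome(cohort, nTaxa = 40, depth = 10000,
                             theta = 80, seed = seed)
    cm <- SummarizedExperiment::assay(se)
    tax <- as.data.frame(SummarizedExperiment::rowData(se))
    g <- tax$genus[1]
    mask <- cohort$smoking == "ever"
    cm[tax$genus == g, mask] <- cm[tax$genus == g, mask] * 10
    hits <- lefseTwoClass(AbundanceExperiment(cm, tax, cohort),
                          ifelse(mask, "exposed", "non_exposed"),
                          seed = seed)
    hitG <- hits[grepl(g, hits$lineage, fixed = TRUE), ]
    lineageG <- paste(unlist(tax[tax$genus == g, ][1,
                      c("kingdom", "phylum", "class", "order", "family",
                        "genus")]), collapse = "|")
    ## the top-ranked hit is the planted clade or one of its ancestors
    topIsPlanted <- startsWith(lineageG, hits$lineage[1]) ||
      startsWith(hits$lineage[1], lineageG)
    if (nrow(hitG) && all(hitG$enriched_class == "exposed") &&
        topIsPlanted) {
      found <- found + 1
    }
  }
  expect_gte(found, 4)
})
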