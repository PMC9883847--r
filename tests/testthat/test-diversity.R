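test_that("chao1 follows the bias-corrected closed form", {
  expect_equal(chao1(c(5, 5, 5)), 3)
  expect_equal(chao1(c(1, 1, 2, 2)), 4 + 2 * 1 / (2 * 3))
  expect_equal(chao1(c(1, 1, 1)), 6)
  expect_gte(chao1(c(1, 3, 0, 7)), 3)  # never below observed richness
  expect_error(chao1(c(1.5, 2)), "integer")
  expect_error(chao1(c(-1, 2)), "integer")
  expect_equal(discretizeIntake(c(0.2, 0, 3.6)), c(1L, 0L, 4L))
})

test_that("shannon and simpson match their closed forms", {
  expect_equal(shannonIndex(rep(1, 4)), log(4))
  expect_equal(simpsonIndex(rep(1, 4)), 0.75)
  expect_equal(shannonIndex(c(5, 0, 0)), 0)
  expect_equal(simpsonIndex(c(5, 0, 0)), 0)
  expect_equal(shannonIndex(c(0.5, 0.25, 0.25)),
               -(0.5 * log(0.5) + 2 * 0.25 * log(0.25)))
  expect_error(shannonIndex(c(0, 0)), "domain error")
  expect_error(simpsonIndex(c(0, 0)), "domain error")
})

test_that("ruzicka similarity matches hand values and stays bounded", {
  expect_equal(ruzickaSimilarity(c(1, 2), c(2, 1)), 0.5)
  expect_equal(ruzickaSimilarity(c(3, 1, 4), c(3, 1, 4)), 1)
  expect_equal(ruzickaSimilarity(c(1, 0), c(0, 2)), 0)
  expect_error(ruzickaSimilarity(1:3, 1:2), "shape error")
  expect_error(ruzickaSimilarity(c(0, 0), c(0, 0)), "domain error")
  set.seed(1)
  for (i in 1:20) {
    x <- rgamma(8, 1)
    y <- rgamma(8, 1)
    s <- ruzickaSimilarity(x, y)
    expect_gte(s, 0)
    expect_lte(s, 1)
    ## scale invariance under a common rescaling
    expect_equal(ruzickaSimilarity(3.7 * x, 3.7 * y), s)
    ## adding a shared equal-abundance taxon never decreases similarity
    a <- runif(1, 0, 5)
    expect_gte(ruzickaSimilarity(c(x, a), c(y, a)), s - 1e-12)
  }
})

test_that("pairwise ruzicka equals the brute-force double loop", {
  set.seed(42)
  for (i in 1:20) {
    m <- randomCountMatrix(5, 12)
    s <- pairwiseRuzicka(m)
    rel <- m / rowSums(m)
    for (a in 1:4) {
      for (b in (a + 1):5) {
        expect_equal(s[a, b], bruteRuzicka(rel[a, ], rel[b, ]),
                     tolerance = 1e-12)
      }
    }
  }
})

test_that("unifrac matches hand-computed branch sums", {
  tr <- readNewick(text = "((A:1,B:1):1,(C:1,D:1):1);")
  expect_equal(unweightedUnifrac(tr, c(A = 1), c(B = 1)), 2 / 3)
  expect_equal(unweightedUnifrac(tr, c(A = 1), c(A = 2)), 0)
  expect_equal(weightedUnifrac(tr, c(A = 1), c(C = 1)), 1)
  expect_equal(weightedUnifrac(tr, c(A = 1), c(C = 1), normalized = FALSE),
               4)
  expect_equal(weightedUnifrac(tr, c(A = 2, B = 2), c(A = 1, B = 1)), 0)
  expect_error(unweightedUnifrac(tr, c(E = 1), c(A = 1)), "mapping error")
})

test_that("unifrac agrees with the phyloseq reference on random instances", {
  skip_if_not_installed("phyloseq")
  set.seed(9)
  for (i in 1:20) {
    nt <- sample(4:8, 1)
    tr <- ape::rtree(nt)
    m <- randomCountMatrix(4, nt)
    colnames(m) <- tr$tip.label
    ps <- phyloseq::phyloseq(
      phyloseq::otu_table(t(m), taxa_are_rows = TRUE),
      phyloseq::phy_tree(tr))
    du <- unifracDistance(m, tr, "unweighted")
    dw <- unifracDistance(m, tr, "weighted", normalized = TRUE)
    duRef <- as.matrix(phyloseq::UniFrac(ps, weighted = FALSE))
    dwRef <- as.matrix(phyloseq::UniFrac(ps, weighted = TRUE,
                                         normalized = TRUE))
    expect_equal(du, duRef[rownames(du), colnames(du)], tolerance = 1e-10)
    expect_equal(dw, dwRef[rownames(dw), colnames(dw)], tolerance = 1e-10)
    expect_true(all(du >= -1e-12 & du <= 1 + 1e-12))
    expect_true(all(dw >= -1e-12 & dw <= 1 + 1e-12))
  }
})

test_that("aitchison distance is compositional and matches the clr form", {
  x <- rbind(a = c(1, exp(1)), b = c(exp(1), 1))
  expect_equal(aitchisonDistance(x, pseudocount = 0)[1, 2], sqrt(2))
  xx <- rbind(a = c(2, 3, 5), b = c(2, 3, 5))
  expect_equal(aitchisonDistance(xx, pseudocount = 0)[1, 2], 0)
  ## sample-wise rescaling leaves distances unchanged
  y <- rbind(a = c(2, 3, 5), b = c(1, 7, 2), c = c(4, 4, 2))
  d1 <- aitchisonDistance(y, pseudocount = 0)
  y2 <- y
  y2[1, ] <- y2[1, ] * 13
  expect_equal(aitchisonDistance(y2, pseudocount = 0), d1)
  ## triangle inequality
  expect_lte(d1[1, 3], d1[1, 2] + d1[2, 3] + 1e-12)
  expect_error(aitchisonDistance(rbind(c(0, 1)), pseudocount = 0),
               "parameter error")
  expect_error(aitchisonDistance(y, pseudocount = -1), "parameter error")
})

test_that("aitchison distance agrees with the vegan reference", {
  skip_if_not_installed("vegan")
  set.seed(4)
  m <- randomCountMatrix(6, 10)
  d <- aitchisonDistance(m, pseudocount = 1)
  dRef <- as.matrix(vegan::vegdist(m + 1, method = "aitchison"))
  expect_equal(unname(d), unname(dRef), tolerance = 1e-10)
})

test_that("pcoa recovers Euclidean configurations up to isometry", {
  set.seed(5)
  y <- matrix(rnorm(15 * 2), 15, 2)
  d <- as.matrix(dist(y))
  dimnames(d) <- list(paste0("s", 1:15), paste0("s", 1:15))
  ord <- pcoaOrdination(d)
  ## the recovered inter-point distances reproduce the originals
  expect_equal(as.matrix(dist(ord$coordinates[, 1:2])), unname(d),
               ignore_attr = TRUE, tolerance = 1e-8)
  ## three equidistant points: two equal positive eigenvalues
  d3 <- matrix(1, 3, 3) - diag(3)
  dimnames(d3) <- list(letters[1:3], letters[1:3])
  e3 <- pcoaOrdination(d3)$eigenvalues
  expect_equal(length(e3), 2L)
  expect_equal(e3[1], e3[2], tolerance = 1e-10)
  ## n = 2: coordinates at +/- d/2
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(unname(sort(pcoaOrdination(d2)$coordinates[, 1])),
               c(-1.5, 1.5))
  expect_error(pcoaOrdination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})
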