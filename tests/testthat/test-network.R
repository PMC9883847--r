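test_that("hurdle encoding separates incidence from CLR-on-nonzero", {
  counts <- rbind(t1 = c(0, 5, 5), t2 = c(2, 4, 8), t3 = c(1, 1, 1))
  colnames(counts) <- paste0("s", 1:3)
  des <- hurdleEncode(counts)
  expect_equal(unname(des@incidence[, "t1"]), c(0, 1, 1))
  expect_true(is.na(des@abundance["s1", "t1"]))
  ## sample s2 has counts (5, 4, 1): CLR over all three entries sums to 0
  expect_equal(sum(des@abundance["s2", ]), 0, tolerance = 1e-12)
  expect_equal(sum(des@abundance["s3", ]), 0, tolerance = 1e-12)
  ## sample with counts (0, 2, 1): CLR over the two positive entries
  expect_equal(unname(des@abundance["s1", c("t2", "t3")]),
               c(log(2) - log(2) / 2, log(1) - log(2) / 2))
  ## sample (0, 5, 5): incidence (0, 1, 1), CLR over the two fives = (0, 0)
  d2 <- hurdleEncode(cbind(s1 = c(a = 0, b = 5, c = 5),
                           s2 = c(a = 1, b = 1, c = 1)))
  expect_equal(unname(d2@incidence["s1", ]), c(0, 1, 1))
  expect_equal(unname(d2@abundance["s1", c("b", "c")]), c(0, 0))
})

test_that("all-zero taxa are dropped with a warning", {
  counts <- rbind(t1 = c(1, 2), t2 = c(0, 0), t3 = c(3, 1))
  colnames(counts) <- c("s1", "s2")
  expect_warning(des <- hurdleEncode(counts), "t2")
  expect_equal(des@dropped, "t2")
  expect_equal(colnames(des@incidence), c("t1", "t3"))
})

test_that("network estimation needs at least 3 taxa and warns when short", {
  sim <- rHurdleNetwork(10, diag(1, 2), seed = 1)
  expect_error(estimateNetwork(sim$design), "size error")
  sim2 <- rHurdleNetwork(8, diag(1, 5), seed = 1)
  expect_warning(estimateNetwork(sim2$design), "unstable")
})

test_that("independent taxa give an (almost) empty network", {
  for (seed in 1:3) {
    sim <- rHurdleNetwork(200, diag(1, 10), seed = seed)
    g <- estimateNetwork(sim$design, selection = "bic")
    expect_lte(networkDensity(g), 0.05)
  }
})

test_that("a planted sparse structure is recovered with high F1", {
  sim <- rHurdleNetwork(200, chainPrecision(10), seed = 1)
  g <- estimateNetwork(sim$design, selection = "bic")
  expect_gte(edgeF1(g, sim$adjacency), 0.8)
  expect_true(all(abs(networkEdges(g)$weight) <= 1))
  ## true chain neighbours carry positive partial correlations
  e <- networkEdges(g)
  chainEdges <- e[abs(as.integer(sub("T", "", e$u)) -
                      as.integer(sub("T", "", e$v))) == 1, ]
  expect_true(all(chainEdges$weight > 0))
})

test_that("the estimate is invariant to sample and taxon order", {
  sim <- rHurdleNetwork(120, chainPrecision(6), seed = 2)
  g1 <- estimateNetwork(sim$design, selection = "bic")
  des <- sim$design
  set.seed(1)
  rowPerm <- sample.int(nrow(des@incidence))
  colPerm <- sample.int(ncol(des@incidence))
  des2 <- new("HurdleDesign",
              incidence = des@incidence[rowPerm, colPerm],
              abundance = des@abundance[rowPerm, colPerm],
              level = des@level, dropped = character(0))
  g2 <- estimateNetwork(des2, selection = "bic")
  e1 <- networkEdges(g1)
  e2 <- networkEdges(g2)
  key <- function(e) sort(paste(e$u, e$v))
  expect_equal(key(e1), key(e2))
  expect_equal(e2$weight[order(paste(e2$u, e2$v))],
               e1$weight[order(paste(e1$u, e1$v))], tolerance = 1e-8)
})

test_that("a duplicated taxon yields a near-unit edge weight", {
  sim <- rHurdleNetwork(150, diag(1, 6), zeroProb = 0, seed = 3)
  ab <- sim$design@abundance
  set.seed(3)
  ab <- cbind(ab, T07 = ab[, 1] + rnorm(150, sd = 0.05))
  des <- new("HurdleDesign", incidence = (!is.na(ab)) * 1, abundance = ab,
             level = "simulated", dropped = character(0))
  e <- networkEdges(estimateNetwork(des))
  dup <- e[(e$u == "T01" & e$v == "T07"), ]
  expect_equal(nrow(dup), 1L)
  expect_gt(abs(dup$weight), 0.95)
  expect_equal(dup$sign, "positive")
})

test_that("connectivity comparison reports densities, degrees and hubs", {
  nodes <- paste0("T", 1:5)
  complete <- t(combn(nodes, 2))
  gFull <- new("CoabundanceNetwork", nodes = nodes,
               edges = data.frame(u = complete[, 1], v = complete[, 2],
                                  weight = 0.5, sign = "positive",
                                  stringsAsFactors = FALSE),
               selection = "bic")
  gEmpty <- new("CoabundanceNetwork", nodes = nodes,
                edges = data.frame(u = character(0), v = character(0),
                                   weight = numeric(0), sign = character(0),
                                   stringsAsFactors = FALSE),
                selection = "bic")
  cc <- compareConnectivity(gFull, gEmpty)
  expect_equal(cc$densityDiff, 1)
  expect_equal(cc$edgeCountDiff, 10L)
  same <- compareConnectivity(gFull, gFull)
  expect_equal(same$densityDiff, 0)
  expect_equal(same$edgeCountDiff, 0L)
  ## planted hub: T3 connected to everyone, others only to T3
  star <- data.frame(u = "T3", v = setdiff(nodes, "T3"), weight = 0.4,
                     sign = "positive", stringsAsFactors = FALSE)
  gStar <- new("CoabundanceNetwork", nodes = nodes, edges = star,
               selection = "bic")
  cs <- compareConnectivity(gStar, gEmpty)
  expect_equal(unname(cs$mostConnected[["exposed"]]), "T3")
  gOther <- new("CoabundanceNetwork", nodes = paste0("X", 1:5),
                edges = gEmpty@edges, selection = "bic")
  expect_error(compareConnectivity(gFull, gOther), "alignment error")
})
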