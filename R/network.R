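#' Hurdle encoding of a count table
#'
#' Aggregates counts to the requested taxonomic rank, then represents the
#' zero-inflated table as a binary incidence matrix plus a compositional
#' abundance matrix in which the centered log-ratio transform is applied,
#' per sample, to the non-zero counts only. Structural zeros are carried as
#' NA in the abundance part. Taxa absent from every sample are dropped with
#' a warning.
#'
#' @param x a `SummarizedExperiment` (aggregated via [aggregateByRank()]) or
#'   an already-aggregated taxa x samples count matrix.
#' @param level taxonomic rank to aggregate to (default "phylum").
#' @return a [HurdleDesign-class].
#' @examples
#' # sample counts (0, 5, 5): incidence (0, 1, 1), CLR over {5, 5} = {0, 0}
#' @export
hurdleEncode <- function(x, level = "phylum") {
  m <- if (is(x, "SummarizedExperiment")) aggregateByRank(x, level)
       else as.matrix(x)
  if (any(m < 0)) stop("counts must be non-negative")
  allZero <- rowSums(m) == 0
  if (any(allZero)) {
    warning("dropping taxa absent in all samples: ",
            paste(rownames(m)[allZero], collapse = ", "))
  }
  dropped <- rownames(m)[allZero]
  m <- m[!allZero, , drop = FALSE]
  s <- t(m)  # samples x taxa
  incidence <- (s > 0) * 1
  abundance <- matrix(NA_real_, nrow(s), ncol(s), dimnames = dimnames(s))
  for (i in seq_len(nrow(s))) {
    pos <- s[i, ] > 0
    lx <- log(s[i, pos])
    abundance[i, pos] <- lx - mean(lx)
  }
  new("HurdleDesign", incidence = incidence, abundance = abundance,
      level = level, dropped = as.character(dropped))
}

## Extended-BIC selection over a glmnet gaussian path (EBIC gamma = 0.5,
## the standard choice for neighbourhood selection), excluding degenerate
## solutions: CLR-encoded hurdle designs obey an exact per-sample zero-sum
## constraint, so regressions using (almost) every other taxon's abundance
## column fit spuriously well and must be kept out of the model search.
.bicSelect <- function(xmat, y, abundCols, nLambda, ebicGamma = 0.5) {
  keep <- apply(xmat, 2, function(cc) sd(cc) > 0)
  if (!any(keep)) return(character(0))
  xk <- xmat[, keep, drop = FALSE]
  if (ncol(xk) < 2) {
    ## glmnet needs >= 2 columns; fall back to marginal BIC check
    r <- cor(xk[, 1], y)
    n <- length(y)
    bic1 <- n * log(1 - r^2)
    return(if (bic1 + log(n) < 0) colnames(xk) else character(0))
  }
  fit <- glmnet::glmnet(xk, y, family = "gaussian", nlambda = nLambda)
  n <- length(y)
  beta <- as.matrix(fit$beta)
  ## relaxed selection: score each support by an OLS refit so shrinkage
  ## does not distort the likelihood term
  bic <- vapply(seq_len(ncol(beta)), function(l) {
    s <- which(beta[, l] != 0)
    if (length(s) >= n - 2) return(Inf)
    r <- if (length(s)) {
      residuals(stats::lm.fit(cbind(1, xk[, s, drop = FALSE]), y))
    } else {
      y - mean(y)
    }
    n * log(max(sum(r^2), 1e-12) / n) +
      length(s) * (log(n) + 2 * ebicGamma * log(ncol(xk)))
  }, numeric(1))
  ## cap the abundance-column count per neighbourhood: CLR-encoded designs
  ## obey an exact per-sample zero-sum constraint, so regressions using
  ## (almost) every other taxon's abundance column fit spuriously well
  nAvail <- length(intersect(abundCols, colnames(xk)))
  maxAbund <- max(2L, floor(nAvail / 2))
  nAbund <- colSums(beta[rownames(beta) %in% abundCols, , drop = FALSE] != 0)
  valid <- nAbund <= maxAbund
  if (!any(valid) || all(!is.finite(bic[valid]))) return(character(0))
  best <- which(valid)[which.min(bic[valid])]
  rownames(beta)[beta[, best] != 0]
}

## rank vector of a hurdle column: zeros tie at the minimum rank
.hurdleRanks <- function(abund, incid) {
  v <- abund
  v[incid == 0] <- -Inf
  rank(v, ties.method = "average")
}

## Spearman partial correlation of taxa u, v given control taxa
.partialSpearman <- function(ranks, u, v, controls) {
  ru <- ranks[, u]
  rv <- ranks[, v]
  if (length(controls)) {
    z <- ranks[, controls, drop = FALSE]
    z <- z[, apply(z, 2, sd) > 0, drop = FALSE]
    if (ncol(z)) {
      ru <- residuals(stats::lm.fit(cbind(1, z), ru))
      rv <- residuals(stats::lm.fit(cbind(1, z), rv))
    }
  }
  if (sd(ru) == 0 || sd(rv) == 0) return(0)
  max(-1, min(1, cor(ru, rv)))
}

#' Estimate a zero-aware co-abundance network
#'
#' Edge support comes from node-wise L1-penalized regressions: each taxon's
#' hurdle columns (incidence and CLR abundance) are regressed on all other
#' taxa's columns; a pair is connected when either direction selects the
#' other (OR rule), with the penalty chosen by BIC or by stability
#' selection. Edge weights are Spearman partial correlations between the
#' pair's abundance ranks (zeros tied at the minimum) given the union of
#' their selected neighbours.
#'
#' @param design a [HurdleDesign-class].
#' @param selection "bic" (default) or "stability" (frequency >= `stabilityThreshold`
#'   over `nSubsample` half-sample refits).
#' @param nLambda penalty-path length (default 30).
#' @param seed integer seed (used by stability selection).
#' @param stabilityThreshold,nSubsample stability-selection parameters.
#' @return a [CoabundanceNetwork-class].
#' @export
estimateNetwork <- function(design, selection = c("bic", "stability"),
                            nLambda = 30, seed = NULL,
                            stabilityThreshold = 0.9, nSubsample = 50) {
  selection <- match.arg(selection)
  .checkSeed(seed)
  stopifnot(is(design, "HurdleDesign"))
  taxa <- colnames(design@incidence)
  p <- length(taxa)
  n <- nrow(design@incidence)
  if (p < 3) stop("size error: at least 3 taxa required")
  if (n < 3 * p) {
    warning("fewer than 3 samples per taxon (n = ", n, ", p = ", p,
            "); estimates may be unstable")
  }
  filled <- design@abundance
  filled[is.na(filled)] <- 0
  cols <- cbind(design@incidence, filled)
  colnames(cols) <- c(paste0("inc.", taxa), paste0("ab.", taxa))

  selectFor <- function(rows) {
    adj <- matrix(FALSE, p, p, dimnames = list(taxa, taxa))
    for (j in seq_len(p)) {
      others <- setdiff(taxa, taxa[j])
      xmat <- cols[rows, c(paste0("inc.", others), paste0("ab.", others)),
                   drop = FALSE]
      abundCols <- paste0("ab.", others)
      responses <- list(design@incidence[rows, j], filled[rows, j])
      chosen <- character(0)
      for (y in responses) {
        if (sd(y) == 0) next
        chosen <- union(chosen,
                        .bicSelect(xmat, y, abundCols, nLambda))
      }
      neigh <- unique(sub("^(inc|ab)\\.", "", chosen))
      adj[j, match(neigh, taxa)] <- TRUE
    }
    adj | t(adj)  # OR rule
  }

  if (selection == "bic") {
    adj <- selectFor(seq_len(n))
  } else {
    if (!is.null(seed)) set.seed(.substreamSeed(seed, "network"))
    freq <- matrix(0, p, p, dimnames = list(taxa, taxa))
    half <- floor(n / 2)
    for (b in seq_len(nSubsample)) {
      rows <- sample.int(n, half)
      freq <- freq + selectFor(rows)
    }
    adj <- (freq / nSubsample) >= stabilityThreshold
  }

  ranks <- vapply(seq_len(p), function(j) {
    .hurdleRanks(design@abundance[, j], design@incidence[, j])
  }, numeric(n))
  colnames(ranks) <- taxa

  pairs <- which(upper.tri(adj) & adj, arr.ind = TRUE)
  edges <- data.frame(u = character(0), v = character(0),
                      weight = numeric(0), sign = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(pairs)) {
    neighborSets <- lapply(seq_len(p), function(j) taxa[adj[j, ]])
    w <- vapply(seq_len(nrow(pairs)), function(r) {
      u <- pairs[r, 1]; v <- pairs[r, 2]
      controls <- setdiff(union(neighborSets[[u]], neighborSets[[v]]),
                          taxa[c(u, v)])
      .partialSpearman(ranks, u, v, controls)
    }, numeric(1))
    uu <- taxa[pairs[, 1]]
    vv <- taxa[pairs[, 2]]
    edges <- data.frame(u = pmin(uu, vv), v = pmax(uu, vv),
                        weight = w,
                        sign = ifelse(w >= 0, "positive", "negative"),
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$u, edges$v), , drop = FALSE]
    rownames(edges) <- NULL
  }
  new("CoabundanceNetwork", nodes = taxa, edges = edges,
      selection = selection)
}

#' Compare the connectivity of two group networks
#'
#' @param gExposed,gNonExposed [CoabundanceNetwork-class] objects on the
#'   same node set.
#' @return list with `densityDiff` (exposed - non-exposed),
#'   `edgeCountDiff`, a per-node `degree` data.frame, and the
#'   `mostConnected` node per graph (ties broken lexicographically).
#' @export
compareConnectivity <- function(gExposed, gNonExposed) {
  stopifnot(is(gExposed, "CoabundanceNetwork"),
            is(gNonExposed, "CoabundanceNetwork"))
  if (!setequal(networkNodes(gExposed), networkNodes(gNonExposed))) {
    stop("alignment error: node sets differ between the two networks")
  }
  nodes <- sort(networkNodes(gExposed))
  degOf <- function(g) {
    e <- networkEdges(g)
    d <- table(factor(c(e$u, e$v), levels = nodes))
    as.integer(d)
  }
  dE <- degOf(gExposed)
  dNE <- degOf(gNonExposed)
  hub <- function(d) nodes[order(-d, nodes)][1]
  list(densityDiff = networkDensity(gExposed) - networkDensity(gNonExposed),
       edgeCountDiff = nrow(networkEdges(gExposed)) -
         nrow(networkEdges(gNonExposed)),
       degree = data.frame(node = nodes, exposed = dE, non_exposed = dNE,
                           stringsAsFactors = FALSE),
       mostConnected = c(exposed = hub(dE), non_exposed = hub(dNE)))
}

#' Simulate a hurdle design with a known sparse partial-correlation
#' structure
#'
#' Draws the abundance part from a multivariate normal with the supplied
#' sparse precision matrix and masks entries through an independent
#' Bernoulli occurrence layer, so the planted conditional-independence
#' graph lives in the same (encoded) space the network estimator operates
#' on -- the standard way hurdle-model network estimators are benchmarked.
#' The ground-truth adjacency (non-zero off-diagonal precision entries)
#' and partial correlations are returned alongside.
#'
#' @param n number of samples.
#' @param precision p x p symmetric positive-definite precision matrix.
#' @param mu latent abundance means (length p, default 0).
#' @param zeroProb per-taxon structural-zero probability (scalar or length
#'   p; default 0.15 for the last third of taxa, 0 elsewhere).
#' @param seed integer seed.
#' @return list with `design` (a [HurdleDesign-class]), `adjacency`
#'   (logical p x p) and `partialCor` (ground-truth partial correlations).
#' @export
rHurdleNetwork <- function(n, precision, mu = NULL, zeroProb = NULL,
                           seed = NULL) {
  .checkSeed(seed)
  precision <- as.matrix(precision)
  p <- nrow(precision)
  if (!isTRUE(all.equal(precision, t(precision)))) {
    stop("precision must be symmetric")
  }
  ev <- eigen(precision, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("precision must be positive definite")
  if (is.null(mu)) mu <- rep(0, p)
  if (is.null(zeroProb)) {
    zeroProb <- rep(0, p)
    zeroProb[seq.int(floor(2 * p / 3) + 1, p)] <- 0.15
  }
  zeroProb <- rep_len(zeroProb, p)
  if (!is.null(seed)) set.seed(.substreamSeed(seed, "network"))
  ch <- chol(solve(precision))
  z <- matrix(rnorm(n * p), n, p) %*% ch
  z <- sweep(z, 2, mu, "+")
  taxa <- sprintf("T%02d", seq_len(p))
  dimnames(z) <- list(sprintf("S%03d", seq_len(n)), taxa)
  present <- matrix(runif(n * p), n, p) >= rep(zeroProb, each = n)
  dimnames(present) <- dimnames(z)
  ## every sample keeps at least one observed taxon
  none <- rowSums(present) == 0
  present[none, 1] <- TRUE
  abundance <- z
  abundance[!present] <- NA_real_
  design <- new("HurdleDesign", incidence = (present) * 1,
                abundance = abundance, level = "simulated",
                dropped = character(0))
  d <- sqrt(diag(precision))
  pc <- -precision / outer(d, d)
  diag(pc) <- 1
  adj <- abs(precision) > 1e-12
  diag(adj) <- FALSE
  dimnames(adj) <- dimnames(pc) <- list(taxa, taxa)
  list(design = design, adjacency = adj, partialCor = pc)
}

#' Convert a CoabundanceNetwork to an igraph object
#' @param g a [CoabundanceNetwork-class].
#' @return an undirected weighted `igraph` graph.
#' @export
asIgraph <- function(g) {
  stopifnot(is(g, "CoabundanceNetwork"))
  e <- networkEdges(g)
  ig <- igraph::graph_from_data_frame(e[, c("u", "v")], directed = FALSE,
                                      vertices = networkNodes(g))
  if (nrow(e)) {
    igraph::E(ig)$weight <- e$weight
    igraph::E(ig)$sign <- e$sign
  }
  ig
}

#' Write a network as GraphML
#' @param g a [CoabundanceNetwork-class].
#' @param file output path.
#' @export
writeGraphML <- function(g, file) {
  igraph::write_graph(asIgraph(g), file, format = "graphml")
  invisible(file)
}

#' Write a network as edge-list TSV
#' @param g a [CoabundanceNetwork-class].
#' @param file output path.
#' @param provenance header line.
#' @export
writeEdgeList <- function(g, file, provenance = "AKPtools") {
  .writeProvenancedTable(networkEdges(g), file, provenance)
}
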