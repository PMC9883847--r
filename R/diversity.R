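#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` where F1 and F2 are the numbers of
#' singleton and doubleton categories. Defined for integer counts only;
#' continuous dietary intakes must be discretized first, see
#' [discretizeIntake()].
#'
#' @param counts non-negative integer vector.
#' @return the Chao1 estimate (>= observed richness).
#' @examples
#' chao1(c(1, 1, 2, 2))  # 4 + 2*1/(2*3)
#' @export
chao1 <- function(counts) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("chao1 requires non-negative integer counts; discretize ",
         "continuous intakes first (see discretizeIntake)")
  }
  counts <- round(counts)
  sObs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  sObs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Discretize continuous intakes to pseudo-counts
#'
#' Rounds amount/scale to the nearest integer, with a floor of 1 for any
#' positive intake so presence is never lost.
#'
#' @param amounts non-negative numeric vector (g/day).
#' @param scale grams per pseudo-count (default 1).
#' @return integer pseudo-count vector.
#' @export
discretizeIntake <- function(amounts, scale = 1) {
  if (any(amounts < 0)) stop("intake amounts must be non-negative")
  if (scale <= 0) stop("scale must be positive")
  x <- round(amounts / scale)
  x[amounts > 0 & x < 1] <- 1
  as.integer(x)
}

.toProportions <- function(x) {
  if (any(x < 0)) stop("abundances must be non-negative")
  s <- sum(x)
  if (s <= 0) stop("domain error: all-zero abundance vector")
  x / s
}

#' Shannon diversity (natural log)
#'
#' @param abundances non-negative vector; proportions are computed
#'   internally and zero entries contribute zero.
#' @return H in nats.
#' @export
shannonIndex <- function(abundances) {
  p <- .toProportions(abundances)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Gini-Simpson diversity
#'
#' @param abundances non-negative vector.
#' @return 1 - sum(p^2).
#' @export
simpsonIndex <- function(abundances) {
  p <- .toProportions(abundances)
  1 - sum(p^2)
}

#' Ruzicka similarity (weighted Jaccard)
#'
#' `sum(min(x, y)) / sum(max(x, y))` for non-negative abundance vectors;
#' the ingredient of the intra-group C-index. Scale-invariant when both
#' inputs are rescaled by the same factor; by convention applied to
#' relative abundances (see [intraGroupSimilarity()]).
#'
#' @param x,y non-negative vectors of equal length, not both all-zero.
#' @return similarity in [0, 1].
#' @examples
#' ruzickaSimilarity(c(1, 2), c(2, 1))  # 0.5
#' @export
ruzickaSimilarity <- function(x, y) {
  if (length(x) != length(y)) {
    stop("shape error: x and y must have equal length")
  }
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  denom <- sum(pmax(x, y))
  if (denom == 0) {
    stop("domain error: Ruzicka similarity undefined for two all-zero vectors")
  }
  sum(pmin(x, y)) / denom
}

#' Full pairwise Ruzicka similarity matrix
#'
#' @param x samples x taxa non-negative matrix.
#' @param relative close each row to relative abundance first (default
#'   `TRUE`).
#' @return symmetric n x n similarity matrix with unit diagonal.
#' @export
pairwiseRuzicka <- function(x, relative = TRUE) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("abundances must be non-negative")
  rs <- rowSums(x)
  if (any(rs == 0)) stop("domain error: all-zero sample rows")
  if (relative) x <- x / rs
  n <- nrow(x)
  s <- diag(1, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      rest <- (i + 1):n
      xi <- matrix(x[i, ], nrow = length(rest), ncol = ncol(x),
                   byrow = TRUE)
      mins <- rowSums(pmin(xi, x[rest, , drop = FALSE]))
      maxs <- rowSums(pmax(xi, x[rest, , drop = FALSE]))
      s[i, rest] <- s[rest, i] <- mins / maxs
    }
  }
  dimnames(s) <- list(rownames(x), rownames(x))
  s
}

## --- UniFrac machinery ----------------------------------------------------
## Branch decomposition of a rooted tree: for every edge, which tips descend
## through it, plus root-to-tip depths. Profiles are mapped to per-edge
## masses by a tips x edges incidence matrix.
.branchStructure <- function(tree) {
  phy <- if (is(tree, "FoodHierarchy")) foodTree(tree) else tree
  if (!inherits(phy, "phylo")) {
    stop("tree must be a FoodHierarchy or an ape phylo object")
  }
  phy <- ape::reorder.phylo(phy, "postorder")
  nTip <- length(phy$tip.label)
  nNode <- nTip + phy$Nnode
  nEdge <- nrow(phy$edge)
  ## tip x edge incidence via postorder accumulation
  below <- matrix(FALSE, nrow = nTip, ncol = nNode)
  below[cbind(seq_len(nTip), seq_len(nTip))] <- TRUE
  for (i in seq_len(nEdge)) {
    par <- phy$edge[i, 1]
    chd <- phy$edge[i, 2]
    below[, par] <- below[, par] | below[, chd]
  }
  incidence <- below[, phy$edge[, 2], drop = FALSE]
  lengths <- phy$edge.length
  if (is.null(lengths)) lengths <- rep(1, nEdge)
  depths <- colSums(t(incidence) * lengths)  # root-to-tip depth per tip
  rownames(incidence) <- phy$tip.label
  list(incidence = incidence, lengths = lengths, tipDepths = depths,
       tips = phy$tip.label)
}

.profileOnTips <- function(x, tips) {
  if (is.null(names(x))) {
    if (length(x) != length(tips)) {
      stop("mapping error: unnamed profile length must equal tip count")
    }
    names(x) <- tips
  }
  unknown <- setdiff(names(x), tips)
  if (length(unknown)) {
    stop("mapping error: unknown leaves: ", paste(unknown, collapse = ", "))
  }
  full <- stats::setNames(numeric(length(tips)), tips)
  full[names(x)] <- x
  if (any(full < 0)) stop("profile masses must be non-negative")
  if (sum(full) <= 0) stop("domain error: profile has no positive mass")
  full
}

#' Unweighted UniFrac distance between two leaf profiles
#'
#' Fraction of branch length unique to one profile among the branch length
#' in the union of the two profiles' ancestries (presence-based).
#'
#' @param tree a [FoodHierarchy] or `phylo`.
#' @param x,y non-negative leaf profiles (named by leaf, or in tip order).
#' @return distance in [0, 1].
#' @export
unweightedUnifrac <- function(tree, x, y) {
  bs <- .branchStructure(tree)
  px <- .profileOnTips(x, bs$tips) > 0
  py <- .profileOnTips(y, bs$tips) > 0
  inX <- as.vector(crossprod(bs$incidence, px) > 0)
  inY <- as.vector(crossprod(bs$incidence, py) > 0)
  union <- sum(bs$lengths[inX | inY])
  unique <- sum(bs$lengths[xor(inX, inY)])
  if (union == 0) stop("domain error: empty union of branches")
  unique / union
}

#' Weighted UniFrac distance between two leaf profiles
#'
#' Raw form `sum_b l_b |p_b - q_b|`, where p_b and q_b are the fractions of
#' each profile's mass descending through branch b. The normalized variant
#' (default) divides by `sum_j depth_j (p_j + q_j)` over leaves and lies in
#' [0, 1].
#'
#' @param tree a [FoodHierarchy] or `phylo`.
#' @param x,y non-negative leaf profiles.
#' @param normalized divide by the depth-weighted total mass (default
#'   `TRUE`).
#' @return distance (in [0, 1] when normalized).
#' @export
weightedUnifrac <- function(tree, x, y, normalized = TRUE) {
  bs <- .branchStructure(tree)
  px <- .profileOnTips(x, bs$tips)
  py <- .profileOnTips(y, bs$tips)
  px <- px / sum(px)
  py <- py / sum(py)
  bx <- as.vector(crossprod(bs$incidence, px))
  by <- as.vector(crossprod(bs$incidence, py))
  d <- sum(bs$lengths * abs(bx - by))
  if (normalized) {
    denom <- sum(bs$tipDepths * (px + py))
    d <- d / denom
  }
  d
}

#' Pairwise UniFrac distance matrix
#'
#' Computes all pairwise unweighted or (normalized) weighted UniFrac
#' distances for a set of leaf profiles via the branch-mass decomposition,
#' so the cost is one matrix product plus O(n^2) branch comparisons.
#'
#' @param x samples x leaves non-negative matrix, columns named by leaf.
#' @param tree a [FoodHierarchy] or `phylo`.
#' @param method "unweighted" or "weighted".
#' @param normalized for the weighted variant (default `TRUE`).
#' @return symmetric distance matrix with sample ids.
#' @export
unifracDistance <- function(x, tree, method = c("unweighted", "weighted"),
                            normalized = TRUE) {
  method <- match.arg(method)
  x <- as.matrix(x)
  bs <- .branchStructure(tree)
  unknown <- setdiff(colnames(x), bs$tips)
  if (length(unknown)) {
    stop("mapping error: unknown leaves: ", paste(unknown, collapse = ", "))
  }
  full <- matrix(0, nrow(x), length(bs$tips),
                 dimnames = list(rownames(x), bs$tips))
  full[, colnames(x)] <- x
  if (any(full < 0)) stop("profile masses must be non-negative")
  rs <- rowSums(full)
  if (any(rs <= 0)) stop("domain error: samples with no positive mass")
  full <- full / rs

  n <- nrow(full)
  d <- matrix(0, n, n, dimnames = list(rownames(full), rownames(full)))
  if (method == "unweighted") {
    pres <- (full %*% bs$incidence) > 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        un <- sum(bs$lengths[pres[i, ] | pres[j, ]])
        uq <- sum(bs$lengths[xor(pres[i, ], pres[j, ])])
        d[i, j] <- d[j, i] <- uq / un
      }
    }
  } else {
    bm <- full %*% bs$incidence
    depths <- as.vector(full %*% bs$tipDepths)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        num <- sum(bs$lengths * abs(bm[i, ] - bm[j, ]))
        d[i, j] <- d[j, i] <-
          if (normalized) num / (depths[i] + depths[j]) else num
      }
    }
  }
  d
}

#' Aitchison distance matrix
#'
#' Adds a pseudocount, closes each sample to proportions, applies the
#' centered log-ratio transform and takes pairwise Euclidean distances.
#' A metric on compositions; invariant to sample-wise rescaling.
#'
#' @param x samples x taxa non-negative count matrix (or a
#'   `SummarizedExperiment`, samples taken from columns).
#' @param pseudocount positive count added to every cell (default 1); 0 is
#'   accepted only when the data are strictly positive.
#' @return symmetric distance matrix.
#' @export
aitchisonDistance <- function(x, pseudocount = 1) {
  if (is(x, "SummarizedExperiment")) x <- .sampleMatrix(x)
  x <- as.matrix(x)
  if (any(x < 0)) stop("counts must be non-negative")
  if (pseudocount < 0) stop("parameter error: pseudocount must be >= 0")
  if (pseudocount == 0 && any(x == 0)) {
    stop("parameter error: pseudocount 0 requires strictly positive data")
  }
  y <- x + pseudocount
  y <- y / rowSums(y)
  ly <- log(y)
  clr <- ly - rowMeans(ly)
  as.matrix(dist(clr))
}

#' Principal coordinates analysis
#'
#' Double-centers -D^2/2 and eigen-decomposes; coordinates are scaled by
#' the square root of their eigenvalues. Negative eigenvalues are either
#' discarded or removed by the Cailliez additive correction.
#'
#' @param d symmetric distance matrix with zero diagonal.
#' @param negEigPolicy "discard" or "cailliez".
#' @param k number of axes to keep (default: all positive-eigenvalue axes).
#' @return list with `ids`, `coordinates` (n x k, centered), `eigenvalues`
#'   (descending).
#' @export
pcoaOrdination <- function(d, negEigPolicy = c("discard", "cailliez"),
                           k = NULL) {
  negEigPolicy <- match.arg(negEigPolicy)
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (negEigPolicy == "cailliez" && n > 3) {
    res <- ape::pcoa(as.dist(d), correction = "cailliez")
    vec <- if (!is.null(res$vectors.cor)) res$vectors.cor else res$vectors
    eig <- if (!is.null(res$values$Corr_eig)) res$values$Corr_eig
           else res$values$Eigenvalues
  } else {
    ## direct Gower double-centering; also covers tiny n where ape's
    ## correction machinery needs n > 3
    a <- -0.5 * d^2
    g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
    ee <- eigen(g, symmetric = TRUE)
    pos <- ee$values > max(ee$values[1], 0) * 1e-10
    if (!any(pos)) {
      stop("no positive eigenvalues; degenerate distance matrix")
    }
    vec <- sweep(ee$vectors[, pos, drop = FALSE], 2,
                 sqrt(ee$values[pos]), "*")
    eig <- ee$values[pos]
  }
  keep <- which(eig > max(eig[1], 0) * 1e-10)
  vec <- as.matrix(vec)[, keep, drop = FALSE]
  eig <- eig[keep]
  if (!is.null(k)) {
    if (k > n - 1) stop("k must be at most n - 1")
    k <- min(k, ncol(vec))
    vec <- vec[, seq_len(k), drop = FALSE]
    eig <- eig[seq_len(k)]
  }
  vec <- sweep(vec, 2, colMeans(vec))
  colnames(vec) <- paste0("PC", seq_len(ncol(vec)))
  rownames(vec) <- rownames(d)
  list(ids = rownames(d), coordinates = vec, eigenvalues = eig)
}

#' Write a distance matrix as square TSV
#' @param d distance matrix.
#' @param file path.
#' @param provenance header line.
#' @export
writeDistanceMatrix <- function(d, file, provenance = "AKPtools") {
  d <- .checkDistanceMatrix(d)
  df <- cbind(id = rownames(d), as.data.frame(d))
  .writeProvenancedTable(df, file, provenance)
}
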