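#' Procrustes comparison of two beta-diversity matrices with PROTEST
#'
#' Both matrices are embedded by principal coordinates, the configurations
#' centered and scaled to unit sum of squares, and the optimal rotation
#' obtained from the singular value decomposition of their cross-product.
#' The residual statistic is `m2 = 1 - (sum of singular values)^2`.
#' Significance comes from the PROTEST permutation: row order of one
#' configuration is permuted `nPerm` times and permuted m2 values
#' smaller than or equal to the observed one count as extreme (a better
#' fit).
#'
#' @param d1,d2 distance matrices over the same ids.
#' @param k embedding dimension; default is the number of positive
#'   eigenvalues of each embedding, capped at 10.
#' @param nPerm number of permutations (default 999).
#' @param seed integer seed.
#' @return a [ProcrustesResult-class].
#' @export
procrustesProtest <- function(d1, d2, k = NULL, nPerm = 999, seed = NULL) {
  .checkSeed(seed)
  d1 <- .checkDistanceMatrix(d1, "d1")
  d2 <- .checkDistanceMatrix(d2, "d2")
  if (!setequal(rownames(d1), rownames(d2))) {
    stop("alignment error: the two matrices must share their ids")
  }
  d2 <- d2[rownames(d1), rownames(d1)]
  n <- nrow(d1)
  if (!is.null(k) && k > n - 1) stop("k must be at most n - 1")

  o1 <- pcoaOrdination(d1, k = k)
  o2 <- pcoaOrdination(d2, k = k)
  kk <- min(ncol(o1$coordinates), ncol(o2$coordinates), 10)
  x <- o1$coordinates[, seq_len(kk), drop = FALSE]
  y <- o2$coordinates[, seq_len(kk), drop = FALSE]
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  x <- x / sqrt(sum(x^2))
  y <- y / sqrt(sum(y^2))

  m2Of <- function(xx) {
    sv <- svd(crossprod(xx, y))$d
    max(0, 1 - sum(sv)^2)
  }
  m2 <- m2Of(x)
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  for (b in seq_len(nPerm)) {
    if (m2Of(x[sample.int(n), , drop = FALSE]) <= m2 + 1e-15) {
      hits <- hits + 1L
    }
  }
  new("ProcrustesResult", m2 = min(m2, 1), pPerm = (1 + hits) / (1 + nPerm),
      nPerm = nPerm, k = kk)
}

## pseudo-F and R2 from squared distances, Gower-centered formulation:
## SS_total = sum_{i<j} d2 / n, SS_within = sum_g sum_{i<j in g} d2 / n_g
.permanovaF <- function(d2mat, mask) {
  n <- nrow(d2mat)
  ut <- upper.tri(d2mat)
  ssTotal <- sum(d2mat[ut]) / n
  g1 <- which(mask)
  g0 <- which(!mask)
  ssW <- sum(d2mat[g1, g1][upper.tri(diag(length(g1)))]) / length(g1) +
    sum(d2mat[g0, g0][upper.tri(diag(length(g0)))]) / length(g0)
  ssB <- ssTotal - ssW
  list(F = (ssB / 1) / (ssW / (n - 2)), R2 = ssB / ssTotal)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Pseudo-F from within- and between-group sums of squared distances
#' (Gower-centered formulation), with significance by raw label
#' permutation. When the number of distinct label assignments
#' `choose(n, n1)` is at most 10,000 every assignment is enumerated and the
#' p-value is exact; otherwise `nPerm` random permutations are used.
#'
#' @param d distance matrix.
#' @param labels binary factor/logical/character over the samples.
#' @param nPerm number of random permutations (default 999).
#' @param seed integer seed.
#' @param maxExhaustive enumeration cutoff (default 10000 assignments).
#' @return a [PermanovaResult-class].
#' @export
permanova <- function(d, labels, nPerm = 999, seed = NULL,
                      maxExhaustive = 10000) {
  .checkSeed(seed)
  d <- .checkDistanceMatrix(d)
  n <- nrow(d)
  if (length(labels) != n) stop("labels length must match the matrix")
  f <- as.factor(labels)
  if (nlevels(droplevels(f)) != 2) {
    stop("degenerate design: labels must have exactly two classes")
  }
  mask <- f == levels(droplevels(f))[2]
  if (sum(mask) < 2 || sum(!mask) < 2) {
    stop("degenerate design: both groups need at least 2 samples")
  }
  d2 <- d^2
  obs <- .permanovaF(d2, mask)

  nSplits <- choose(n, sum(mask))
  if (nSplits <= maxExhaustive) {
    combs <- combn(n, sum(mask))
    fs <- apply(combs, 2, function(idx) {
      mk <- logical(n)
      mk[idx] <- TRUE
      .permanovaF(d2, mk)$F
    })
    p <- sum(fs >= obs$F - 1e-12) / length(fs)
    res <- new("PermanovaResult", pseudoF = obs$F, R2 = obs$R2, pPerm = p,
               nPerm = length(fs), exhaustive = TRUE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (b in seq_len(nPerm)) {
      if (.permanovaF(d2, mask[sample.int(n)])$F >= obs$F - 1e-12) {
        hits <- hits + 1L
      }
    }
    res <- new("PermanovaResult", pseudoF = obs$F, R2 = obs$R2,
               pPerm = (1 + hits) / (1 + nPerm), nPerm = nPerm,
               exhaustive = FALSE)
  }
  res
}

#' Linear-model association of an alpha-diversity index with a factor
#'
#' Gaussian linear model fit by least squares; with a single binary factor
#' and no covariates the p-value equals the pooled-variance two-sample
#' t-test. Perfectly collinear covariates raise a design error.
#'
#' @param alphaValues per-subject diversity values.
#' @param factor binary factor (two levels).
#' @param covariates optional data.frame of adjustment covariates.
#' @return data.frame with `beta`, `se`, `p` for the factor term.
#' @export
alphaGlm <- function(alphaValues, factor, covariates = NULL) {
  if (length(alphaValues) < 3) stop("need at least 3 observations")
  f <- droplevels(as.factor(factor))
  if (nlevels(f) < 2) stop("design error: constant factor")
  df <- data.frame(.y = alphaValues, .f = f)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    df <- cbind(df, covariates)
  }
  fit <- lm(.y ~ ., data = df)
  if (any(is.na(coef(fit)))) {
    stop("design error: collinear terms in the model matrix")
  }
  sm <- summary(fit)$coefficients
  term <- grep("^\\.f", rownames(sm), value = TRUE)[1]
  data.frame(beta = sm[term, 1], se = sm[term, 2], p = sm[term, 4],
             row.names = NULL)
}

#' Clade-summed relative abundances on the parts-per-million scale
#'
#' For every taxonomic rank, sums each clade's descendant leaf relative
#' abundances (per sample, scaled to 1e6), producing the clade x sample
#' feature matrix LEfSe operates on. Feature names are full lineages joined
#' with "|"; duplicated feature vectors arising from single-child lineage
#' steps are retained (they name distinct clades).
#'
#' @param se a `SummarizedExperiment` with a counts assay and 7-rank
#'   lineages.
#' @return features x samples matrix in ppm.
#' @export
cladeAbundance <- function(se) {
  rel <- relativeAbundance(se) * 1e6
  tax <- as.data.frame(SummarizedExperiment::rowData(se))
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  out <- list()
  for (r in seq_along(ranks)) {
    lineage <- apply(tax[, ranks[seq_len(r)], drop = FALSE], 1, paste,
                     collapse = "|")
    agg <- rowsum(rel, group = lineage)
    out[[r]] <- agg
  }
  res <- do.call(rbind, out)
  res[order(rownames(res)), , drop = FALSE]
}

## ridge-regularized two-class linear discriminant direction
.ldaDirection <- function(x, classMask) {
  m1 <- colMeans(x[classMask, , drop = FALSE])
  m0 <- colMeans(x[!classMask, , drop = FALSE])
  s1 <- stats::cov(x[classMask, , drop = FALSE])
  s0 <- stats::cov(x[!classMask, , drop = FALSE])
  sw <- ((sum(classMask) - 1) * s1 + (sum(!classMask) - 1) * s0) /
    (nrow(x) - 2)
  ridge <- 1e-6 * mean(diag(sw)) + 1e-12
  solve(sw + diag(ridge, ncol(x)), m1 - m0)
}

#' Two-class LEfSe-style differential abundance
#'
#' Stage 1 screens every clade with the Kruskal-Wallis test at `kwAlpha`.
#' Stage 2 estimates, over `nBoot` bootstrap rounds of 2/3 subsampling, a
#' regularized linear discriminant on the surviving clades; each clade's
#' effect size averages its raw between-class mean difference with its
#' share of the class separation along the discriminant, and the LDA score
#' is the log10 of that bootstrap-averaged effect on the ppm scale. Hits
#' require `|lda_score| >= ldaThreshold`; the enriched class is the one
#' with the higher mean.
#'
#' @param se a `SummarizedExperiment`, or a precomputed features x samples
#'   ppm matrix from [cladeAbundance()].
#' @param classes binary class labels over the samples.
#' @param kwAlpha Kruskal-Wallis screening level (default 0.05).
#' @param ldaThreshold minimum absolute LDA score (default 2.0).
#' @param nBoot bootstrap rounds (default 30).
#' @param seed integer seed.
#' @return data.frame of hits: lineage, enriched_class, kw_p, lda_score;
#'   the full screen (all clades) is attached as attribute `"screen"`.
#' @export
lefseTwoClass <- function(se, classes, kwAlpha = 0.05, ldaThreshold = 2,
                          nBoot = 30, seed = NULL) {
  .checkSeed(seed)
  feat <- if (is(se, "SummarizedExperiment")) cladeAbundance(se)
          else as.matrix(se)
  cls <- droplevels(as.factor(classes))
  if (nlevels(cls) != 2) {
    stop("design error: exactly two classes required")
  }
  if (any(table(cls) == 0)) stop("design error: one class is empty")
  if (ncol(feat) != length(cls)) {
    stop("classes length must match the number of samples")
  }
  classMask <- cls == levels(cls)[2]

  kwP <- apply(feat, 1, function(v) {
    if (sd(v) == 0) return(1)
    kruskal.test(v, cls)$p.value
  })
  survivors <- which(kwP < kwAlpha)
  screen <- data.frame(lineage = rownames(feat), kw_p = kwP,
                       row.names = NULL, stringsAsFactors = FALSE)

  empty <- data.frame(lineage = character(0), enriched_class = character(0),
                      kw_p = numeric(0), lda_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(survivors)) {
    attr(empty, "screen") <- screen
    return(empty)
  }

  x <- t(feat[survivors, , drop = FALSE])  # samples x survivors
  if (!is.null(seed)) set.seed(seed)
  i1 <- which(classMask)
  i0 <- which(!classMask)
  eff <- matrix(0, nBoot, ncol(x))
  for (b in seq_len(nBoot)) {
    s1 <- sample(i1, max(2, floor(2 * length(i1) / 3)))
    s0 <- sample(i0, max(2, floor(2 * length(i0) / 3)))
    xb <- x[c(s1, s0), , drop = FALSE]
    mb <- c(rep(TRUE, length(s1)), rep(FALSE, length(s0)))
    keep <- apply(xb, 2, sd) > 0
    gm <- abs(colMeans(xb[mb, , drop = FALSE]) -
              colMeans(xb[!mb, , drop = FALSE]))
    coefPart <- numeric(ncol(x))
    if (sum(keep) >= 1) {
      w <- .ldaDirection(xb[, keep, drop = FALSE], mb)
      wUnit <- w / sqrt(sum(w^2))
      proj <- xb[, keep, drop = FALSE] %*% wUnit
      sep <- abs(mean(proj[mb]) - mean(proj[!mb]))
      coefPart[keep] <- abs(wUnit) * sep
    }
    eff[b, ] <- (gm + coefPart) / 2
  }
  effMean <- colMeans(eff)
  score <- log10(pmax(effMean, 1))
  dir1 <- colMeans(x[classMask, , drop = FALSE]) >
    colMeans(x[!classMask, , drop = FALSE])

  hit <- score >= ldaThreshold
  res <- data.frame(
    lineage = colnames(x)[hit],
    enriched_class = ifelse(dir1[hit], levels(cls)[2], levels(cls)[1]),
    kw_p = kwP[survivors][hit],
    lda_score = score[hit],
    stringsAsFactors = FALSE)
  res <- res[order(-res$lda_score), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "screen") <- screen
  res
}
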