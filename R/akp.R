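#' Within-group pairwise C-index collection
#'
#' Scores every unordered within-group pair of samples with the Ruzicka
#' similarity after closing each sample to relative abundance. The
#' resulting collection is the group's intra-sample similarity (C-index)
#' set, the ingredient of the AKP screen.
#'
#' @param x a `SummarizedExperiment` (samples in columns) or a samples x
#'   taxa non-negative matrix.
#' @param groupMask logical vector selecting the group's samples.
#' @param metric similarity metric; only "ruzicka" is defined.
#' @param group label stored on the result (default "group").
#' @return a [SimilaritySet-class].
#' @export
intraGroupSimilarity <- function(x, groupMask, metric = "ruzicka",
                                 group = "group") {
  metric <- match.arg(metric, "ruzicka")
  m <- if (is(x, "SummarizedExperiment")) .sampleMatrix(x) else as.matrix(x)
  if (length(groupMask) != nrow(m)) {
    stop("groupMask length must equal the number of samples")
  }
  m <- m[groupMask, , drop = FALSE]
  if (nrow(m) < 2) {
    stop("insufficient group: need at least 2 samples, got ", nrow(m))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  s <- pairwiseRuzicka(m, relative = TRUE)
  idx <- which(upper.tri(s), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  new("SimilaritySet", group = group,
      pairs = cbind(rownames(m)[idx[, 1]], rownames(m)[idx[, 2]]),
      values = s[idx], metric = metric)
}

.verdictFromPs <- function(pTwo, pGreater, pLess, alpha, convention) {
  v <- if (pTwo < alpha && pGreater < alpha) "AKP"
       else if (pTwo < alpha && pLess < alpha) "anti-AKP"
       else "none"
  if (convention == "ecological" && v != "none") {
    v <- if (v == "AKP") "anti-AKP" else "AKP"
  }
  v
}

#' Three-hypothesis Wilcoxon AKP test
#'
#' Compares the exposed and non-exposed C-index collections with the
#' two-sample rank-sum (Mann-Whitney) test: two-sided plus both one-sided
#' alternatives. Under the "paper" convention a significantly HIGHER
#' exposed C-index is called AKP and a significantly lower one anti-AKP;
#' the "ecological" convention swaps the two labels (higher within-group
#' similarity read as less heterogeneity). Medians and interquartile
#' ranges of both collections are reported alongside.
#'
#' Pairwise C-values within a group share samples and are not independent;
#' the rank-sum p reproduces the conventional procedure, while
#' [akpPermutationTest()] provides the calibration-grade companion.
#'
#' @param cExposed,cNonExposed [SimilaritySet-class] objects (non-empty).
#' @param alpha significance level (default 0.05).
#' @param convention "paper" (default) or "ecological".
#' @param factor factor name recorded in the verdict.
#' @return an [AkpVerdict-class].
#' @export
akpTest <- function(cExposed, cNonExposed, alpha = 0.05,
                    convention = c("paper", "ecological"),
                    factor = "factor") {
  convention <- match.arg(convention)
  if (!is(cExposed, "SimilaritySet") || !is(cNonExposed, "SimilaritySet")) {
    stop("inputs must be SimilaritySet objects")
  }
  e <- cValues(cExposed)
  ne <- cValues(cNonExposed)
  if (!length(e) || !length(ne)) {
    stop("insufficient data: empty similarity set")
  }
  ## wilcox.test uses the exact distribution for small untied samples and
  ## the tie-corrected normal approximation otherwise
  exact <- length(e) <= 25 && length(ne) <= 25 &&
    !anyDuplicated(c(e, ne))
  pTwo <- wilcox.test(e, ne, alternative = "two.sided",
                      exact = exact)$p.value
  pGreater <- wilcox.test(e, ne, alternative = "greater",
                          exact = exact)$p.value
  pLess <- wilcox.test(e, ne, alternative = "less", exact = exact)$p.value
  new("AkpVerdict", factor = factor,
      medianE = median(e), medianNE = median(ne),
      iqrE = unname(quantile(e, c(0.25, 0.75))),
      iqrNE = unname(quantile(ne, c(0.25, 0.75))),
      pTwo = pTwo, pGreater = pGreater, pLess = pLess,
      verdict = .verdictFromPs(pTwo, pGreater, pLess, alpha, convention),
      convention = convention)
}

#' Label-permutation test for the AKP median contrast
#'
#' Null distribution of `median(C_exposed) - median(C_non_exposed)` built
#' by permuting the exposure labels and re-partitioning the (precomputed)
#' pairwise similarity matrix. Because the pairwise C-values within a group
#' share samples, this subject-level permutation is the statistically
#' calibrated companion to [akpTest()].
#'
#' @param x `SummarizedExperiment` or samples x taxa matrix.
#' @param groupMask logical exposure mask over samples.
#' @param nPerm number of permutations (>= 99).
#' @param seed integer seed.
#' @return list with `statistic`, `pTwo`, `pGreater`, `pLess`, `nPerm`.
#' @export
akpPermutationTest <- function(x, groupMask, nPerm = 999, seed = NULL) {
  if (nPerm < 99) stop("parameter error: nPerm must be at least 99")
  .checkSeed(seed)
  m <- if (is(x, "SummarizedExperiment")) .sampleMatrix(x) else as.matrix(x)
  groupMask <- as.logical(groupMask)
  if (length(groupMask) != nrow(m)) {
    stop("groupMask length must equal the number of samples")
  }
  if (sum(groupMask) < 2 || sum(!groupMask) < 2) {
    stop("insufficient group: both groups need at least 2 samples")
  }
  s <- pairwiseRuzicka(m, relative = TRUE)
  ut <- upper.tri(s)
  statFor <- function(mask) {
    within <- outer(mask, mask, "&") & ut
    between <- outer(!mask, !mask, "&") & ut
    median(s[within]) - median(s[between])
  }
  obs <- statFor(groupMask)
  if (!is.null(seed)) set.seed(seed)
  n <- length(groupMask)
  perm <- numeric(nPerm)
  for (b in seq_len(nPerm)) {
    perm[b] <- statFor(groupMask[sample.int(n)])
  }
  list(statistic = obs,
       pTwo = (1 + sum(abs(perm) >= abs(obs) - 1e-15)) / (1 + nPerm),
       pGreater = (1 + sum(perm >= obs - 1e-15)) / (1 + nPerm),
       pLess = (1 + sum(perm <= obs + 1e-15)) / (1 + nPerm),
       nPerm = nPerm)
}

#' AKP screen over several exposure factors
#'
#' Runs [intraGroupSimilarity()] and [akpTest()] for each binary factor and
#' assembles the summary table: median (IQR) of the exposed and non-exposed
#' C-index collections, the three rank-sum p-values and the verdict.
#'
#' @param se a `SummarizedExperiment` whose column data carry the factors.
#' @param factors character vector of factor column names (exposed level is
#'   "ever"/"yes").
#' @param alpha significance level.
#' @param convention "paper" or "ecological".
#' @return data.frame, one row per factor.
#' @export
akpTable <- function(se, factors = c("smoking", "alcohol", "obesity",
                                     "hypertension", "diabetes"),
                     alpha = 0.05, convention = c("paper", "ecological")) {
  convention <- match.arg(convention)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  m <- .sampleMatrix(se)
  sim <- pairwiseRuzicka(m, relative = TRUE)
  ut <- which(upper.tri(sim), arr.ind = TRUE)
  rows <- lapply(factors, function(f) {
    mask <- .exposureMask(meta, f)
    keepE <- mask[ut[, 1]] & mask[ut[, 2]]
    keepNE <- !mask[ut[, 1]] & !mask[ut[, 2]]
    setE <- new("SimilaritySet", group = "exposed",
                pairs = cbind(rownames(sim)[ut[keepE, 1]],
                              rownames(sim)[ut[keepE, 2]]),
                values = sim[ut[keepE, , drop = FALSE]], metric = "ruzicka")
    setNE <- new("SimilaritySet", group = "non_exposed",
                 pairs = cbind(rownames(sim)[ut[keepNE, 1]],
                               rownames(sim)[ut[keepNE, 2]]),
                 values = sim[ut[keepNE, , drop = FALSE]],
                 metric = "ruzicka")
    as.data.frame(akpTest(setE, setNE, alpha = alpha,
                          convention = convention, factor = f))
  })
  do.call(rbind, rows)
}

#' Write an AKP summary table
#'
#' @param tab data.frame from [akpTable()].
#' @param file output path.
#' @param provenance header line.
#' @export
writeAkpTable <- function(tab, file, provenance = "AKPtools") {
  out <- data.frame(
    factor = tab$factor,
    exposed = sprintf("%.3f (%.3f-%.3f)", tab$median_e, tab$q1_e, tab$q3_e),
    non_exposed = sprintf("%.3f (%.3f-%.3f)", tab$median_ne, tab$q1_ne,
                          tab$q3_ne),
    p_two = signif(tab$p_two, 3),
    p_greater = signif(tab$p_greater, 3),
    p_less = signif(tab$p_less, 3),
    verdict = tab$verdict,
    stringsAsFactors = FALSE)
  .writeProvenancedTable(out, file, provenance)
}
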