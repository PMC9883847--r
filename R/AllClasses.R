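#' SimilaritySet: within-group pairwise C-index collection
#'
#' Holds every unordered within-group pair of samples together with its
#' Ruzicka similarity (C-index) value. For a group of size g there are
#' exactly g(g-1)/2 values; cross-group pairs are never stored.
#'
#' @slot group single character group label (e.g. "exposed").
#' @slot pairs two-column character matrix of sample ids, row i < j order.
#' @slot values numeric vector of similarities in [0, 1], one per pair.
#' @slot metric character, the similarity metric used.
#' @exportClass SimilaritySet
setClass("SimilaritySet",
  representation(group = "character", pairs = "matrix", values = "numeric",
                 metric = "character"))

setValidity("SimilaritySet", function(object) {
  msg <- NULL
  if (ncol(object@pairs) != 2L) {
    msg <- c(msg, "pairs must have two columns")
  }
  if (nrow(object@pairs) != length(object@values)) {
    msg <- c(msg, "one value per pair required")
  }
  if (length(object@values) &&
      (min(object@values) < -1e-12 || max(object@values) > 1 + 1e-12)) {
    msg <- c(msg, "values must lie in [0, 1]")
  }
  g <- length(unique(as.vector(object@pairs)))
  if (length(object@values) != g * (g - 1L) / 2L) {
    msg <- c(msg, "pair count must be g(g-1)/2 for group size g")
  }
  if (is.null(msg)) TRUE else msg
})

#' @describeIn SimilaritySet number of pairs
#' @param x,object a `SimilaritySet`
#' @export
setMethod("length", "SimilaritySet", function(x) length(x@values))

#' Extract C-index values from a SimilaritySet
#' @param x a `SimilaritySet`
#' @return numeric vector of pairwise similarities
#' @export
cValues <- function(x) {
  stopifnot(is(x, "SimilaritySet"))
  x@values
}

#' Group label of a SimilaritySet
#' @param x a `SimilaritySet`
#' @export
groupLabel <- function(x) {
  stopifnot(is(x, "SimilaritySet"))
  x@group
}

setMethod("show", "SimilaritySet", function(object) {
  cat("SimilaritySet (", object@metric, ") group '", object@group, "': ",
      length(object@values), " pairs, median C = ",
      format(stats::median(object@values), digits = 4), "\n", sep = "")
})

#' AkpVerdict: outcome of the three-hypothesis Wilcoxon AKP screen
#'
#' One exposure factor's summary: medians and interquartile ranges of the
#' exposed and non-exposed C-index collections, the two-sided and both
#' one-sided rank-sum p-values, and the verdict under the active convention.
#'
#' @slot factor exposure factor name.
#' @slot medianE,medianNE medians of the exposed / non-exposed C values.
#' @slot iqrE,iqrNE quartile pairs (named numeric length 2).
#' @slot pTwo,pGreater,pLess rank-sum p-values (two-sided, E > NE, E < NE).
#' @slot verdict one of "AKP", "anti-AKP", "none".
#' @slot convention "paper" or "ecological" (label duality, see vignette).
#' @exportClass AkpVerdict
setClass("AkpVerdict",
  representation(factor = "character", medianE = "numeric",
                 medianNE = "numeric", iqrE = "numeric", iqrNE = "numeric",
                 pTwo = "numeric", pGreater = "numeric", pLess = "numeric",
                 verdict = "character", convention = "character"))

setValidity("AkpVerdict", function(object) {
  if (!object@verdict %in% c("AKP", "anti-AKP", "none")) {
    return("verdict must be AKP, anti-AKP or none")
  }
  if (!object@convention %in% c("paper", "ecological")) {
    return("convention must be 'paper' or 'ecological'")
  }
  TRUE
})

setMethod("show", "AkpVerdict", function(object) {
  fmtIqr <- function(m, q) sprintf("%.3f (%.3f-%.3f)", m, q[1], q[2])
  cat("AkpVerdict [", object@convention, " convention]\n", sep = "")
  cat("  factor      :", object@factor, "\n")
  cat("  exposed     :", fmtIqr(object@medianE, object@iqrE), "\n")
  cat("  non-exposed :", fmtIqr(object@medianNE, object@iqrNE), "\n")
  cat(sprintf("  p(E!=NE)=%.3g  p(E>NE)=%.3g  p(E<NE)=%.3g\n",
              object@pTwo, object@pGreater, object@pLess))
  cat("  verdict     :", object@verdict, "\n")
})

#' @describeIn AkpVerdict flatten to a one-row summary data frame
#' @param row.names,optional,... passed through (unused)
#' @export
setMethod("as.data.frame", "AkpVerdict",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(factor = x@factor,
               median_e = x@medianE, q1_e = x@iqrE[1], q3_e = x@iqrE[2],
               median_ne = x@medianNE, q1_ne = x@iqrNE[1], q3_ne = x@iqrNE[2],
               p_two = x@pTwo, p_greater = x@pGreater, p_less = x@pLess,
               verdict = x@verdict, convention = x@convention,
               stringsAsFactors = FALSE)
  })

#' FoodHierarchy: rooted hierarchical food classification tree
#'
#' Wraps an `ape` phylo object whose tips are food items (or subitems) and
#' whose internal nodes are the coarser classification levels, together with
#' a node-name to level map.
#'
#' @slot tree a rooted `phylo` with node labels and branch lengths.
#' @slot levels named character vector mapping node name to its level
#'   (root, top, group17, group35, item, subitem).
#' @slot leafLevel level of the leaves ("item" or "subitem").
#' @exportClass FoodHierarchy
setClass("FoodHierarchy",
  representation(tree = "ANY", levels = "character", leafLevel = "character"))

setValidity("FoodHierarchy", function(object) {
  tr <- object@tree
  if (!inherits(tr, "phylo")) {
    return("tree slot must be an ape 'phylo' object")
  }
  nms <- c(tr$tip.label, tr$node.label)
  if (!all(nms %in% names(object@levels))) {
    return("every node must have a level assignment")
  }
  if (anyDuplicated(tr$tip.label)) {
    return("leaf names must be unique")
  }
  TRUE
})

#' Access the underlying phylo tree of a FoodHierarchy
#' @param x a `FoodHierarchy`
#' @return an `ape::phylo`
#' @export
foodTree <- function(x) {
  stopifnot(is(x, "FoodHierarchy"))
  x@tree
}

#' Leaf (item) names of a FoodHierarchy
#' @param x a `FoodHierarchy`
#' @export
leafNames <- function(x) {
  stopifnot(is(x, "FoodHierarchy"))
  x@tree$tip.label
}

#' Node-to-level map of a FoodHierarchy
#' @param x a `FoodHierarchy`
#' @export
nodeLevels <- function(x) {
  stopifnot(is(x, "FoodHierarchy"))
  x@levels
}

setMethod("show", "FoodHierarchy", function(object) {
  tab <- table(object@levels)
  cat("FoodHierarchy with", length(object@tree$tip.label), "leaves (level:",
      object@leafLevel, ")\n")
  cat("  nodes per level:",
      paste(names(tab), as.integer(tab), sep = "=", collapse = ", "), "\n")
})

#' HurdleDesign: zero-aware encoding of a count table
#'
#' A sample x taxon binary incidence matrix plus a matching abundance matrix
#' carrying the centered log-ratio transform computed, per sample, over the
#' non-zero entries only. Structural zeros are carried as NA in the abundance
#' part.
#'
#' @slot incidence sample x taxon 0/1 matrix.
#' @slot abundance sample x taxon numeric matrix, NA where incidence is 0.
#'   Designs built by [hurdleEncode()] carry the per-sample CLR over the
#'   non-zero support (finite entries sum to 0); simulated benchmark
#'   designs may carry general zero-aware abundances.
#' @slot level taxonomic rank the taxa were aggregated to.
#' @slot dropped names of taxa removed because absent in every sample.
#' @exportClass HurdleDesign
setClass("HurdleDesign",
  representation(incidence = "matrix", abundance = "matrix",
                 level = "character", dropped = "character"))

setValidity("HurdleDesign", function(object) {
  msg <- NULL
  if (!identical(dim(object@incidence), dim(object@abundance))) {
    msg <- c(msg, "incidence and abundance must have identical dimensions")
  }
  if (!all(object@incidence %in% c(0, 1))) {
    msg <- c(msg, "incidence must be 0/1")
  }
  if (!identical(unname(is.na(object@abundance)),
                 unname(object@incidence == 0))) {
    msg <- c(msg, "abundance must be NA exactly where incidence is 0")
  }
  if (any(!is.finite(object@abundance[object@incidence == 1]))) {
    msg <- c(msg, "observed abundances must be finite")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "HurdleDesign", function(object) {
  cat("HurdleDesign:", nrow(object@incidence), "samples x",
      ncol(object@incidence), "taxa at rank '", object@level, "'\n", sep = " ")
  cat("  zero fraction:",
      format(mean(object@incidence == 0), digits = 3), "\n")
  if (length(object@dropped)) {
    cat("  dropped all-zero taxa:", paste(object@dropped, collapse = ", "),
        "\n")
  }
})

#' CoabundanceNetwork: undirected taxon co-abundance graph
#'
#' @slot nodes taxon names.
#' @slot edges data.frame with columns u, v, weight (partial correlation in
#'   [-1, 1]) and sign.
#' @slot selection penalty-selection rule used ("bic" or "stability").
#' @exportClass CoabundanceNetwork
setClass("CoabundanceNetwork",
  representation(nodes = "character", edges = "data.frame",
                 selection = "character"))

setValidity("CoabundanceNetwork", function(object) {
  e <- object@edges
  msg <- NULL
  if (!all(c("u", "v", "weight", "sign") %in% colnames(e))) {
    msg <- c(msg, "edges must have columns u, v, weight, sign")
  } else {
    if (any(e$u == e$v)) msg <- c(msg, "self loops are not allowed")
    if (!all(c(e$u, e$v) %in% object@nodes)) {
      msg <- c(msg, "edge endpoints must be nodes")
    }
    if (nrow(e) && (any(!is.finite(e$weight)) || max(abs(e$weight)) > 1 + 1e-9)) {
      msg <- c(msg, "weights must be finite and in [-1, 1]")
    }
  }
  if (is.null(msg)) TRUE else msg
})

#' Edge density of a CoabundanceNetwork
#' @param x a `CoabundanceNetwork`
#' @return 2|E| / (|V|(|V|-1))
#' @export
networkDensity <- function(x) {
  stopifnot(is(x, "CoabundanceNetwork"))
  p <- length(x@nodes)
  if (p < 2) return(0)
  2 * nrow(x@edges) / (p * (p - 1))
}

#' Edge table of a CoabundanceNetwork
#' @param x a `CoabundanceNetwork`
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "CoabundanceNetwork"))
  x@edges
}

#' Node names of a CoabundanceNetwork
#' @param x a `CoabundanceNetwork`
#' @export
networkNodes <- function(x) {
  stopifnot(is(x, "CoabundanceNetwork"))
  x@nodes
}

setMethod("show", "CoabundanceNetwork", function(object) {
  cat("CoabundanceNetwork:", length(object@nodes), "nodes,",
      nrow(object@edges), "edges (density",
      format(networkDensity(object), digits = 3), ")\n")
  cat("  selection:", object@selection, "\n")
})

#' ProcrustesResult: PROTEST comparison of two ordinations
#'
#' @slot m2 residual sum of squares in [0, 1] after optimal superimposition
#'   of the unit-normalized configurations.
#' @slot pPerm permutation p-value.
#' @slot nPerm number of permutations.
#' @slot k embedding dimension used.
#' @exportClass ProcrustesResult
setClass("ProcrustesResult",
  representation(m2 = "numeric", pPerm = "numeric", nPerm = "numeric",
                 k = "numeric"))

setValidity("ProcrustesResult", function(object) {
  if (object@m2 < -1e-9 || object@m2 > 1 + 1e-9) {
    return("m2 must lie in [0, 1]")
  }
  if (object@pPerm <= 0 || object@pPerm > 1) {
    return("pPerm must lie in (0, 1]")
  }
  TRUE
})

setMethod("show", "ProcrustesResult", function(object) {
  cat(sprintf("ProcrustesResult: m2 = %.4g, p = %.4g (%d permutations, k = %d)\n",
              object@m2, object@pPerm, as.integer(object@nPerm),
              as.integer(object@k)))
})

#' PermanovaResult: one-factor permutational multivariate ANOVA
#'
#' @slot pseudoF pseudo-F statistic.
#' @slot R2 fraction of distance-matrix variation explained by the factor.
#' @slot pPerm permutation (or exhaustive-enumeration) p-value.
#' @slot nPerm number of permutations / enumerated label assignments.
#' @slot exhaustive whether every distinct label assignment was enumerated.
#' @exportClass PermanovaResult
setClass("PermanovaResult",
  representation(pseudoF = "numeric", R2 = "numeric", pPerm = "numeric",
                 nPerm = "numeric", exhaustive = "logical"))

setValidity("PermanovaResult", function(object) {
  if (object@R2 < -1e-9 || object@R2 > 1 + 1e-9) {
    return("R2 must lie in [0, 1]")
  }
  if (object@pseudoF < 0) {
    return("pseudo-F must be non-negative")
  }
  TRUE
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf("PermanovaResult: F = %.4g, R2 = %.4g, p = %.4g (%s, n = %d)\n",
              object@pseudoF, object@R2, object@pPerm,
              if (object@exhaustive) "exhaustive" else "sampled",
              as.integer(object@nPerm)))
})
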