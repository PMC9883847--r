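#' Default cohort marginals
#'
#' Positive-case counts for the packaged default cohort of 331 colorectal
#' cancer patients: 115 with dietary records, 209 male, 40 with a family
#' history, 41 with neoadjuvant therapy, 65 ever smokers, 126 ever drinkers,
#' 134 obese (BMI >= 25 kg/m2), 130 hypertensive and 70 diabetic.
#'
#' @return named list of positive-case counts plus `n`.
#' @export
cohortMarginals <- function() {
  list(n = 331L, dietary_data = 115L, sex = 209L, family_history = 40L,
       neoadjuvant = 41L, smoking = 65L, alcohol = 126L, obesity = 134L,
       hypertension = 130L, diabetes = 70L)
}

## inverse-CDF truncated normal draw (deterministic given RNG stream)
.rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

#' Generate a synthetic cohort with exact factor marginals
#'
#' Draws per-subject metadata whose positive-case counts match the requested
#' marginals EXACTLY: each factor's positive cases are assigned to a random
#' permutation of subjects rather than by independent coin flips, so fixture
#' counts are deterministic test targets. BMI is drawn from two truncated
#' normals split at the 25.0 kg/m2 obesity cutoff so that the obesity count
#' is exact and the `obesity == "yes" <=> bmi >= 25` invariant holds.
#'
#' @param n number of subjects (>= 2).
#' @param marginals named list of positive-case counts (or proportions in
#'   (0,1)) for any of: dietary_data, sex (male count), family_history,
#'   neoadjuvant, smoking, alcohol, obesity, hypertension, diabetes.
#'   Defaults to [cohortMarginals()]; omitted factors fall back to the
#'   default scaled to `n` (or 0 when a bare list is supplied).
#' @param ageMean,ageSd age distribution parameters in years (default 61.9,
#'   11.0, truncated below at 18).
#' @param seed integer seed; same seed, same table.
#' @return data.frame with one row per subject: subject_id, age, sex,
#'   family_history, neoadjuvant, smoking, alcohol, bmi, obesity,
#'   hypertension, diabetes, dietary_data.
#' @examples
#' cohort <- generateCohort(seed = 42)
#' sum(cohort$smoking == "ever")  # 65, matching the default marginals
#' @export
generateCohort <- function(n = 331L, marginals = cohortMarginals(),
                           ageMean = 61.9, ageSd = 11.0, seed = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("cohort size 'n' must be at least 2")
  }
  n <- as.integer(n)
  .checkSeed(seed)

  factors <- c("dietary_data", "sex", "family_history", "neoadjuvant",
               "smoking", "alcohol", "obesity", "hypertension", "diabetes")
  ## a marginal list carrying its reference size n (as cohortMarginals()
  ## does) is rescaled when the requested cohort size differs
  scaleBy <- if (!is.null(marginals$n) && marginals$n != n) {
    n / marginals$n
  } else {
    1
  }
  counts <- integer(length(factors))
  names(counts) <- factors
  for (f in factors) {
    k <- marginals[[f]]
    if (is.null(k)) k <- 0L
    if (is.numeric(k) && length(k) == 1L && k > 0 && k < 1) {
      k <- round(k * n)
    } else if (is.numeric(k)) {
      k <- round(k * scaleBy)
    }
    if (!is.numeric(k) || length(k) != 1L || k < 0 ||
        abs(k - round(k)) > 1e-8) {
      stop("marginal for '", f, "' must be a count or a proportion")
    }
    if (k > n) {
      stop("invalid marginal: '", f, "' = ", k, " exceeds n = ", n)
    }
    counts[[f]] <- as.integer(round(k))
  }

  if (!is.null(seed)) set.seed(.substreamSeed(seed, "cohort"))
  subject_id <- sprintf("S%04d", seq_len(n))
  assignYes <- function(k) {
    out <- logical(n)
    out[sample.int(n, k)] <- TRUE
    out
  }
  yes <- lapply(counts, assignYes)

  age <- .rtruncnorm(n, ageMean, ageSd, lower = 18)

  ## BMI: truncated normals either side of the 25.0 cutoff; the blend
  ## reproduces an overall mean near 24.4 and sd near 3 kg/m2.
  bmi <- numeric(n)
  obese <- yes$obesity
  bmi[obese] <- .rtruncnorm(sum(obese), 27.2, 2.0, lower = 25)
  bmi[!obese] <- .rtruncnorm(sum(!obese), 22.7, 1.9, upper = 25 - 1e-9)

  yn <- function(v) factor(ifelse(v, "yes", "no"), levels = c("no", "yes"))
  data.frame(
    subject_id = subject_id,
    age = age,
    sex = factor(ifelse(yes$sex, "male", "female"),
                 levels = c("female", "male")),
    family_history = yn(yes$family_history),
    neoadjuvant = yn(yes$neoadjuvant),
    smoking = factor(ifelse(yes$smoking, "ever", "never"),
                     levels = c("never", "ever")),
    alcohol = factor(ifelse(yes$alcohol, "ever", "never"),
                     levels = c("never", "ever")),
    bmi = bmi,
    obesity = yn(obese),
    hypertension = yn(yes$hypertension),
    diabetes = yn(yes$diabetes),
    dietary_data = yn(yes$dietary_data),
    row.names = subject_id,
    stringsAsFactors = FALSE)
}

#' Specify a planted exposure effect on the microbiome generator
#'
#' `mode = "akp"` plants the responder model: a `responderFraction` subset of
#' exposed subjects each receives an idiosyncratic, per-subject re-drawn
#' community mean (mild dysbiosis affecting part of the group, which raises
#' between-subject heterogeneity). `mode = "anti_akp"` plants the
#' homogenizing model: ALL exposed subjects share one depleted mean with a
#' `richnessLoss` fraction of taxa structurally zeroed and between-subject
#' dispersion tightened (severe dysbiosis affecting the whole group).
#'
#' @param factor name of a binary exposure column in the cohort table.
#' @param mode "null", "akp" or "anti_akp".
#' @param responderFraction fraction of exposed subjects that respond
#'   (akp mode; forced to 0 under mode "null").
#' @param shiftMagnitude log-scale displacement of the shifted Dirichlet
#'   means (positive real).
#' @param dispersionRatio between-subject concentration change for affected
#'   subjects, applied in the direction of the planted mode: anti_akp
#'   multiplies the exposed-group concentration by this ratio (tighter),
#'   akp divides the responders' concentration by it (looser). Values > 1
#'   therefore always strengthen the planted effect.
#' @param richnessLoss fraction of taxa zeroed in the shared depleted mean
#'   (anti_akp only).
#' @return a list of class `EffectSpec`.
#' @export
effectSpec <- function(factor, mode = c("null", "akp", "anti_akp"),
                       responderFraction = 0.5, shiftMagnitude = 1,
                       dispersionRatio = 1, richnessLoss = 0) {
  mode <- match.arg(mode)
  stopifnot(is.character(factor), length(factor) == 1L)
  if (mode == "null") responderFraction <- 0
  if (responderFraction < 0 || responderFraction > 1) {
    stop("responderFraction must lie in [0, 1]")
  }
  if (shiftMagnitude <= 0 && mode != "null") {
    stop("shiftMagnitude must be positive")
  }
  if (dispersionRatio <= 0) {
    stop("dispersionRatio must be positive")
  }
  if (richnessLoss < 0 || richnessLoss > 1) {
    stop("richnessLoss must lie in [0, 1]")
  }
  if (richnessLoss > 0 && mode != "anti_akp") {
    warning("richnessLoss > 0 only takes effect under mode 'anti_akp'")
  }
  structure(list(factor = factor, mode = mode,
                 responderFraction = responderFraction,
                 shiftMagnitude = shiftMagnitude,
                 dispersionRatio = dispersionRatio,
                 richnessLoss = richnessLoss),
            class = "EffectSpec")
}

#' Specify diet-microbiome coupling strength
#'
#' `rho` scales a shared per-subject latent score mixed into both the
#' microbiome and the dietary generator; `rho = 0` makes the two tables
#' independent.
#'
#' @param rho coupling strength in [0, 1].
#' @return a list of class `CouplingSpec`.
#' @export
couplingSpec <- function(rho = 0) {
  if (!is.numeric(rho) || length(rho) != 1L || rho < 0 || rho > 1) {
    stop("rho must be a single number in [0, 1]")
  }
  structure(list(rho = rho), class = "CouplingSpec")
}

## Shared latent subject scores used by both generators; keyed only on the
## master seed and cohort size so diet and microbiome see the same scores.
.couplingLatent <- function(n, seed) {
  if (is.null(seed)) seed <- 0L
  set.seed(.substreamSeed(seed, "coupling"))
  rnorm(n)
}

## Synthetic nested 7-rank taxonomy for generated OTU tables.
.syntheticTaxonomy <- function(nTaxa, seed = NULL) {
  if (!is.null(seed)) set.seed(.substreamSeed(seed, "taxonomy"))
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia", "Tenericutes",
             "Fusobacteria", "Synergistetes")
  probs <- c(0.34, 0.28, 0.12, 0.08, 0.06, 0.05, 0.04, 0.03)
  phylum <- sample(phyla, nTaxa, replace = TRUE, prob = probs)
  pick <- function(parent, k, tag) paste0(parent, "_", tag,
                                          sample.int(k, length(parent),
                                                     replace = TRUE))
  cls <- pick(phylum, 2, "c")
  ord <- pick(cls, 2, "o")
  fam <- pick(ord, 2, "f")
  gen <- pick(fam, 3, "g")
  spc <- pick(gen, 2, "s")
  data.frame(kingdom = "Bacteria", phylum = phylum, class = cls,
             order = ord, family = fam, genus = gen, species = spc,
             row.names = sprintf("OTU%04d", seq_len(nTaxa)),
             stringsAsFactors = FALSE)
}

.normalizeMean <- function(m) {
  s <- sum(m)
  if (s <= 0) stop("community mean degenerated to all zeros")
  m / s
}

#' Generate a synthetic microbiome count table with planted effects
#'
#' Hierarchical Dirichlet-multinomial sampler: each subject's composition is
#' drawn from Dirichlet(theta_s * m_s), where m_s is the subject's (possibly
#' shifted) community mean and theta_s the between-subject concentration,
#' and counts follow Multinomial(depth). [effectSpec()] entries plant AKP
#' (responder) or anti-AKP (shared depleted mean) structure on binary
#' exposures; a [couplingSpec()] mixes the shared diet latent score into the
#' community means.
#'
#' @param cohort a cohort table from [generateCohort()].
#' @param nTaxa number of OTUs (>= 2). Ignored when `baseAlpha` is given.
#' @param depth reads per sample (fixed; >= 1).
#' @param baseAlpha optional Dirichlet concentration vector; its sum is the
#'   baseline between-subject concentration and its normalization the
#'   baseline community mean. Default: power-law mean `(1:nTaxa)^-0.7`
#'   scaled by `theta`.
#' @param theta baseline between-subject concentration when `baseAlpha` is
#'   not supplied (default 50; larger = more homogeneous subjects).
#' @param effects list of [effectSpec()] objects, applied in order.
#' @param coupling a [couplingSpec()].
#' @param seed integer seed.
#' @return a `SummarizedExperiment` (see [AbundanceExperiment()]); the
#'   shared depleted group means planted by anti-AKP effects are stored in
#'   `S4Vectors::metadata(.)$groupMeans`.
#' @export
generateMicrobiome <- function(cohort, nTaxa = 100L, depth = 10000L,
                               baseAlpha = NULL, theta = 50,
                               effects = list(),
                               coupling = couplingSpec(0), seed = NULL) {
  .checkSeed(seed)
  if (inherits(effects, "EffectSpec")) effects <- list(effects)
  for (ef in effects) {
    if (!inherits(ef, "EffectSpec")) {
      stop("'effects' must be a list of effectSpec() objects")
    }
    if (!ef$factor %in% colnames(cohort)) {
      stop("configuration error: effect factor '", ef$factor,
           "' not present in the cohort table")
    }
  }
  if (!is.null(baseAlpha)) {
    if (any(baseAlpha <= 0)) stop("baseAlpha entries must be positive")
    nTaxa <- length(baseAlpha)
    theta <- sum(baseAlpha)
    m0 <- baseAlpha / theta
  } else {
    if (nTaxa < 2) stop("nTaxa must be at least 2")
    m0 <- .normalizeMean(seq_len(nTaxa)^-0.7)
  }
  if (depth < 1) stop("depth must be at least 1")

  n <- nrow(cohort)
  z <- .couplingLatent(n, seed)
  if (!is.null(seed)) set.seed(.substreamSeed(seed, "microbiome"))

  means <- matrix(m0, nrow = nTaxa, ncol = n)
  thetas <- rep(theta, n)
  groupMeans <- list()

  for (ef in effects) {
    exposed <- which(.exposureMask(cohort, ef$factor))
    if (ef$mode == "anti_akp") {
      nZero <- round(ef$richnessLoss * nTaxa)
      zeroIdx <- if (nZero > 0) sample.int(nTaxa, nZero) else integer(0)
      shifted <- m0 * exp(ef$shiftMagnitude * rnorm(nTaxa))
      shifted[zeroIdx] <- 0
      shifted <- .normalizeMean(shifted)
      means[, exposed] <- shifted
      thetas[exposed] <- thetas[exposed] * ef$dispersionRatio
      groupMeans[[ef$factor]] <- shifted
    } else if (ef$mode == "akp") {
      nResp <- round(ef$responderFraction * length(exposed))
      responders <- if (nResp > 0) sample(exposed, nResp) else integer(0)
      for (s in responders) {
        means[, s] <- .normalizeMean(
          means[, s] * exp(ef$shiftMagnitude * rnorm(nTaxa)))
        thetas[s] <- thetas[s] / ef$dispersionRatio
      }
    }
  }

  if (coupling$rho > 0) {
    v <- rnorm(nTaxa)
    for (s in seq_len(n)) {
      means[, s] <- .normalizeMean(means[, s] * exp(coupling$rho * z[s] * v))
    }
  }

  counts <- matrix(0L, nrow = nTaxa, ncol = n)
  for (s in seq_len(n)) {
    alpha <- thetas[s] * means[, s]
    g <- numeric(nTaxa)
    pos <- alpha > 0
    g[pos] <- rgamma(sum(pos), shape = alpha[pos])
    if (sum(g) <= 0) g[which.max(alpha)] <- 1
    counts[, s] <- rmultinom(1, size = depth, prob = g / sum(g))
  }
  rownames(counts) <- sprintf("OTU%04d", seq_len(nTaxa))
  colnames(counts) <- rownames(cohort)

  se <- AbundanceExperiment(counts, .syntheticTaxonomy(nTaxa, seed), cohort)
  S4Vectors::metadata(se)$groupMeans <- groupMeans
  S4Vectors::metadata(se)$depth <- depth
  se
}

#' Generate synthetic dietary intakes on a food hierarchy
#'
#' Leaf intakes are log-normal and sparsified: each subject with dietary
#' data consumes a random subset of food items, with grams/day drawn on the
#' log scale. A positive coupling `rho` mixes the shared per-subject latent
#' score (the same scores used by [generateMicrobiome()] under the same
#' master seed) into both the consumption probabilities and the log-intake
#' means, so diet and microbiome ordinations become correlated.
#'
#' @param cohort a cohort table from [generateCohort()]; only subjects with
#'   `dietary_data == "yes"` receive intakes.
#' @param tree a [FoodHierarchy].
#' @param composition item x channel coefficient matrix covering all tree
#'   leaves (default [defaultFoodComposition()]).
#' @param coupling a [couplingSpec()].
#' @param meanLog,sdLog log-scale intake mean and sd (grams/day; defaults
#'   2.5 and 1.0, i.e. median ~12 g/day per consumed item).
#' @param consumptionProb baseline probability that a subject consumes a
#'   given item (default 0.45).
#' @param seed integer seed.
#' @return long-format intake table (subject_id, leaf_id, channel, amount)
#'   over the 12 standard channels, with the raw grams/day FFQ matrix as
#'   attribute `"ffq"`.
#' @export
generateDiet <- function(cohort, tree, composition = NULL,
                         coupling = couplingSpec(0), meanLog = 2.5,
                         sdLog = 1, consumptionProb = 0.45, seed = NULL) {
  .checkSeed(seed)
  stopifnot(is(tree, "FoodHierarchy"))
  if (is.null(composition)) composition <- defaultFoodComposition(tree)
  leaves <- leafNames(tree)
  if (!all(leaves %in% rownames(composition))) {
    stop("schema error: composition rows must cover all tree leaves")
  }

  dietary <- which(cohort$dietary_data == "yes")
  if (length(dietary) == 0) {
    stop("no subjects flagged as having dietary data")
  }
  z <- .couplingLatent(nrow(cohort), seed)[dietary]
  if (!is.null(seed)) set.seed(.substreamSeed(seed, "diet"))

  p <- length(leaves)
  u <- rnorm(p)  # latent direction on log-intake means
  w <- rnorm(p)  # latent direction on consumption log-odds

  ffq <- matrix(0, nrow = length(dietary), ncol = p,
                dimnames = list(rownames(cohort)[dietary], leaves))
  for (i in seq_along(dietary)) {
    eta <- stats::qlogis(consumptionProb) + coupling$rho * z[i] * w
    consumed <- runif(p) < stats::plogis(eta)
    if (!any(consumed)) consumed[which.max(eta)] <- TRUE
    grams <- exp(meanLog + coupling$rho * z[i] * u[consumed] +
                 rnorm(sum(consumed), sd = sdLog))
    ffq[i, consumed] <- grams
  }
  intake <- mapIntake(ffq, composition)
  attr(intake, "ffq") <- ffq
  intake
}
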