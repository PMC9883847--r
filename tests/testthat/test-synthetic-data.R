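test_that("cohort marginals are matched exactly for every factor and seed", {
  marg <- cohortMarginals()
  for (seed in c(1, 7, 42)) {
    cohort <- generateCohort(seed = seed)
    expect_equal(nrow(cohort), 331L)
    expect_equal(sum(cohort$dietary_data == "yes"), marg$dietary_data)
    expect_equal(sum(cohort$sex == "male"), marg$sex)
    expect_equal(sum(cohort$family_history == "yes"), marg$family_history)
    expect_equal(sum(cohort$neoadjuvant == "yes"), marg$neoadjuvant)
    expect_equal(sum(cohort$smoking == "ever"), marg$smoking)
    expect_equal(sum(cohort$alcohol == "ever"), marg$alcohol)
    expect_equal(sum(cohort$obesity == "yes"), marg$obesity)
    expect_equal(sum(cohort$hypertension == "yes"), marg$hypertension)
    expect_equal(sum(cohort$diabetes == "yes"), marg$diabetes)
    expect_false(anyDuplicated(cohort$subject_id) > 0)
  }
})

test_that("obesity flag agrees with the BMI cutoff and ages are plausible", {
  cohort <- generateCohort(seed = 3)
  expect_identical(cohort$obesity == "yes", cohort$bmi >= 25)
  expect_true(all(cohort$age > 0))
  expect_true(all(cohort$bmi > 0))
  expect_lt(abs(mean(cohort$bmi) - 24.4), 1)
})

test_that("degenerate marginals give an all-negative cohort", {
  cohort <- generateCohort(n = 10, marginals = list(), seed = 1)
  expect_true(all(cohort$smoking == "never"))
  expect_true(all(cohort$alcohol == "never"))
  expect_true(all(cohort$obesity == "no"))
  expect_true(all(cohort$dietary_data == "no"))
})

test_that("the same seed reproduces the cohort byte-identically", {
  expect_identical(generateCohort(seed = 99), generateCohort(seed = 99))
  expect_false(identical(generateCohort(seed = 1), generateCohort(seed = 2)))
})

test_that("impossible marginals and tiny cohorts are rejected", {
  expect_error(generateCohort(n = 10, marginals = list(smoking = 11)),
               "invalid marginal")
  expect_error(generateCohort(n = 1), "at least 2")
})

test_that("anti-AKP planting zeroes the requested fraction of the group mean", {
  cohort <- generateCohort(n = 40, marginals = list(smoking = 20), seed = 5)
  ef <- effectSpec("smoking", "anti_akp", shiftMagnitude = 1,
                   dispersionRatio = 2, richnessLoss = 0.5)
  se <- generateMicrobiome(cohort, nTaxa = 100, depth = 1000,
                           effects = list(ef), seed = 5)
  gm <- S4Vectors::metadata(se)$groupMeans[["smoking"]]
  expect_equal(sum(gm == 0), 50)
  expect_equal(sum(gm), 1, tolerance = 1e-12)
})

test_that("responder-mode planting raises exposed-group dissimilarity", {
  cohort <- generateCohort(n = 300, marginals = list(smoking = 150),
                           seed = 1)
  ef <- effectSpec("smoking", "akp", responderFraction = 0.5,
                   shiftMagnitude = 1, dispersionRatio = 4)
  se <- generateMicrobiome(cohort, nTaxa = 100, depth = 10000,
                           effects = list(ef), seed = 1)
  mask <- cohort$smoking == "ever"
  s <- pairwiseRuzicka(t(SummarizedExperiment::assay(se)))
  ut <- upper.tri(s)
  dissE <- 1 - s[outer(mask, mask, "&") & ut]
  dissNE <- 1 - s[outer(!mask, !mask, "&") & ut]
  expect_lt(wilcox.test(dissE, dissNE, alternative = "greater")$p.value,
            0.05)
})

test_that("a null microbiome leaves exposure groups exchangeable", {
  ps <- vapply(11:30, function(seed) {
    cohort <- generateCohort(n = 50, marginals = list(smoking = 25),
                             seed = seed)
    se <- generateMicrobiome(cohort, nTaxa = 60, depth = 2000, seed = seed)
    akpPermutationTest(se, cohort$smoking == "ever", nPerm = 199,
                       seed = seed)$pTwo
  }, numeric(1))
  ## the permutation p is valid, so rejections at 0.05 stay near level
  expect_lte(mean(ps <= 0.05), 0.15)
  expect_gt(median(ps), 0.1)
  cohort <- generateCohort(n = 50, marginals = list(smoking = 25),
                           seed = 11)
  expect_identical(
    SummarizedExperiment::assay(
      generateMicrobiome(cohort, nTaxa = 60, depth = 2000, seed = 11)),
    SummarizedExperiment::assay(
      generateMicrobiome(cohort, nTaxa = 60, depth = 2000, seed = 11)))
})

test_that("effect specs validate their fields", {
  expect_error(generateMicrobiome(generateCohort(n = 10, seed = 1),
                                  effects = list(effectSpec("nope", "akp")),
                                  nTaxa = 10, depth = 100, seed = 1),
               "configuration error")
  expect_warning(effectSpec("smoking", "akp", richnessLoss = 0.2),
                 "anti_akp")
  expect_equal(effectSpec("smoking", "null")$responderFraction, 0)
  expect_error(couplingSpec(1.2), "rho")
})

test_that("dietary intakes respect the composition table", {
  cohort <- generateCohort(n = 30, marginals = list(dietary_data = 20),
                           seed = 2)
  tree <- buildFoodHierarchy(defaultFoodClassification())
  comp <- defaultFoodComposition(tree)
  comp[, "fiber"] <- 0
  intake <- generateDiet(cohort, tree, comp, seed = 2)
  expect_equal(sum(intake$amount[intake$channel == "fiber"]), 0)
  expect_equal(sort(unique(intake$channel)), sort(intakeChannels()))
  expect_equal(length(unique(intake$subject_id)), 20)
  ## weight channel carries the raw grams
  ffq <- attr(intake, "ffq")
  w <- intakeMatrix(intake, "weight", leaves = colnames(ffq))
  expect_equal(w[rownames(ffq), colnames(ffq)], ffq)
  expect_error(generateDiet(cohort, tree, comp[1:10, ], seed = 2),
               "schema error")
})
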