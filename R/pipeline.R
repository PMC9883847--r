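#' Default pipeline configuration
#'
#' A complete simulation-mode configuration: the packaged cohort marginals,
#' a 100-taxon microbiome at depth 10,000 with an AKP effect planted on
#' smoking and an anti-AKP effect on obesity, the default food hierarchy
#' and composition, and the standard test parameters. Any element can be
#' overridden before passing the list to [runPipeline()], or the list can
#' be serialized to YAML and edited.
#'
#' @param seed master seed (default 42).
#' @return nested configuration list.
#' @export
defaultRunConfig <- function(seed = 42) {
  list(
    seed = seed,
    simulation = list(
      n = 331, nTaxa = 100, depth = 10000, theta = 50,
      effects = list(
        list(factor = "smoking", mode = "akp", responderFraction = 0.5,
             shiftMagnitude = 1, dispersionRatio = 2, richnessLoss = 0),
        list(factor = "obesity", mode = "anti_akp", responderFraction = 0,
             shiftMagnitude = 1, dispersionRatio = 4, richnessLoss = 0.3)),
      rho = 0),
    factors = c("smoking", "alcohol", "obesity", "hypertension",
                "diabetes"),
    channels = intakeChannels(),
    tests = list(nPerm = 199, kwAlpha = 0.05, ldaThreshold = 2,
                 pseudocount = 1, convention = "paper", alpha = 0.05),
    networkLevel = "phylum")
}

#' Read a pipeline configuration from YAML
#' @param file YAML path.
#' @return configuration list.
#' @export
readRunConfig <- function(file) {
  yaml::read_yaml(file)
}

.configEffects <- function(cfg) {
  lapply(cfg$simulation$effects, function(e) {
    effectSpec(factor = e$factor, mode = e$mode,
               responderFraction = e$responderFraction %||% 0.5,
               shiftMagnitude = e$shiftMagnitude %||% 1,
               dispersionRatio = e$dispersionRatio %||% 1,
               richnessLoss = e$richnessLoss %||% 0)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full analysis pipeline
#'
#' Orchestrates every stage end-to-end from a configuration list (or YAML
#' path): data simulation (or loading from `input` paths), the food
#' hierarchy, the AKP screen over all factors, per-group co-abundance
#' networks with connectivity comparison, LEfSe-style differential
#' abundance, Procrustes coupling of the 12 dietary channels (both UniFrac
#' variants) against the microbiome Aitchison distance, and dietary
#' alpha/beta-diversity associations. All outputs are TSV files in
#' `outdir` plus a deterministic run manifest; given the same seed the
#' bundle is byte-identical across runs.
#'
#' @param config configuration list (see [defaultRunConfig()]) or a YAML
#'   path.
#' @param outdir output directory.
#' @param seed optional override of `config$seed`.
#' @return invisibly, a list with the in-memory stage results.
#' @export
runPipeline <- function(config = defaultRunConfig(), outdir, seed = NULL) {
  if (is.character(config)) config <- readRunConfig(config)
  if (!is.null(seed)) config$seed <- seed
  seed <- config$seed %||% 42
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  prov <- paste0("AKPtools v", packageVersion("AKPtools"), " seed=", seed)
  tests <- config$tests
  started <- proc.time()[["elapsed"]]
  say <- function(...) message(sprintf("[%6.1fs] ",
                                       proc.time()[["elapsed"]] - started),
                               ...)

  ## ---- inputs: simulate or load -----------------------------------------
  if (!is.null(config$simulation) && !is.null(config$input)) {
    stop("config error: exactly one of 'simulation' or 'input' allowed")
  }
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    say("simulating cohort (n = ", sim$n, ")")
    cohort <- generateCohort(n = sim$n, seed = seed)
    tree <- buildFoodHierarchy(defaultFoodClassification())
    composition <- defaultFoodComposition(tree)
    say("simulating microbiome (", sim$nTaxa, " taxa)")
    se <- generateMicrobiome(cohort, nTaxa = sim$nTaxa, depth = sim$depth,
                             theta = sim$theta,
                             effects = .configEffects(config),
                             coupling = couplingSpec(sim$rho %||% 0),
                             seed = seed)
    say("simulating dietary intakes")
    intake <- generateDiet(cohort, tree, composition,
                           coupling = couplingSpec(sim$rho %||% 0),
                           seed = seed)
  } else {
    inp <- config$input
    if (is.null(inp)) stop("config error: no 'simulation' or 'input' block")
    se <- readAbundanceTables(inp$dir)
    cohort <- as.data.frame(SummarizedExperiment::colData(se))
    cls <- .readTsv(inp$classification)
    tree <- buildFoodHierarchy(cls)
    composition <- as.matrix(.readTsv(inp$composition))
    ffq <- .readTsv(inp$ffq)
    intake <- mapIntake(ffq, composition)
  }
  missingFactors <- setdiff(config$factors, colnames(cohort))
  if (length(missingFactors)) {
    stop("config error: factors absent from metadata: ",
         paste(missingFactors, collapse = ", "))
  }
  checkIntakeLeaves(intake, tree)

  writeAbundanceTables(se, outdir, prov)
  writeNewick(tree, file.path(outdir, "food_tree.nwk"))
  writeIntakeTables(intake, outdir, prov)
  yaml::write_yaml(config, file.path(outdir, "config.yaml"))

  ## ---- AKP screen -------------------------------------------------------
  say("AKP screen over ", length(config$factors), " factors")
  akp <- akpTable(se, factors = config$factors,
                  alpha = tests$alpha %||% 0.05,
                  convention = tests$convention %||% "paper")
  writeAkpTable(akp, file.path(outdir, "akp_table.tsv"), prov)

  ## ---- co-abundance networks -------------------------------------------
  say("co-abundance networks at rank '", config$networkLevel, "'")
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  connRows <- list()
  networks <- list()
  for (f in config$factors) {
    mask <- .exposureMask(meta, f)
    gE <- estimateNetwork(
      suppressWarnings(hurdleEncode(se[, mask], config$networkLevel)),
      seed = seed)
    gNE <- estimateNetwork(
      suppressWarnings(hurdleEncode(se[, !mask], config$networkLevel)),
      seed = seed)
    ## align node sets (a rare taxon may be absent within one group)
    common <- intersect(networkNodes(gE), networkNodes(gNE))
    gE <- .restrictNetwork(gE, common)
    gNE <- .restrictNetwork(gNE, common)
    writeEdgeList(gE, file.path(outdir, paste0("network_", f,
                                               "_exposed.tsv")), prov)
    writeEdgeList(gNE, file.path(outdir, paste0("network_", f,
                                                "_non_exposed.tsv")), prov)
    cc <- compareConnectivity(gE, gNE)
    connRows[[f]] <- data.frame(
      factor = f,
      density_exposed = networkDensity(gE),
      density_non_exposed = networkDensity(gNE),
      density_diff = cc$densityDiff,
      edge_count_diff = cc$edgeCountDiff,
      hub_exposed = cc$mostConnected[["exposed"]],
      hub_non_exposed = cc$mostConnected[["non_exposed"]],
      stringsAsFactors = FALSE)
    networks[[f]] <- list(exposed = gE, non_exposed = gNE)
  }
  .writeProvenancedTable(do.call(rbind, c(connRows,
                                          make.row.names = FALSE)),
                         file.path(outdir, "connectivity.tsv"), prov)

  ## ---- LEfSe ------------------------------------------------------------
  say("LEfSe-style differential abundance")
  lefse <- list()
  for (f in config$factors) {
    mask <- .exposureMask(meta, f)
    hits <- lefseTwoClass(se, ifelse(mask, "exposed", "non_exposed"),
                          kwAlpha = tests$kwAlpha %||% 0.05,
                          ldaThreshold = tests$ldaThreshold %||% 2,
                          seed = seed)
    .writeProvenancedTable(hits, file.path(outdir,
                                           paste0("lefse_", f, ".tsv")),
                           prov)
    lefse[[f]] <- hits
  }

  ## ---- diet-microbiome Procrustes (12 channels x 2 UniFrac variants) ----
  say("Procrustes over ", length(config$channels), " channels")
  dietIds <- rownames(meta)[meta$dietary_data == "yes"]
  micD <- aitchisonDistance(se[, dietIds],
                            pseudocount = tests$pseudocount %||% 1)
  procRows <- list()
  dietDists <- list()
  for (ch in config$channels) {
    m <- intakeMatrix(intake, ch, leaves = leafNames(tree))
    m <- m[dietIds, , drop = FALSE]
    ok <- rowSums(m) > 0
    for (variant in c("unweighted", "weighted")) {
      dch <- unifracDistance(m[ok, , drop = FALSE], tree, method = variant)
      pr <- procrustesProtest(dch, micD[ok, ok],
                              nPerm = tests$nPerm %||% 199, seed = seed)
      procRows[[paste(ch, variant)]] <- data.frame(
        channel = ch, distance_type = paste0(variant, "_unifrac"),
        m2 = pr@m2, p = pr@pPerm, n = sum(ok), stringsAsFactors = FALSE)
      dietDists[[paste(ch, variant)]] <- dch
    }
  }
  .writeProvenancedTable(do.call(rbind, c(procRows,
                                          make.row.names = FALSE)),
                         file.path(outdir, "procrustes.tsv"), prov)

  ## ---- dietary diversity vs factors (alpha GLM + PERMANOVA) -------------
  say("dietary diversity associations")
  assocRows <- list()
  for (ch in config$channels) {
    m <- intakeMatrix(intake, ch, leaves = leafNames(tree))[dietIds, ,
                                                            drop = FALSE]
    ok <- rowSums(m) > 0
    counts <- t(apply(m[ok, , drop = FALSE], 1, discretizeIntake))
    alphas <- data.frame(
      chao1 = apply(counts, 1, chao1),
      shannon = apply(m[ok, , drop = FALSE], 1, shannonIndex),
      simpson = apply(m[ok, , drop = FALSE], 1, simpsonIndex))
    for (f in config$factors) {
      mask <- .exposureMask(meta[dietIds, , drop = FALSE][ok, , drop = FALSE],
                            f)
      if (sum(mask) < 2 || sum(!mask) < 2) next
      for (ix in colnames(alphas)) {
        gl <- alphaGlm(alphas[[ix]], mask)
        assocRows[[paste(ch, f, ix)]] <- data.frame(
          factor = f, channel = ch, test = paste0("glm_", ix),
          statistic = gl$beta, p = gl$p, stringsAsFactors = FALSE)
      }
      for (variant in c("unweighted", "weighted")) {
        dch <- dietDists[[paste(ch, variant)]]
        pm <- permanova(dch, mask, nPerm = tests$nPerm %||% 199,
                        seed = seed)
        assocRows[[paste(ch, f, variant)]] <- data.frame(
          factor = f, channel = ch,
          test = paste0("permanova_", variant, "_unifrac"),
          statistic = pm@R2, p = pm@pPerm, stringsAsFactors = FALSE)
      }
    }
  }
  .writeProvenancedTable(do.call(rbind, c(assocRows,
                                          make.row.names = FALSE)),
                         file.path(outdir, "diet_association.tsv"), prov)

  ## ---- manifest ---------------------------------------------------------
  manifest <- list(
    package = paste0("AKPtools ", as.character(packageVersion("AKPtools"))),
    seed = seed,
    config_md5 = unname(tools::md5sum(file.path(outdir, "config.yaml"))),
    n_samples = ncol(se), n_taxa = nrow(se),
    n_dietary = length(dietIds),
    factors = config$factors,
    outputs = sort(list.files(outdir)))
  yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  say("done")
  invisible(list(se = se, cohort = cohort, tree = tree, intake = intake,
                 akp = akp, networks = networks, lefse = lefse,
                 procrustes = do.call(rbind, procRows),
                 associations = do.call(rbind, assocRows)))
}

## keep only edges among a restricted node set
.restrictNetwork <- function(g, nodes) {
  e <- networkEdges(g)
  e <- e[e$u %in% nodes & e$v %in% nodes, , drop = FALSE]
  rownames(e) <- NULL
  new("CoabundanceNetwork", nodes = sort(nodes), edges = e,
      selection = g@selection)
}
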