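## The 12 intake channels analysed throughout (weight in g/day, energy in
## kcal/day, all others g/day).
.CHANNELS <- c("weight", "energy", "plant_protein", "animal_protein",
               "plant_fat", "animal_fat", "carbohydrate", "fiber",
               "total_fatty_acids", "SFA", "MUFA", "PUFA")

#' Intake channels
#'
#' The 12 per-item intake channels supported by [mapIntake()]: consumed
#' weight, energy, plant/animal protein, plant/animal fat, carbohydrate,
#' fiber, total fatty acids and the saturated / monounsaturated /
#' polyunsaturated fractions.
#' @return character vector of channel names.
#' @export
intakeChannels <- function() .CHANNELS

#' Packaged default food classification
#'
#' A synthetic hierarchical classification with the canonical level sizes of
#' a Korean semi-quantitative FFQ: 4 top categories (plant-based foods,
#' animal-based foods, beverages, condiments), 17 and 35 intermediate food
#' groups, 106 items and, optionally, 663 subitems. Node names are
#' systematic (synthetic stand-ins, not a curated food database); level
#' sizes and nesting are the structural targets.
#'
#' @param subitems include the 663-subitem layer (default `FALSE`).
#' @return data.frame with columns top, group17, group35, item and, when
#'   requested, subitem.
#' @examples
#' cls <- defaultFoodClassification()
#' length(unique(cls$item))  # 106
#' @export
defaultFoodClassification <- function(subitems = FALSE) {
  g17 <- list(
    plant_based_foods = c("grains", "potatoes_starches", "legumes",
                          "vegetables", "mushrooms", "fruits", "seaweeds",
                          "nuts_seeds"),
    animal_based_foods = c("meats", "fish_shellfish", "eggs", "dairy"),
    beverages = c("teas", "coffee_cocoa", "alcoholic_beverages"),
    condiments = c("oils_fats", "seasonings"))
  g35Counts <- c(grains = 3, potatoes_starches = 1, legumes = 2,
                 vegetables = 4, mushrooms = 1, fruits = 3, seaweeds = 1,
                 nuts_seeds = 1, meats = 4, fish_shellfish = 3, eggs = 1,
                 dairy = 2, teas = 1, coffee_cocoa = 1,
                 alcoholic_beverages = 2, oils_fats = 2, seasonings = 3)

  rows <- list()
  for (top in names(g17)) {
    for (g in g17[[top]]) {
      for (i in seq_len(g35Counts[[g]])) {
        rows[[length(rows) + 1L]] <- data.frame(
          top = top, group17 = g, group35 = sprintf("%s_g%d", g, i),
          stringsAsFactors = FALSE)
      }
    }
  }
  g35 <- do.call(rbind, rows)

  itemCounts <- rep(3L, nrow(g35))
  itemCounts[1] <- itemCounts[1] + (106L - sum(itemCounts))
  out <- g35[rep(seq_len(nrow(g35)), itemCounts), ]
  idx <- unlist(lapply(itemCounts, seq_len))
  out$item <- sprintf("%s_it%02d", out$group35, idx)
  rownames(out) <- NULL

  if (subitems) {
    subCounts <- rep(6L, 106L)
    extra <- 663L - sum(subCounts)
    subCounts[seq_len(extra)] <- subCounts[seq_len(extra)] + 1L
    out <- out[rep(seq_len(106L), subCounts), ]
    sidx <- unlist(lapply(subCounts, seq_len))
    out$subitem <- sprintf("%s_s%d", out$item, sidx)
    rownames(out) <- NULL
  }
  out
}

#' Build a food hierarchy tree from a level-columns classification
#'
#' Constructs the rooted tree root -> top -> group17 -> group35 -> item
#' (-> subitem) with deterministic lexicographic node ordering within each
#' level and unit branch lengths by default.
#'
#' @param classification data.frame with columns top, group17, group35,
#'   item and optionally subitem; no missing cells.
#' @param useSubitems take subitems as leaves (requires a subitem column;
#'   default `FALSE`, leaves are the 106 items).
#' @param branchLengths scalar edge length, or a named vector giving the
#'   length of the edge above each level (`top`, `group17`, `group35`,
#'   `item`, `subitem`).
#' @return a [FoodHierarchy].
#' @export
buildFoodHierarchy <- function(classification, useSubitems = FALSE,
                               branchLengths = 1) {
  cls <- as.data.frame(classification, stringsAsFactors = FALSE)
  need <- c("top", "group17", "group35", "item")
  if (useSubitems) need <- c(need, "subitem")
  if (nrow(cls) == 0) {
    stop("schema error: empty classification table")
  }
  if (!all(need %in% colnames(cls))) {
    stop("schema error: classification must have columns ",
         paste(need, collapse = ", "))
  }
  cls <- cls[, need, drop = FALSE]
  for (cc in need) cls[[cc]] <- as.character(cls[[cc]])
  if (any(is.na(cls)) || any(unlist(cls) == "")) {
    stop("schema error: classification has missing cells")
  }

  ## each child must sit under exactly one parent
  for (i in seq_len(length(need) - 1L)) {
    parent <- cls[[need[i]]]
    child <- cls[[need[i + 1L]]]
    nPar <- tapply(parent, child, function(p) length(unique(p)))
    if (any(nPar > 1L)) {
      stop("ambiguity error: ", need[i + 1L], " '",
           names(nPar)[which(nPar > 1L)[1]], "' appears under multiple ",
           need[i], " parents")
    }
  }
  allNames <- unlist(lapply(need, function(cc) unique(cls[[cc]])))
  if (anyDuplicated(allNames)) {
    stop("ambiguity error: node name '", allNames[duplicated(allNames)][1],
         "' is reused across levels")
  }

  levelNames <- c("top", "group17", "group35", "item",
                  if (useSubitems) "subitem")
  leafLevel <- levelNames[length(levelNames)]
  internalLevels <- levelNames[-length(levelNames)]

  tips <- sort(unique(cls[[leafLevel]]))
  nodesPerLevel <- lapply(internalLevels,
                          function(l) sort(unique(cls[[l]])))
  names(nodesPerLevel) <- internalLevels

  nTip <- length(tips)
  rootNum <- nTip + 1L
  nodeNum <- c(root = rootNum)
  nxt <- rootNum + 1L
  for (l in internalLevels) {
    nn <- seq.int(nxt, length.out = length(nodesPerLevel[[l]]))
    names(nn) <- nodesPerLevel[[l]]
    nodeNum <- c(nodeNum, nn)
    nxt <- nxt + length(nn)
  }
  tipNum <- seq_len(nTip)
  names(tipNum) <- tips

  bl <- function(level) {
    if (length(branchLengths) == 1L && is.null(names(branchLengths))) {
      return(as.numeric(branchLengths))
    }
    if (!level %in% names(branchLengths)) {
      stop("branchLengths must name every level below the root")
    }
    as.numeric(branchLengths[[level]])
  }

  edges <- list()
  lens <- numeric(0)
  addEdges <- function(parents, children, level) {
    e <- cbind(parents, children)
    edges[[length(edges) + 1L]] <<- e
    lens <<- c(lens, rep(bl(level), nrow(e)))
  }
  addEdges(rep(rootNum, length(nodesPerLevel$top)),
           nodeNum[nodesPerLevel$top], "top")
  for (i in seq_len(length(levelNames) - 1L)) {
    pl <- levelNames[i]
    chl <- levelNames[i + 1L]
    if (pl == "top" && i == 1L) {
      ## root -> top already added above; now add top -> next level
    }
    link <- unique(cls[, c(pl, chl)])
    link <- link[order(link[[chl]]), , drop = FALSE]
    childNums <- if (chl == leafLevel) tipNum[link[[chl]]]
                 else nodeNum[link[[chl]]]
    addEdges(nodeNum[link[[pl]]], childNums, chl)
  }
  edge <- do.call(rbind, edges)
  dimnames(edge) <- NULL
  storage.mode(edge) <- "integer"

  phy <- list(edge = edge, tip.label = tips,
              Nnode = length(nodeNum),
              edge.length = lens,
              node.label = names(nodeNum))
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")

  levels <- c(stats::setNames("root", "root"),
              unlist(lapply(internalLevels, function(l) {
                stats::setNames(rep(l, length(nodesPerLevel[[l]])),
                                nodesPerLevel[[l]])
              })),
              stats::setNames(rep(leafLevel, nTip), tips))
  ## root's stored name is "root"
  names(levels)[1] <- "root"
  new("FoodHierarchy", tree = phy, levels = levels, leafLevel = leafLevel)
}

## top-level ancestor ("plant_based_foods", ...) of every leaf
.leafTopAncestor <- function(hierarchy) {
  phy <- foodTree(hierarchy)
  levels <- nodeLevels(hierarchy)
  nTip <- length(phy$tip.label)
  parent <- integer(nTip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  nodeName <- c(phy$tip.label, phy$node.label)
  out <- character(nTip)
  for (i in seq_len(nTip)) {
    node <- i
    repeat {
      node <- parent[node]
      if (node == 0L) break
      if (levels[[nodeName[node]]] == "top") {
        out[i] <- nodeName[node]
        break
      }
    }
  }
  stats::setNames(out, phy$tip.label)
}

#' Packaged default food-composition coefficients
#'
#' A synthetic item x channel coefficient matrix for the leaves of a food
#' hierarchy: weight coefficient 1 g/g, energy density in kcal/g, and
#' macronutrient / fatty-acid coefficients in g per g of food, with
#' plant-only channels zeroed for animal-based items and vice versa, and
#' total fatty acids equal to SFA + MUFA + PUFA. Coefficients are drawn
#' once from a fixed internal stream, so the matrix is deterministic; it is
#' a synthetic stand-in for a curated nutrient database.
#'
#' @param hierarchy a [FoodHierarchy].
#' @return numeric matrix, rows = leaves, columns = [intakeChannels()].
#' @export
defaultFoodComposition <- function(hierarchy) {
  leaves <- leafNames(hierarchy)
  tops <- .leafTopAncestor(hierarchy)[leaves]
  p <- length(leaves)
  set.seed(.substreamSeed(1907L, "composition"))
  plantish <- tops %in% c("plant_based_foods", "beverages", "condiments")

  protein <- runif(p, 0, 0.25)
  fat <- runif(p, 0, 0.30)
  sfaFrac <- runif(p)
  mufaFrac <- runif(p)
  pufaFrac <- runif(p)
  fracSum <- sfaFrac + mufaFrac + pufaFrac

  m <- matrix(0, nrow = p, ncol = length(.CHANNELS),
              dimnames = list(leaves, .CHANNELS))
  m[, "weight"] <- 1
  m[, "energy"] <- runif(p, 0.3, 6)
  m[, "plant_protein"] <- ifelse(plantish, protein, 0)
  m[, "animal_protein"] <- ifelse(plantish, 0, protein)
  m[, "plant_fat"] <- ifelse(plantish, fat, 0)
  m[, "animal_fat"] <- ifelse(plantish, 0, fat)
  m[, "carbohydrate"] <- ifelse(plantish, runif(p, 0, 0.6),
                                runif(p, 0, 0.05))
  m[, "fiber"] <- ifelse(tops == "plant_based_foods", runif(p, 0, 0.1), 0)
  m[, "SFA"] <- fat * sfaFrac / fracSum
  m[, "MUFA"] <- fat * mufaFrac / fracSum
  m[, "PUFA"] <- fat * pufaFrac / fracSum
  m[, "total_fatty_acids"] <- m[, "SFA"] + m[, "MUFA"] + m[, "PUFA"]
  m
}

#' Map FFQ grams onto the 12 intake channels
#'
#' Channel amounts are grams/day multiplied by the item's composition
#' coefficient; the weight channel always carries the raw grams (its
#' coefficient is fixed at 1). Totals are preserved: summing a channel over
#' leaves gives the subject's channel total.
#'
#' @param ffq subject x item grams/day matrix, or a long data.frame with
#'   columns subject_id, item, grams_per_day.
#' @param composition item x channel matrix of non-negative coefficients;
#'   rows must cover every FFQ item.
#' @return long-format intake table: subject_id, leaf_id, channel, amount.
#' @examples
#' ffq <- matrix(c(100, 50), 1, dimnames = list("S1", c("rice", "beef")))
#' comp <- matrix(c(1, 1, 0.3, 0), 2,
#'                dimnames = list(c("rice", "beef"),
#'                                c("weight", "carbohydrate")))
#' it <- mapIntake(ffq, comp)
#' sum(it$amount[it$channel == "carbohydrate"])  # 30 g/day
#' @export
mapIntake <- function(ffq, composition) {
  if (is.data.frame(ffq) && all(c("subject_id", "item", "grams_per_day")
                                %in% colnames(ffq))) {
    subjects <- sort(unique(ffq$subject_id))
    items <- sort(unique(ffq$item))
    m <- matrix(0, length(subjects), length(items),
                dimnames = list(subjects, items))
    m[cbind(match(ffq$subject_id, subjects), match(ffq$item, items))] <-
      ffq$grams_per_day
    ffq <- m
  }
  ffq <- as.matrix(ffq)
  if (any(ffq < 0)) stop("FFQ grams must be non-negative")
  composition <- as.matrix(composition)
  if (any(composition < 0)) {
    stop("composition coefficients must be non-negative")
  }
  unknown <- setdiff(colnames(ffq), rownames(composition))
  if (length(unknown)) {
    stop("mapping error: items missing from the composition table: ",
         paste(unknown, collapse = ", "))
  }
  channels <- intersect(.CHANNELS, colnames(composition))
  if (!"weight" %in% channels) channels <- c("weight", channels)

  items <- colnames(ffq)
  subjects <- rownames(ffq)
  if (is.null(subjects)) subjects <- paste0("S", seq_len(nrow(ffq)))
  out <- vector("list", length(channels))
  for (ci in seq_along(channels)) {
    ch <- channels[ci]
    coefs <- if (ch == "weight") rep(1, length(items))
             else composition[items, ch]
    amounts <- sweep(ffq, 2, coefs, "*")
    out[[ci]] <- data.frame(
      subject_id = rep(subjects, times = length(items)),
      leaf_id = rep(items, each = length(subjects)),
      channel = ch,
      amount = as.vector(amounts),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Extract a subject x leaf intake matrix for one channel
#'
#' @param intake long intake table from [mapIntake()] / [generateDiet()].
#' @param channel one of [intakeChannels()].
#' @param leaves optional leaf universe; missing leaves are zero-filled.
#' @return subject x leaf numeric matrix.
#' @export
intakeMatrix <- function(intake, channel, leaves = NULL) {
  channel <- match.arg(channel, unique(intake$channel))
  sub <- intake[intake$channel == channel, , drop = FALSE]
  subjects <- sort(unique(sub$subject_id))
  cols <- if (is.null(leaves)) sort(unique(sub$leaf_id)) else leaves
  m <- matrix(0, length(subjects), length(cols),
              dimnames = list(subjects, cols))
  keep <- sub$leaf_id %in% cols
  m[cbind(match(sub$subject_id[keep], subjects),
          match(sub$leaf_id[keep], cols))] <- sub$amount[keep]
  m
}

#' Check that an intake table is compatible with a food hierarchy
#'
#' Every `leaf_id` must resolve to a tree leaf; called before any
#' tree-based beta-diversity computation.
#'
#' @param intake long intake table.
#' @param hierarchy a [FoodHierarchy].
#' @return invisibly `TRUE`, or an error listing unresolved leaves.
#' @export
checkIntakeLeaves <- function(intake, hierarchy) {
  unknown <- setdiff(unique(intake$leaf_id), leafNames(hierarchy))
  if (length(unknown)) {
    stop("mapping error: intake leaves not in the hierarchy: ",
         paste(unknown, collapse = ", "))
  }
  invisible(TRUE)
}

#' Serialize a food hierarchy to Newick
#'
#' @param hierarchy a [FoodHierarchy].
#' @param file optional path; when `NULL` the Newick string is returned.
#' @return the Newick string (invisibly when written to file).
#' @export
writeNewick <- function(hierarchy, file = NULL) {
  stopifnot(is(hierarchy, "FoodHierarchy"))
  txt <- ape::write.tree(foodTree(hierarchy))
  if (is.null(file)) return(txt)
  writeLines(txt, file)
  invisible(txt)
}

#' Read a food hierarchy from Newick
#'
#' The tree must be level-structured: all leaves at the same depth below
#' the root, with depth interpreted as top / group17 / group35 / item
#' (/ subitem).
#'
#' @param text Newick string, or `NULL` when reading from `file`.
#' @param file optional path to a Newick file.
#' @return a [FoodHierarchy].
#' @export
readNewick <- function(text = NULL, file = NULL) {
  phy <- tryCatch({
    if (!is.null(text)) ape::read.tree(text = text)
    else ape::read.tree(file)
  }, error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy) || !inherits(phy, "phylo")) {
    stop("parse error: malformed Newick input")
  }
  nTip <- length(phy$tip.label)
  parent <- integer(nTip + phy$Nnode)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])[1]
  depth <- integer(nTip + phy$Nnode)
  ## edges are ordered parent-before-child after reorder
  phy <- ape::reorder.phylo(phy, "cladewise")
  for (i in seq_len(nrow(phy$edge))) {
    depth[phy$edge[i, 2]] <- depth[phy$edge[i, 1]] + 1L
  }
  tipDepths <- unique(depth[seq_len(nTip)])
  if (length(tipDepths) != 1L) {
    stop("parse error: leaves are not all at the same classification depth")
  }
  levelChain <- c("root", "top", "group17", "group35", "item", "subitem")
  if (tipDepths + 1L > length(levelChain)) {
    stop("parse error: tree deeper than the supported level chain")
  }
  if (is.null(phy$node.label)) {
    phy$node.label <- paste0("node", seq_len(phy$Nnode))
  }
  nodeName <- c(phy$tip.label, phy$node.label)
  levels <- stats::setNames(levelChain[depth + 1L], nodeName)
  new("FoodHierarchy", tree = phy, levels = levels,
      leafLevel = levelChain[tipDepths + 1L])
}

#' Write per-channel intake tables as TSV
#'
#' @param intake long intake table.
#' @param dir output directory.
#' @param provenance header line content.
#' @return invisibly, the paths written.
#' @export
writeIntakeTables <- function(intake, dir, provenance = "AKPtools") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (ch in unique(intake$channel)) {
    m <- intakeMatrix(intake, ch)
    df <- cbind(subject_id = rownames(m), as.data.frame(m))
    p <- file.path(dir, paste0("intake_", ch, ".tsv"))
    .writeProvenancedTable(df, p, provenance)
    paths <- c(paths, p)
  }
  invisible(paths)
}
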