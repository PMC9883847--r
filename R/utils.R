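#' @importFrom stats rnorm runif rgamma rmultinom rbinom qnorm pnorm median
#'   quantile wilcox.test kruskal.test lm glm coef residuals sd cor dist
#'   var predict cov setNames plogis qlogis as.dist lm.fit
#' @importFrom utils write.table read.table combn packageVersion
#' @importFrom tools md5sum
#' @import methods
NULL

## Deterministic substream seeds: one master seed fans out to named stages so
## each generator can be re-run independently with identical output.
.substreamSeed <- function(seed, stage) {
  stages <- c(cohort = 11L, microbiome = 23L, diet = 37L, coupling = 41L,
              taxonomy = 53L, network = 67L, pipeline = 79L, composition = 97L)
  if (!stage %in% names(stages)) {
    stop("unknown substream stage: ", stage)
  }
  offset <- stages[[stage]]
  (as.integer(seed) %% 1000003L) * 1009L + offset
}

.checkSeed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("'seed' must be a single integer or NULL")
    }
  }
  invisible(seed)
}

## Write a TSV with a provenance comment header; readers skip '#' lines.
.writeProvenancedTable <- function(x, file, provenance = NULL,
                                   row.names = FALSE) {
  con <- file(file, open = "wt")
  on.exit(close(con))
  if (!is.null(provenance)) {
    writeLines(paste0("# ", provenance), con)
  }
  write.table(x, con, sep = "\t", quote = FALSE, row.names = row.names,
              col.names = TRUE)
  invisible(file)
}

.readTsv <- function(file, ...) {
  read.table(file, sep = "\t", header = TRUE, comment.char = "#",
             stringsAsFactors = FALSE, check.names = FALSE, ...)
}

## Square symmetric distance matrix with ids; used throughout in place of a
## dedicated container class.
.checkDistanceMatrix <- function(d, arg = "d") {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) {
    stop("'", arg, "' must be square")
  }
  if (any(!is.finite(d))) {
    stop("'", arg, "' must have finite entries")
  }
  if (max(abs(d - t(d))) > 1e-8) {
    stop("'", arg, "' must be symmetric")
  }
  if (any(abs(diag(d)) > 1e-8)) {
    stop("'", arg, "' must have a zero diagonal")
  }
  if (any(d < -1e-12)) {
    stop("'", arg, "' must be non-negative")
  }
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- paste0("S", seq_len(nrow(d)))
  }
  d
}

## Binary exposure mask from a metadata column; exposed levels follow the
## questionnaire coding ("ever"/"yes").
.exposureMask <- function(metadata, factorName,
                          exposedLevels = c("ever", "yes")) {
  if (!factorName %in% colnames(metadata)) {
    stop("factor '", factorName, "' not found in metadata")
  }
  as.character(metadata[[factorName]]) %in% exposedLevels
}
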