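#' Assemble a sample-by-taxon abundance experiment
#'
#' Bundles an integer count matrix (taxa in rows, samples in columns), a
#' 7-rank taxonomy table and per-sample metadata into a
#' [SummarizedExperiment::SummarizedExperiment], the container used by every
#' downstream stage. Column data carry the cohort exposures and covariates,
#' row data the resolved lineages.
#'
#' @param counts integer matrix, taxa x samples.
#' @param taxonomy data.frame with columns kingdom, phylum, class, order,
#'   family, genus, species; one row per taxon, rownames matching `counts`.
#' @param metadata data.frame of per-sample metadata; rownames (or a
#'   `subject_id` column) matching the sample columns of `counts`.
#' @return a `SummarizedExperiment` with assay `"counts"`.
#' @examples
#' cohort <- generateCohort(n = 12, marginals = list(smoking = 4), seed = 1)
#' se <- generateMicrobiome(cohort, nTaxa = 20, depth = 500, seed = 1)
#' dim(se)
#' @export
AbundanceExperiment <- function(counts, taxonomy, metadata) {
  counts <- as.matrix(counts)
  if (!all(counts >= 0) || any(abs(counts - round(counts)) > 1e-8)) {
    stop("counts must be non-negative integers")
  }
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  if (!all(ranks %in% colnames(taxonomy))) {
    stop("taxonomy must contain the 7 ranks: ",
         paste(ranks, collapse = ", "))
  }
  if (nrow(taxonomy) != nrow(counts)) {
    stop("taxonomy rows must match count-table taxa")
  }
  if (is.null(rownames(metadata)) && "subject_id" %in% colnames(metadata)) {
    rownames(metadata) <- metadata$subject_id
  }
  if (!is.null(colnames(counts)) &&
      !all(colnames(counts) %in% rownames(metadata))) {
    stop("every sample column must have a metadata row")
  }
  metadata <- metadata[colnames(counts), , drop = FALSE]
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy[, ranks, drop = FALSE]),
    colData = S4Vectors::DataFrame(metadata))
}

#' Per-sample relative abundances
#'
#' @param x a `SummarizedExperiment` with a `counts` assay, or a taxa x
#'   samples matrix.
#' @return matrix of the same shape with columns summing to 1.
#' @export
relativeAbundance <- function(x) {
  m <- .countMatrix(x)
  cs <- colSums(m)
  if (any(cs == 0)) {
    stop("samples with zero total count: ",
         paste(colnames(m)[cs == 0], collapse = ", "))
  }
  sweep(m, 2, cs, "/")
}

.countMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) {
    SummarizedExperiment::assay(x, "counts")
  } else {
    as.matrix(x)
  }
}

.sampleMatrix <- function(x) {
  ## samples in rows, taxa in columns
  t(.countMatrix(x))
}

#' Aggregate counts to a taxonomic rank
#'
#' Sums counts over all taxa sharing the same lineage down to the requested
#' rank.
#'
#' @param se a `SummarizedExperiment` built by [AbundanceExperiment()].
#' @param rank one of kingdom, phylum, class, order, family, genus, species.
#' @return taxa-at-rank x samples count matrix, rownames = rank labels.
#' @export
aggregateByRank <- function(se, rank = "phylum") {
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus",
             "species")
  rank <- match.arg(rank, ranks)
  tax <- as.data.frame(SummarizedExperiment::rowData(se))
  labels <- as.character(tax[[rank]])
  m <- .countMatrix(se)
  agg <- rowsum(m, group = labels)
  agg[order(rownames(agg)), , drop = FALSE]
}

#' Write an abundance experiment as plain-text tables
#'
#' Emits the count table (taxa x samples), the 7-column taxonomy sidecar and
#' the sample metadata as TSV files, each with a provenance header line.
#'
#' @param se a `SummarizedExperiment`.
#' @param dir output directory (created if absent).
#' @param provenance character scalar recorded in the header of each file.
#' @return invisibly, the paths written.
#' @export
writeAbundanceTables <- function(se, dir, provenance = "AKPtools") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- as.data.frame(.countMatrix(se))
  counts <- cbind(taxon = rownames(counts), counts)
  tax <- as.data.frame(SummarizedExperiment::rowData(se))
  tax <- cbind(taxon = rownames(tax), tax)
  meta <- as.data.frame(SummarizedExperiment::colData(se))
  paths <- c(file.path(dir, "counts.tsv"), file.path(dir, "taxonomy.tsv"),
             file.path(dir, "metadata.tsv"))
  .writeProvenancedTable(counts, paths[1], provenance)
  .writeProvenancedTable(tax, paths[2], provenance)
  .writeProvenancedTable(meta, paths[3], provenance)
  invisible(paths)
}

#' Read an abundance experiment back from plain-text tables
#'
#' @param dir directory holding `counts.tsv`, `taxonomy.tsv`, `metadata.tsv`
#'   as written by [writeAbundanceTables()].
#' @return a `SummarizedExperiment`.
#' @export
readAbundanceTables <- function(dir) {
  counts <- .readTsv(file.path(dir, "counts.tsv"))
  rownames(counts) <- counts$taxon
  counts$taxon <- NULL
  tax <- .readTsv(file.path(dir, "taxonomy.tsv"))
  rownames(tax) <- tax$taxon
  tax$taxon <- NULL
  meta <- .readTsv(file.path(dir, "metadata.tsv"))
  rownames(meta) <- meta$subject_id
  AbundanceExperiment(as.matrix(counts), tax, meta)
}
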