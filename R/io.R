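#' Write a cohort bundle to a directory of standard plain-text files
#'
#' Layout: one subdirectory per layer with `matrix.mtx` (MatrixMarket,
#' cells x features), `barcodes.tsv` and `features.tsv`; plus `cells.tsv`
#' (annotations), `samples.tsv`, `peaks.bed` (BED3+name), `genes.tsv`,
#' `genotypes.tsv` (snv_id, chrom, pos, then one dosage column per donor)
#' and, when present, `motif_hits.tsv`. The write -> read round trip is
#' lossless for counts and metadata.
#'
#' @param bundle A `cohort_bundle` (see [simulate_cohort()]).
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
write_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(x, f) utils::write.table(
    x, file.path(path, f), sep = "\t", quote = FALSE, row.names = FALSE)
  for (nm in names(bundle$layers)) {
    lay <- bundle$layers[[nm]]
    d <- file.path(path, nm)
    dir.create(d, showWarnings = FALSE)
    Matrix::writeMM(lay$counts, file.path(d, "matrix.mtx"))
    writeLines(rownames(lay$counts), file.path(d, "barcodes.tsv"))
    writeLines(colnames(lay$counts), file.path(d, "features.tsv"))
  }
  tsv(bundle$cells, "cells.tsv")
  tsv(bundle$samples, "samples.tsv")
  utils::write.table(bundle$peaks[, c("chrom", "start", "end", "peak_id")],
                     file.path(path, "peaks.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  tsv(bundle$genes, "genes.tsv")
  tsv(bundle$genotypes, "genotypes.tsv")
  if (!is.null(bundle$motif_hits)) tsv(bundle$motif_hits, "motif_hits.tsv")
  invisible(path)
}

#' Read a cohort bundle written by [write_bundle()]
#'
#' Validates structural invariants while reading: BED intervals must satisfy
#' `start < end` (violations are reported with their line number), every
#' cell barcode must have an annotation, and peak/gene ids must be unique.
#'
#' @param path Bundle directory.
#' @return A `cohort_bundle`.
#' @export
read_bundle <- function(path) {
  tsv <- function(f) utils::read.table(file.path(path, f), sep = "\t",
                                       header = TRUE, stringsAsFactors = FALSE,
                                       check.names = FALSE)
  layers <- list()
  for (nm in intersect(c("snRNA", "scRNA", "snATAC"), list.dirs(path, FALSE, FALSE))) {
    d <- file.path(path, nm)
    m <- methods::as(Matrix::readMM(file.path(d, "matrix.mtx")), "CsparseMatrix")
    rownames(m) <- readLines(file.path(d, "barcodes.tsv"))
    colnames(m) <- readLines(file.path(d, "features.tsv"))
    layers[[nm]] <- count_layer(nm, m)
  }
  cells <- tsv("cells.tsv")
  samples <- tsv("samples.tsv")
  peaks <- utils::read.table(file.path(path, "peaks.bed"), sep = "\t",
                             header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("chrom", "start", "end", "peak_id"))
  bad <- which(peaks$start >= peaks$end)
  if (length(bad)) {
    stop("malformed BED interval (start >= end) at line ", bad[1], " of peaks.bed")
  }
  peaks <- peaks[, c("peak_id", "chrom", "start", "end")]
  genes <- tsv("genes.tsv")
  genotypes <- tsv("genotypes.tsv")
  motif_hits <- if (file.exists(file.path(path, "motif_hits.tsv"))) {
    tsv("motif_hits.tsv")
  } else NULL
  bundle <- structure(list(layers = layers, cells = cells, samples = samples,
                           peaks = peaks, genes = genes, genotypes = genotypes,
                           motif_hits = motif_hits), class = "cohort_bundle")
  validate_bundle(bundle)
  bundle
}

#' Validate the structural invariants of a cohort bundle
#'
#' Checks count integrality and non-negativity, unique ids, complete cell
#' annotation per layer, timepoint levels, peak interval sanity and sorted
#' order, matched case/control pairs, and dosage values in {0, 1, 2, NA}.
#'
#' @param bundle A `cohort_bundle`.
#' @return The bundle, invisibly; errors describe the first violation.
#' @export
validate_bundle <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  for (nm in names(bundle$layers)) {
    lay <- bundle$layers[[nm]]
    ids <- rownames(lay$counts)
    ann <- bundle$cells[bundle$cells$layer == nm, ]
    missing <- setdiff(ids, ann$cell_id)
    if (length(missing)) {
      stop("missing cell annotation for cell(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  if (!all(bundle$cells$timepoint %in% c("T1", "T2", "T3"))) {
    stop("timepoint must be one of T1, T2, T3")
  }
  if (!all(bundle$cells$donor_id %in% bundle$samples$donor_id)) {
    stop("cell annotation references unknown donor")
  }
  .check_pairs(bundle$samples)
  .check_peaks(bundle$peaks)
  if (anyDuplicated(bundle$genes$gene_id)) stop("duplicate gene_ids")
  donor_cols <- intersect(names(bundle$genotypes), bundle$samples$donor_id)
  dos <- unlist(bundle$genotypes[, donor_cols])
  if (!all(is.na(dos) | dos %in% 0:2)) {
    stop("genotype dosages must be 0, 1, 2 or missing")
  }
  invisible(bundle)
}

#' Positions of all features (gene TSS and peak midpoints)
#'
#' @param bundle A `cohort_bundle`.
#' @return Data frame `feature_id`, `chrom`, `pos`.
#' @export
feature_positions <- function(bundle) {
  rbind(
    data.frame(feature_id = bundle$genes$gene_id, chrom = bundle$genes$chrom,
               pos = bundle$genes$tss, stringsAsFactors = FALSE),
    data.frame(feature_id = bundle$peaks$peak_id, chrom = bundle$peaks$chrom,
               pos = floor((bundle$peaks$start + bundle$peaks$end) / 2),
               stringsAsFactors = FALSE))
}
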