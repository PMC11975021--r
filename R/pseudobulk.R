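#' Construct a count layer
#'
#' A count layer holds the sparse cell-by-feature count matrix of one
#' modality together with its identity. Counts must be non-negative integers;
#' row names are cell barcodes, column names are feature ids (gene ids for
#' RNA layers, peak ids for ATAC).
#'
#' @param modality One of `"snRNA"`, `"scRNA"`, `"snATAC"`.
#' @param counts Matrix or sparse `Matrix` of non-negative integer counts,
#'   cells in rows, features in columns, with unique dimnames.
#' @return An object of class `count_layer`.
#' @export
count_layer <- function(modality, counts) {
  modality <- match.arg(modality, c("snRNA", "scRNA", "snATAC"))
  if (!methods::is(counts, "Matrix")) counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(methods::as(counts, "dMatrix"),
                                    "generalMatrix"), "CsparseMatrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("count matrix must carry cell (row) and feature (column) names")
  }
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts))) {
    stop("cell and feature ids must be unique within a layer")
  }
  x <- counts@x
  if (length(x) && (min(x) < 0 || any(x != round(x)))) {
    stop("counts must be non-negative integers")
  }
  structure(list(modality = modality, counts = counts), class = "count_layer")
}

#' @export
print.count_layer <- function(x, ...) {
  cat(sprintf("<count_layer> %s: %d cells x %d features (%.2f%% non-zero)\n",
              x$modality, nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  invisible(x)
}

#' Aggregate a count layer into lineage-collapsed pseudobulk profiles
#'
#' Sums per-cell counts within each (donor, timepoint, parent lineage) key
#' after collapsing sub-lineage annotations with [collapse_lineage()]. The
#' totals conserve reads: summed over keys and features they equal the sum of
#' the input matrix restricted to annotated cells. Keys with no cells simply
#' do not appear.
#'
#' @param layer A [count_layer()].
#' @param cells Data frame of cell annotations with columns `cell_id`,
#'   `donor_id`, `timepoint` (one of T1/T2/T3), `sublineage`, `layer`.
#'   Every cell in the matrix must have exactly one annotation row for this
#'   layer's modality.
#' @param lineage_map Label mapping passed to [collapse_lineage()].
#' @return An object of class `pseudobulk`: a list with `modality`, `counts`
#'   (dense features x keys matrix of read totals) and `keys` (data frame
#'   with `key`, `donor_id`, `timepoint`, `lineage`, `n_cells`).
#' @export
make_pseudobulk <- function(layer, cells, lineage_map = default_lineage_map()) {
  stopifnot(inherits(layer, "count_layer"), is.data.frame(cells))
  ann <- cells[cells$layer == layer$modality, , drop = FALSE]
  if (anyDuplicated(ann$cell_id)) {
    stop("duplicate annotations for cell(s): ",
         paste(utils::head(ann$cell_id[duplicated(ann$cell_id)], 5), collapse = ", "))
  }
  ids <- rownames(layer$counts)
  hit <- match(ids, ann$cell_id)
  if (anyNA(hit)) {
    stop("missing cell annotation for cell(s): ",
         paste(utils::head(ids[is.na(hit)], 5), collapse = ", "))
  }
  ann <- ann[hit, , drop = FALSE]
  if (!all(ann$timepoint %in% c("T1", "T2", "T3"))) {
    stop("timepoint must be one of T1, T2, T3")
  }
  lineage <- collapse_lineage(ann$sublineage, lineage_map)
  key <- paste(ann$donor_id, ann$timepoint, lineage, sep = "|")
  fkey <- factor(key, levels = unique(key[order(ann$donor_id, ann$timepoint, lineage)]))
  ind <- Matrix::sparseMatrix(i = seq_along(fkey), j = as.integer(fkey), x = 1,
                              dims = c(length(fkey), nlevels(fkey)))
  totals <- as.matrix(Matrix::t(Matrix::crossprod(ind, layer$counts)))
  colnames(totals) <- levels(fkey)
  parts <- do.call(rbind, strsplit(levels(fkey), "|", fixed = TRUE))
  keys <- data.frame(key = levels(fkey), donor_id = parts[, 1],
                     timepoint = parts[, 2], lineage = parts[, 3],
                     n_cells = as.integer(table(fkey)[levels(fkey)]),
                     stringsAsFactors = FALSE)
  structure(list(modality = layer$modality, counts = totals, keys = keys),
            class = "pseudobulk")
}

#' @export
print.pseudobulk <- function(x, ...) {
  cat(sprintf("<pseudobulk> %s: %d features x %d keys%s\n", x$modality,
              nrow(x$counts), nrow(x$keys),
              if (!is.null(x$cpm)) ", normalized" else ""))
  invisible(x)
}

#' Reads-per-million normalization of pseudobulk profiles
#'
#' Within each (donor, timepoint, lineage) key, each feature's read total is
#' divided by the key's total reads over all features and scaled to one
#' million, so normalized signals sum to 1e6 per key. Keys with zero total
#' reads have no defined normalized signal: they are recorded in
#' `$zero_keys`, their normalized column is `NA`, and downstream analyses
#' exclude them.
#'
#' @param pb A `pseudobulk` object from [make_pseudobulk()].
#' @return The same object with a `cpm` matrix (features x keys) and a
#'   `zero_keys` character vector added.
#' @export
normalize_per_million <- function(pb) {
  stopifnot(inherits(pb, "pseudobulk"))
  totals <- colSums(pb$counts)
  zero <- totals == 0
  cpm <- sweep(pb$counts, 2, ifelse(zero, NA_real_, totals), "/") * 1e6
  pb$cpm <- cpm
  pb$zero_keys <- colnames(pb$counts)[zero]
  if (any(zero)) {
    message("normalize_per_million: ", sum(zero),
            " zero-total key(s) flagged and excluded downstream: ",
            paste(utils::head(pb$zero_keys, 5), collapse = ", "))
  }
  pb
}
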