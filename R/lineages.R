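#' Default sub-lineage to parent-lineage mapping
#'
#' The five parent immune lineages used throughout the package are
#' `Monocyte`, `B`, `CD4T`, `CD8T` and `NK`. Fine-grained PBMC cluster
#' labels (as produced by reference-based label transfer) are collapsed onto
#' these parents before any pseudobulk aggregation: CD4 subsets map to
#' `CD4T`, CD8 subsets to `CD8T`, naive/memory/plasma B cells to `B`,
#' NK/NKT and CD56 bright/dim clusters to `NK`, and CD14/CD16 monocytes
#' plus conventional and plasmacytoid dendritic cells to `Monocyte`.
#'
#' The mapping is an ordinary named character vector (label -> parent), so a
#' study with a different annotation vocabulary can extend or replace it and
#' pass the result to [collapse_lineage()].
#'
#' @return Named character vector mapping sub-lineage labels to one of the
#'   five parent lineages.
#' @seealso [collapse_lineage()]
#' @export
default_lineage_map <- function() {
  c(
    ## T helper compartment
    "CD4 Naive"   = "CD4T", "CD4 TCM" = "CD4T", "CD4 TEM" = "CD4T",
    "CD4 CTL"     = "CD4T", "CD4 Proliferating" = "CD4T", "Treg" = "CD4T",
    ## cytotoxic T compartment
    "CD8 Naive"   = "CD8T", "CD8 TCM" = "CD8T", "CD8 TEM" = "CD8T",
    "CD8 Proliferating" = "CD8T", "MAIT" = "CD8T", "gdT" = "CD8T",
    ## B compartment
    "B naive"     = "B", "B intermediate" = "B", "B memory" = "B",
    "Plasmablast" = "B", "Plasma" = "B",
    ## NK compartment: includes NKT and CD56 bright/dim clusters
    "NK"          = "NK", "NK CD56bright" = "NK", "NK CD56dim" = "NK",
    "NK Proliferating" = "NK", "NKT" = "NK",
    ## monocyte compartment: classical/non-classical monocytes and DCs
    "CD14 Mono"   = "Monocyte", "CD16 Mono" = "Monocyte",
    "cDC"         = "Monocyte", "cDC1" = "Monocyte", "cDC2" = "Monocyte",
    "pDC"         = "Monocyte", "ASDC" = "Monocyte"
  )
}

#' Parent lineage names
#'
#' @return Character vector of the five parent lineages, in canonical order.
#' @export
parent_lineages <- function() c("Monocyte", "B", "CD4T", "CD8T", "NK")

#' Collapse sub-lineage labels onto the five parent lineages
#'
#' Deterministically maps fine-grained cluster labels to the parent lineage
#' used for pseudobulk differential analysis. Unknown labels raise an error
#' (listing the offending labels) rather than being dropped silently, so that
#' annotation drift between a cohort and the mapping table is surfaced
#' immediately.
#'
#' @param sublineage_label Character vector of sub-lineage labels.
#' @param map Named character vector mapping labels to parent lineages;
#'   defaults to [default_lineage_map()].
#' @return Character vector of parent lineages, same length as the input.
#' @examples
#' collapse_lineage(c("NK CD56bright", "CD14 Mono", "cDC"))
#' @export
collapse_lineage <- function(sublineage_label, map = default_lineage_map()) {
  if (length(sublineage_label) == 0) return(character(0))
  stopifnot(is.character(sublineage_label))
  if (any(is.na(sublineage_label) | !nzchar(sublineage_label))) {
    stop("sub-lineage labels must be non-empty strings")
  }
  bad_target <- setdiff(unique(map), parent_lineages())
  if (length(bad_target)) {
    stop("lineage map targets outside the five parent lineages: ",
         paste(bad_target, collapse = ", "))
  }
  parent <- unname(map[sublineage_label])
  if (anyNA(parent)) {
    offending <- sort(unique(sublineage_label[is.na(parent)]))
    stop("unmapped sub-lineage label(s): ", paste(offending, collapse = ", "))
  }
  parent
}
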