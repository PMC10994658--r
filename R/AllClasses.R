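#' @import methods
#' @importFrom Rcpp sourceCpp
#' @useDynLib spiculeMorph, .registration = TRUE
NULL

#' VoxelVolume: a 3D scalar grid with physical voxel spacing
#'
#' The substrate of all image data in the package. Values live on an
#' (nz, ny, nx) grid; axis order is fixed as (z, y, x), matching
#' stack-of-slices acquisition, and spacing is given in the same order in
#' micrometres per voxel. Voxel indices are 1-based in R; the physical
#' position of voxel (i, j, k) is ((i,j,k) - 1) * spacing (voxel-centre
#' convention; exported coordinate files use the equivalent 0-based form).
#'
#' @slot data 3D numeric/integer/logical array, dims (nz, ny, nx)
#' @slot spacing numeric(3), micrometres per voxel along (z, y, x); all > 0
#' @slot kind one of "grayscale", "binary", "labels"; binary volumes contain
#'   only values 0 and 1
#' @slot meta free-form list of provenance (thresholds, modes, origin)
#' @exportClass VoxelVolume
setClass("VoxelVolume",
         representation(data = "array", spacing = "numeric",
                        kind = "character", meta = "list"),
         prototype(spacing = c(1, 1, 1), kind = "grayscale", meta = list()))

setValidity("VoxelVolume", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3D array (nz, ny, nx)")
  if (any(dim(object@data) < 1L))
    msg <- c(msg, "all dimensions must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    msg <- c(msg, "spacing must be 3 positive finite values (z, y, x)")
  if (!object@kind %in% c("grayscale", "binary", "labels"))
    msg <- c(msg, "kind must be grayscale, binary or labels")
  if (object@kind == "binary" && !all(object@data %in% c(0, 1)))
    msg <- c(msg, "binary volume must contain only 0 and 1")
  if (length(msg)) msg else TRUE
})

#' Construct a VoxelVolume
#'
#' @param data 3D array in (z, y, x) order
#' @param spacing micrometres per voxel along (z, y, x)
#' @param kind "grayscale", "binary" or "labels"
#' @param meta optional provenance list
#' @return a \linkS4class{VoxelVolume}
#' @export
VoxelVolume <- function(data, spacing = c(1, 1, 1), kind = "grayscale",
                        meta = list()) {
  if (is.logical(data)) {
    data <- array(as.integer(data), dim = dim(data))
    if (identical(kind, "grayscale")) kind <- "binary"
  }
  new("VoxelVolume", data = data, spacing = as.numeric(spacing),
      kind = kind, meta = meta)
}

#' LabelField: integer per-spicule labels on a voxel grid
#'
#' A \linkS4class{VoxelVolume} whose values are integer labels, 0 for
#' background and 1..K for individual objects; labels are consecutive and
#' ordered by decreasing component size after segmentation.
#'
#' @exportClass LabelField
setClass("LabelField", contains = "VoxelVolume")

setValidity("LabelField", function(object) {
  msg <- character()
  if (object@kind != "labels")
    msg <- c(msg, "kind must be 'labels'")
  vals <- unique(as.vector(object@data))
  vals <- sort(vals[vals != 0])
  if (length(vals) && !identical(as.integer(vals), seq_len(length(vals))))
    msg <- c(msg, "nonzero labels must be consecutive integers from 1")
  if (length(msg)) msg else TRUE
})

#' SkeletonGraph: a medial skeleton organised into nodes and branches
#'
#' Produced from a thinned mask. Nodes are endpoints (degree-1 voxels) or
#' junctions (26-adjacent clusters of degree >= 3 voxels); branches are
#' maximal degree-2 voxel paths connecting them, each path stepping only
#' between 26-neighbours.
#'
#' @slot voxels integer matrix (n x 3) of 1-based (z, y, x) skeleton voxels
#' @slot nodes data.frame: id, kind ("endpoint"/"junction"), z, y, x
#'   (cluster representative voxel)
#' @slot branches list of lists: id, node_a, node_b, path (m x 3 matrix of
#'   ordered voxels incl. terminal node voxels), closed (logical)
#' @slot spacing numeric(3) micrometres per voxel (z, y, x)
#' @slot meta provenance list
#' @exportClass SkeletonGraph
setClass("SkeletonGraph",
         representation(voxels = "matrix", nodes = "data.frame",
                        branches = "list", spacing = "numeric", meta = "list"))

#' GroupComparison: one named statistical comparison
#'
#' Carries a test statistic (z, t or H), its p-value, tail count, group
#' sizes and an effect estimate (fold change or growth rate) where one is
#' defined.
#'
#' @slot test_name character
#' @slot statistic numeric test statistic
#' @slot p_value numeric in [0, 1]
#' @slot tails 1 or 2
#' @slot group_sizes integer vector
#' @slot effect numeric effect estimate (NA when not applicable)
#' @slot effect_name character, e.g. "fold_change" or "growth_rate_um3_hr"
#' @slot df numeric degrees of freedom (NA for the z test)
#' @exportClass GroupComparison
setClass("GroupComparison",
         representation(test_name = "character", statistic = "numeric",
                        p_value = "numeric", tails = "numeric",
                        group_sizes = "numeric", effect = "numeric",
                        effect_name = "character", df = "numeric"))

setValidity("GroupComparison", function(object) {
  msg <- character()
  if (!is.na(object@p_value) &&
      (object@p_value < 0 || object@p_value > 1))
    msg <- c(msg, "p_value must lie in [0, 1]")
  if (!object@tails %in% c(1, 2))
    msg <- c(msg, "tails must be 1 or 2")
  if (length(msg)) msg else TRUE
})

GroupComparison <- function(test_name, statistic, p_value, tails,
                            group_sizes, effect = NA_real_,
                            effect_name = NA_character_, df = NA_real_) {
  new("GroupComparison", test_name = test_name, statistic = statistic,
      p_value = p_value, tails = tails,
      group_sizes = as.numeric(group_sizes), effect = effect,
      effect_name = effect_name, df = df)
}
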