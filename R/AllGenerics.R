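#' Accessors for voxel volumes and skeleton graphs
#'
#' `voxelData` returns the raw array, `voxelSpacing` the per-axis spacing in
#' micrometres (z, y, x), `voxelKind` the data kind flag, and `voxelMeta`
#' the provenance list.
#'
#' @param x a \linkS4class{VoxelVolume} or \linkS4class{SkeletonGraph}
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setGeneric("voxelSpacing", function(x) standardGeneric("voxelSpacing"))
#' @rdname accessors
#' @export
setGeneric("voxelKind", function(x) standardGeneric("voxelKind"))
#' @rdname accessors
#' @export
setGeneric("voxelMeta", function(x) standardGeneric("voxelMeta"))

#' @rdname accessors
setMethod("voxelData", "VoxelVolume", function(x) x@data)
#' @rdname accessors
setMethod("voxelSpacing", "VoxelVolume", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelSpacing", "SkeletonGraph", function(x) x@spacing)
#' @rdname accessors
setMethod("voxelKind", "VoxelVolume", function(x) x@kind)
#' @rdname accessors
setMethod("voxelMeta", "VoxelVolume", function(x) x@meta)

#' @describeIn accessors grid dimensions (nz, ny, nx)
#' @export
setMethod("dim", "VoxelVolume", function(x) dim(x@data))

setMethod("show", "VoxelVolume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s of class %s: %d x %d x %d voxels (z,y,x), spacing %s um\n",
              object@kind, class(object), d[1], d[2], d[3],
              paste(signif(object@spacing, 4), collapse = " x ")))
  if (object@kind == "labels")
    cat(sprintf("  %d label(s)\n", max(object@data)))
  invisible(NULL)
})

setMethod("show", "SkeletonGraph", function(object) {
  kinds <- table(factor(object@nodes$kind, c("endpoint", "junction")))
  cat(sprintf(
    "SkeletonGraph: %d voxels, %d endpoint(s), %d junction(s), %d branch(es)\n",
    nrow(object@voxels), kinds[["endpoint"]], kinds[["junction"]],
    length(object@branches)))
  invisible(NULL)
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g (%d-tailed), n = %s\n",
              object@test_name, object@statistic, object@p_value,
              as.integer(object@tails),
              paste(object@group_sizes, collapse = "/")))
  if (!is.na(object@effect))
    cat(sprintf("  effect (%s) = %.4f\n", object@effect_name, object@effect))
  invisible(NULL)
})

#' Coerce a GroupComparison to a one-row data.frame
#'
#' @param x a \linkS4class{GroupComparison}
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
as.data.frame.GroupComparison <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  data.frame(test_name = x@test_name, statistic = x@statistic,
             p_value = x@p_value, tails = x@tails,
             df = x@df,
             group_sizes = paste(x@group_sizes, collapse = "/"),
             effect = x@effect, effect_name = x@effect_name,
             stringsAsFactors = FALSE)
}
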