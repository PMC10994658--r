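# Segmentation of grayscale micro-CT volumes into per-spicule label
# fields: automatic (Otsu) or fixed thresholding, connected-component
# labeling with a speckle filter, and an optional seed mask standing in
# for interactive user augmentation.

#' Binarize a grayscale volume
#'
#' A voxel is foreground iff its intensity is >= the threshold. With
#' `method = "otsu"` the threshold is chosen by Otsu's criterion on the
#' intensity histogram; with `method = "fixed"` the supplied `threshold`
#' is used. The chosen threshold is recorded in the result's metadata.
#'
#' @param volume grayscale \linkS4class{VoxelVolume}
#' @param method "otsu" or "fixed"
#' @param threshold numeric threshold, required for `method = "fixed"`
#' @return binary \linkS4class{VoxelVolume}; a warning is emitted if the
#'   result is all background or all foreground
#' @export
binarize <- function(volume, method = c("otsu", "fixed"), threshold = NULL) {
  method <- match.arg(method)
  a <- voxelData(volume)
  t <- if (method == "otsu") otsuThreshold(a) else {
    check(is.numeric(threshold) && length(threshold) == 1 && is.finite(threshold),
          "fixed method needs a finite numeric threshold")
    threshold
  }
  fg <- a >= t
  if (!any(fg)) warning("binarize: all-background result", call. = FALSE)
  if (all(fg)) warning("binarize: all-foreground result", call. = FALSE)
  VoxelVolume(array(as.integer(fg), dim = dim(a)),
              spacing = voxelSpacing(volume), kind = "binary",
              meta = c(volume@meta,
                       list(threshold = t, threshold_method = method)))
}

# Otsu's threshold on arbitrary non-negative intensities; data are mapped
# to [0, 1] and EBImage's histogram implementation does the search. The
# returned cut sits between histogram bins, so `>= t` keeps the upper mode.
otsuThreshold <- function(a, levels = 4096L) {
  v <- as.numeric(a)
  lo <- min(v); hi <- max(v)
  if (hi == lo) return(hi)
  t01 <- EBImage::otsu(array((v - lo) / (hi - lo), dim = c(length(v), 1)),
                       range = c(0, 1), levels = levels)
  lo + t01 * (hi - lo)
}

#' Label connected foreground components
#'
#' Components are found under the requested connectivity, components
#' smaller than `min_voxels` are removed, and the survivors are renumbered
#' 1..K by decreasing voxel count (ties broken by scan order), so label 1
#' is always the largest object.
#'
#' @param binary binary \linkS4class{VoxelVolume}
#' @param connectivity 6, 18 or 26 (default 26 for foreground, the
#'   complement of 6-connected background)
#' @param min_voxels minimum component size in voxels; the default keeps
#'   components of at least 100 um^3 (100 voxels at 1 um isotropic),
#'   scaled by the voxel volume
#' @return a \linkS4class{LabelField}; metadata records per-label voxel
#'   counts
#' @export
labelComponents <- function(binary, connectivity = 26L, min_voxels = NULL) {
  check(voxelKind(binary) == "binary", "input must be a binary volume")
  check(connectivity %in% c(6L, 18L, 26L), "connectivity must be 6, 18 or 26")
  sp <- voxelSpacing(binary)
  if (is.null(min_voxels)) min_voxels <- ceiling(100 / prod(sp))
  d <- dim(binary)
  lab <- .cpp_label(asFlatLogical(voxelData(binary)), d, as.integer(connectivity))
  if (any(lab > 0)) {
    sizes <- tabulate(lab)
    keep <- which(sizes >= min_voxels)
    remap <- integer(length(sizes))
    # decreasing size; ties by original (scan-order) label
    ord <- keep[order(-sizes[keep], keep)]
    remap[ord] <- seq_along(ord)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
    counts <- sizes[ord]
  } else counts <- integer(0)
  new("LabelField",
      data = array(as.integer(lab), dim = d), spacing = sp, kind = "labels",
      meta = c(binary@meta, list(connectivity = as.integer(connectivity),
                                 min_voxels = min_voxels,
                                 label_voxel_counts = counts)))
}

#' Segment spicules from a grayscale volume
#'
#' Pipeline: binarize, optionally keep only components intersecting a
#' user-supplied seed mask (the automated stand-in for interactive
#' segmentation), then label components with the speckle filter.
#'
#' @param gray grayscale \linkS4class{VoxelVolume}
#' @param method,threshold passed to \code{\link{binarize}}
#' @param connectivity,min_voxels passed to \code{\link{labelComponents}}
#' @param seed_mask optional binary mask (array or VoxelVolume); only
#'   components intersecting it are kept
#' @return a \linkS4class{LabelField}; error "no spicules found" when
#'   nothing survives
#' @export
segmentSpicules <- function(gray, method = "otsu", threshold = NULL,
                            connectivity = 26L, min_voxels = NULL,
                            seed_mask = NULL) {
  bin <- withCallingHandlers(
    binarize(gray, method = method, threshold = threshold),
    warning = function(w) invokeRestart("muffleWarning"))
  labels <- labelComponents(bin, connectivity = connectivity,
                            min_voxels = min_voxels)
  if (!is.null(seed_mask)) {
    sm <- if (is(seed_mask, "VoxelVolume")) voxelData(seed_mask) != 0
          else seed_mask != 0
    check(all(dim(sm) == dim(labels)), "seed mask shape must match volume")
    keep <- sort(unique(voxelData(labels)[sm]))
    keep <- keep[keep > 0]
    lab <- voxelData(labels)
    remap <- integer(max(lab, 1))
    remap[keep] <- seq_along(keep)
    pos <- lab > 0L
    lab[pos] <- remap[lab[pos]]
    labels <- new("LabelField", data = array(as.integer(lab), dim = dim(labels)),
                  spacing = voxelSpacing(labels), kind = "labels",
                  meta = c(labels@meta, list(seed_mask_labels_kept = keep)))
  }
  if (max(voxelData(labels)) == 0)
    stop("no spicules found", call. = FALSE)
  labels
}
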