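# Region-based fluorescence quantification: stained-pixel counts per ROI,
# region-to-region signal ratios (skeletogenic vs ectoderm, spicule tip vs
# back) and calcein blob (vesicle) counting.

#' Count stained pixels in a region of interest
#'
#' @param image 2D numeric matrix of intensities
#' @param roi_mask logical/0-1 matrix of the same shape
#' @param threshold finite intensity threshold; a pixel is "stained" iff
#'   intensity >= threshold. Use \code{\link{imageOtsu}} for an automated
#'   default.
#' @return list(stained_px, area_px)
#' @export
countStainedPixels <- function(image, roi_mask, threshold) {
  check(all(dim(image) == dim(roi_mask)), "mask shape must match image")
  check(is.finite(threshold), "threshold must be finite")
  m <- roi_mask != 0
  if (!any(m)) stop("empty ROI", call. = FALSE)
  list(stained_px = sum(image[m] >= threshold), area_px = sum(m))
}

#' Otsu threshold for a 2D fluorescence image
#'
#' @param image 2D numeric matrix
#' @return numeric threshold on the image's intensity scale
#' @export
imageOtsu <- function(image) otsuThreshold(image)

#' Build one region measurement row
#'
#' @param image,roi_mask,threshold as in \code{\link{countStainedPixels}}
#' @param region_name,embryo_id,condition,timepoint_hpf annotations
#' @param blobs optionally also count blobs (logical)
#' @param min_px blob size filter (see \code{\link{countBlobs}})
#' @return one-row data.frame in the RegionMeasurement schema
#' @export
measureRegion <- function(image, roi_mask, threshold, region_name,
                          embryo_id = NA_character_,
                          condition = NA_character_,
                          timepoint_hpf = NA_real_, blobs = FALSE,
                          min_px = 4L) {
  cs <- countStainedPixels(image, roi_mask, threshold)
  data.frame(embryo_id = embryo_id, condition = condition,
             timepoint_hpf = timepoint_hpf, region_name = region_name,
             area_px = cs$area_px, stained_px = cs$stained_px,
             n_blobs = if (blobs)
               countBlobs(image, roi_mask, threshold, min_px) else NA_integer_,
             stringsAsFactors = FALSE)
}

#' Ratio of stained-pixel densities between two regions
#'
#' (stained_a / area_a) / (stained_b / area_b). A zero-stain denominator
#' region makes the ratio undefined; such embryos are meant to be logged
#' and excluded from downstream statistics rather than imputed.
#'
#' @param m_a,m_b one-row region measurements (data.frames or lists with
#'   stained_px and area_px)
#' @return the density ratio
#' @export
regionRatio <- function(m_a, m_b) {
  if (m_b$stained_px == 0)
    stop("undefined ratio: zero stained pixels in denominator region",
         call. = FALSE)
  (m_a$stained_px / m_a$area_px) / (m_b$stained_px / m_b$area_px)
}

#' Tip-to-back stained-signal ratio for one spicule image
#'
#' Specialization of \code{\link{regionRatio}} with the two regions fixed
#' as the growing tip and the back of the spicule.
#'
#' @param image 2D numeric matrix
#' @param tip_roi,back_roi logical masks
#' @param threshold intensity threshold
#' @return the tip/back density ratio
#' @export
tipBackRatio <- function(image, tip_roi, back_roi, threshold) {
  a <- countStainedPixels(image, tip_roi, threshold)
  b <- countStainedPixels(image, back_roi, threshold)
  regionRatio(a, b)
}

#' Count stained blobs (vesicles) in a region of interest
#'
#' Number of 8-connected above-threshold components within the ROI with at
#' least `min_px` pixels.
#'
#' @param image 2D numeric matrix
#' @param roi_mask logical/0-1 matrix
#' @param threshold intensity threshold
#' @param min_px minimum blob size in pixels (default 4)
#' @return integer blob count
#' @export
countBlobs <- function(image, roi_mask, threshold, min_px = 4L) {
  check(all(dim(image) == dim(roi_mask)), "mask shape must match image")
  m <- roi_mask != 0
  if (!any(m)) stop("empty ROI", call. = FALSE)
  fg <- (image >= threshold) & m
  d <- dim(fg)
  # 8-connectivity in 2D == 26-connectivity on a one-slice 3D grid
  lab <- .cpp_label(as.vector(array(fg, dim = c(1, d))), c(1L, d), 26L)
  if (!any(lab > 0)) return(0L)
  sum(tabulate(lab) >= min_px)
}

#' Read a 2D image (TIFF or PNG) as an intensity matrix
#'
#' 16-bit samples map to integers in [0, 65535].
#'
#' @param path image path
#' @return numeric matrix; multi-channel images are reduced to their
#'   first channel
#' @export
readImage2D <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    "tif" = , "tiff" = tiff::readTIFF(path),
    "png" = png::readPNG(path),
    stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(img)) == 3) img <- img[, , 1]
  round(img * 65535)
}
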