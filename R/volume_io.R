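# Reading/writing 3D volumes (multi-page TIFF, minimal NRRD) and tabular
# morphometric records, plus the grayscale pre-processing steps applied to
# reconstructed micro-CT stacks (16-bit conversion, cropping).

recordColumns <- c("spicule_id", "condition", "timepoint_hpf", "volume_um3",
                   "surface_area_um2", "total_length_um", "mean_thickness_um",
                   "n_tips", "n_junctions")

sidecarPath <- function(path) paste0(path, ".json")

#' Read a 3D volume from disk
#'
#' Multi-page TIFF stacks are read one z-slice per page; 16-bit samples are
#' mapped back to integer intensities in [0, 65535]. Voxel spacing is taken
#' from (in order of precedence) the `spacing` argument, a sidecar JSON file
#' `<path>.json` with a `spacing_um` field, or, for NRRD files, the
#' `spacings` header line.
#'
#' @param path file path (.tif/.tiff or .nrrd)
#' @param spacing optional numeric(3) micrometres per voxel (z, y, x)
#' @return a \linkS4class{VoxelVolume}
#' @export
readVolume <- function(path, spacing = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  kind <- NULL
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) < 2)
      stop("non-3D data: TIFF has a single page; a volume needs >= 2 z-slices",
           call. = FALSE)
    if (any(vapply(pages, function(p) length(dim(p)) != 2, TRUE)))
      stop("non-3D data: multi-channel pages are not a scalar volume",
           call. = FALSE)
    nz <- length(pages)
    d <- dim(pages[[1]])
    a <- array(0L, dim = c(nz, d[1], d[2]))
    for (z in seq_len(nz)) a[z, , ] <- as.integer(round(pages[[z]] * 65535))
    sc <- sidecarPath(path)
    if (is.null(spacing) && file.exists(sc)) {
      meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
      spacing <- meta$spacing_um
      kind <- meta$kind
    }
  } else if (ext == "nrrd") {
    nr <- readNRRD(path)
    a <- nr$data
    if (length(dim(a)) != 3) stop("non-3D data in NRRD file", call. = FALSE)
    if (is.null(spacing)) spacing <- nr$spacing
    kind <- nr$kind
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  if (is.null(spacing))
    stop("missing spacing: supply spacing= or a sidecar metadata file",
         call. = FALSE)
  if (!is.null(kind) && !kind %in% c("grayscale", "binary", "labels"))
    kind <- NULL
  if (is.null(kind))
    kind <- if (all(a %in% c(0, 1))) "binary" else "grayscale"
  vol <- VoxelVolume(a, spacing = as.numeric(spacing), kind = kind)
  if (kind == "labels") vol <- as(vol, "LabelField")
  vol
}

#' Write a 3D volume to disk
#'
#' TIFF output is a multi-page 16-bit stack (one page per z-slice) with a
#' sidecar JSON recording spacing and kind; NRRD output stores the raw
#' doubles with spacing in the header, so no sidecar is needed.
#'
#' @param volume a \linkS4class{VoxelVolume}
#' @param path destination (.tif/.tiff or .nrrd)
#' @return the path, invisibly
#' @export
writeVolume <- function(volume, path) {
  ext <- tolower(tools::file_ext(path))
  a <- voxelData(volume)
  if (ext %in% c("tif", "tiff")) {
    if (any(a < 0) || any(a > 65535))
      stop("TIFF output requires values in [0, 65535]", call. = FALSE)
    pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
    jsonlite::write_json(list(spacing_um = voxelSpacing(volume),
                              kind = voxelKind(volume)),
                         sidecarPath(path), auto_unbox = TRUE, digits = NA)
  } else if (ext == "nrrd") {
    writeNRRD(volume, path)
  } else stop("unsupported volume format: .", ext, call. = FALSE)
  invisible(path)
}

# Minimal NRRD support (raw and ascii encodings), spacing from the header.
readNRRD <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character()
  repeat {
    line <- readLines(con, n = 1, warn = FALSE)
    if (!length(line) || !nzchar(line)) break
    header <- c(header, line)
  }
  fields <- list()
  for (h in header[-1]) {
    if (startsWith(h, "#")) next
    kv <- regmatches(h, regexpr(":", h), invert = TRUE)[[1]]
    if (length(kv) == 2)
      fields[[tolower(trimws(kv[1]))]] <- trimws(sub("^=", "", kv[2]))
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  type <- fields$type
  enc <- tolower(fields$encoding)
  n <- prod(sizes)
  if (enc == "raw") {
    data <- switch(type,
      "double" = readBin(con, "double", n, size = 8, endian = "little"),
      "float" = readBin(con, "double", n, size = 4, endian = "little"),
      "unsigned short" = , "uint16" = readBin(con, "integer", n, size = 2,
                                              signed = FALSE, endian = "little"),
      "unsigned char" = , "uint8" = as.integer(readBin(con, "raw", n)),
      stop("unsupported NRRD type: ", type, call. = FALSE))
  } else if (enc %in% c("ascii", "text", "txt")) {
    data <- scan(con, what = numeric(), n = n, quiet = TRUE)
  } else stop("unsupported NRRD encoding: ", enc, call. = FALSE)
  spacing <- if (!is.null(fields$spacings))
    rev(as.numeric(strsplit(fields$spacings, "\\s+")[[1]])) else NULL
  # NRRD sizes are fastest-first; our arrays are (z, y, x) with z fastest,
  # so we write sizes as (nz, ny, nx) and spacings in x y z order.
  list(data = array(data, dim = sizes), spacing = spacing,
       kind = fields[["kind"]])
}

writeNRRD <- function(volume, path) {
  a <- voxelData(volume)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# spiculeMorph volume",
           "type: double",
           "dimension: 3",
           sprintf("sizes: %d %d %d", dim(a)[1], dim(a)[2], dim(a)[3]),
           sprintf("spacings: %.12g %.12g %.12g",
                   voxelSpacing(volume)[3], voxelSpacing(volume)[2],
                   voxelSpacing(volume)[1]),
           sprintf("kind: %s", voxelKind(volume)),
           "encoding: raw",
           "endian: little",
           "")
  writeLines(hdr, con, sep = "\n")
  writeBin(as.numeric(as.vector(a)), con, size = 8, endian = "little")
  invisible(path)
}

#' Convert a grayscale volume to 16-bit
#'
#' Linear global rescale of [min, max] to [0, 65535], rounded half up; a
#' constant volume maps to all zeros.
#'
#' @param volume grayscale \linkS4class{VoxelVolume} with finite values
#' @return 16-bit grayscale \linkS4class{VoxelVolume}
#' @export
convertTo16bit <- function(volume) {
  a <- voxelData(volume)
  if (any(!is.finite(a))) stop("non-finite values in volume", call. = FALSE)
  lo <- min(a); hi <- max(a)
  out <- if (hi == lo) array(0, dim = dim(a))
         else floor((a - lo) / (hi - lo) * 65535 + 0.5)
  VoxelVolume(out, spacing = voxelSpacing(volume), kind = "grayscale",
              meta = c(volume@meta, list(rescaled_from = c(lo, hi))))
}

#' Crop a volume to its foreground bounding box
#'
#' @param volume a \linkS4class{VoxelVolume}
#' @param threshold_or_mask numeric threshold (foreground = values >=
#'   threshold) or a binary mask (array or VoxelVolume) of the same shape
#' @param pad_voxels margin added to the tight box, clipped to the grid
#' @return cropped \linkS4class{VoxelVolume}, spacing preserved
#' @export
cropToForeground <- function(volume, threshold_or_mask, pad_voxels = 0L) {
  check(pad_voxels >= 0, "pad_voxels must be >= 0")
  a <- voxelData(volume)
  fg <- if (is(threshold_or_mask, "VoxelVolume")) voxelData(threshold_or_mask) != 0
        else if (is.array(threshold_or_mask)) threshold_or_mask != 0
        else a >= threshold_or_mask
  if (!any(fg)) stop("empty foreground: nothing to crop to", call. = FALSE)
  ix <- which(fg, arr.ind = TRUE)
  lo <- unname(pmax(apply(ix, 2, min) - pad_voxels, 1L))
  hi <- unname(pmin(apply(ix, 2, max) + pad_voxels, dim(a)))
  out <- a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  vol <- VoxelVolume(array(out, dim = hi - lo + 1L),
                     spacing = voxelSpacing(volume), kind = voxelKind(volume),
                     meta = c(volume@meta, list(crop_offset = lo - 1L)))
  if (voxelKind(volume) == "labels") vol <- as(vol, "LabelField")
  vol
}

#' Write / read per-spicule morphometric records
#'
#' CSV with the fixed column schema: spicule_id, condition, timepoint_hpf,
#' volume_um3, surface_area_um2, total_length_um, mean_thickness_um,
#' n_tips, n_junctions. Extra columns round-trip unchanged.
#'
#' @param records data.frame of morphometric records
#' @param path CSV path
#' @return `writeRecords` the path invisibly; `readRecords` the data.frame
#' @export
writeRecords <- function(records, path) {
  missing <- setdiff(recordColumns, names(records))
  if (length(missing))
    stop("records are missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRecords
#' @export
readRecords <- function(path) {
  if (!file.exists(path)) stop("unreadable file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(recordColumns, names(df))
  if (length(missing))
    stop("records file is missing required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df
}
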