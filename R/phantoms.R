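# Synthetic phantoms with analytic ground truth.
#
# Spicule rods are idealized as capsules (cylinders with hemispherical
# caps). The medial axis of a capsule is exactly its centreline segment,
# which makes centreline length, local radius and topology exact ground
# truths for the skeleton-based measurements. Voxelization is by the
# voxel-centre rule: a voxel is foreground iff its centre lies within the
# capsule radius of the segment; partial-volume effects are emulated only
# by the grayscale renderer.

#' A capsule rod primitive
#'
#' @param p0,p1 numeric(3) segment ends in micrometres, (z, y, x) order
#' @param radius capsule radius in micrometres
#' @return a `RodPrimitive` list
#' @export
rodPrimitive <- function(p0, p1, radius) {
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  check(length(p0) == 3 && length(p1) == 3, "p0 and p1 must be length-3 (z,y,x)")
  check(radius > 0, "radius must be > 0")
  check(sqrt(sum((p1 - p0)^2)) > 0, "p0 and p1 must differ")
  structure(list(p0 = p0, p1 = p1, radius = radius), class = "RodPrimitive")
}

#' A phantom specification
#'
#' @param primitives list of \code{\link{rodPrimitive}} capsules
#' @param spacing micrometres per voxel (z, y, x)
#' @param pad background margin in voxels around the primitive bounding box
#' @param seed integer seed (carried into stochastic renderers)
#' @return a `PhantomSpec` list
#' @export
phantomSpec <- function(primitives, spacing = c(1, 1, 1), pad = 4, seed = 1L) {
  check(length(primitives) >= 1, "at least one primitive required")
  check(all(spacing > 0), "spacing must be positive per axis")
  check(pad >= 1, "pad must be >= 1")
  structure(list(primitives = primitives, spacing = as.numeric(spacing),
                 pad = as.integer(pad), seed = as.integer(seed)),
            class = "PhantomSpec")
}

capsuleVolume <- function(r, L) pi * r^2 * L + 4 / 3 * pi * r^3
capsuleArea <- function(r, L) 2 * pi * r * L + 4 * pi * r^2
segLength <- function(p0, p1) sqrt(sum((p1 - p0)^2))

# Voxelize a union of capsules on a common grid. Returns a binary
# VoxelVolume whose meta carries the physical origin of voxel (1,1,1).
voxelizeCapsules <- function(primitives, spacing, pad) {
  r <- vapply(primitives, function(p) p$radius, 0)
  if (any(r < max(spacing) / 2))
    stop("under-resolved phantom: radius < max(spacing)/2, foreground may disconnect",
         call. = FALSE)
  pts <- do.call(rbind, lapply(primitives, function(p) rbind(p$p0, p$p1)))
  rmax <- max(r)
  lo <- apply(pts, 2, min) - rmax - pad * spacing
  hi <- apply(pts, 2, max) + rmax + pad * spacing
  n <- pmax(1L, as.integer(floor((hi - lo) / spacing)) + 1L)
  coords <- lapply(1:3, function(a) lo[a] + (seq_len(n[a]) - 1) * spacing[a])
  Z <- array(rep(coords[[1]], times = n[2] * n[3]), dim = n)
  Y <- array(rep(rep(coords[[2]], each = n[1]), times = n[3]), dim = n)
  X <- array(rep(coords[[3]], each = n[1] * n[2]), dim = n)
  fg <- array(FALSE, dim = n)
  for (p in primitives) {
    ab <- p$p1 - p$p0
    len2 <- sum(ab^2)
    apz <- Z - p$p0[1]; apy <- Y - p$p0[2]; apx <- X - p$p0[3]
    t <- (apz * ab[1] + apy * ab[2] + apx * ab[3]) / len2
    t[t < 0] <- 0; t[t > 1] <- 1
    d2 <- (apz - t * ab[1])^2 + (apy - t * ab[2])^2 + (apx - t * ab[3])^2
    fg <- fg | (d2 <= p$radius^2)
  }
  VoxelVolume(array(as.integer(fg), dim = n), spacing = spacing,
              kind = "binary", meta = list(origin_um = as.numeric(lo)))
}

#' Generate a single capsule-rod phantom
#'
#' @param spec a \code{\link{phantomSpec}} holding exactly one primitive
#' @return list with `volume` (binary \linkS4class{VoxelVolume}) and
#'   `truth` (centreline length, radius, analytic capsule volume and
#'   area, expected tip/junction counts, rod endpoints, grid origin)
#' @export
makeRodPhantom <- function(spec) {
  check(inherits(spec, "PhantomSpec") && length(spec$primitives) == 1,
        "spec must hold exactly one primitive")
  p <- spec$primitives[[1]]
  vol <- voxelizeCapsules(spec$primitives, spec$spacing, spec$pad)
  L <- segLength(p$p0, p$p1)
  truth <- list(total_centerline_length_um = L,
                radius_um = p$radius,
                analytic_volume_um3 = capsuleVolume(p$radius, L),
                analytic_area_um2 = capsuleArea(p$radius, L),
                expected_tips = 2L, expected_junctions = 0L,
                ends_um = rbind(p$p0, p$p1),
                origin_um = vol@meta$origin_um)
  list(volume = vol, truth = truth)
}

#' Generate a triradiate phantom (three arms meeting at one junction)
#'
#' @param center numeric(3) junction position in micrometres (z, y, x)
#' @param directions 3 x 3 matrix, one unit-lengthable direction per row
#' @param lengths numeric(3) arm lengths in micrometres
#' @param radius capsule radius in micrometres
#' @param spacing,pad grid parameters as in \code{\link{phantomSpec}}
#' @return list(volume, truth) as in \code{\link{makeRodPhantom}}, with
#'   expected 3 tips and 1 junction at `center`
#' @export
makeTriradiatePhantom <- function(center, directions, lengths, radius,
                                  spacing = c(1, 1, 1), pad = 4) {
  center <- as.numeric(center)
  directions <- as.matrix(directions)
  check(nrow(directions) == 3 && ncol(directions) == 3,
        "directions must be a 3 x 3 matrix (one per arm)")
  check(length(lengths) == 3 && all(lengths > 0), "three positive arm lengths required")
  dn <- directions / sqrt(rowSums(directions^2))
  for (i in 1:2) for (j in (i + 1):3)
    check(abs(sum(dn[i, ] * dn[j, ])) < 1 - 1e-9,
          "arm directions must be pairwise non-parallel")
  prim <- lapply(1:3, function(i)
    rodPrimitive(center, center + lengths[i] * dn[i, ], radius))
  vol <- voxelizeCapsules(prim, spacing, pad)
  truth <- list(total_centerline_length_um = sum(lengths),
                radius_um = radius,
                analytic_volume_um3 = sum(vapply(lengths, function(L)
                  capsuleVolume(radius, L), 0)),
                expected_tips = 3L, expected_junctions = 1L,
                junction_um = center,
                tips_um = t(vapply(1:3, function(i) center + lengths[i] * dn[i, ],
                                   numeric(3))),
                origin_um = vol@meta$origin_um)
  list(volume = vol, truth = truth)
}

#' Generate a branched-rod phantom (tip splitting or back branching)
#'
#' A side branch is attached to a base rod at the fractional position
#' `branch_fraction` along its centreline: a fraction of 1 emulates tip
#' splitting, fractions well below 1 emulate ectopic "dripping" at the
#' back of the rod.
#'
#' At exactly `branch_fraction = 1` the branch continues from the base
#' endpoint, so the union is a bent path: the ground truth then records 2
#' tips and no junction. A morphological tip split needs the junction a
#' short, resolvable distance back from the end (e.g. fraction 0.9 on a
#' thin rod), leaving a terminal stub longer than the spur-pruning scale
#' of about three local radii.
#'
#' @param base a \code{\link{rodPrimitive}}
#' @param branch_fraction position of the branch point in (0, 1]
#' @param branch_direction numeric(3) branch direction (z, y, x)
#' @param branch_length branch centreline length in micrometres
#' @param spacing,pad grid parameters
#' @return list(volume, truth); truth records the junction position, its
#'   arc-length position along the base and the distance to the nearest
#'   base endpoint, so tip splitting and back branching can be told apart
#' @export
makeBranchedPhantom <- function(base, branch_fraction, branch_direction,
                                branch_length, spacing = c(1, 1, 1), pad = 4) {
  check(inherits(base, "RodPrimitive"), "base must be a rodPrimitive")
  check(branch_fraction > 0 && branch_fraction <= 1,
        "branch_fraction must be in (0, 1]")
  if (branch_length < 2 * base$radius)
    stop("unresolvable branch: branch_length < 2 * radius", call. = FALSE)
  d <- as.numeric(branch_direction)
  d <- d / sqrt(sum(d^2))
  L <- segLength(base$p0, base$p1)
  q <- base$p0 + branch_fraction * (base$p1 - base$p0)
  prim <- list(base, rodPrimitive(q, q + branch_length * d, base$radius))
  vol <- voxelizeCapsules(prim, spacing, pad)
  bend <- branch_fraction == 1
  truth <- list(total_centerline_length_um = L + branch_length,
                radius_um = base$radius,
                analytic_volume_um3 = capsuleVolume(base$radius, L) +
                  capsuleVolume(base$radius, branch_length),
                expected_tips = if (bend) 2L else 3L,
                expected_junctions = if (bend) 0L else 1L,
                junction_um = q,
                junction_arc_um = branch_fraction * L,
                junction_to_nearest_end_um = min(branch_fraction,
                                                 1 - branch_fraction) * L,
                origin_um = vol@meta$origin_um)
  list(volume = vol, truth = truth)
}

#' Render a binary phantom as a noisy 16-bit grayscale volume
#'
#' Emulates a reconstructed micro-CT scan: the label map is mapped to
#' foreground/background mean intensities, blurred with a Gaussian
#' (partial-volume emulation) and perturbed with Gaussian noise, then
#' clipped and rounded to the 16-bit range.
#'
#' @param binary binary \linkS4class{VoxelVolume}
#' @param fg_mean,bg_mean mean intensities; `fg_mean > bg_mean >= 0`
#' @param blur_sigma Gaussian sigma in voxels (0 disables)
#' @param noise_sd additive Gaussian noise s.d. (0 disables)
#' @param seed integer seed; identical seeds give identical volumes
#' @return grayscale \linkS4class{VoxelVolume} with values in [0, 65535]
#' @export
renderGrayscale <- function(binary, fg_mean = 40000, bg_mean = 10000,
                            blur_sigma = 0.5, noise_sd = 2000, seed = 1L) {
  check(voxelKind(binary) == "binary", "input must be a binary volume")
  check(fg_mean > bg_mean && bg_mean >= 0, "need fg_mean > bg_mean >= 0")
  check(noise_sd >= 0, "noise_sd must be >= 0")
  d <- dim(binary)
  img <- bg_mean + (fg_mean - bg_mean) * as.numeric(as.vector(voxelData(binary)))
  if (blur_sigma > 0)
    img <- .cpp_gauss3d(img, d, rep(blur_sigma, 3))
  if (noise_sd > 0)
    img <- img + withSeed(seed, stats::rnorm(length(img), 0, noise_sd))
  img <- round(pmin(pmax(img, 0), 65535))
  VoxelVolume(array(img, dim = d), spacing = voxelSpacing(binary),
              kind = "grayscale",
              meta = c(binary@meta, list(fg_mean = fg_mean, bg_mean = bg_mean,
                                         blur_sigma = blur_sigma,
                                         noise_sd = noise_sd, seed = seed)))
}

#' Specification of a simulated two-condition, two-timepoint cohort
#'
#' Defaults encode the micro-CT study design this package targets: a
#' control and a ROCK-inhibited condition sampled at 48 and 72 hpf, with
#' mean spicule volumes chosen so the control grows at 325.5 um^3/hr and
#' the inhibited condition at 119.8 um^3/hr between the two timepoints,
#' a 2.5-fold control/inhibited volume ratio at 48 hpf, 44 spicules per
#' group and a 20% coefficient of variation. Ectopic branching is far more
#' frequent under inhibition.
#'
#' @param n_per_group spicules per condition x timepoint group (>= 2);
#'   either one count for all groups or a 2 x 2 matrix (rows = conditions,
#'   cols = timepoints) mirroring the unequal group sizes of a real
#'   dissection series
#' @param conditions two condition labels
#' @param timepoints_hpf two timepoints, hours post fertilization
#' @param mean_volume_um3 2 x 2 matrix of group mean volumes
#'   (rows = conditions, cols = timepoints)
#' @param volume_cv coefficient of variation of per-spicule volume
#' @param branch_probability named per-condition probability of an
#'   ectopically branched spicule
#' @param radius_um capsule radius held fixed within the cohort, so
#'   thickness ground truth is constant
#' @param spacing voxel spacing for rendered phantoms; the default is the
#'   0.65 um isotropic voxel size of synchrotron micro-CT scans
#' @param seed master integer seed; per-phantom sub-streams are derived
#'   deterministically from it
#' @return a `CohortSpec` list
#' @export
cohortSpec <- function(n_per_group = 44L,
                       conditions = c("control", "ROCK-inhibited"),
                       timepoints_hpf = c(48, 72),
                       mean_volume_um3 = NULL,
                       volume_cv = 0.2,
                       branch_probability = c(0.05, 0.6),
                       radius_um = 3,
                       spacing = c(0.65, 0.65, 0.65),
                       seed = 1L) {
  if (length(n_per_group) == 1) n_per_group <- matrix(n_per_group, 2, 2)
  n_per_group <- as.matrix(n_per_group)
  check(all(dim(n_per_group) == c(2, 2)) && all(n_per_group >= 2),
        "n_per_group must be >= 2 (scalar or 2 x 2 matrix)")
  check(length(conditions) == 2, "exactly two conditions")
  check(length(timepoints_hpf) == 2 && diff(timepoints_hpf) > 0,
        "two increasing timepoints required")
  check(volume_cv >= 0, "volume_cv must be >= 0")
  check(all(branch_probability >= 0 & branch_probability <= 1),
        "branch probabilities must lie in [0, 1]")
  if (is.null(mean_volume_um3)) {
    dt <- diff(timepoints_hpf)
    mean_volume_um3 <- rbind(c(5000, 5000 + 325.5 * dt),
                             c(2000, 2000 + 119.8 * dt))
  }
  mean_volume_um3 <- as.matrix(mean_volume_um3)
  check(all(dim(mean_volume_um3) == c(2, 2)) && all(mean_volume_um3 > 0),
        "mean_volume_um3 must be a positive 2 x 2 matrix")
  dimnames(mean_volume_um3) <- list(conditions, as.character(timepoints_hpf))
  dimnames(n_per_group) <- list(conditions, as.character(timepoints_hpf))
  names(branch_probability) <- conditions
  structure(list(n_per_group = matrix(as.integer(n_per_group), 2, 2,
                                      dimnames = dimnames(n_per_group)),
                 conditions = conditions,
                 timepoints_hpf = as.numeric(timepoints_hpf),
                 mean_volume_um3 = mean_volume_um3,
                 volume_cv = volume_cv,
                 branch_probability = branch_probability,
                 radius_um = radius_um, spacing = as.numeric(spacing),
                 seed = as.integer(seed)),
            class = "CohortSpec")
}

#' Simulate a spicule cohort with per-spicule ground truth
#'
#' Per-spicule volumes are drawn around their group mean at the requested
#' coefficient of variation; volume variation is realised by scaling rod
#' length at fixed radius. Branched phantoms (tip split or back branch)
#' are inserted with the per-condition probability.
#'
#' @param spec a \code{\link{cohortSpec}}
#' @param render if TRUE, binary voxel phantoms are generated for each
#'   spicule; if FALSE only the analytic truth table is produced
#' @return list with `phantoms` (list of list(volume, truth), or NULL) and
#'   `truth` (data.frame in the morphometric record schema)
#' @export
makeCohort <- function(spec, render = TRUE) {
  check(inherits(spec, "CohortSpec"), "spec must be a cohortSpec")
  r <- spec$radius_um
  rows <- list(); phantoms <- if (render) list() else NULL
  idx <- 0L
  for (cond in spec$conditions) for (tp in spec$timepoints_hpf) {
    mu <- spec$mean_volume_um3[cond, as.character(tp)]
    for (i in seq_len(spec$n_per_group[cond, as.character(tp)])) {
      idx <- idx + 1L
      ss <- subSeed(spec$seed, idx)
      draw <- withSeed(ss, {
        v <- stats::rnorm(1, mu, spec$volume_cv * mu)
        b <- stats::runif(1) < spec$branch_probability[[cond]]
        f <- stats::runif(1, 0.3, 0.8)
        list(v = v, b = b, f = f)
      })
      v <- max(draw$v, capsuleVolume(r, 6 * r))  # keep rods resolvable
      Ltot <- (v - 4 / 3 * pi * r^3) / (pi * r^2)
      branched <- draw$b
      id <- sprintf("%s_%ghpf_%03d", gsub("[^A-Za-z0-9]+", "_", cond), tp, i)
      rows[[idx]] <- data.frame(
        spicule_id = id, condition = cond, timepoint_hpf = tp,
        volume_um3 = v, surface_area_um2 = capsuleArea(r, Ltot),
        total_length_um = Ltot, mean_thickness_um = 2 * r,
        n_tips = if (branched) 3L else 2L,
        n_junctions = if (branched) 1L else 0L,
        stringsAsFactors = FALSE)
      if (render) {
        ph <- if (branched) {
          Lb <- 0.75 * Ltot
          Lbr <- max(0.25 * Ltot, 2.5 * r)
          base <- rodPrimitive(c(0, 0, 0), c(0, 0, Lb), r)
          makeBranchedPhantom(base, draw$f, c(0, 1, 0), Lbr,
                              spacing = spec$spacing)
        } else {
          makeRodPhantom(phantomSpec(list(
            rodPrimitive(c(0, 0, 0), c(0, 0, Ltot), r)),
            spacing = spec$spacing, seed = ss))
        }
        ph$truth$spicule_id <- id
        phantoms[[idx]] <- ph
      }
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  list(phantoms = phantoms, truth = truth, spec = spec)
}

#' Generate a cohort of per-embryo fluorescence fixtures
#'
#' Emulates an immunostaining experiment: each embryo gets its own 2D
#' fixture whose per-region stained-pixel densities are jittered
#' log-normally around the requested values (multiplicative biological
#' variability between embryos).
#'
#' @param n_embryos number of embryos (the study typically measured >= 33
#'   per condition)
#' @param densities named mean stained-pixel fractions per region
#' @param jitter_cv log-normal coefficient of variation of the per-embryo
#'   densities
#' @param seed master seed; one sub-stream per embryo
#' @return list of fixtures as returned by \code{\link{makeFluorFixture}}
#' @export
makeFluorCohort <- function(n_embryos = 33L,
                            densities = c(skeletogenic = 0.3, ectoderm = 0.1),
                            jitter_cv = 0.1, seed = 1L) {
  check(n_embryos >= 2, "need at least two embryos")
  lapply(seq_len(n_embryos), function(i) {
    ss <- subSeed(seed, i)
    d <- withSeed(ss, {
      f <- exp(stats::rnorm(length(densities), -jitter_cv^2 / 2, jitter_cv))
      pmin(pmax(densities * f, 0), 1)
    })
    makeFluorFixture(densities = d, seed = subSeed(ss, 1))
  })
}

#' Generate a 2D fluorescence fixture with exact staining ground truth
#'
#' Within each named region mask, an exact fraction of pixels is raised to
#' the stain intensity; optionally, non-overlapping circular blobs
#' (emulating calcein-stained vesicles) are stamped into one region. The
#' returned truth table records the exact stained-pixel and blob counts.
#'
#' @param shape image dimensions c(ny, nx) in pixels
#' @param regions named list of logical masks (must be pairwise disjoint);
#'   by default two side-by-side square regions named "skeletogenic" and
#'   "ectoderm"
#' @param densities named fractions in [0, 1] of stained pixels per region
#' @param blobs optional list(region =, n =, radius =) of disks to place
#' @param stain_value,bg_value intensities for stained and background pixels
#' @param seed integer seed
#' @return list(image, masks, truth, threshold); `truth` has one row per
#'   region with area_px, stained_px, n_blobs
#' @export
makeFluorFixture <- function(shape = c(128, 128), regions = NULL,
                             densities = c(skeletogenic = 0.3, ectoderm = 0.1),
                             blobs = NULL, stain_value = 40000,
                             bg_value = 5000, seed = 1L) {
  ny <- shape[1]; nx <- shape[2]
  if (is.null(regions)) {
    side <- min(40, floor(min(ny, nx / 2) * 0.8))
    mk <- function(x0) {
      m <- matrix(FALSE, ny, nx)
      m[seq_len(side) + 4, seq_len(side) + x0] <- TRUE
      m
    }
    regions <- list(skeletogenic = mk(4), ectoderm = mk(floor(nx / 2) + 4))
    names(regions) <- names(densities)[1:2]
  }
  check(all(vapply(regions, function(m) all(dim(m) == c(ny, nx)), TRUE)),
        "all region masks must match the image shape")
  overlap <- Reduce(`+`, lapply(regions, function(m) m * 1L))
  check(max(overlap) <= 1, "region masks must be disjoint")
  check(all(densities >= 0 & densities <= 1), "densities must lie in [0, 1]")
  check(all(names(densities) %in% names(regions)),
        "density names must match region names")

  img <- matrix(bg_value, ny, nx)
  withSeed(seed, {
    for (rg in names(densities)) {
      pix <- which(regions[[rg]])
      k <- round(densities[[rg]] * length(pix))
      if (k > 0) img[sample(pix, k)] <- stain_value
    }
    if (!is.null(blobs)) {
      m <- regions[[blobs$region]]
      rr <- blobs$radius
      centers <- matrix(numeric(0), 0, 2)
      tries <- 0L
      while (nrow(centers) < blobs$n) {
        tries <- tries + 1L
        if (tries > 200L * blobs$n)
          stop("blob placement impossible in region area", call. = FALSE)
        cy <- sample(ny, 1); cx <- sample(nx, 1)
        # disk fully inside region
        ys <- (cy - rr):(cy + rr); xs <- (cx - rr):(cx + rr)
        if (min(ys) < 1 || min(xs) < 1 || max(ys) > ny || max(xs) > nx) next
        disk <- outer(ys - cy, xs - cx, function(a, b) a^2 + b^2 <= rr^2)
        if (!all(m[cbind(rep(ys, times = length(xs))[disk],
                         rep(xs, each = length(ys))[disk])])) next
        if (nrow(centers) &&
            any((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2 <= (2 * rr + 2)^2))
          next
        img[cbind(rep(ys, times = length(xs))[disk],
                  rep(xs, each = length(ys))[disk])] <- stain_value
        centers <- rbind(centers, c(cy, cx))
      }
    }
  })
  threshold <- (bg_value + stain_value) / 2
  truth <- do.call(rbind, lapply(names(regions), function(rg) {
    m <- regions[[rg]]
    data.frame(region = rg, area_px = sum(m),
               stained_px = sum(img >= threshold & m),
               n_blobs = if (!is.null(blobs) && identical(blobs$region, rg))
                 as.integer(blobs$n) else 0L,
               stringsAsFactors = FALSE)
  }))
  list(image = img, masks = regions, truth = truth, threshold = threshold)
}
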