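# Morphometric core: volume, surface area, EDT, skeleton, graph,
# pruning, lengths, thickness, topology.

test_that("voxel-count volume scales with voxel size", {
  cube <- labVol(array(1L, c(10, 10, 10)))
  expect_equal(computeVolume(cube, 1), 1000)
  cube065 <- labVol(array(1L, c(10, 10, 10)), spacing = rep(0.65, 3))
  expect_equal(computeVolume(cube065, 1), 1000 * 0.65^3)
  expect_error(computeVolume(cube, 7), "unknown id")
})

test_that("surface area: exact faces for a cube, mesh accuracy for a ball", {
  cube <- labVol(array(1L, c(10, 10, 10)))
  expect_equal(computeSurfaceArea(cube, 1, method = "voxel_face"), 600)
  ball <- labVol(digitBall(10))
  a <- computeSurfaceArea(ball, 1, method = "mesh")
  expect_lt(abs(a - 4 * pi * 100) / (4 * pi * 100), 0.05)
  # voxel-face counting overestimates the smooth sphere
  expect_gt(computeSurfaceArea(ball, 1, method = "voxel_face"), a)
})

test_that("surface area is unchanged under 90-degree grid rotations", {
  ph <- rodPhantomFixture(L = 20, r = 3)
  a <- voxelData(ph$volume)
  areas <- vapply(list(a, aperm(a, c(2, 1, 3)), aperm(a, c(3, 2, 1))),
                  function(x) computeSurfaceArea(labVol(x), 1), 0)
  expect_equal(areas[2], areas[1], tolerance = 1e-9)
  expect_equal(areas[3], areas[1], tolerance = 1e-9)
})

test_that("EDT handles the canonical small cases", {
  a <- array(0L, c(3, 3, 3)); a[2, 2, 2] <- 1L
  expect_equal(voxelData(euclideanDistanceTransform(binVol(a)))[2, 2, 2], 1.0)
  b <- array(1L, c(5, 5, 5))   # borders are implicit background
  expect_equal(voxelData(euclideanDistanceTransform(binVol(b)))[3, 3, 3], 3.0)
})

test_that("EDT matches the brute-force oracle exactly on random volumes", {
  set.seed(42)
  for (i in 1:25) {
    a <- array(as.integer(stats::runif(12^3) < stats::runif(1, 0.2, 0.8)),
               dim = c(12, 12, 12))
    sp <- if (i %% 5 == 0) c(0.5, 0.65, 1.0) else c(1, 1, 1)
    got <- voxelData(euclideanDistanceTransform(binVol(a, sp), sp))
    expect_equal(got, bruteEDT(a, sp), tolerance = 1e-12)
  }
})

test_that("skeletonization preserves trivial inputs and component counts", {
  a <- array(0L, c(3, 3, 3)); a[2, 2, 2] <- 1L
  expect_identical(voxelData(skeletonize3d(binVol(a))), a)
  empty <- array(0L, c(3, 3, 3))
  expect_true(all(voxelData(skeletonize3d(binVol(empty))) == 0))
  # two disjoint rods stay two components
  b <- array(0L, c(9, 20, 40))
  b[3, 4 + 0:2, 4:36] <- 1L; b[7, 14 + 0:2, 4:36] <- 1L
  sk <- skeletonize3d(binVol(b))
  expect_identical(max(voxelData(labelComponents(sk, 26, 1))), 2L)
})

test_that("a straight capsule thins to a single path of near-true extent", {
  ph <- rodPhantomFixture(L = 50, r = 3)
  g <- skeletonGraph(ph$volume)
  tj <- countTipsJunctions(g)
  expect_identical(unname(tj["n_tips"]), 2L)
  expect_identical(unname(tj["n_junctions"]), 0L)
  xs <- g@voxels[, "x"]
  extent <- (max(xs) - min(xs)) * voxelSpacing(ph$volume)[3]
  # thinning may stop up to r short of each medial end, or overshoot the
  # cap centre by about one voxel step
  expect_gte(extent, 50 - 2 * 3)
  expect_lte(extent, 50 + 2 * sqrt(3))
})

test_that("triradiate phantoms thin to exactly three tips after pruning", {
  tri <- makeTriradiatePhantom(c(0, 0, 0),
                               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                               c(50, 50, 50), 3)
  tj <- countTipsJunctions(skeletonGraph(tri$volume))
  expect_identical(unname(tj["n_tips"]), 3L)
  expect_identical(unname(tj["n_junctions"]), 1L)
})

test_that("skeleton graphs organise paths, junction clusters and reject thick masks", {
  # 11 collinear voxels
  a <- array(0L, c(3, 3, 13)); a[2, 2, 2:12] <- 1L
  g <- buildSkeletonGraph(binVol(a))
  expect_identical(nrow(g@nodes), 2L)
  expect_true(all(g@nodes$kind == "endpoint"))
  expect_length(g@branches, 1)
  expect_identical(nrow(g@branches[[1]]$path), 11L)
  # Y of three 10-voxel arms
  y <- array(0L, c(3, 23, 23))
  y[2, 12, 2:12] <- 1L          # arm along x up to centre (12,12)
  y[2, 12:22, 12] <- 1L         # arm along y
  y[cbind(2, 12 - 0:10, 12 + 0:10)] <- 1L  # diagonal arm
  gy <- buildSkeletonGraph(binVol(y))
  tj <- countTipsJunctions(gy)
  expect_identical(unname(tj["n_tips"]), 3L)
  expect_identical(unname(tj["n_junctions"]), 1L)
  expect_length(gy@branches, 3)
  # two 26-adjacent degree-3 voxels merge into one junction node
  tt <- array(0L, c(3, 9, 9))
  tt[2, 5, 2:8] <- 1L; tt[2, 2:4, 4] <- 1L; tt[2, 6:8, 5] <- 1L
  gt <- buildSkeletonGraph(binVol(tt))
  expect_identical(sum(gt@nodes$kind == "junction"), 1L)
  expect_identical(sum(gt@nodes$kind == "endpoint"), 4L)
  # solid blocks are not skeletons
  blk <- array(1L, c(2, 2, 2))
  expect_error(buildSkeletonGraph(binVol(blk)), "not a thinned mask")
})

test_that("isolated cycles yield one anchor node and one closed branch", {
  a <- array(0L, c(3, 9, 9))
  ring <- rbind(c(2, 5), c(3, 4), c(4, 3), c(5, 2), c(6, 3), c(7, 4),
                c(8, 5), c(7, 6), c(6, 7), c(5, 8), c(4, 7), c(3, 6))
  a[cbind(2, ring[, 1], ring[, 2])] <- 1L    # diamond loop, all degree 2
  g <- buildSkeletonGraph(binVol(a))
  expect_length(g@branches, 1)
  expect_true(g@branches[[1]]$closed)
  tj <- countTipsJunctions(g)
  expect_identical(unname(tj["n_tips"]), 0L)
  expect_identical(unname(tj["n_junctions"]), 0L)
})

test_that("spur pruning removes short arms, dissolves junctions, and is idempotent", {
  # single long branch untouched
  a <- array(0L, c(3, 3, 103)); a[2, 2, 2:102] <- 1L
  g <- pruneSpurs(buildSkeletonGraph(binVol(a)), min_length_um = 5)
  expect_length(g@branches, 1)
  # Y with arms 50/50/2: the 2-um arm goes, the junction dissolves
  y <- array(0L, c(3, 5, 103))
  y[2, 3, 2:102] <- 1L; y[2, 4:5, 52] <- 1L
  gy <- buildSkeletonGraph(binVol(y))
  expect_identical(unname(countTipsJunctions(gy)["n_tips"]), 3L)
  py <- pruneSpurs(gy, min_length_um = 5)
  expect_identical(unname(countTipsJunctions(py)["n_tips"]), 2L)
  expect_identical(unname(countTipsJunctions(py)["n_junctions"]), 0L)
  # idempotent
  py2 <- pruneSpurs(py, min_length_um = 5)
  expect_identical(py2@voxels, py@voxels)
})

test_that("total length follows the path geometry in both modes", {
  a <- array(0L, c(3, 3, 13)); a[2, 2, 2:12] <- 1L
  g <- buildSkeletonGraph(binVol(a))
  expect_equal(as.numeric(totalLength(g, "path")), 10)
  expect_equal(as.numeric(totalLength(g, "chord")), 10)
  # 6 voxels stepping (1,1,1) diagonally
  d <- array(0L, c(8, 8, 8)); for (i in 1:6) d[i + 1, i + 1, i + 1] <- 1L
  gd <- buildSkeletonGraph(binVol(d))
  expect_equal(as.numeric(totalLength(gd, "path")), 5 * sqrt(3))
  expect_equal(as.numeric(totalLength(gd, "chord")), 5 * sqrt(3))
  expect_identical(attr(totalLength(gd), "mode"), "path")
  # triradiate arms within 5% of the centreline total
  tri <- makeTriradiatePhantom(c(0, 0, 0),
                               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                               c(50, 50, 50), 3)
  L <- as.numeric(totalLength(skeletonGraph(tri$volume), "path"))
  expect_lt(abs(L - 150) / 150, 0.05)
})

test_that("mean thickness reads the local radius off the EDT", {
  a <- array(0L, c(3, 3, 13)); a[2, 2, 2:12] <- 1L
  v <- binVol(a)
  expect_equal(meanThickness(v, v, mode = "radius"), 1.0)
  ph <- rodPhantomFixture(L = 100, r = 4)
  skel <- skeletonize3d(ph$volume)
  r <- meanThickness(ph$volume, skel, mode = "radius")
  expect_lt(abs(r - 4) / 4, 0.10)
  expect_equal(meanThickness(ph$volume, skel, mode = "diameter"), 2 * r)
  expect_error(meanThickness(v, binVol(array(0L, c(3, 3, 13)))),
               "empty skeleton")
})

test_that("eroding a capsule strictly decreases its mean thickness", {
  ph <- rodPhantomFixture(L = 40, r = 4)
  edt <- voxelData(euclideanDistanceTransform(ph$volume))
  eroded <- binVol(array(as.integer(edt > 1), dim = dim(edt)))
  t1 <- meanThickness(ph$volume, skeletonize3d(ph$volume))
  t2 <- meanThickness(eroded, skeletonize3d(eroded))
  expect_lt(t2, t1)
})

test_that("skeleton graphs satisfy the Euler relation on acyclic components", {
  shapes <- list(
    rodPhantomFixture(L = 40, r = 3)$volume,
    makeTriradiatePhantom(c(0, 0, 0),
                          rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                          c(30, 35, 40), 3)$volume,
    makeBranchedPhantom(rodPrimitive(c(0, 0, 0), c(0, 0, 60), 3),
                        0.5, c(0, 1, 0), 15)$volume)
  for (v in shapes) {
    g <- skeletonGraph(v)
    expect_identical(length(g@branches), nrow(g@nodes) - 1L)
  }
})

test_that("measurements are invariant under axis permutation with matching spacing", {
  ph <- rodPhantomFixture(L = 30, r = 3)
  a <- voxelData(ph$volume)
  rec1 <- measureSpicules(binVol(a))
  rec2 <- measureSpicules(binVol(aperm(a, c(3, 1, 2))))
  expect_equal(rec2$volume_um3, rec1$volume_um3)
  expect_equal(rec2$surface_area_um2, rec1$surface_area_um2, tolerance = 1e-9)
  expect_identical(rec2$n_tips, rec1$n_tips)
  expect_identical(rec2$n_junctions, rec1$n_junctions)
  # directional thinning makes skeleton ends only approximately
  # orientation-invariant: allow a couple of voxel steps
  expect_lt(abs(rec2$total_length_um - rec1$total_length_um), 4)
  expect_lt(abs(rec2$mean_thickness_um - rec1$mean_thickness_um), 0.5)
})

test_that("length scales linearly and volume cubically with voxel size", {
  mk <- function(s) {
    a <- rodPhantomFixture(L = 30, r = 3, spacing = rep(1, 3))$volume
    binVol(voxelData(a), spacing = rep(s, 3))
  }
  r1 <- measureSpicules(mk(1)); r2 <- measureSpicules(mk(2))
  expect_equal(r2$volume_um3 / r1$volume_um3, 8)
  expect_equal(r2$total_length_um / r1$total_length_um, 2)
})

test_that("anisotropic stacks are resampled before skeleton measurements", {
  ph <- rodPhantomFixture(L = 80, r = 4, spacing = c(2, 1, 1))
  rec <- measureSpicules(ph$volume)
  expect_lt(abs(rec$total_length_um - 80) / 80, 0.06)
  expect_lt(abs(rec$mean_thickness_um / 2 - 4) / 4, 0.15)
})

test_that("the full measurement chain matches phantom truth end to end", {
  ph <- rodPhantomFixture(L = 100, r = 4)
  rec <- measureSpicules(ph$volume)
  expect_identical(nrow(rec), 1L)
  expect_lt(abs(rec$volume_um3 - capsVol(4, 100)) / capsVol(4, 100), 0.05)
  expect_lt(abs(rec$total_length_um - 100) / 100, 0.05)
  expect_lt(abs(rec$mean_thickness_um / 2 - 4) / 4, 0.10)
  expect_identical(rec$n_tips, 2L)
  expect_identical(rec$n_junctions, 0L)
  # deterministic ids across reruns
  rec2 <- measureSpicules(ph$volume)
  expect_identical(rec, rec2)
  expect_error(measureSpicules(binVol(array(0L, c(3, 3, 3)))),
               "no spicules found")
})

test_that("skeleton export writes voxel and branch tables", {
  ph <- rodPhantomFixture(L = 20, r = 3)
  g <- skeletonGraph(ph$volume)
  td <- withr::local_tempdir()
  out <- exportSkeleton(g, file.path(td, "vox.csv"), file.path(td, "br.csv"))
  expect_identical(nrow(out$voxels), nrow(g@voxels))
  expect_true(all(out$voxels >= 0))       # 0-based indices
  expect_identical(nrow(out$branches), length(g@branches))
})
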