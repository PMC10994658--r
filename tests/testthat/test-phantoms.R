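# Phantom generator: analytic truths, voxelization accuracy, determinism.

test_that("rod phantom carries its analytic ground truth", {
  ph <- rodPhantomFixture(L = 100, r = 4)
  expect_equal(ph$truth$total_centerline_length_um, 100)
  expect_identical(ph$truth$expected_tips, 2L)
  expect_identical(ph$truth$expected_junctions, 0L)
  expect_equal(ph$truth$analytic_volume_um3, capsVol(4, 100))
  # voxel-count volume close to the analytic capsule volume
  vox <- sum(voxelData(ph$volume)) * prod(voxelSpacing(ph$volume))
  expect_lt(abs(vox - capsVol(4, 100)) / capsVol(4, 100), 0.05)
})

test_that("under-resolved phantoms are refused", {
  expect_error(rodPhantomFixture(L = 20, r = 0.3), "under-resolved")
})

test_that("voxelized capsule volume converges as spacing shrinks", {
  relerr <- function(sp) {
    ph <- rodPhantomFixture(L = 40, r = 3, spacing = rep(sp, 3))
    vox <- sum(voxelData(ph$volume)) * sp^3
    abs(vox - capsVol(3, 40)) / capsVol(3, 40)
  }
  expect_lt(relerr(0.5), relerr(1.0))
})

test_that("triradiate phantom truth: three arms, one junction", {
  tri <- makeTriradiatePhantom(c(0, 0, 0),
                               rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                               c(40, 50, 60), 3)
  expect_identical(tri$truth$expected_tips, 3L)
  expect_identical(tri$truth$expected_junctions, 1L)
  expect_equal(tri$truth$total_centerline_length_um, 150)
  # union volume cannot exceed the sum of the three capsule volumes
  vox <- sum(voxelData(tri$volume))
  expect_lte(vox, sum(vapply(c(40, 50, 60), function(L)
    capsVol(3, L), 0)) * 1.0)
  expect_error(
    makeTriradiatePhantom(c(0, 0, 0),
                          rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 0, 1)),
                          c(40, 50, 60), 3),
    "non-parallel")
})

test_that("branched phantom truth distinguishes tip split from back branch", {
  base <- rodPrimitive(c(0, 0, 0), c(0, 0, 100), 4)
  bb <- makeBranchedPhantom(base, 0.5, c(0, 1, 0), 20)
  expect_identical(bb$truth$expected_tips, 3L)
  expect_identical(bb$truth$expected_junctions, 1L)
  expect_equal(bb$truth$junction_arc_um, 50)
  expect_equal(bb$truth$junction_um, c(0, 0, 50))
  expect_equal(bb$truth$total_centerline_length_um, 120)
  # a branch continuing from the very end is a bend, not a junction
  ts <- makeBranchedPhantom(base, 1.0, c(0, 1, 0), 20)
  expect_equal(ts$truth$junction_arc_um, 100)
  expect_identical(ts$truth$expected_tips, 2L)
  expect_equal(ts$truth$total_centerline_length_um, 120)
  expect_error(makeBranchedPhantom(base, 0.5, c(0, 1, 0), 5),
               "unresolvable branch")
})

test_that("ground-truth topology is invariant under 90-degree rotations", {
  dirsets <- list(rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
                  rbind(c(0, 1, 0), c(0, 0, 1), c(1, 0, 0)),
                  rbind(c(0, 0, -1), c(0, 1, 0), c(1, 0, 0)))
  tips <- vapply(dirsets, function(d)
    makeTriradiatePhantom(c(0, 0, 0), d, c(30, 30, 30), 3)$truth$expected_tips,
    integer(1))
  expect_true(all(tips == 3L))
})

test_that("grayscale rendering is deterministic and exactly recoverable without noise", {
  ph <- rodPhantomFixture(L = 30, r = 3)
  clean <- renderGrayscale(ph$volume, fg_mean = 40000, bg_mean = 10000,
                           blur_sigma = 0, noise_sd = 0)
  vals <- sort(unique(as.vector(voxelData(clean))))
  expect_identical(vals, c(10000, 40000))
  expect_identical(voxelData(clean) >= 25000, voxelData(ph$volume) == 1)
  g1 <- renderGrayscale(ph$volume, seed = 9)
  g2 <- renderGrayscale(ph$volume, seed = 9)
  expect_identical(voxelData(g1), voxelData(g2))
  expect_false(identical(voxelData(g1),
                         voxelData(renderGrayscale(ph$volume, seed = 10))))
  expect_error(renderGrayscale(ph$volume, noise_sd = -1), "noise_sd")
  expect_true(all(voxelData(g1) >= 0 & voxelData(g1) <= 65535))
})

test_that("cohort truth tables are deterministic and recover the group means", {
  sp <- cohortSpec(n_per_group = 40, seed = 5)
  a <- makeCohort(sp, render = FALSE)
  b <- makeCohort(sp, render = FALSE)
  expect_identical(a$truth, b$truth)
  expect_identical(nrow(a$truth), 160L)
  # sample mean within 3 s.e.m. of the requested mean
  g <- a$truth[a$truth$condition == "control" & a$truth$timepoint_hpf == 48, ]
  sem <- 0.2 * 5000 / sqrt(40)
  expect_lt(abs(mean(g$volume_um3) - 5000), 3 * sem)
  # no branching when the probability is zero
  sp0 <- cohortSpec(n_per_group = 10, branch_probability = c(0, 0), seed = 2)
  t0 <- makeCohort(sp0, render = FALSE)$truth
  expect_true(all(t0$n_junctions == 0L))
  expect_true(all(t0$n_tips == 2L))
})

test_that("rendered cohort phantoms match their truth rows", {
  sp <- cohortSpec(n_per_group = 3, branch_probability = c(0, 0), seed = 8)
  co <- makeCohort(sp, render = TRUE)
  expect_length(co$phantoms, nrow(co$truth))
  for (i in c(1, 7)) {
    vol <- co$phantoms[[i]]$volume
    vox_um3 <- sum(voxelData(vol)) * prod(voxelSpacing(vol))
    expect_lt(abs(vox_um3 - co$truth$volume_um3[i]) / co$truth$volume_um3[i],
              0.06)
  }
})

test_that("fluorescence fixtures carry exact stained counts and blob counts", {
  fx <- makeFluorFixture(densities = c(skeletogenic = 0.5, ectoderm = 0.1),
                         seed = 3)
  tr <- fx$truth
  area <- tr$area_px[tr$region == "skeletogenic"]
  expect_identical(tr$stained_px[tr$region == "skeletogenic"],
                   as.integer(round(0.5 * area)))
  dens <- tr$stained_px / tr$area_px
  expect_equal(dens[tr$region == "skeletogenic"] /
                 dens[tr$region == "ectoderm"], 5.0)
  fb <- makeFluorFixture(densities = c(skeletogenic = 0, ectoderm = 0),
                         blobs = list(region = "skeletogenic", n = 5,
                                      radius = 3), seed = 4)
  expect_identical(fb$truth$n_blobs[fb$truth$region == "skeletogenic"], 5L)
  expect_error(
    makeFluorFixture(shape = c(30, 60),
                     densities = c(skeletogenic = 0, ectoderm = 0),
                     blobs = list(region = "skeletogenic", n = 50,
                                  radius = 5), seed = 1),
    "blob placement")
})
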