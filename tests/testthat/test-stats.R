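# Group-comparison statistics: worked examples, formula oracles,
# invariances and parameter recovery on simulated cohorts.

test_that("one-sample z test reproduces hand computations", {
  sym <- oneSampleZTest(c(0.9, 1.1), mu0 = 1)
  expect_equal(sym@statistic, 0)
  expect_equal(sym@p_value, 1)
  # mean 1.6, sd 0.31623, n 5 -> z = 0.6/(0.31623/sqrt(5))
  z <- oneSampleZTest(c(1.2, 1.4, 1.6, 1.8, 2.0), mu0 = 1)
  expect_equal(z@statistic, 4.242640687, tolerance = 1e-9)
  expect_error(oneSampleZTest(c(1, 1, 1), 1), "degenerate")
  # two-tailed p is twice the smaller one-tailed p
  p1 <- oneSampleZTest(c(1.2, 1.4, 1.6, 1.8, 2.0), 1, tails = 1)@p_value
  expect_equal(z@p_value, 2 * min(p1, 1 - p1), tolerance = 1e-6)
})

test_that("z and t statistics are location-scale equivariant", {
  x <- c(1.3, 0.9, 1.7, 1.2, 1.5)
  z1 <- oneSampleZTest(x, 1)@statistic
  z2 <- oneSampleZTest(3 * x + 2, 3 * 1 + 2)@statistic
  expect_equal(z2, z1, tolerance = 1e-12)
})

test_that("paired t test works on differences with df = n - 1", {
  a <- c(5, 6, 7); b <- a - c(1, 2, 3)          # d = 1, 2, 3
  tt <- pairedTTest(a, b)
  expect_equal(tt@statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(tt@df, 2)
  z <- c(0.1, 0.2, -0.3)
  t0 <- pairedTTest(z + c(2, 2, 2), c(2, 2, 2))  # mean difference 0
  expect_equal(t0@statistic, 0, tolerance = 1e-12)
  expect_equal(t0@p_value, 1, tolerance = 1e-12)
  expect_error(pairedTTest(1:3, 1:4), "unequal lengths")
  expect_error(pairedTTest(c(2, 3, 4), c(1, 2, 3)), "degenerate")
})

test_that("Kruskal-Wallis matches the rank-formula oracle, with ties", {
  gs <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  kw <- suppressWarnings(kruskalWallis(gs))
  expect_equal(kw@statistic, 7.2, tolerance = 1e-12)
  expect_equal(kw@statistic, kwFormula(gs), tolerance = 1e-12)
  expect_equal(kw@df, 2)
  set.seed(7)
  for (i in 1:5) {
    g2 <- list(round(stats::rnorm(8), 1), round(stats::rnorm(7), 1),
               round(stats::rnorm(9), 1))
    expect_equal(suppressWarnings(kruskalWallis(g2))@statistic,
                 kwFormula(g2), tolerance = 1e-10)
  }
  expect_error(kruskalWallis(list(c(1, 1), c(1, 1))), "no variation")
})

test_that("H is invariant under monotone transforms of the pooled data", {
  set.seed(11)
  gs <- list(stats::rnorm(12), stats::rnorm(10) + 0.5)
  h1 <- kruskalWallis(gs)@statistic
  h2 <- kruskalWallis(lapply(gs, function(v) exp(v)))@statistic
  expect_equal(h2, h1, tolerance = 1e-12)
})

test_that("fold change and growth rate are simple mean ratios and slopes", {
  expect_equal(foldChange(c(1.8, 2.2), c(0.7, 0.9)), 2.5)
  expect_equal(foldChange(1:5, 1:5), 1)
  expect_error(foldChange(1:3, c(-1, 1)), "zero denominator")
  rec <- data.frame(condition = "control",
                    timepoint_hpf = rep(c(48, 72), each = 2),
                    volume_um3 = c(900, 1100, 1900, 2100))
  expect_equal(growthRate(rec, "control", 48, 72), 1000 / 24)
  expect_equal(growthRate(rec, "control", 48, 72, field = "volume_um3"),
               41.6667, tolerance = 1e-4)
  expect_error(growthRate(rec, "treated", 48, 72), "missing group")
  rec0 <- rec; rec0$volume_um3 <- rep(c(1000, 1000), 2)
  expect_equal(growthRate(rec0, "control", 48, 72), 0)
})

test_that("compareCohorts recovers a true 2.5x fold on a simulated cohort", {
  truth <- makeCohort(cohortSpec(n_per_group = 40, seed = 21),
                      render = FALSE)$truth
  plan <- list(
    list(name = "fold48", test = "fold_change", field = "volume_um3",
         conditions = c("control", "ROCK-inhibited"), timepoint = 48),
    list(name = "kw48", test = "kruskal_wallis", field = "volume_um3",
         conditions = c("control", "ROCK-inhibited"), timepoint = 48),
    list(name = "rate_ctrl", test = "growth_rate", field = "volume_um3",
         conditions = "control", timepoints = c(48, 72)))
  out <- compareCohorts(truth, plan)
  expect_identical(nrow(out), 3L)
  fold <- out$effect[out$name == "fold48"]
  expect_gt(fold, 2.2); expect_lt(fold, 2.8)
  expect_lt(out$p_value[out$name == "kw48"], 0.001)
  rate <- out$effect[out$name == "rate_ctrl"]
  expect_lt(abs(rate - 325.5) / 325.5, 0.15)
  expect_identical(attr(out, "p_correction"), "none")
  bad <- list(list(name = "oops", test = "fold_change", field = "volume_um3",
                   conditions = c("control", "missing"), timepoint = 48))
  expect_error(compareCohorts(truth, bad), "oops")
})

test_that("fold and rate estimates tighten with sample size", {
  est <- function(n) {
    tr <- makeCohort(cohortSpec(n_per_group = n, seed = 100 + n),
                     render = FALSE)$truth
    c(fold = foldChange(
        tr$volume_um3[tr$condition == "control" & tr$timepoint_hpf == 48],
        tr$volume_um3[tr$condition == "ROCK-inhibited" & tr$timepoint_hpf == 48]),
      rate = growthRate(tr, "control", 48, 72))
  }
  e40 <- est(40); e160 <- est(160)
  expect_lt(abs(e160["fold"] - 2.5), abs(e40["fold"] - 2.5))
  expect_lt(abs(e160["rate"] - 325.5), abs(e40["rate"] - 325.5))
})
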