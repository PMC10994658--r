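# Shared fixtures and independent brute-force oracles for the test suite.

binVol <- function(arr, spacing = c(1, 1, 1)) {
  VoxelVolume(array(as.integer(arr != 0), dim = dim(arr)),
              spacing = spacing, kind = "binary")
}

labVol <- function(arr, spacing = c(1, 1, 1)) {
  new("LabelField", data = array(as.integer(arr), dim = dim(arr)),
      spacing = spacing, kind = "labels", meta = list())
}

# O(n^2) Euclidean distance transform: for every foreground voxel, the
# minimum distance to any background voxel centre, with the grid padded by
# one layer of background. Completely independent of the package's
# separable transform.
bruteEDT <- function(arr, spacing = c(1, 1, 1)) {
  d <- dim(arr)
  pd <- d + 2L
  p <- array(FALSE, pd)
  p[1L + seq_len(d[1]), 1L + seq_len(d[2]), 1L + seq_len(d[3])] <- arr != 0
  co <- which(p | !p, arr.ind = TRUE)   # all voxels
  pos <- sweep(co - 1, 2, spacing, `*`)
  fg <- which(as.vector(p))
  bg <- which(!as.vector(p))
  out <- numeric(length(p))
  if (length(fg) && length(bg)) {
    for (i in fg) {
      dd <- (pos[bg, 1] - pos[i, 1])^2 + (pos[bg, 2] - pos[i, 2])^2 +
        (pos[bg, 3] - pos[i, 3])^2
      out[i] <- sqrt(min(dd))
    }
  }
  array(out, dim = pd)[1L + seq_len(d[1]), 1L + seq_len(d[2]),
                       1L + seq_len(d[3]), drop = FALSE]
}

# Kruskal-Wallis H by the rank formula with tie correction, independent of
# stats::kruskal.test.
kwFormula <- function(groups) {
  pooled <- unlist(groups)
  N <- length(pooled)
  rk <- rank(pooled)   # mid-ranks
  ns <- lengths(groups)
  idx <- rep(seq_along(groups), ns)
  R <- tapply(rk, idx, sum)
  H <- 12 / (N * (N + 1)) * sum(R^2 / ns) - 3 * (N + 1)
  ties <- table(pooled)
  C <- 1 - sum(ties^3 - ties) / (N^3 - N)
  H / C
}

# Digitized ball of radius r (voxel-centre rule) in a cube with margin.
digitBall <- function(r, margin = 3) {
  n <- 2 * (r + margin) + 1
  c0 <- r + margin + 1
  g <- expand.grid(z = 1:n, y = 1:n, x = 1:n)
  array(as.integer((g$z - c0)^2 + (g$y - c0)^2 + (g$x - c0)^2 <= r^2),
        dim = c(n, n, n))
}

capsVol <- function(r, L) pi * r^2 * L + 4 / 3 * pi * r^3

rodPhantomFixture <- function(L = 100, r = 4, spacing = c(1, 1, 1)) {
  makeRodPhantom(phantomSpec(list(
    rodPrimitive(c(0, 0, 0), c(0, 0, L), r)), spacing = spacing))
}
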