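# Internal helpers: deterministic sub-seeds, RNG hygiene, array utilities.

# Derive a reproducible 32-bit sub-seed from a master seed and an index.
subSeed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(index) * 16807) %% 2147483647)
}

# Run expr with a local RNG state so generators never disturb the caller's.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Flat array -> logical vector in R's native (z fastest) order.
asFlatLogical <- function(a) as.logical(as.vector(a) != 0)

# 26-connected hit test: is any solid 2x2x2 block present?
hasSolidBlock <- function(mask) {
  d <- dim(mask)
  if (any(d < 2)) return(FALSE)
  m <- mask != 0
  s <- m[-d[1], -d[2], -d[3]] & m[-1, -d[2], -d[3]] &
       m[-d[1], -1, -d[3]]   & m[-1, -1, -d[3]] &
       m[-d[1], -d[2], -1]   & m[-1, -d[2], -1] &
       m[-d[1], -1, -1]      & m[-1, -1, -1]
  any(s)
}

# stopifnot-style check with a custom message
check <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
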