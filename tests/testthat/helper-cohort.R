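# Shared fixtures, built in code. The small cohort keeps unit tests fast;
# acceptance tests build the full-size default cohort themselves.

smallCohortConfig <- function(rng_seed = 7L, ...) {
  cohortConfig(n_als = 8L, n_hc = 8L, n_regions = 16L,
               grid_shape = c(21L, 16L, 11L), block = 4L,
               rng_seed = rng_seed, ...)
}

# memoized small cohort (generated once per test run)
.fixtures <- new.env(parent = emptyenv())
smallCohort <- function() {
  if (is.null(.fixtures$co)) .fixtures$co <- generateCohort(smallCohortConfig())
  .fixtures$co
}
smallScaled <- function() {
  if (is.null(.fixtures$scaled))
    .fixtures$scaled <- lapply(smallCohort()$volumes, proportionalScale)
  .fixtures$scaled
}

# a tiny hand-built volume: 4x4x4 grid, value v everywhere
constantVolume <- function(v = 1, dims = c(4L, 4L, 4L), id = "const") {
  arr <- array(v, dims)
  new("SuvVolume", subjectId = id, suv = arr, voxelSize = c(2, 2, 2),
      mask = array(TRUE, dims))
}

# brute-force Benjamini-Hochberg step-up, written independently of
# p.adjust: q_i = min over j >= rank(i) of p_(j) * m / j, capped at 1.
bruteForceBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (k in m:1) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- min(prev, 1)
  }
  q
}
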