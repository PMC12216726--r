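mkDensity <- function(probs, grid = seq_along(probs)) {
  structure(list(grid = grid, probs = probs, bw = 1),
            class = "DensityEstimate")
}

test_that("symmetric KL matches the analytic two-point oracle", {
  p <- mkDensity(c(0.75, 0.25)); q <- mkDensity(c(0.25, 0.75))
  ## 0.75 ln 3 + 0.25 ln(1/3) + 0.25 ln(1/3)... summed = ln 3
  expect_equal(symmetricKL(p, q), log(3), tolerance = 1e-12)
  expect_equal(klsScore(symmetricKL(p, q)), 1 / 3, tolerance = 1e-12)
  expect_identical(symmetricKL(p, p), 0)
  expect_identical(klsScore(0), 1)
})

test_that("symmetric KL equals the sum of the two directed divergences", {
  set.seed(4)
  for (n in c(2, 3, 17, 64)) {
    p <- mkDensity(prop.table(runif(n) + 0.01))
    q <- mkDensity(prop.table(runif(n) + 0.01), grid = p$grid)
    kl <- function(a, b) sum(a$probs * (log(a$probs) - log(b$probs)))
    expect_equal(symmetricKL(p, q), kl(p, q) + kl(q, p), tolerance = 1e-12)
    expect_identical(symmetricKL(p, q), symmetricKL(q, p))
    expect_gte(symmetricKL(p, q), 0)
  }
})

test_that("symmetric KL rejects mismatched grids and zero probabilities", {
  p <- mkDensity(c(0.5, 0.5)); q <- mkDensity(c(0.5, 0.5), grid = c(1, 3))
  expect_error(symmetricKL(p, q), "same evaluation grid")
  z <- mkDensity(c(1, 0))
  expect_error(symmetricKL(z, z), "strictly positive")
  expect_error(klsScore(-0.1), "non-negative")
})

test_that("KLS score is strictly decreasing in the divergence", {
  d <- sort(runif(20, 0, 5))
  expect_true(all(diff(klsScore(d)) < 0))
  expect_true(all(klsScore(d) > 0 & klsScore(d) <= 1))
})

test_that("density estimation recovers the generating distribution's centre", {
  set.seed(12)
  x <- rnorm(500)
  de <- estimateDensity(x, 1024L, -5, 5)
  expect_equal(sum(de$probs), 1, tolerance = 1e-9)
  expect_true(all(de$probs > 0))
  m <- sum(de$grid * de$probs)
  expect_lt(abs(m - 0), 3 / sqrt(500))      # 3 SE of the sample mean
  expect_lt(abs(which.max(de$probs) - which.min(abs(de$grid))), 60)

  ## determinism: identical samples give identical estimates
  expect_identical(estimateDensity(x, 256L, -5, 5),
                   estimateDensity(x, 256L, -5, 5))

  ## zero-variance fallback bandwidth
  cz <- estimateDensity(c(2, 2, 2), 64L, 0, 4)
  expect_equal(cz$bw, 1e-3 * 4)
  expect_equal(sum(cz$probs), 1, tolerance = 1e-9)

  expect_error(estimateDensity(c(1), 64L, 0, 1), ">= 2")
  expect_error(estimateDensity(c(1, 2), 8L, 0, 1), "at least 16")
  expect_error(estimateDensity(c(1, 2), 64L, 1, 0), "grid_lo < grid_hi")
})

test_that("connectome equals the hand-composed pairwise KLS on a toy volume", {
  ## 3 regions of 4 voxels on a 12-voxel grid
  dims <- c(12L, 1L, 1L)
  arr <- array(c(1.0, 1.1, 0.9, 1.05, 2.0, 2.2, 1.8, 2.1, 3.0, 3.3, 2.7, 3.1),
               dims)
  vol <- new("SuvVolume", subjectId = "toy", suv = arr,
             voxelSize = c(2, 2, 2), mask = array(TRUE, dims))
  labs <- array(rep(1:3, each = 4L), dims)
  parc <- new("Parcellation", labels = labs,
              regions = data.frame(region_id = 1:3,
                                   name = c("A", "B", "C"),
                                   lobe_group = c("FL", "OL", "TL")))
  K <- similarityValues(buildConnectome(vol, parc, n_points = 128L))
  ## hand composition on the same shared grid
  lo <- min(arr); hi <- max(arr)
  dens <- lapply(1:3, function(r)
    estimateDensity(arr[labs == r], 128L, lo, hi))
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(K[i, j], klsScore(symmetricKL(dens[[i]], dens[[j]])),
                 tolerance = 1e-12)
  expect_identical(diag(K), c(1, 1, 1))
  expect_identical(K, t(K))
})

test_that("regions with identical voxel multisets have KLS exactly 1", {
  dims <- c(8L, 1L, 1L)
  arr <- array(rep(c(1, 2, 1.5, 2.5), 2), dims)
  vol <- new("SuvVolume", subjectId = "dup", suv = arr,
             voxelSize = c(1, 1, 1), mask = array(TRUE, dims))
  labs <- array(rep(1:2, each = 4L), dims)
  parc <- new("Parcellation", labels = labs,
              regions = data.frame(region_id = 1:2, name = c("A", "B"),
                                   lobe_group = c("FL", "FL")))
  K <- similarityValues(buildConnectome(vol, parc, n_points = 64L))
  expect_equal(K[1, 2], 1)
})

test_that("every synthetic connectome is symmetric with unit diagonal and (0,1] edges", {
  co <- smallCohort()
  for (v in smallScaled()) {
    K <- similarityValues(buildConnectome(v, co$atlas, n_points = 256L))
    expect_identical(K, t(K))
    expect_identical(diag(K), rep(1, nrow(K)))
    off <- K[upper.tri(K)]
    expect_true(all(off > 0 & off <= 1))
  }
})

test_that("nodal degree counts edges at the requested density", {
  A <- matrix(1, 3, 3); diag(A) <- 0
  expect_equal(nodalDegree(A, 1)$degree, c(2L, 2L, 2L))

  ## binary significance mode: a node attached to 17 of its edges
  R <- 20L
  B <- matrix(0, R, R)
  B[1, 2:18] <- 1; B <- B + t(B)
  expect_equal(nodalDegree(B, mode = "significance")$degree[1], 17L)

  set.seed(9)
  W <- matrix(runif(15 * 15), 15); W <- (W + t(W)) / 2; diag(W) <- 0
  prof <- nodalDegree(W, 0.5)
  expect_equal(attr(prof, "n_edges"), floor(0.5 * choose(15, 2)))
  expect_equal(sum(prof$degree), 2L * attr(prof, "n_edges"))

  expect_error(nodalDegree(matrix(1, 2, 3)), "square")
  expect_error(nodalDegree(W, 1.5), "density_level")
})

test_that("nodal degree is monotone in connection density per node", {
  set.seed(10)
  W <- matrix(runif(12 * 12), 12); W <- (W + t(W)) / 2; diag(W) <- 0
  degs <- sapply(seq(0.5, 1, by = 0.1),
                 function(d) nodalDegree(W, d)$degree)
  expect_true(all(apply(degs, 1, function(x) all(diff(x) >= 0))))
})

test_that("parameter sweep reports perfect correlation for identical groups", {
  co <- smallCohort()
  vols <- smallScaled()[1:3]
  sw <- sweepParameters(vols, vols, co$atlas,
                        n_points_list = c(64L, 128L),
                        density_list = c(0.5, 1))
  expect_equal(nrow(sw$settings), 4L)       # 2 x 2 settings evaluated
  ## identical groups: all t are 0/NA; correlations undefined rather than low
  expect_true(all(is.na(sw$patterns) | sw$patterns == 0))

  sw2 <- sweepParameters(smallScaled()[co$subjects$group == "ALS"][1:4],
                         smallScaled()[co$subjects$group == "HC"][1:4],
                         co$atlas, n_points_list = c(128L, 256L),
                         density_list = c(0.8, 1))
  expect_equal(dim(sw2$correlations), c(4L, 4L))
  expect_true(sw2$min_correlation > 0.5)    # same data, nearby settings
})
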