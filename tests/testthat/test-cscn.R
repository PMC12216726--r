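test_that("sequencing sorts by stage with the documented tie-breaks", {
  subjects <- data.frame(
    subject_id = c("s1", "s2", "s3"), group = "ALS",
    kings_stage = c("3", "1", "2a"),
    duration_months = c(10, 20, 30), alsfrs_r = c(30, 44, 40))
  expect_equal(subjects$subject_id[synconn:::.sequence_order(subjects)],
               c("s2", "s3", "s1"))

  ## ties at stage 2b broken by duration ascending, deterministically
  tied <- data.frame(
    subject_id = c("a", "b", "c", "d"), group = "ALS",
    kings_stage = "2b", duration_months = c(9, 3, 7, 3),
    alsfrs_r = c(40, 38, 40, 41))
  o <- synconn:::.sequence_order(tied)
  expect_equal(tied$subject_id[o], c("d", "b", "c", "a"))
})

test_that("the default stage composition sorts into a length-21 sequence", {
  stages <- synconn:::.default_stages(21L)
  expect_length(stages, 21L)
  expect_equal(as.vector(table(stages)[c("1", "2a", "2b", "3", "4a", "4b")]),
               c(2L, 2L, 9L, 6L, 1L, 1L))
  co <- smallCohort()
  sc <- sequenceCohort(co$subjects, smallScaled(), co$atlas)
  expect_false(is.unsorted(cohortOrdering(sc)$stage_numeric))
  expect_equal(ncol(roiMeans(sc)), sum(co$subjects$group == "ALS"))
})

test_that("subjects without a valid stage are excluded with a warning", {
  co <- smallCohort()
  subj <- co$subjects
  subj$kings_stage[subj$subject_id == "ALS03"] <- NA
  expect_warning(sc <- sequenceCohort(subj, smallScaled(), co$atlas),
                 "ALS03")
  expect_false("ALS03" %in% subjectId(sc))
})

test_that("signed-path GC recovers a known lagged coefficient", {
  set.seed(41)
  n <- 200
  x <- rnorm(n)
  y <- c(0, 0.9 * x[-n]) + rnorm(n, 0, 0.02)
  g <- signedPathGC(x, y)
  ## on standardized series the path coefficient is scaled by sd(x)/sd(y)
  expect_lt(abs(as.numeric(g) - 0.9 * sd(x) / sd(y)), 0.05)
  expect_false(attr(g, "degenerate"))

  ## direction specificity: the reverse direction collapses toward zero
  expect_lt(abs(as.numeric(signedPathGC(y, x))), 0.15)

  ## independent white noise: mean GC over replicates is near zero
  gs <- replicate(400, {
    as.numeric(signedPathGC(rnorm(30), rnorm(30)))
  })
  expect_lt(abs(mean(gs)), 3 * sd(gs) / sqrt(length(gs)))

  ## degenerate inputs
  expect_true(attr(signedPathGC(rep(1, 10), rnorm(10)), "degenerate"))
  expect_identical(as.numeric(signedPathGC(rep(1, 10), rnorm(10))), 0)
  expect_error(signedPathGC(1:3, 1:3), "too short")
  expect_error(signedPathGC(1:5, 1:4), "equal length")
})

test_that("higher-order GC sums the x-lag coefficients", {
  set.seed(42)
  n <- 300
  x <- rnorm(n)
  y <- c(0, 0.5 * x[-n]) + c(0, 0, 0.3 * x[-c(n - 1, n)]) + rnorm(n, 0, 0.05)
  g2 <- as.numeric(signedPathGC(x, y, order = 2))
  expect_lt(abs(g2 - 0.8 * sd(x) / sd(y)), 0.1)
})

test_that("the ROI causal matrix matches per-pair signed-path GC", {
  co <- smallCohort()
  sc <- sequenceCohort(co$subjects, smallScaled(), co$atlas)
  cm <- roiCscn(sc, threshold = 0.82)
  S <- roiMeans(sc)
  for (i in c(1, 5)) for (j in c(2, 9)) {
    if (i == j) next
    expect_equal(gcValues(cm)[i, j],
                 as.numeric(signedPathGC(S[i, ], S[j, ])), tolerance = 1e-10)
  }
  ## degree bookkeeping
  expect_equal(sum(outDegree(cm)), sum(binaryNetwork(cm)))
  expect_equal(sum(inDegree(cm)), sum(binaryNetwork(cm)))
  ## a threshold above every coefficient empties the network
  cm2 <- roiCscn(sc, threshold = max(gcValues(cm)) + 1)
  expect_equal(sum(binaryNetwork(cm2)), 0L)
  expect_true(all(outDegree(cm2) == 0L) && all(inDegree(cm2) == 0L))
})

test_that("a planted two-region causal direction is recovered asymmetrically", {
  set.seed(43)
  n <- 24
  x <- cumsum(rnorm(n, 0, 0.4)) + rnorm(n, 0, 0.4)
  y <- c(0, x[-n]) + rnorm(n, 0, 0.05)
  sc <- new("SequencedCohort", subjectIds = sprintf("s%02d", 1:n),
            ordering = data.frame(subject_id = sprintf("s%02d", 1:n)),
            roiMeans = rbind(x, y), regionIds = c(1L, 2L))
  cm <- roiCscn(sc, threshold = 0.82)
  expect_equal(binaryNetwork(cm)[1, 2], 1L)
  expect_equal(binaryNetwork(cm)[2, 1], 0L)
})

test_that("voxelwise map is degenerate on constant volumes and z-normalized otherwise", {
  co <- smallCohort()
  scaled <- smallScaled()
  sc <- sequenceCohort(co$subjects, scaled, co$atlas)

  const <- lapply(subjectId(sc), function(id)
    new("SuvVolume", subjectId = id, suv = array(1, c(4, 4, 4)),
        voxelSize = c(2, 2, 2), mask = array(TRUE, c(4, 4, 4))))
  sc0 <- initialize(sc, roiMeans = sc@roiMeans)
  gm0 <- voxelwiseCscn(sc0, const, regionIds(sc)[1])
  expect_true(all(gm0@degenerate[gm0@mask]))
  expect_equal(sum(qMap(gm0) < 0.01, na.rm = TRUE), 0L)

  gm <- voxelwiseCscn(sc, scaled, co$truth$seed_region)
  ok <- gm@mask & !gm@degenerate
  expect_equal(mean(zMap(gm)[ok]), 0, tolerance = 1e-6)
  expect_equal(sd(zMap(gm)[ok]), 1, tolerance = 1e-6)

  ## z-map is invariant to a common positive rescaling of all series
  scaled2 <- lapply(scaled, function(v) initialize(v, suv = v@suv * 3))
  sc2 <- sequenceCohort(co$subjects, scaled2, co$atlas)
  gm2 <- voxelwiseCscn(sc2, scaled2, co$truth$seed_region)
  expect_equal(zMap(gm2)[ok], zMap(gm)[ok], tolerance = 1e-8)
})

test_that("voxelwise GC agrees with the scalar signed-path fit per voxel", {
  co <- smallCohort()
  scaled <- smallScaled()
  sc <- sequenceCohort(co$subjects, scaled, co$atlas)
  gm <- voxelwiseCscn(sc, scaled, co$truth$seed_region)
  x <- roiMeans(sc)[match(co$truth$seed_region, regionIds(sc)), ]
  vox <- which(gm@mask)[c(3, 100, 400)]
  ids <- match(subjectId(sc), vapply(scaled, subjectId, character(1)))
  for (v in vox) {
    y <- vapply(scaled[ids], function(s) s@suv[v], numeric(1))
    expect_equal(gm@gc[v], as.numeric(signedPathGC(x, y)), tolerance = 1e-8)
  }
})

test_that("voxelwise map enriches positive z in the lagged striatum", {
  co <- generateCohort(cohortConfig(n_als = 21L, n_hc = 5L, n_regions = 16L,
                                    grid_shape = c(21L, 16L, 11L), block = 4L,
                                    rng_seed = 57L))
  scaled <- lapply(co$volumes, proportionalScale)
  sc <- sequenceCohort(co$subjects, scaled, co$atlas)
  gm <- voxelwiseCscn(sc, scaled, co$truth$seed_region)
  lab <- regionLabels(co$atlas)
  str_ids <- co$truth$affected_regions$region_id[
    co$truth$affected_regions$group == "striatum"]
  in_str <- lab %in% str_ids & gm@mask
  out_str <- !(lab %in% c(str_ids, co$truth$seed_region)) & lab != 0 & gm@mask
  expect_gt(mean(zMap(gm)[in_str]), 0.5)
  expect_gt(mean(zMap(gm)[in_str]), mean(zMap(gm)[out_str]) + 0.5)
  ## strongly positive voxels concentrate in the planted targets
  expect_gt(mean(zMap(gm)[in_str] > 1), mean(zMap(gm)[out_str] > 1))
})

test_that("reversing the pseudo-temporal ordering destroys planted causality", {
  set.seed(44)
  hits <- replicate(10, {
    n <- 21
    x <- cumsum(rnorm(n, 0, 0.3)) + rnorm(n, 0, 0.3)
    y <- c(0, x[-n]) + rnorm(n, 0, 0.05)
    fwd <- as.numeric(signedPathGC(x, y))
    rev <- as.numeric(signedPathGC(rev(x), rev(y)))
    c(fwd, rev)
  })
  expect_gt(mean(hits[1, ]), mean(hits[2, ]) + 0.3)
})

test_that("pathway extraction matches a brute-force DFS oracle", {
  skip_if_not_installed("igraph")
  set.seed(45)
  for (trial in 1:12) {
    R <- sample(4:10, 1)
    B <- matrix(rbinom(R * R, 1, 0.3), R); diag(B) <- 0
    G <- matrix(0, R, R); G[B == 1] <- 1
    cm <- new("CausalMatrix", regionIds = seq_len(R), gc = G,
              binary = matrix(as.integer(B), R), threshold = 0.5,
              outDegree = as.integer(rowSums(B)),
              inDegree = as.integer(colSums(B)))
    src <- sample(R, 1)
    got <- extractPathways(cm, src)
    g <- igraph::graph_from_adjacency_matrix(B, mode = "directed")
    want <- igraph::all_simple_paths(g, from = src, cutoff = 2)
    want <- lapply(want, as.integer)
    key_want <- sort(vapply(want, paste, character(1), collapse = "-"))
    key_got <- sort(apply(got, 1, function(r)
      paste(na.omit(c(r["from"], r["via"], r["to"])), collapse = "-")))
    expect_identical(key_got, key_want)
  }
  ## empty network gives an empty path list
  empty <- new("CausalMatrix", regionIds = 1:3, gc = matrix(0, 3, 3),
               binary = matrix(0L, 3, 3), threshold = 1,
               outDegree = rep(0L, 3), inDegree = rep(0L, 3))
  expect_equal(nrow(extractPathways(empty, 1)), 0L)
})

test_that("the tie-ordering audit reports one row per permutation", {
  co <- smallCohort()
  sc <- sequenceCohort(co$subjects, smallScaled(), co$atlas)
  aud <- tieOrderingAudit(sc, co$truth$seed_region, n_perm = 5L)
  expect_equal(nrow(aud), 5L)
  expect_true(all(aud$out_degree >= 0 & aud$in_degree >= 0))
})
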