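test_that("NIfTI write/read round trip preserves data, geometry and mask", {
  co <- smallCohort()
  vol <- co$volumes[[1]]
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  writeSuvVolume(vol, tmp)
  back <- readSuvVolume(tmp, subjectId = subjectId(vol))
  expect_identical(dim(suvData(back)), dim(suvData(vol)))
  expect_identical(as.numeric(suvData(back)), as.numeric(suvData(vol)))
  expect_equal(voxelSize(back), voxelSize(vol))
  expect_identical(brainMask(back), brainMask(vol))

  lab <- withr::local_tempfile(fileext = ".nii.gz")
  csv <- withr::local_tempfile(fileext = ".csv")
  writeParcellation(co$atlas, lab, csv)
  parc2 <- readParcellation(lab, csv)
  expect_identical(regionLabels(parc2), regionLabels(co$atlas))
  expect_identical(regionTable(parc2)$name, regionTable(co$atlas)$name)
})

test_that("reading rejects non-3D images and missing files", {
  tmp <- withr::local_tempfile(fileext = ".nii.gz")
  img4d <- RNifti::asNifti(array(1, c(3, 3, 3, 2)))
  RNifti::writeNifti(img4d, tmp)
  expect_error(readSuvVolume(tmp), "4D")
  expect_error(readSuvVolume(file.path(tempdir(), "nope.nii")), "no such file")
})

test_that("a volume of ones gives a full default mask", {
  tmp <- withr::local_tempfile(fileext = ".nii")
  RNifti::writeNifti(RNifti::asNifti(array(1, c(4, 4, 4))), tmp)
  vol <- readSuvVolume(tmp)
  expect_equal(sum(brainMask(vol)), 64L)
})

test_that("proportional scaling normalizes the in-mask mean and is idempotent", {
  expect_equal(unique(as.numeric(suvData(proportionalScale(constantVolume(5))))), 1)

  vol <- constantVolume(0, dims = c(2L, 1L, 1L))
  vol@suv[] <- c(1, 3)
  expect_equal(as.numeric(suvData(proportionalScale(vol))), c(0.5, 1.5))

  rnd <- constantVolume(1, dims = c(6L, 5L, 4L))
  set.seed(11)
  rnd@suv[] <- runif(prod(dim(rnd@suv)), 0.5, 3)
  sc <- proportionalScale(rnd)
  expect_equal(mean(suvData(sc)[brainMask(sc)]), 1, tolerance = 1e-12)
  sc2 <- proportionalScale(sc)
  expect_equal(suvData(sc2), suvData(sc), tolerance = 1e-12)
  ## relative ratios preserved: scaling is one common factor
  ratio <- as.numeric(suvData(sc)) / as.numeric(suvData(rnd))
  expect_lt(diff(range(ratio)), 1e-12)
  ## out-of-mask voxels untouched
  masked <- rnd
  masked@mask[1, 1, 1] <- FALSE
  expect_equal(suvData(proportionalScale(masked))[1, 1, 1],
               suvData(masked)[1, 1, 1])
})

test_that("proportional scaling rejects an all-zero mask region", {
  vol <- constantVolume(0)
  expect_error(proportionalScale(vol), "positive in-mask mean")
})

test_that("Gaussian smoothing preserves constants, mass, and kernel width", {
  const <- constantVolume(2, dims = c(8L, 8L, 8L))
  sm <- gaussianSmooth(const, fwhm_mm = 8)
  expect_equal(suvData(sm), suvData(const), tolerance = 1e-12)

  ## interior unit impulse: peak equals the product of the per-axis
  ## discrete kernel centre weights, and total mass is conserved
  imp <- constantVolume(0, dims = c(15L, 15L, 15L))
  imp@mask[] <- TRUE
  imp@suv[8, 8, 8] <- 1
  fwhm <- 8; vox <- 2
  smi <- gaussianSmooth(imp, fwhm)
  sigma <- fwhm / (vox * sqrt(8 * log(2)))
  expect_equal(sigma, 1.6986, tolerance = 1e-4)
  r <- max(1, ceiling(4 * sigma))
  k <- dnorm(seq(-r, r), sd = sigma); k <- k / sum(k)
  expect_equal(max(suvData(smi)), k[r + 1]^3, tolerance = 1e-12)
  expect_equal(sum(suvData(smi)), 1, tolerance = 0.01)

  expect_error(gaussianSmooth(const, -1), "positive")
})

test_that("ROI extraction partitions labelled in-mask voxels", {
  co <- smallCohort()
  vol <- co$volumes[[2]]
  s <- extractRoiSamples(vol, co$atlas)
  lab <- regionLabels(co$atlas)
  expect_equal(sum(lengths(s)), sum(lab != 0 & brainMask(vol)))
  ## per-region counts match the generator's block layout (4^3 voxels)
  expect_true(all(lengths(s) == 64L))

  ## two-region toy atlas over an 8-voxel volume
  toy <- constantVolume(1, dims = c(2L, 2L, 2L))
  toy@suv[] <- 1:8
  labs <- array(c(1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L), c(2, 2, 2))
  parc <- new("Parcellation", labels = labs,
              regions = data.frame(region_id = 1:2, name = c("A", "B"),
                                   lobe_group = c("FL", "OL")))
  s2 <- extractRoiSamples(toy, parc)
  expect_equal(sort(unlist(s2, use.names = FALSE)), as.numeric(1:8))
  expect_length(s2, 2L)

  ## a region entirely outside the mask lands in the dropped report
  toy2 <- toy
  toy2@mask[labs == 2L] <- FALSE
  expect_warning(s3 <- extractRoiSamples(toy2, parc), "dropping 1 region")
  expect_identical(attr(s3, "dropped"), 2L)

  ## shape mismatch is an error
  expect_error(extractRoiSamples(vol, parc), "does not match")
})
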