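#' Read a 3D SUV volume from a NIfTI-1 file
#'
#' Reads a subject's PET standardized-uptake-value image. The brain mask
#' defaults to the strictly positive voxels of the image; pass
#' \code{maskPath} to override with an explicit mask image. Images that are
#' not 3D, or that carry non-finite values inside the mask, are rejected.
#'
#' @param path path to a readable NIfTI-1 file (.nii or .nii.gz).
#' @param subjectId identifier for the subject; defaults to the file name
#'   without extension.
#' @param maskPath optional path to a mask image of identical shape;
#'   non-zero voxels are taken as in-mask.
#' @return A [SuvVolume-class] object.
#' @examples
#' \dontrun{vol <- readSuvVolume("sub01_suv.nii.gz")}
#' @export
readSuvVolume <- function(path, subjectId = NULL, maskPath = NULL) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  if (length(dim(img)) != 3L)
    stop("expected a 3D image, got ", length(dim(img)), "D: ", path)
  arr <- array(as.numeric(img), dim(img))
  vs <- RNifti::pixdim(img)[seq_len(3)]
  if (is.null(subjectId))
    subjectId <- sub("\\.nii(\\.gz)?$", "", basename(path))
  if (!is.null(maskPath)) {
    mimg <- RNifti::readNifti(maskPath)
    m <- array(as.numeric(mimg), dim(mimg))
    if (!identical(dim(m), dim(arr)))
      stop("mask shape ", paste(dim(m), collapse = "x"),
           " does not match image shape ", paste(dim(arr), collapse = "x"))
    mask <- array(m != 0, dim(arr))
    if (any(!is.finite(arr[mask])))
      stop("non-finite SUV values inside the supplied mask: ", path)
  } else {
    arr[!is.finite(arr)] <- 0
    mask <- array(arr > 0, dim(arr))
  }
  new("SuvVolume", subjectId = subjectId, suv = arr,
      voxelSize = as.numeric(vs), mask = mask)
}

#' Write a SuvVolume to a NIfTI-1 file
#'
#' Stores the SUV grid as float64 so that a write/read round trip
#' reproduces the data bit for bit.
#'
#' @param vol a [SuvVolume-class].
#' @param path output path (.nii or .nii.gz).
#' @param maskPath optional path to also write the brain mask as an
#'   integer image.
#' @return \code{path}, invisibly.
#' @export
writeSuvVolume <- function(vol, path, maskPath = NULL) {
  stopifnot(is(vol, "SuvVolume"))
  img <- RNifti::asNifti(vol@suv, list(pixdim = c(1, vol@voxelSize, 1, 1, 1, 1)),
                         datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  if (!is.null(maskPath)) {
    m <- RNifti::asNifti(array(as.integer(vol@mask), dim(vol@mask)),
                         list(pixdim = c(1, vol@voxelSize, 1, 1, 1, 1)), datatype = "uint8")
    RNifti::writeNifti(m, maskPath, datatype = "uint8")
  }
  invisible(path)
}

#' Read a parcellation (label image + region table)
#'
#' @param labelPath NIfTI-1 image of integer region labels (0 = background).
#' @param regionCsv CSV with columns \code{region_id,name,lobe_group}.
#' @return A [Parcellation-class].
#' @export
readParcellation <- function(labelPath, regionCsv) {
  img <- RNifti::readNifti(labelPath)
  if (length(dim(img)) != 3L)
    stop("expected a 3D label image, got ", length(dim(img)), "D")
  lab <- array(as.numeric(img), dim(img))
  regions <- utils::read.csv(regionCsv, stringsAsFactors = FALSE)
  new("Parcellation", labels = array(as.integer(round(lab)), dim(lab)),
      regions = regions)
}

#' Write a parcellation to a label image and region CSV
#'
#' @param parc a [Parcellation-class].
#' @param labelPath output NIfTI path for the label grid.
#' @param regionCsv output CSV path for the region table.
#' @param voxelSize voxel edge lengths in mm recorded in the NIfTI header.
#' @return \code{labelPath}, invisibly.
#' @export
writeParcellation <- function(parc, labelPath, regionCsv,
                              voxelSize = c(2, 2, 2)) {
  stopifnot(is(parc, "Parcellation"))
  img <- RNifti::asNifti(parc@labels, list(pixdim = c(1, voxelSize, 1, 1, 1, 1)),
                         datatype = "int16")
  RNifti::writeNifti(img, labelPath, datatype = "int16")
  utils::write.csv(parc@regions, regionCsv, row.names = FALSE)
  invisible(labelPath)
}

#' Proportional (global-mean) SUV scaling
#'
#' Divides every in-mask voxel by the in-mask mean so that the scaled
#' volume has in-mask mean exactly 1. This removes individual differences
#' in global tracer uptake that would otherwise mask local changes.
#' Out-of-mask voxels are left untouched, relative ratios of in-mask
#' voxels are preserved, and the operation is idempotent.
#'
#' @param vol a [SuvVolume-class] with positive in-mask mean.
#' @return A scaled [SuvVolume-class].
#' @export
setGeneric("proportionalScale", function(vol) standardGeneric("proportionalScale"))

#' @rdname proportionalScale
#' @export
setMethod("proportionalScale", "SuvVolume", function(vol) {
  m <- mean(vol@suv[vol@mask])
  if (!is.finite(m) || m <= 0)
    stop("proportional scaling requires a positive in-mask mean (got ",
         format(m), ")")
  out <- vol@suv
  out[vol@mask] <- out[vol@mask] / m
  initialize(vol, suv = out)
})

.gaussian_kernel_1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Separable 1D convolution along the first array dimension with the chosen
# boundary mode, then restore the original dimension order.
.convolve_axis <- function(arr, k, axis, boundary) {
  d <- dim(arr)
  perm <- c(axis, setdiff(seq_along(d), axis))
  a <- aperm(arr, perm)
  dp <- dim(a)
  n <- dp[1]
  m <- prod(dp[-1])
  M <- matrix(a, n, m)
  r <- (length(k) - 1L) / 2L
  idx <- seq_len(n)
  if (r > 0) {
    pre <- pmin(pmax(r:1, 1L), n)        # reflected indices (edge-clamped for tiny n)
    post <- pmin(pmax(n - (1:r) + 1L, 1L), n)
    if (boundary == "reflect") {
      Mp <- rbind(M[pre, , drop = FALSE], M, M[post, , drop = FALSE])
    } else {
      Mp <- rbind(matrix(0, r, m), M, matrix(0, r, m))
    }
  } else Mp <- M
  out <- matrix(0, n, m)
  for (j in seq_along(k))
    out <- out + k[j] * Mp[idx + (j - 1L), , drop = FALSE]
  a <- array(out, dp)
  aperm(a, order(perm))
}

#' 3D Gaussian smoothing of an SUV volume
#'
#' Applies a separable Gaussian filter with the given full width at half
#' maximum (in millimetres). The per-axis kernel standard deviation in
#' voxel units is \code{fwhm / (voxelSize * sqrt(8 * log(2)))}. The default
#' boundary handling is reflective padding.
#'
#' @param vol a [SuvVolume-class].
#' @param fwhm_mm positive filter width (FWHM) in millimetres.
#' @param boundary \code{"reflect"} (default) or \code{"zero"} padding.
#' @return A smoothed [SuvVolume-class] (mask unchanged).
#' @export
setGeneric("gaussianSmooth",
           function(vol, fwhm_mm, boundary = c("reflect", "zero"))
             standardGeneric("gaussianSmooth"))

#' @rdname gaussianSmooth
#' @export
setMethod("gaussianSmooth", "SuvVolume",
          function(vol, fwhm_mm, boundary = c("reflect", "zero")) {
  boundary <- match.arg(boundary)
  if (!is.numeric(fwhm_mm) || length(fwhm_mm) != 1L || !is.finite(fwhm_mm) ||
      fwhm_mm <= 0)
    stop("fwhm_mm must be a single positive number")
  sigmas <- fwhm_mm / (vol@voxelSize * sqrt(8 * log(2)))
  out <- vol@suv
  for (axis in 1:3)
    out <- .convolve_axis(out, .gaussian_kernel_1d(sigmas[axis]), axis, boundary)
  initialize(vol, suv = out)
})

#' Extract per-region SUV voxel samples
#'
#' Collects, for every region of the parcellation, the SUV values of the
#' voxels that are both labelled with that region and inside the brain
#' mask. These samples are the raw material for the per-region density
#' estimates of the KLS connectome. Regions left with fewer than 2 usable
#' voxels cannot support a density estimate; they are dropped with a
#' warning and reported in the \code{"dropped"} attribute.
#'
#' @param vol a [SuvVolume-class].
#' @param parc a [Parcellation-class] on the same grid.
#' @return A named list of numeric vectors (names are region ids), with
#'   attribute \code{"dropped"}: an integer vector of dropped region ids.
#' @export
extractRoiSamples <- function(vol, parc) {
  stopifnot(is(vol, "SuvVolume"), is(parc, "Parcellation"))
  if (!identical(dim(parc@labels), dim(vol@suv)))
    stop("parcellation grid ", paste(dim(parc@labels), collapse = "x"),
         " does not match volume grid ", paste(dim(vol@suv), collapse = "x"))
  lab <- as.integer(parc@labels)
  keep <- lab != 0L & as.logical(vol@mask)
  samples <- split(as.numeric(vol@suv)[keep], lab[keep])
  ids <- parc@regions$region_id
  out <- stats::setNames(vector("list", length(ids)), ids)
  out[names(samples)] <- samples
  sizes <- vapply(out, length, integer(1))
  dropped <- ids[sizes < 2L]
  if (length(dropped))
    warning("dropping ", length(dropped),
            " region(s) with < 2 in-mask voxels: ",
            paste(dropped, collapse = ", "))
  out <- out[sizes >= 2L]
  attr(out, "dropped") <- as.integer(dropped)
  out
}
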