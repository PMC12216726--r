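#' @import methods
NULL

## Fixed display vocabulary for lobe groupings used throughout the package.
.LOBE_GROUPS <- c("BS", "Str", "Tha", "Amy", "Hip", "CG", "FL", "PL",
                  "OL", "INS", "SOM", "TL", "Broca")

#' SuvVolume: a single subject's standardized-uptake-value volume
#'
#' Container for one subject's 3D SUV grid together with its voxel geometry
#' and a brain mask. All in-mask values must be finite and non-negative;
#' the mask must have the same shape as the data grid.
#'
#' @slot subjectId character scalar identifying the subject.
#' @slot suv 3D numeric array of SUV values.
#' @slot voxelSize numeric length-3, voxel edge lengths in millimetres.
#' @slot mask 3D logical array, \code{TRUE} for in-brain voxels.
#'
#' @seealso [readSuvVolume()], [proportionalScale()], [gaussianSmooth()]
#' @export
setClass("SuvVolume",
         representation(subjectId = "character",
                        suv = "array",
                        voxelSize = "numeric",
                        mask = "array"))

setValidity("SuvVolume", function(object) {
  msg <- character()
  if (length(dim(object@suv)) != 3L)
    msg <- c(msg, "suv must be a 3D array")
  if (!identical(dim(object@mask), dim(object@suv)))
    msg <- c(msg, "mask and suv must have identical dimensions")
  if (length(object@voxelSize) != 3L || any(!is.finite(object@voxelSize)) ||
      any(object@voxelSize <= 0))
    msg <- c(msg, "voxelSize must be three positive finite numbers")
  if (length(object@subjectId) != 1L || is.na(object@subjectId))
    msg <- c(msg, "subjectId must be a single non-NA string")
  inmask <- object@suv[object@mask]
  if (length(inmask) && (any(!is.finite(inmask)) || any(inmask < 0)))
    msg <- c(msg, "in-mask SUV values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Parcellation: an integer-labelled atlas with a region table
#'
#' A 3D grid of integer labels (0 = background) together with a region
#' table mapping each label to a region name and a lobe grouping from the
#' fixed display vocabulary (BS, Str, Tha, Amy, Hip, CG, FL, PL, OL, INS,
#' SOM, TL, Broca). Every region in the table must own at least one voxel;
#' degenerate atlases are rejected at construction.
#'
#' @slot labels 3D integer array of region labels.
#' @slot regions data.frame with columns \code{region_id}, \code{name},
#'   \code{lobe_group}.
#'
#' @seealso [buildAtlas()], [extractRoiSamples()]
#' @export
setClass("Parcellation",
         representation(labels = "array",
                        regions = "data.frame"))

setValidity("Parcellation", function(object) {
  msg <- character()
  if (length(dim(object@labels)) != 3L)
    msg <- c(msg, "labels must be a 3D array")
  req <- c("region_id", "name", "lobe_group")
  if (!all(req %in% names(object@regions)))
    return(paste("regions table needs columns:", paste(req, collapse = ", ")))
  ids <- object@regions$region_id
  if (anyDuplicated(ids))
    msg <- c(msg, "duplicated region_id in region table")
  present <- sort(unique(as.integer(object@labels)))
  present <- present[present != 0L]
  if (!all(present %in% ids))
    msg <- c(msg, "label grid contains ids missing from the region table")
  if (!all(ids %in% present))
    msg <- c(msg, "every region in the table must own at least one voxel")
  if (!all(object@regions$lobe_group %in% .LOBE_GROUPS))
    msg <- c(msg, paste("lobe_group values must come from:",
                        paste(.LOBE_GROUPS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' SimilarityMatrix: a per-subject KLS connectome
#'
#' Symmetric region-by-region matrix of Kullback-Leibler similarity scores
#' KLS = exp(-D_KL) for one subject. The diagonal is exactly 1 and every
#' off-diagonal entry lies in (0, 1].
#'
#' @slot subjectId character scalar.
#' @slot regionIds integer vector giving the region label for each row.
#' @slot values numeric matrix of similarity scores.
#'
#' @seealso [buildConnectome()], [nodalDegree()]
#' @export
setClass("SimilarityMatrix",
         representation(subjectId = "character",
                        regionIds = "integer",
                        values = "matrix"))

setValidity("SimilarityMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v)) msg <- c(msg, "values must be square")
  if (length(object@regionIds) != nrow(v))
    msg <- c(msg, "regionIds length must match matrix dimension")
  if (!identical(v, t(v))) msg <- c(msg, "values must be exactly symmetric")
  if (any(diag(v) != 1)) msg <- c(msg, "diagonal must equal 1")
  off <- v[row(v) != col(v)]
  if (length(off) && (any(off <= 0) || any(off > 1)))
    msg <- c(msg, "off-diagonal similarities must lie in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' SequencedCohort: ALS subjects ordered by King's stage for cSCN
#'
#' Holds the disease-stage ordering used as a pseudo-temporal axis: subject
#' ids sorted by (numeric King's stage, a/b sub-rank, disease duration,
#' descending ALSFRS-R, subject id), together with per-region mean-SUV
#' series aligned to that ordering.
#'
#' @slot subjectIds character, subjects in pseudo-temporal order.
#' @slot ordering data.frame recording the sort keys for audit.
#' @slot roiMeans numeric matrix, regions x subjects, mean SUV per region
#'   following the same subject order.
#' @slot regionIds integer vector of region labels for the rows.
#'
#' @seealso [sequenceCohort()], [roiCscn()], [voxelwiseCscn()]
#' @export
setClass("SequencedCohort",
         representation(subjectIds = "character",
                        ordering = "data.frame",
                        roiMeans = "matrix",
                        regionIds = "integer"))

setValidity("SequencedCohort", function(object) {
  msg <- character()
  if (ncol(object@roiMeans) != length(object@subjectIds))
    msg <- c(msg, "roiMeans columns must match subjectIds")
  if (nrow(object@roiMeans) != length(object@regionIds))
    msg <- c(msg, "roiMeans rows must match regionIds")
  if (!is.null(object@ordering$stage_numeric) &&
      is.unsorted(object@ordering$stage_numeric))
    msg <- c(msg, "ordering must be non-decreasing in King's stage")
  if (length(msg)) msg else TRUE
})

#' GcMap: a voxelwise seed-based causal covariance map
#'
#' Signed-path-coefficient Granger causality from a seed region's mean-SUV
#' series to every in-mask voxel, with its z-score transform (in-mask mean
#' 0, SD 1 over non-degenerate voxels) and FDR-adjusted two-tailed normal
#' p-values.
#'
#' @slot seedRegionId integer, the seed region label.
#' @slot gc 3D numeric array of signed GC coefficients (0 outside mask).
#' @slot z 3D numeric array of z-scores.
#' @slot q 3D numeric array of FDR-adjusted p-values (NA outside mask).
#' @slot mask 3D logical array of analyzed voxels.
#' @slot degenerate 3D logical array flagging constant voxel series.
#'
#' @seealso [voxelwiseCscn()]
#' @export
setClass("GcMap",
         representation(seedRegionId = "integer",
                        gc = "array",
                        z = "array",
                        q = "array",
                        mask = "array",
                        degenerate = "array"))

setValidity("GcMap", function(object) {
  msg <- character()
  dims <- dim(object@gc)
  for (s in c("z", "q", "mask", "degenerate"))
    if (!identical(dim(slot(object, s)), dims))
      msg <- c(msg, sprintf("slot '%s' must match gc dimensions", s))
  ok <- object@mask & !object@degenerate
  zz <- object@z[ok]
  if (length(zz) > 1L &&
      (abs(mean(zz)) > 1e-6 || abs(stats::sd(zz) - 1) > 1e-6))
    msg <- c(msg, "z must have in-mask mean 0 and SD 1")
  if (length(msg)) msg else TRUE
})

#' CausalMatrix: a directed ROI-to-ROI causal covariance network
#'
#' Region-by-region signed Granger causality coefficients (rows = sources,
#' columns = targets, zero diagonal), the binary network after applying the
#' GC threshold, and the binary out- and in-degrees.
#'
#' @slot regionIds integer vector of region labels.
#' @slot gc numeric matrix of signed GC coefficients.
#' @slot binary integer matrix, 1 where \code{gc > threshold}.
#' @slot threshold numeric scalar used for binarization.
#' @slot outDegree integer vector, row sums of \code{binary}.
#' @slot inDegree integer vector, column sums of \code{binary}.
#'
#' @seealso [roiCscn()], [extractPathways()]
#' @export
setClass("CausalMatrix",
         representation(regionIds = "integer",
                        gc = "matrix",
                        binary = "matrix",
                        threshold = "numeric",
                        outDegree = "integer",
                        inDegree = "integer"))

setValidity("CausalMatrix", function(object) {
  msg <- character()
  R <- length(object@regionIds)
  if (!all(dim(object@gc) == R) || !all(dim(object@binary) == R))
    msg <- c(msg, "gc and binary must be RxR for R regions")
  if (any(diag(object@gc) != 0)) msg <- c(msg, "gc diagonal must be 0")
  if (!identical(as.integer(rowSums(object@binary)), object@outDegree))
    msg <- c(msg, "outDegree must equal row sums of binary")
  if (!identical(as.integer(colSums(object@binary)), object@inDegree))
    msg <- c(msg, "inDegree must equal column sums of binary")
  if (!identical(unname(object@binary > 0),
                 unname(object@gc > object@threshold)))
    msg <- c(msg, "binary must equal gc > threshold")
  if (length(msg)) msg else TRUE
})
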