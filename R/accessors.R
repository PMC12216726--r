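#' Accessors for synconn classes
#'
#' Small accessor generics so that downstream code never reaches into
#' slots directly: subject identity, the SUV grid, the brain mask, voxel
#' geometry, region tables and matrix values.
#'
#' @param object a synconn S4 object.
#' @return The corresponding component; see individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("subjectId", function(object) standardGeneric("subjectId"))
#' @rdname accessors
#' @export
setGeneric("suvData", function(object) standardGeneric("suvData"))
#' @rdname accessors
#' @export
setGeneric("brainMask", function(object) standardGeneric("brainMask"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("regionTable", function(object) standardGeneric("regionTable"))
#' @rdname accessors
#' @export
setGeneric("regionLabels", function(object) standardGeneric("regionLabels"))
#' @rdname accessors
#' @export
setGeneric("regionIds", function(object) standardGeneric("regionIds"))
#' @rdname accessors
#' @export
setGeneric("similarityValues", function(object) standardGeneric("similarityValues"))
#' @rdname accessors
#' @export
setGeneric("gcValues", function(object) standardGeneric("gcValues"))
#' @rdname accessors
#' @export
setGeneric("binaryNetwork", function(object) standardGeneric("binaryNetwork"))
#' @rdname accessors
#' @export
setGeneric("outDegree", function(object) standardGeneric("outDegree"))
#' @rdname accessors
#' @export
setGeneric("inDegree", function(object) standardGeneric("inDegree"))
#' @rdname accessors
#' @export
setGeneric("zMap", function(object) standardGeneric("zMap"))
#' @rdname accessors
#' @export
setGeneric("qMap", function(object) standardGeneric("qMap"))
#' @rdname accessors
#' @export
setGeneric("cohortOrdering", function(object) standardGeneric("cohortOrdering"))
#' @rdname accessors
#' @export
setGeneric("roiMeans", function(object) standardGeneric("roiMeans"))

#' @rdname accessors
#' @export
setMethod("subjectId", "SuvVolume", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("subjectId", "SimilarityMatrix", function(object) object@subjectId)
#' @rdname accessors
#' @export
setMethod("suvData", "SuvVolume", function(object) object@suv)
#' @rdname accessors
#' @export
setMethod("brainMask", "SuvVolume", function(object) object@mask)
#' @rdname accessors
#' @export
setMethod("voxelSize", "SuvVolume", function(object) object@voxelSize)
#' @rdname accessors
#' @export
setMethod("regionTable", "Parcellation", function(object) object@regions)
#' @rdname accessors
#' @export
setMethod("regionLabels", "Parcellation", function(object) object@labels)
#' @rdname accessors
#' @export
setMethod("regionIds", "SimilarityMatrix", function(object) object@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "CausalMatrix", function(object) object@regionIds)
#' @rdname accessors
#' @export
setMethod("regionIds", "SequencedCohort", function(object) object@regionIds)
#' @rdname accessors
#' @export
setMethod("similarityValues", "SimilarityMatrix", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("gcValues", "CausalMatrix", function(object) object@gc)
#' @rdname accessors
#' @export
setMethod("gcValues", "GcMap", function(object) object@gc)
#' @rdname accessors
#' @export
setMethod("binaryNetwork", "CausalMatrix", function(object) object@binary)
#' @rdname accessors
#' @export
setMethod("outDegree", "CausalMatrix", function(object) object@outDegree)
#' @rdname accessors
#' @export
setMethod("inDegree", "CausalMatrix", function(object) object@inDegree)
#' @rdname accessors
#' @export
setMethod("zMap", "GcMap", function(object) object@z)
#' @rdname accessors
#' @export
setMethod("qMap", "GcMap", function(object) object@q)
#' @rdname accessors
#' @export
setMethod("subjectId", "SequencedCohort", function(object) object@subjectIds)
#' @rdname accessors
#' @export
setMethod("cohortOrdering", "SequencedCohort", function(object) object@ordering)
#' @rdname accessors
#' @export
setMethod("roiMeans", "SequencedCohort", function(object) object@roiMeans)

setMethod("show", "SuvVolume", function(object) {
  d <- dim(object@suv)
  cat(sprintf("SuvVolume '%s': %d x %d x %d voxels (%.3g x %.3g x %.3g mm), %d in mask\n",
              object@subjectId, d[1], d[2], d[3],
              object@voxelSize[1], object@voxelSize[2], object@voxelSize[3],
              sum(object@mask)))
  v <- object@suv[object@mask]
  if (length(v))
    cat(sprintf("  in-mask SUV: mean %.4g, range [%.4g, %.4g]\n",
                mean(v), min(v), max(v)))
})

setMethod("show", "Parcellation", function(object) {
  d <- dim(object@labels)
  cat(sprintf("Parcellation: %d regions on a %d x %d x %d grid\n",
              nrow(object@regions), d[1], d[2], d[3]))
  tab <- table(object@regions$lobe_group)
  cat("  lobe groups:", paste(sprintf("%s(%d)", names(tab), tab), collapse = " "), "\n")
})

setMethod("show", "SimilarityMatrix", function(object) {
  off <- object@values[upper.tri(object@values)]
  cat(sprintf("SimilarityMatrix '%s': %d x %d KLS connectome\n",
              object@subjectId, nrow(object@values), ncol(object@values)))
  cat(sprintf("  off-diagonal KLS: median %.3f, range [%.3g, %.3g]\n",
              stats::median(off), min(off), max(off)))
})

setMethod("show", "SequencedCohort", function(object) {
  cat(sprintf("SequencedCohort: %d subjects, %d regions\n",
              length(object@subjectIds), length(object@regionIds)))
  cat("  stage order:", paste(object@ordering$kings_stage, collapse = " "), "\n")
})

setMethod("show", "GcMap", function(object) {
  ok <- object@mask & !object@degenerate
  cat(sprintf("GcMap (seed region %d): %d in-mask voxels (%d degenerate)\n",
              object@seedRegionId, sum(object@mask), sum(object@degenerate)))
  if (any(ok))
    cat(sprintf("  GC range [%.3g, %.3g]; %d voxels with q < 0.01\n",
                min(object@gc[ok]), max(object@gc[ok]),
                sum(object@q[ok] < 0.01, na.rm = TRUE)))
})

setMethod("show", "CausalMatrix", function(object) {
  cat(sprintf("CausalMatrix: %d regions, GC threshold %.3g, %d directed edges\n",
              length(object@regionIds), object@threshold, sum(object@binary)))
})
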