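#' Configuration for an end-to-end pipeline run
#'
#' Two input modes: simulate a cohort from a [cohortConfig()] (default),
#' or load a cohort previously written by [writeCohort()] from
#' \code{input_dir}. Referenced paths are validated here, before any
#' computation starts.
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort_config a [cohortConfig()] used when simulating.
#' @param input_dir optional directory holding \code{*_suv.nii.gz}
#'   volumes, \code{atlas_labels.nii.gz}, \code{atlas_regions.csv} and
#'   \code{subjects.csv}.
#' @param n_points KDE sampling points (default 1024).
#' @param density_list connection densities for the degree profiles
#'   (default 50-100\% in 10\% steps).
#' @param fdr_q_edges edgewise significance threshold (default 0.01).
#' @param fdr_q_regions regional significance threshold (default 0.05).
#' @param gc_threshold ROI GC binarization threshold (default 0.82).
#' @param seed_region name of the causal seed region (default
#'   \code{"Medulla_R"}).
#' @return A validated list of class \code{"PipelineConfig"}.
#' @export
pipelineConfig <- function(out_dir,
                           cohort_config = cohortConfig(),
                           input_dir = NULL,
                           n_points = 1024L,
                           density_list = seq(0.5, 1, by = 0.1),
                           fdr_q_edges = 0.01,
                           fdr_q_regions = 0.05,
                           gc_threshold = 0.82,
                           seed_region = "Medulla_R") {
  if (missing(out_dir)) stop("out_dir is required")
  for (q in c(fdr_q_edges, fdr_q_regions))
    if (q <= 0 || q >= 1) stop("FDR thresholds must lie in (0, 1)")
  if (gc_threshold <= 0) stop("gc_threshold must be positive")
  if (!is.null(input_dir)) {
    need <- file.path(input_dir, c("atlas_labels.nii.gz",
                                   "atlas_regions.csv", "subjects.csv"))
    miss <- need[!file.exists(need)]
    if (length(miss))
      stop("input_dir is missing required files: ",
           paste(basename(miss), collapse = ", "))
  } else stopifnot(inherits(cohort_config, "CohortConfig"))
  structure(list(out_dir = out_dir, cohort_config = cohort_config,
                 input_dir = input_dir, n_points = as.integer(n_points),
                 density_list = density_list,
                 fdr_q_edges = fdr_q_edges, fdr_q_regions = fdr_q_regions,
                 gc_threshold = gc_threshold, seed_region = seed_region),
            class = "PipelineConfig")
}

.load_cohort_dir <- function(dir) {
  atlas <- readParcellation(file.path(dir, "atlas_labels.nii.gz"),
                            file.path(dir, "atlas_regions.csv"))
  subjects <- utils::read.csv(file.path(dir, "subjects.csv"),
                              stringsAsFactors = FALSE)
  vols <- lapply(subjects$subject_id, function(id)
    readSuvVolume(file.path(dir, paste0(id, "_suv.nii.gz")), subjectId = id))
  list(volumes = vols, subjects = subjects, atlas = atlas, truth = NULL)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: cohort simulation (or loading), proportional
#' scaling, per-subject KLS connectome construction, edgewise and
#' regional group statistics, nodal degree profiles, the voxelwise
#' seed-based causal covariance map and the ROI-to-ROI causal network
#' with pathway extraction. Every stage writes its artifact under
#' \code{out_dir} and the run closes with a JSON manifest (configuration,
#' package version, per-stage summaries and md5 checksums of all outputs)
#' sufficient to reproduce the run byte for byte with the same seed.
#'
#' @param config a [pipelineConfig()].
#' @return The manifest, invisibly (also written to
#'   \code{out_dir/manifest.json}).
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  step <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    stages[[name]] <<- res
    res
  }

  ## stage 1: cohort
  cohort <- step("cohort", function() {
    if (is.null(config$input_dir)) {
      co <- generateCohort(config$cohort_config)
      writeCohort(co, file.path(out, "cohort"))
      co
    } else .load_cohort_dir(config$input_dir)
  })
  subjects <- cohort$subjects
  atlas <- cohort$atlas
  scaled <- step("scaling", function()
    lapply(cohort$volumes, proportionalScale))
  grp <- subjects$group
  vols_als <- scaled[grp == "ALS"]
  vols_hc <- scaled[grp == "HC"]

  ## stage 2: connectomes
  mats <- step("connectome", function() {
    m <- lapply(scaled, buildConnectome, parc = atlas,
                n_points = config$n_points)
    dir.create(file.path(out, "connectomes"), showWarnings = FALSE)
    for (sm in m)
      utils::write.csv(sm@values,
                       file.path(out, "connectomes",
                                 paste0(sm@subjectId, "_kls.csv")),
                       row.names = FALSE)
    m
  })
  mats_als <- mats[grp == "ALS"]
  mats_hc <- mats[grp == "HC"]

  ## stage 3: group statistics
  edge_stats <- step("edge_stats", function() {
    es <- edgewiseTTest(mats_als, mats_hc, q_threshold = config$fdr_q_edges)
    utils::write.csv(es, file.path(out, "edge_stats.csv"), row.names = FALSE)
    es
  })
  step("degree_profiles", function() {
    R <- length(mats[[1]]@regionIds)
    sig <- matrix(0, R, R)
    ix <- cbind(match(edge_stats$region_i, mats[[1]]@regionIds),
                match(edge_stats$region_j, mats[[1]]@regionIds))
    sig[ix[edge_stats$significant, , drop = FALSE]] <- 1
    sig <- sig + t(sig)
    prof <- nodalDegree(sig, mode = "significance")
    prof$name <- atlas@regions$name[match(prof$region_id,
                                          atlas@regions$region_id)]
    utils::write.csv(prof, file.path(out, "degree_significance.csv"),
                     row.names = FALSE)
    dens <- do.call(rbind, lapply(config$density_list, function(d) {
      avg <- Reduce(`+`, lapply(mats_als, similarityValues)) /
        length(mats_als)
      p <- nodalDegree(avg, density_level = d)
      p$density_level <- d
      p
    }))
    utils::write.csv(dens, file.path(out, "degree_by_density.csv"),
                     row.names = FALSE)
    prof
  })
  step("regional_stats", function() {
    rs <- regionalDensityTTest(vols_als, vols_hc, atlas,
                               q_threshold = config$fdr_q_regions)
    utils::write.csv(rs, file.path(out, "regional_stats.csv"),
                     row.names = FALSE)
    rs
  })

  ## stage 4: causal covariance networks
  seq_cohort <- step("sequencing", function()
    sequenceCohort(subjects, scaled, atlas))
  seed_id <- atlas@regions$region_id[atlas@regions$name == config$seed_region]
  if (length(seed_id) != 1L)
    stop("seed region '", config$seed_region, "' not found in the atlas")
  step("cscn_voxel", function() {
    gm <- voxelwiseCscn(seq_cohort, scaled, seed_id)
    for (nm in c("gc", "z")) {
      img <- RNifti::asNifti(slot(gm, nm),
                             list(pixdim = c(1, scaled[[1]]@voxelSize,
                                             1, 1, 1, 1)),
                             datatype = "double")
      RNifti::writeNifti(img, file.path(out, paste0("cscn_", nm, ".nii.gz")),
                         datatype = "double")
    }
    vox <- which(gm@mask)
    utils::write.csv(data.frame(voxel = vox, gc = gm@gc[vox], z = gm@z[vox],
                                q = gm@q[vox]),
                     file.path(out, "cscn_voxel_table.csv"),
                     row.names = FALSE)
    gm
  })
  cm <- step("cscn_roi", function() {
    cm <- roiCscn(seq_cohort, threshold = config$gc_threshold)
    utils::write.csv(cm@gc, file.path(out, "cscn_roi_gc.csv"),
                     row.names = FALSE)
    utils::write.csv(cm@binary, file.path(out, "cscn_roi_binary.csv"),
                     row.names = FALSE)
    utils::write.csv(data.frame(region_id = cm@regionIds,
                                name = atlas@regions$name[
                                  match(cm@regionIds,
                                        atlas@regions$region_id)],
                                out_degree = cm@outDegree,
                                in_degree = cm@inDegree),
                     file.path(out, "cscn_roi_degrees.csv"),
                     row.names = FALSE)
    el <- which(cm@binary == 1, arr.ind = TRUE)
    utils::write.csv(data.frame(source = cm@regionIds[el[, 1]],
                                target = cm@regionIds[el[, 2]],
                                gc = cm@gc[el]),
                     file.path(out, "cscn_roi_edges.csv"), row.names = FALSE)
    cm
  })
  step("pathways", function() {
    gmap <- if (!is.null(cohort$truth))
      data.frame(region_id = cohort$truth$affected_regions$region_id,
                 group = cohort$truth$affected_regions$group)
    else NULL
    pw <- extractPathways(cm, seed_id, gmap)
    utils::write.csv(pw, file.path(out, "pathways.csv"), row.names = FALSE)
    pw
  })

  ## manifest
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("synconn")),
    r_version = R.version.string,
    config = config[setdiff(names(config), "cohort_config")],
    cohort_config = if (is.null(config$input_dir))
      unclass(config$cohort_config) else NULL,
    stage_summaries = list(
      n_subjects = length(scaled),
      n_regions = length(mats[[1]]@regionIds),
      n_significant_edges = sum(edge_stats$significant),
      n_causal_edges = sum(cm@binary),
      stages_complete = names(stages)),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        sub(paste0(out, "/?"), "", files))))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}
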