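#' Sequence ALS subjects by King's stage for causal covariance analysis
#'
#' Orders the ALS subjects from low to high King's stage to form the
#' pseudo-temporal axis of the causal synaptic covariance network. Ties
#' are broken deterministically by a/b sub-stage, then disease duration
#' (ascending), then ALSFRS-R (descending), then subject id. Subjects
#' without a valid stage are excluded with a warning. The full ordering
#' is recorded for audit.
#'
#' @param subjects data.frame with columns \code{subject_id},
#'   \code{group}, \code{kings_stage} (e.g. \code{"2b"}),
#'   \code{duration_months}, \code{alsfrs_r}.
#' @param volumes list of [SuvVolume-class]; matched to rows of
#'   \code{subjects} by subject id.
#' @param parc a [Parcellation-class] used to form per-region mean-SUV
#'   series.
#' @return A [SequencedCohort-class].
#' @export
sequenceCohort <- function(subjects, volumes, parc) {
  als <- subjects[subjects$group == "ALS", , drop = FALSE]
  bad <- is.na(als$kings_stage) |
    !(.stage_numeric(als$kings_stage) %in% 1:5)
  if (any(bad)) {
    warning("excluding ", sum(bad), " ALS subject(s) without a valid ",
            "King's stage: ", paste(als$subject_id[bad], collapse = ", "))
    als <- als[!bad, , drop = FALSE]
  }
  if (nrow(als) < 4L)
    stop("need >= 4 ALS subjects with a valid King's stage")
  als <- als[.sequence_order(als), , drop = FALSE]
  vol_ids <- vapply(volumes, subjectId, character(1))
  idx <- match(als$subject_id, vol_ids)
  if (anyNA(idx))
    stop("missing volumes for: ",
         paste(als$subject_id[is.na(idx)], collapse = ", "))
  rm_mat <- .roi_mean_matrix(volumes[idx], parc)
  ordering <- data.frame(subject_id = als$subject_id,
                         kings_stage = als$kings_stage,
                         stage_numeric = .stage_numeric(als$kings_stage),
                         sub_rank = .stage_subrank(als$kings_stage),
                         duration_months = als$duration_months,
                         alsfrs_r = als$alsfrs_r,
                         row.names = NULL)
  new("SequencedCohort", subjectIds = als$subject_id, ordering = ordering,
      roiMeans = rm_mat, regionIds = as.integer(rownames(rm_mat)))
}

# Standardize a series to mean 0 / SD 1; a constant series comes back as
# zeros with the "degenerate" attribute set.
.standardize <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0)
    return(structure(rep(0, length(x)), degenerate = TRUE))
  structure((x - mean(x)) / s, degenerate = FALSE)
}

#' Signed-path-coefficient Granger causality between two ordered series
#'
#' Standardizes both series to mean 0 / SD 1, then fits by least squares
#' \deqn{y_t = \beta_0 + \sum_{l=1}^{k} \alpha_l y_{t-l} +
#'       \sum_{l=1}^{k} \beta_l x_{t-l} + \epsilon_t}
#' and returns the signed path coefficient for the influence of x on y:
#' \eqn{\beta_1} for model order 1, the sum of the x-lag coefficients for
#' higher orders. Constant or collinear series yield 0 with the
#' \code{"degenerate"} attribute set.
#'
#' @param x,y numeric series of equal length, ordered along the
#'   pseudo-temporal axis; length must be at least \code{order + 3}.
#' @param order autoregressive model order (default 1).
#' @return The signed path coefficient, with attribute
#'   \code{"degenerate"}.
#' @export
signedPathGC <- function(x, y, order = 1L) {
  order <- as.integer(order)
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (order < 1L) stop("order must be >= 1")
  if (length(y) < order + 3L)
    stop("series too short: need length >= order + 3")
  xs <- .standardize(x); ys <- .standardize(y)
  if (attr(xs, "degenerate") || attr(ys, "degenerate"))
    return(structure(0, degenerate = TRUE))
  n <- length(ys)
  rows <- (order + 1L):n
  ylags <- sapply(seq_len(order), function(l) ys[rows - l])
  xlags <- sapply(seq_len(order), function(l) xs[rows - l])
  X <- cbind(1, ylags, xlags)
  qx <- qr(X)
  if (qx$rank < ncol(X)) return(structure(0, degenerate = TRUE))
  beta <- qr.coef(qx, ys[rows])
  structure(sum(beta[(order + 2L):(2L * order + 1L)]), degenerate = FALSE)
}

# Order-1 GC matrix over all ordered region pairs, vectorized by
# residualizing on each target's own lag (algebraically identical to the
# per-pair OLS coefficient of signedPathGC).
.gc_matrix_order1 <- function(S) {
  R <- nrow(S); n <- ncol(S)
  Z <- t(apply(S, 1, function(r) as.numeric(.standardize(r))))
  degenerate <- apply(S, 1, function(r) isTRUE(attr(.standardize(r), "degenerate")))
  G <- matrix(0, R, R)
  X1 <- Z[, 1:(n - 1), drop = FALSE]
  for (j in seq_len(R)) {
    if (degenerate[j]) next
    y <- Z[j, 2:n]; ylag <- Z[j, 1:(n - 1)]
    qy <- qr(cbind(1, ylag))
    ry <- qr.resid(qy, y)
    RX <- t(qr.resid(qy, t(X1)))
    d <- rowSums(RX^2)
    b <- as.vector(RX %*% ry) / ifelse(d > 1e-12, d, Inf)
    b[degenerate] <- 0
    b[j] <- 0
    G[, j] <- b
  }
  G
}

#' ROI-to-ROI causal synaptic covariance network
#'
#' Computes the signed-path-coefficient Granger causality from every
#' region's stage-ordered mean-SUV series to every other region's,
#' binarizes at \code{gc > threshold}, and summarizes the directed
#' structure as binary out- and in-degrees. A region with high out-degree
#' acts as a Granger-causal source; high in-degree marks a causal target.
#'
#' @param cohort a [SequencedCohort-class].
#' @param threshold GC binarization threshold (default 0.82).
#' @param order autoregressive model order (default 1).
#' @return A [CausalMatrix-class].
#' @export
roiCscn <- function(cohort, threshold = 0.82, order = 1L) {
  stopifnot(is(cohort, "SequencedCohort"))
  S <- cohort@roiMeans
  if (nrow(S) < 2L) stop("need >= 2 regions")
  if (anyNA(S)) stop("roiMeans contains NA (dropped regions?)")
  if (order == 1L) {
    G <- .gc_matrix_order1(S)
  } else {
    R <- nrow(S)
    G <- matrix(0, R, R)
    for (i in seq_len(R)) for (j in seq_len(R))
      if (i != j) G[i, j] <- as.numeric(signedPathGC(S[i, ], S[j, ], order))
  }
  B <- matrix(as.integer(G > threshold), nrow(G))
  new("CausalMatrix", regionIds = cohort@regionIds, gc = G,
      binary = B, threshold = threshold,
      outDegree = as.integer(rowSums(B)),
      inDegree = as.integer(colSums(B)))
}

#' Voxelwise seed-based causal synaptic covariance map
#'
#' Takes the seed region's stage-ordered mean-SUV series as the source
#' and, for every in-mask voxel, fits the order-1 signed-path Granger
#' model from seed to voxel (only the seed-to-voxel direction is
#' computed). The resulting GC map is z-score transformed over the
#' non-degenerate in-mask voxels (mean 0, SD 1), two-tailed standard
#' normal p-values are attached and BH-FDR adjusted.
#'
#' @param cohort a [SequencedCohort-class].
#' @param volumes list of [SuvVolume-class] containing (at least) the
#'   sequenced subjects.
#' @param seed_region_id integer label of the seed region.
#' @param mask optional logical array of voxels to analyze; defaults to
#'   the intersection of the subjects' brain masks.
#' @return A [GcMap-class].
#' @export
voxelwiseCscn <- function(cohort, volumes, seed_region_id, mask = NULL) {
  stopifnot(is(cohort, "SequencedCohort"))
  if (!(seed_region_id %in% cohort@regionIds))
    stop("seed region ", seed_region_id, " not present in the cohort")
  vol_ids <- vapply(volumes, subjectId, character(1))
  idx <- match(cohort@subjectIds, vol_ids)
  if (anyNA(idx))
    stop("missing volumes for sequenced subjects")
  vols <- volumes[idx]
  dims <- dim(vols[[1]]@suv)
  if (is.null(mask)) {
    mask <- array(TRUE, dims)
    for (v in vols) mask <- mask & v@mask
  }
  n <- length(vols)
  x <- as.numeric(.standardize(cohort@roiMeans[
    match(seed_region_id, cohort@regionIds), ]))
  V <- sum(mask)
  Y <- matrix(NA_real_, n, V)
  for (t in seq_len(n)) Y[t, ] <- vols[[t]]@suv[mask]
  mu <- colMeans(Y); sdv <- sqrt(colMeans((Y - rep(mu, each = n))^2) * n / (n - 1))
  degen <- !(sdv > 0) | abs(x[1]) + stats::sd(x) == 0
  Z <- (Y - rep(mu, each = n)) / rep(ifelse(sdv > 0, sdv, 1), each = n)
  ## per-voxel OLS of y_t on [1, y_{t-1}, x_{t-1}] via vectorized 3x3 solve
  y2 <- Z[2:n, , drop = FALSE]; y1 <- Z[1:(n - 1), , drop = FALSE]
  x1 <- x[1:(n - 1)]
  m <- n - 1
  a12 <- colSums(y1); a13 <- sum(x1)
  a22 <- colSums(y1^2); a23 <- colSums(y1 * x1); a33 <- sum(x1^2)
  b1 <- colSums(y2); b2 <- colSums(y1 * y2); b3 <- colSums(x1 * y2)
  det <- m * (a22 * a33 - a23^2) - a12 * (a12 * a33 - a23 * a13) +
    a13 * (a12 * a23 - a22 * a13)
  ## Cramer's rule for the x-lag coefficient (third column)
  det3 <- m * (a22 * b3 - a23 * b2) - a12 * (a12 * b3 - a23 * b1) +
    a13 * (a12 * b2 - a22 * b1)
  gc_v <- ifelse(abs(det) > 1e-10, det3 / det, 0)
  degen <- degen | !(abs(det) > 1e-10)
  gc_v[degen] <- 0
  ok <- !degen
  z_v <- rep(0, V); q_v <- rep(NA_real_, V)
  if (sum(ok) > 1L) {
    z_v[ok] <- (gc_v[ok] - mean(gc_v[ok])) / stats::sd(gc_v[ok])
    q_v[ok] <- bhFdr(2 * stats::pnorm(-abs(z_v[ok])))
  }
  mk <- function(vals, fill = 0) { a <- array(fill, dims); a[mask] <- vals; a }
  new("GcMap", seedRegionId = as.integer(seed_region_id),
      gc = mk(gc_v), z = mk(z_v), q = mk(q_v, NA_real_),
      mask = mask, degenerate = mk(degen, FALSE) == 1)
}

#' Extract directed causal pathways from a binary causal network
#'
#' Enumerates the simple directed paths of length one and two leaving a
#' source region in the thresholded causal network: direct edges
#' \code{source -> to}, and mediated routes \code{source -> via -> to}.
#' Regions can be annotated with groups (e.g. striatum, neocortex) so the
#' output reads as schematic pathway motifs.
#'
#' @param cm a [CausalMatrix-class].
#' @param source_region integer label of the source region.
#' @param group_map optional data.frame with columns \code{region_id} and
#'   \code{group} used to annotate path endpoints.
#' @return data.frame with columns \code{from}, \code{via} (NA for direct
#'   edges), \code{to}, and, when \code{group_map} is given,
#'   \code{via_group} and \code{to_group}.
#' @export
extractPathways <- function(cm, source_region, group_map = NULL) {
  stopifnot(is(cm, "CausalMatrix"))
  ids <- cm@regionIds
  s <- match(source_region, ids)
  if (is.na(s)) stop("source region not in the network")
  B <- cm@binary
  direct <- which(B[s, ] == 1)
  paths <- if (length(direct))
    data.frame(from = source_region, via = NA_integer_, to = ids[direct])
  else
    data.frame(from = integer(), via = integer(), to = integer())
  for (vtx in direct) {
    nxt <- which(B[vtx, ] == 1)
    nxt <- nxt[nxt != s]
    if (length(nxt))
      paths <- rbind(paths, data.frame(from = source_region,
                                       via = ids[vtx], to = ids[nxt]))
  }
  if (!is.null(group_map) && nrow(paths)) {
    paths$via_group <- group_map$group[match(paths$via, group_map$region_id)]
    paths$to_group <- group_map$group[match(paths$to, group_map$region_id)]
  }
  rownames(paths) <- NULL
  paths
}

#' Audit the causal network's stability under stage-tie permutations
#'
#' The ordering of subjects who share the same King's stage is a
#' convention. This audit re-runs the ROI-to-ROI causal network over
#' random permutations of subjects within tied (stage, sub-stage) blocks
#' and reports the seed region's out- and in-degree for each permutation.
#'
#' @param cohort a [SequencedCohort-class].
#' @param seed_region_id region whose degrees are tracked.
#' @param n_perm number of random tie permutations (default 20).
#' @param threshold GC threshold (default 0.82).
#' @param rng_seed RNG seed for the permutations.
#' @return data.frame with one row per permutation: \code{out_degree},
#'   \code{in_degree} of the seed region.
#' @export
tieOrderingAudit <- function(cohort, seed_region_id, n_perm = 20L,
                             threshold = 0.82, rng_seed = 1L) {
  stopifnot(is(cohort, "SequencedCohort"))
  si <- match(seed_region_id, cohort@regionIds)
  if (is.na(si)) stop("seed region not in the cohort")
  key <- paste(cohort@ordering$stage_numeric, cohort@ordering$sub_rank)
  .with_seed(rng_seed, {
    res <- lapply(seq_len(n_perm), function(p) {
      perm <- unlist(lapply(split(seq_along(key), factor(key, unique(key))),
                            function(ix) ix[sample.int(length(ix))]),
                     use.names = FALSE)
      cm <- roiCscn(initialize(cohort,
                               subjectIds = cohort@subjectIds[perm],
                               ordering = cohort@ordering[perm, ],
                               roiMeans = cohort@roiMeans[, perm]),
                    threshold = threshold)
      data.frame(out_degree = cm@outDegree[si], in_degree = cm@inDegree[si])
    })
    do.call(rbind, res)
  })
}
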