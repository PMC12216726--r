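#' Kernel density estimate of an ROI intensity distribution
#'
#' Gaussian-kernel KDE of a region's SUV voxel sample, evaluated on
#' \code{n_points} equally spaced points over \code{[grid_lo, grid_hi]},
#' floored at a small epsilon (no exact zeros can enter a logarithm) and
#' renormalized to sum to 1. The bandwidth is Silverman's rule of thumb
#' ([stats::bw.nrd0()]); a zero-variance sample falls back to a bandwidth
#' of \code{1e-3 * (grid_hi - grid_lo)} so the estimate is always defined.
#'
#' @param sample numeric vector of at least 2 finite SUV values.
#' @param n_points number of evaluation points (>= 16; default 1024).
#' @param grid_lo,grid_hi grid range, \code{grid_lo < grid_hi}.
#' @param bw optional bandwidth override (positive number).
#' @param eps probability floor (default 1e-12).
#' @return A \code{DensityEstimate}: list with \code{grid}, \code{probs},
#'   \code{bw}; \code{probs} are positive and sum to 1.
#' @export
estimateDensity <- function(sample, n_points = 1024L, grid_lo, grid_hi,
                            bw = NULL, eps = 1e-12) {
  sample <- as.numeric(sample)
  if (length(sample) < 2L || any(!is.finite(sample)))
    stop("density estimation needs >= 2 finite sample values")
  if (!is.numeric(n_points) || n_points < 16L)
    stop("n_points must be at least 16")
  if (!is.finite(grid_lo) || !is.finite(grid_hi) || grid_lo >= grid_hi)
    stop("need grid_lo < grid_hi")
  if (is.null(bw)) {
    if (stats::sd(sample) == 0) {
      bw <- 1e-3 * (grid_hi - grid_lo)   # zero-variance fallback
    } else {
      bw <- tryCatch(stats::bw.nrd0(sample), error = function(e) 0)
      if (!is.finite(bw) || bw <= 0) bw <- 1e-3 * (grid_hi - grid_lo)
    }
  } else if (!is.finite(bw) || bw <= 0) stop("bw must be positive")
  grid <- seq(grid_lo, grid_hi, length.out = as.integer(n_points))
  d <- .rowMeans(stats::dnorm(outer(grid, sample, "-"), sd = bw),
                 length(grid), length(sample))
  d <- pmax(d, eps)
  structure(list(grid = grid, probs = d / sum(d), bw = bw),
            class = "DensityEstimate")
}

#' @export
print.DensityEstimate <- function(x, ...) {
  cat(sprintf("DensityEstimate: %d grid points on [%.4g, %.4g], bw = %.4g\n",
              length(x$grid), min(x$grid), max(x$grid), x$bw))
  invisible(x)
}

#' Symmetric Kullback-Leibler divergence between two discrete densities
#'
#' Computes \eqn{D(P,Q) = \sum_i P_i \log(P_i/Q_i) + Q_i \log(Q_i/P_i)}
#' with natural logarithms. Both densities must live on the same grid.
#' The result is non-negative and exactly symmetric in its arguments.
#'
#' @param p,q \code{DensityEstimate} objects (or lists with \code{grid}
#'   and \code{probs}) sharing an identical grid.
#' @return A non-negative number.
#' @export
symmetricKL <- function(p, q) {
  if (length(p$grid) != length(q$grid) || !isTRUE(all.equal(p$grid, q$grid)))
    stop("densities must share the same evaluation grid")
  if (any(p$probs <= 0) || any(q$probs <= 0))
    stop("probabilities must be strictly positive (apply the epsilon floor)")
  lr <- log(p$probs) - log(q$probs)
  sum(p$probs * lr - q$probs * lr)
}

#' Kullback-Leibler similarity score
#'
#' Maps a symmetric KL divergence into the similarity score
#' \eqn{KLS = e^{-D}}, a strictly decreasing function of the divergence
#' with values in (0, 1].
#'
#' @param d_kl non-negative divergence value(s).
#' @return \code{exp(-d_kl)}.
#' @export
klsScore <- function(d_kl) {
  if (any(!is.finite(d_kl)) || any(d_kl < 0))
    stop("d_kl must be finite and non-negative (KL divergence)")
  exp(-d_kl)
}

#' Build a per-subject synaptic density similarity connectome
#'
#' Estimates every region's SUV intensity density on one shared grid
#' spanning the full in-mask SUV range of the subject (so that all
#' pairwise comparisons use common support), then fills a symmetric
#' region-by-region matrix with KLS = exp(-D_KL) for every pair. The
#' diagonal is set to 1. Regions with fewer than 2 usable voxels are
#' dropped (with a warning) and the matrix shrinks accordingly.
#'
#' The volume is expected to be proportional-scaled ([proportionalScale()]);
#' the connectome itself is invariant to global rescaling, so this only
#' standardizes the grid range across subjects.
#'
#' @param vol a [SuvVolume-class].
#' @param parc a [Parcellation-class] on the same grid.
#' @param n_points KDE evaluation points (default 1024).
#' @return A [SimilarityMatrix-class].
#' @export
buildConnectome <- function(vol, parc, n_points = 1024L) {
  samples <- extractRoiSamples(vol, parc)
  R <- length(samples)
  if (R < 2L) stop("need at least 2 usable regions to build a connectome")
  inmask <- vol@suv[vol@mask]
  lo <- min(inmask); hi <- max(inmask)
  if (lo == hi) { lo <- lo - 0.5; hi <- hi + 0.5 }
  P <- matrix(NA_real_, R, as.integer(n_points))
  for (r in seq_len(R))
    P[r, ] <- estimateDensity(samples[[r]], n_points, lo, hi)$probs
  L <- log(P)
  C <- P %*% t(L)                       # C[i,j] = sum_k P_i log P_j
  S <- C + t(C)                         # exactly symmetric cross term
  D <- pmax(outer(diag(C), diag(C), "+") - S, 0)
  K <- pmin(exp(-D), 1)
  diag(K) <- 1
  new("SimilarityMatrix", subjectId = vol@subjectId,
      regionIds = as.integer(names(samples)), values = K)
}

#' Nodal degree at a connection density
#'
#' In \code{"density"} mode the top \code{density_level} fraction of
#' off-diagonal edges by weight is retained (ties broken deterministically
#' by descending weight then ascending region-pair index) and the
#' surviving edges attached to each node are counted. In
#' \code{"significance"} mode the input is already a binary adjacency
#' matrix and edges are counted directly.
#'
#' @param adjacency a square symmetric numeric matrix, or a
#'   [SimilarityMatrix-class].
#' @param density_level fraction of edges to retain, in (0, 1]; ignored in
#'   significance mode.
#' @param mode \code{"density"} or \code{"significance"}.
#' @return A data.frame with columns \code{region_id} and \code{degree};
#'   the retained edge count is in attribute \code{"n_edges"} and the mode
#'   and density in attributes \code{"mode"} and \code{"density_level"}.
#' @export
nodalDegree <- function(adjacency, density_level = 1,
                        mode = c("density", "significance")) {
  mode <- match.arg(mode)
  if (is(adjacency, "SimilarityMatrix")) {
    ids <- adjacency@regionIds
    A <- adjacency@values
  } else {
    A <- as.matrix(adjacency)
    ids <- if (!is.null(rownames(A))) suppressWarnings(as.integer(rownames(A)))
           else seq_len(nrow(A))
    if (anyNA(ids)) ids <- seq_len(nrow(A))
  }
  if (nrow(A) != ncol(A)) stop("adjacency must be square")
  R <- nrow(A)
  ut <- which(upper.tri(A))
  if (mode == "significance") {
    keep <- A[ut] != 0
  } else {
    if (!is.numeric(density_level) || density_level <= 0 || density_level > 1)
      stop("density_level must lie in (0, 1]")
    w <- A[ut]
    k <- floor(density_level * length(ut))
    ord <- order(-w, seq_along(w))      # stable: weight desc, pair index asc
    keep <- logical(length(w))
    keep[ord[seq_len(k)]] <- TRUE
  }
  B <- matrix(0L, R, R)
  B[ut[keep]] <- 1L
  B <- B + t(B)
  out <- data.frame(region_id = ids, degree = as.integer(rowSums(B)))
  attr(out, "n_edges") <- sum(keep)
  attr(out, "mode") <- mode
  attr(out, "density_level") <- if (mode == "density") density_level else NA_real_
  out
}

# Threshold a symmetric weighted matrix at a connection density, zeroing
# the edges that are not retained (same tie-break as nodalDegree).
.threshold_density <- function(A, density_level) {
  ut <- which(upper.tri(A))
  w <- A[ut]
  k <- floor(density_level * length(ut))
  ord <- order(-w, seq_along(w))
  drop <- ord[-seq_len(k)]
  A[ut[drop]] <- 0
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  A
}

#' Stability sweep over KDE sampling points and connection densities
#'
#' Rebuilds the case-control edgewise difference pattern (Welch t values
#' over all edges) for every combination of KDE sampling points and
#' connection-density threshold, and reports the pairwise Pearson
#' correlations between the patterns of all settings. High correlations
#' indicate that the group-difference pattern does not depend on these
#' construction parameters.
#'
#' @param volumes_a,volumes_b lists of proportional-scaled
#'   [SuvVolume-class] objects for the two groups (e.g. ALS and HC).
#' @param parc a [Parcellation-class].
#' @param n_points_list KDE sampling-point settings
#'   (default \code{c(256, 512, 1024, 2048)}).
#' @param density_list connection densities (default 50-100\% in 10\%
#'   steps).
#' @return A list with \code{settings} (data.frame of the evaluated
#'   combinations), \code{patterns} (edges x settings matrix of t values),
#'   \code{correlations} (settings x settings), and
#'   \code{min_correlation}.
#' @export
sweepParameters <- function(volumes_a, volumes_b, parc,
                            n_points_list = c(256L, 512L, 1024L, 2048L),
                            density_list = seq(0.5, 1.0, by = 0.1)) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L)
    stop("need >= 2 subjects per group")
  settings <- expand.grid(n_points = n_points_list, density = density_list,
                          KEEP.OUT.ATTRS = FALSE)
  patterns <- NULL
  for (np in n_points_list) {
    mats_a <- lapply(volumes_a, buildConnectome, parc = parc, n_points = np)
    mats_b <- lapply(volumes_b, buildConnectome, parc = parc, n_points = np)
    for (dens in density_list) {
      ea <- vapply(mats_a, function(m)
        .threshold_density(m@values, dens)[upper.tri(m@values)],
        numeric(sum(upper.tri(mats_a[[1]]@values))))
      eb <- vapply(mats_b, function(m)
        .threshold_density(m@values, dens)[upper.tri(m@values)],
        numeric(nrow(ea)))
      tt <- .welch_rows(ea, eb)$t
      patterns <- cbind(patterns, tt)
    }
  }
  ## columns were filled density-within-n_points; reorder to match settings
  fill <- expand.grid(density = density_list, n_points = n_points_list,
                      KEEP.OUT.ATTRS = FALSE)
  key <- paste(settings$n_points, settings$density)
  patterns <- patterns[, match(key, paste(fill$n_points, fill$density)),
                       drop = FALSE]
  colnames(patterns) <- key
  cors <- stats::cor(patterns, use = "pairwise.complete.obs")
  list(settings = settings, patterns = patterns, correlations = cors,
       min_correlation = min(cors))
}
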