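# Vectorized Welch two-sample t over matrix rows (rows = features,
# columns = subjects). Zero standard error yields NA (undefined t).
.welch_rows <- function(X, Y) {
  nx <- ncol(X); ny <- ncol(Y)
  mx <- rowMeans(X); my <- rowMeans(Y)
  vx <- rowSums((X - mx)^2) / (nx - 1)
  vy <- rowSums((Y - my)^2) / (ny - 1)
  se2 <- vx / nx + vy / ny
  t <- ifelse(se2 > 0, (mx - my) / sqrt(se2), NA_real_)
  df <- se2^2 / ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(mean_x = mx, mean_y = my, t = t, df = df, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values (monotone, capped at 1) for a family of
#' p-values, via [stats::p.adjust()]. NA entries are passed through and do
#' not count towards the family size.
#'
#' @param p numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values of the same length.
#' @export
bhFdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Edgewise case-control comparison of KLS connectomes
#'
#' Welch two-sample t-test per off-diagonal edge (upper triangle) between
#' two groups of subject connectomes, with Benjamini-Hochberg FDR control
#' across all testable edges in a single family. Edges whose standard
#' error is zero are reported as NA and excluded from the FDR family.
#'
#' @param matrices_a,matrices_b lists of [SimilarityMatrix-class] for the
#'   two groups (a = cases, b = controls), all with identical region sets.
#' @param q_threshold significance threshold on the adjusted q-values
#'   (default 0.01).
#' @return A data.frame with one row per edge: \code{region_i},
#'   \code{region_j}, group means, \code{t}, \code{p}, \code{q},
#'   \code{direction} (\code{"decrease"} if cases < controls),
#'   \code{significant}.
#' @export
edgewiseTTest <- function(matrices_a, matrices_b, q_threshold = 0.01) {
  if (length(matrices_a) < 2L || length(matrices_b) < 2L)
    stop("need >= 2 subjects per group")
  ids <- matrices_a[[1]]@regionIds
  for (m in c(matrices_a, matrices_b))
    if (!identical(m@regionIds, ids))
      stop("all connectomes must share the same region set")
  R <- length(ids)
  ut <- which(upper.tri(matrix(0, R, R)))
  edges <- function(ms) vapply(ms, function(m) m@values[ut],
                               numeric(length(ut)))
  w <- .welch_rows(edges(matrices_a), edges(matrices_b))
  q <- bhFdr(w$p)
  ij <- arrayInd(ut, c(R, R))
  data.frame(region_i = ids[ij[, 1]], region_j = ids[ij[, 2]],
             mean_a = w$mean_x, mean_b = w$mean_y,
             t = w$t, p = w$p, q = q,
             direction = ifelse(w$t < 0, "decrease", "increase"),
             significant = !is.na(q) & q < q_threshold)
}

# Region x subject matrix of mean in-mask SUV per region.
.roi_mean_matrix <- function(volumes, parc) {
  ids <- parc@regions$region_id
  out <- vapply(volumes, function(v) {
    s <- extractRoiSamples(v, parc)
    m <- rep(NA_real_, length(ids))
    m[match(as.integer(names(s)), ids)] <- vapply(s, mean, numeric(1))
    m
  }, numeric(length(ids)))
  rownames(out) <- ids
  colnames(out) <- vapply(volumes, subjectId, character(1))
  out
}

#' Regional synaptic density comparison
#'
#' Per-region mean SUV per subject, then a Welch two-sample t-test per
#' region with BH-FDR correction. Intended for proportional-scaled
#' volumes, where reduced regional means reflect local synaptic loss.
#'
#' @param volumes_a,volumes_b lists of [SuvVolume-class] for cases and
#'   controls.
#' @param parc a [Parcellation-class].
#' @param q_threshold significance threshold on q (default 0.05).
#' @return A data.frame with one row per region: \code{region_id},
#'   \code{name}, group mean SUV, \code{t}, \code{p}, \code{q},
#'   \code{direction}, \code{significant}.
#' @export
regionalDensityTTest <- function(volumes_a, volumes_b, parc,
                                 q_threshold = 0.05) {
  if (length(volumes_a) < 2L || length(volumes_b) < 2L)
    stop("need >= 2 subjects per group")
  A <- .roi_mean_matrix(volumes_a, parc)
  B <- .roi_mean_matrix(volumes_b, parc)
  keep <- stats::complete.cases(A) & stats::complete.cases(B)
  w <- .welch_rows(A[keep, , drop = FALSE], B[keep, , drop = FALSE])
  q <- bhFdr(w$p)
  ids <- parc@regions$region_id[keep]
  data.frame(region_id = ids,
             name = parc@regions$name[keep],
             mean_a = w$mean_x, mean_b = w$mean_y,
             t = w$t, p = w$p, q = q,
             direction = ifelse(w$t < 0, "decrease", "increase"),
             significant = !is.na(q) & q < q_threshold,
             row.names = NULL)
}

#' Group comparison of demographics
#'
#' The three conventional tests for a two-group imaging study: Welch
#' two-sample t-test for age, chi-square independence test for sex (by
#' default without Yates continuity correction), and a Mann-Whitney
#' (Wilcoxon rank-sum) test for years of education.
#'
#' @param subjects data.frame with columns \code{group}, \code{age},
#'   \code{sex}, \code{education_years}.
#' @param correct logical; apply Yates continuity correction to the
#'   chi-square test (default \code{FALSE}).
#' @return A list with the three \code{htest} objects (\code{age},
#'   \code{sex}, \code{education}) and a \code{summary} data.frame of
#'   statistics and p-values.
#' @export
demographicsTests <- function(subjects, correct = FALSE) {
  grp <- factor(subjects$group)
  if (nlevels(grp) != 2L || any(table(grp) == 0))
    stop("need exactly two non-empty groups")
  age <- stats::t.test(age ~ grp, data = subjects)
  sex <- suppressWarnings(
    stats::chisq.test(table(grp, subjects$sex), correct = correct))
  edu <- suppressWarnings(
    stats::wilcox.test(education_years ~ grp, data = subjects))
  list(age = age, sex = sex, education = edu,
       summary = data.frame(
         variable = c("age", "sex", "education_years"),
         test = c("Welch t", if (correct) "chi-square (Yates)" else "chi-square",
                  "Mann-Whitney"),
         statistic = c(unname(age$statistic), unname(sex$statistic),
                       unname(edu$statistic)),
         p = c(age$p.value, sex$p.value, edu$p.value)))
}
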