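#' Fruit sizing from a segmented mask
#'
#' For a non-occluded fruit the diameter is simply the maximum distance
#' (MD) between contour pixels, but MD collapses as soon as part of the
#' fruit is hidden. The flattened silhouette of a paraguayo peach is
#' therefore modeled with an ellipse in *focal form* -- two foci and the
#' constant focal-distance sum 2a (the "string construction") -- fitted to
#' the contour pixels by nonlinear least squares. A first fit (F1) uses
#' every contour pixel; contour pixels whose relative residual exceeds a
#' threshold are rejected and the remaining pixels are refitted (F2).
#' Comparing the two major axis lengths (MAL-F1 vs MAL-F2) gives a rough
#' occlusion-range estimate: similar lengths mean no occlusion, a longer
#' F2 indicates occlusion up to 33\% (keep MAL-F1), a shorter F2 indicates
#' occlusion above 66\% (no usable diameter).
#'
#' @name fruit_geometry
NULL

#' Extract the contour of a single-component mask
#'
#' Contour pixels are foreground pixels with at least one 4-neighbor in
#' the background; pixels on the image border count as adjacent to
#' background.
#'
#' @param mask binary matrix with a single 8-connected component.
#' @return numeric matrix with columns `row`, `col` (1-based pixel
#'   centers), in row-major scan order.
#' @export
extract_contour <- function(mask) {
  m <- mask_to_logical(mask)
  if (!any(m)) stop("cannot extract a contour from an empty mask")
  h <- nrow(m); w <- ncol(m)
  interior <- shift_matrix(m, 1, 0, FALSE) & shift_matrix(m, -1, 0, FALSE) &
    shift_matrix(m, 0, 1, FALSE) & shift_matrix(m, 0, -1, FALSE)
  boundary <- m & !interior
  rows <- row(m)[boundary]; cols <- col(m)[boundary]
  ord <- order(rows, cols)
  cbind(row = as.numeric(rows[ord]), col = as.numeric(cols[ord]))
}

#' Maximum pairwise distance between contour pixels (MD)
#'
#' The diameter proxy for a non-occluded fruit: the largest Euclidean
#' distance between any two contour points. Computed on the convex hull
#' (the maximum pair always lies on it), which keeps the pair search cheap
#' for long contours.
#'
#' @param contour numeric matrix with columns (row, col), at least 2 points.
#' @return the maximum distance in pixels.
#' @export
max_pairwise_distance <- function(contour) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 2) stop("at least 2 contour points are required")
  hull <- unique(grDevices::chull(contour[, 2], contour[, 1]))
  pts <- contour[hull, , drop = FALSE]
  if (nrow(pts) < 2) pts <- unique(contour)  # collinear degenerate case
  if (nrow(pts) < 2) stop("contour has fewer than 2 distinct points")
  max(stats::dist(pts))
}

#' Fit an ellipse in focal form to contour points
#'
#' Minimizes `sum_i (d(p_i, f1) + d(p_i, f2) - 2a)^2` over the two focus
#' locations and the major axis length 2a, using Levenberg-Marquardt
#' ([minpack.lm::nls.lm()]). Default initialization places both foci at
#' the contour centroid with 2a equal to the maximum pairwise distance,
#' i.e. a circle through the extreme points.
#'
#' The raw five-parameter focal parameterization (two free foci plus 2a)
#' has a degenerate attractor: both foci run apart with `2a` equal to
#' their separation, collapsing the "ellipse" onto a long thin sliver
#' through the point cloud with near-zero residuals. The optimizer
#' therefore works in an equivalent geometric parameterization -- center,
#' semi-major axis `a`, axis ratio `b/a` and orientation -- with the axis
#' ratio bounded to the flattened-disc shapes a peach can take
#' (`ratio_bounds`), while the minimized residual stays the focal-form
#' `d1 + d2 - 2a`. Foci and 2a are reported, so results are unchanged
#' wherever the unconstrained optimum is a fruit-like ellipse.
#'
#' @param contour numeric matrix with columns (row, col); at least 5 points
#'   (the fit has 5 free parameters).
#' @param initial_guess optional list with `focus1`, `focus2` (length-2
#'   numeric) and `major_axis_length`.
#' @param ratio_bounds allowed range of the minor/major axis ratio
#'   (default `c(0.5, 1)`; a ripe paraguayo silhouette is around 0.75).
#' @return an `ellipse_fit` with fields `focus1`, `focus2`,
#'   `major_axis_length`, `per_point_residuals` (signed
#'   `d1 + d2 - 2a` at the optimum), `relative_residuals`
#'   (`|residual| / 2a`) and `converged`.
#' @export
fit_ellipse_focal <- function(contour, initial_guess = NULL,
                              ratio_bounds = c(0.5, 1)) {
  contour <- as.matrix(contour)
  if (nrow(contour) < 5) {
    stop("at least 5 contour points are required to fit the 5 ellipse parameters")
  }
  stopifnot(length(ratio_bounds) == 2, ratio_bounds[1] > 0,
            ratio_bounds[2] <= 1, ratio_bounds[1] <= ratio_bounds[2])
  md <- max_pairwise_distance(contour)
  # geometric parameters: center row/col, semi-major a, ratio b/a, theta
  if (is.null(initial_guess)) {
    ctr <- colMeans(contour)
    v <- eigen(stats::cov(contour), symmetric = TRUE)$vectors[, 1]
    par0 <- c(ctr, md / 2, mean(ratio_bounds), atan2(v[2], v[1]))
  } else {
    f1 <- initial_guess$focus1; f2 <- initial_guess$focus2
    a0 <- initial_guess$major_axis_length / 2
    ctr <- (f1 + f2) / 2
    cdist <- sqrt(sum((f1 - f2)^2)) / 2
    ratio0 <- if (cdist >= a0) ratio_bounds[1]
              else sqrt(1 - (cdist / a0)^2)
    theta0 <- if (cdist > 1e-9) atan2(f1[2] - ctr[2], f1[1] - ctr[1]) else 0
    par0 <- c(ctr, a0, ratio0, theta0)
  }
  span <- apply(contour, 2, function(x) diff(range(x)))
  lo_rc <- apply(contour, 2, min) - 0.5 * span
  hi_rc <- apply(contour, 2, max) + 0.5 * span
  lower <- c(lo_rc, md / 8, ratio_bounds[1], -2 * pi)
  upper <- c(hi_rc, 2 * md, ratio_bounds[2], 2 * pi)
  par0 <- pmin(pmax(par0, lower), upper)
  geom_foci <- function(par) {
    par <- unname(par)
    cdist <- par[3] * sqrt(max(1 - par[4]^2, 0))
    u <- c(cos(par[5]), sin(par[5]))
    list(f1 = par[1:2] + cdist * u, f2 = par[1:2] - cdist * u,
         two_a = 2 * par[3])
  }
  resid_fn <- function(par) {
    g <- geom_foci(par)
    d1 <- sqrt((contour[, 1] - g$f1[1])^2 + (contour[, 2] - g$f1[2])^2)
    d2 <- sqrt((contour[, 1] - g$f2[1])^2 + (contour[, 2] - g$f2[2])^2)
    d1 + d2 - g$two_a
  }
  fit <- minpack.lm::nls.lm(par = par0, fn = resid_fn,
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = 200, ftol = 1e-12, ptol = 1e-12))
  g <- geom_foci(fit$par)
  res <- resid_fn(fit$par)
  mal <- g$two_a
  structure(
    list(focus1 = g$f1, focus2 = g$f2,
         major_axis_length = mal,
         per_point_residuals = as.numeric(res),
         relative_residuals = abs(res) / mal,
         converged = fit$info %in% 1:4,
         info = fit$info),
    class = "ellipse_fit")
}

#' @export
print.ellipse_fit <- function(x, ...) {
  cat("<ellipse_fit>\n")
  cat(sprintf("  foci: (%.2f, %.2f) and (%.2f, %.2f)\n",
              x$focus1[1], x$focus1[2], x$focus2[1], x$focus2[2]))
  cat(sprintf("  major axis length (2a): %.2f px\n", x$major_axis_length))
  cat(sprintf("  %d contour points, RMS residual %.4f px, converged: %s\n",
              length(x$per_point_residuals),
              sqrt(mean(x$per_point_residuals^2)), x$converged))
  invisible(x)
}

#' Two-stage ellipse fit with residual-based contour rejection
#'
#' Stage F1 fits all contour points. Points whose relative residual
#' `|d1 + d2 - 2a| / 2a` exceeds `residual_threshold` are rejected, and
#' stage F2 refits the retained points starting from F1's optimum. If
#' rejection would leave fewer than 5 points the refit is skipped
#' (F2 = F1, nothing rejected).
#'
#' @param contour numeric matrix with columns (row, col).
#' @param residual_threshold relative-residual rejection threshold
#'   (default 0.15).
#' @return list with `f1_fit`, `f2_fit` (both `ellipse_fit`) and
#'   `rejected` (integer indices into the contour rows).
#' @export
two_stage_fit <- function(contour, residual_threshold = 0.15) {
  contour <- as.matrix(contour)
  f1 <- fit_ellipse_focal(contour)
  rejected <- which(f1$relative_residuals > residual_threshold)
  if (length(rejected) == 0 || nrow(contour) - length(rejected) < 5) {
    return(list(f1_fit = f1, f2_fit = f1, rejected = integer(0)))
  }
  retained <- contour[-rejected, , drop = FALSE]
  f2 <- fit_ellipse_focal(retained,
                          initial_guess = list(
                            focus1 = f1$focus1, focus2 = f1$focus2,
                            major_axis_length = f1$major_axis_length))
  list(f1_fit = f1, f2_fit = f2, rejected = rejected)
}

#' Classify the occlusion range from the two major axis lengths
#'
#' Decision rule: if MAL-F2 and MAL-F1 agree within `similarity_tol`
#' (relative to MAL-F1) the fruit is not occluded and either value is a
#' usable diameter; if MAL-F2 is longer, occlusion is up to 33\% and the
#' second fit must be discarded (use MAL-F1); if MAL-F2 is shorter,
#' occlusion exceeds 66\% and no diameter estimate can be made.
#'
#' @param mal_f1,mal_f2 major axis lengths (pixels) from the first and
#'   second fit; both must be positive.
#' @param similarity_tol relative tolerance for "similar" lengths
#'   (default 0.05).
#' @return one of `"non_occluded"`, `"occluded_le_33"`, `"occluded_gt_66"`.
#' @export
classify_occlusion <- function(mal_f1, mal_f2, similarity_tol = 0.05) {
  if (mal_f1 <= 0 || mal_f2 <= 0) stop("major axis lengths must be positive")
  rel <- (mal_f2 - mal_f1) / mal_f1
  if (abs(rel) <= similarity_tol) "non_occluded"
  else if (rel > 0) "occluded_le_33"
  else "occluded_gt_66"
}

#' Estimate the diameter and occlusion range of one segmented fruit
#'
#' Composes the full sizing chain: contour extraction, maximum pairwise
#' distance (MD), two-stage focal ellipse fit (MAL-F1, MAL-F2) and the
#' occlusion-range classification. The recommended diameter is MAL-F2
#' when not occluded, MAL-F1 when occlusion is at most 33\% (the second
#' fit is discarded), and `NA` when occlusion exceeds 66\%.
#'
#' @param mask binary matrix with a single cleaned fruit component.
#' @param residual_threshold relative-residual rejection threshold
#'   (default 0.15).
#' @param similarity_tol relative tolerance of the occlusion rule
#'   (default 0.05).
#' @return a `diameter_estimate` with fields `md`, `mal_f1`, `mal_f2`,
#'   `n_rejected`, `occlusion_class` and `recommended_diameter` (pixels,
#'   `NA` if none can be given).
#' @export
estimate_diameter <- function(mask, residual_threshold = 0.15,
                              similarity_tol = 0.05) {
  contour <- extract_contour(mask)
  if (nrow(contour) < 5) {
    stop("mask has fewer than 5 contour pixels; cannot fit an ellipse")
  }
  md <- max_pairwise_distance(contour)
  ts <- two_stage_fit(contour, residual_threshold = residual_threshold)
  mal_f1 <- ts$f1_fit$major_axis_length
  mal_f2 <- ts$f2_fit$major_axis_length
  cls <- classify_occlusion(mal_f1, mal_f2, similarity_tol = similarity_tol)
  recommended <- switch(cls,
                        non_occluded = mal_f2,
                        occluded_le_33 = mal_f1,
                        occluded_gt_66 = NA_real_)
  structure(
    list(md = md, mal_f1 = mal_f1, mal_f2 = mal_f2,
         n_rejected = length(ts$rejected),
         occlusion_class = cls,
         recommended_diameter = recommended,
         f1_fit = ts$f1_fit, f2_fit = ts$f2_fit),
    class = "diameter_estimate")
}

#' @export
print.diameter_estimate <- function(x, ...) {
  cat("<diameter_estimate>\n")
  cat(sprintf("  MD: %.1f px   MAL-F1: %.1f px   MAL-F2: %.1f px\n",
              x$md, x$mal_f1, x$mal_f2))
  cat(sprintf("  rejected contour pixels: %d\n", x$n_rejected))
  cat(sprintf("  occlusion class: %s; recommended diameter: %s\n",
              x$occlusion_class,
              if (is.na(x$recommended_diameter)) "none"
              else sprintf("%.1f px", x$recommended_diameter)))
  invisible(x)
}

#' Serialize diameter estimates to a JSON measurement report
#'
#' One record per fruit with `md`, `mal_f1`, `mal_f2`, `n_rejected`,
#' `occlusion_class` and `recommended_diameter` (null when no estimate
#' can be given).
#'
#' @param estimates list of `diameter_estimate` objects.
#' @param path output JSON path.
#' @export
write_measurements <- function(estimates, path) {
  recs <- lapply(estimates, function(e) {
    list(md = e$md, mal_f1 = e$mal_f1, mal_f2 = e$mal_f2,
         n_rejected = e$n_rejected, occlusion_class = e$occlusion_class,
         recommended_diameter = if (is.na(e$recommended_diameter)) NULL
         else e$recommended_diameter)
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
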