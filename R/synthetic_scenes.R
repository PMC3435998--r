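#' Synthetic orchard scenes with exact ground truth
#'
#' Orchard photographs suitable for validating the pipeline are rarely
#' shareable, so the package generates its own: flattened-ellipse fruit
#' whose pixel colors lie near a "peach" line in the RGB cube (with
#' additive Gaussian noise and, optionally, saturation clipping that
#' reproduces the bright-sun "projection onto the R = 1 plane" effect),
#' on a patchwise leaf/branch background, with leaf-colored occluding
#' blobs covering a controllable fraction of each fruit. Every scene
#' carries exact ground truth: full and visible per-fruit masks, achieved
#' occlusion fractions, true foci and major axis lengths, and the
#' per-pixel class map.
#'
#' @name synthetic_scenes
NULL

#' Default class color lines for scene generation
#'
#' Three linear color trajectories chosen to mimic a red-skinned peach
#' orchard: a red-dominant peach line whose bright end runs out of gamut
#' (saturation clipping), a green-dominant leaf line, and a dull
#' brown-gray branch line. Each entry has `class`, `centroid`,
#' `direction` (unit) and `t_range`.
#'
#' @return named list of line descriptions (`peach`, `leaf`, `branch`).
#' @export
default_color_lines <- function() {
  norm <- function(v) v / sqrt(sum(v^2))
  list(
    peach = list(class = "Peach", centroid = c(0.60, 0.16, 0.14),
                 direction = norm(c(0.85, 0.35, 0.30)),
                 t_range = c(-0.40, 0.55)),
    leaf = list(class = "Leaf", centroid = c(0.25, 0.45, 0.18),
                direction = norm(c(0.55, 0.75, 0.35)),
                t_range = c(-0.30, 0.55)),
    branch = list(class = "Branch", centroid = c(0.38, 0.30, 0.22),
                  direction = norm(c(0.70, 0.58, 0.42)),
                  t_range = c(-0.35, 0.35))
  )
}

#' Configure a synthetic orchard scene
#'
#' @param height,width image size in pixels.
#' @param n_fruits number of non-overlapping fruit to place.
#' @param semi_major_range range (pixels) the semi-major axis is drawn from.
#' @param flattening_range range of the minor/major axis ratio; the default
#'   around 0.75 mimics the circular-but-flattened paraguayo silhouette.
#' @param occlusion_targets target occluded fraction per fruit in `[0, 1)`;
#'   recycled to `n_fruits`.
#' @param noise_sigma standard deviation of the additive Gaussian color
#'   noise (normalized intensity units).
#' @param saturation_clip if `TRUE`, the bright end of the fruit color
#'   ramp may leave the RGB gamut and is clipped at 1 (the sun-saturated
#'   skin effect); if `FALSE`, color ramps are confined to the gamut.
#' @param background_cell side (pixels) of the coherent background patches;
#'   each cell takes one class (leaf or branch) and one illumination
#'   parameter, so the background has leaf-like local structure rather than
#'   per-pixel i.i.d. noise.
#' @param branch_fraction probability that a background cell is branch
#'   rather than leaf.
#' @param colors class color lines, as [default_color_lines()].
#' @param seed integer seed; a given seed reproduces the scene bit for bit.
#' @return a `scene_config` list.
#' @export
scene_config <- function(height = 360, width = 480, n_fruits = 3,
                         semi_major_range = c(40, 60),
                         flattening_range = c(0.70, 0.80),
                         occlusion_targets = 0,
                         noise_sigma = 0.01,
                         saturation_clip = TRUE,
                         background_cell = 16,
                         branch_fraction = 0.2,
                         colors = default_color_lines(),
                         seed = NULL) {
  stopifnot(height >= 16, width >= 16, n_fruits >= 0,
            all(semi_major_range > 0), diff(semi_major_range) >= 0,
            all(flattening_range > 0), all(flattening_range <= 1),
            all(occlusion_targets >= 0), all(occlusion_targets < 1),
            noise_sigma >= 0, background_cell >= 1)
  if (n_fruits > 0) {
    occlusion_targets <- rep_len(occlusion_targets, n_fruits)
  } else {
    occlusion_targets <- numeric(0)
  }
  structure(list(height = height, width = width, n_fruits = n_fruits,
                 semi_major_range = semi_major_range,
                 flattening_range = flattening_range,
                 occlusion_targets = occlusion_targets,
                 noise_sigma = noise_sigma,
                 saturation_clip = saturation_clip,
                 background_cell = background_cell,
                 branch_fraction = branch_fraction,
                 colors = colors, seed = seed),
            class = "scene_config")
}

#' Sample colors along a class color line
#'
#' Returns `centroid + t * direction` plus isotropic Gaussian noise,
#' clipped componentwise to `[0, 1]` (pixels cannot leave the gamut; the
#' clipping is what produces the saturated-skin color distribution).
#'
#' @param line a line description (fields `centroid`, `direction`).
#' @param t numeric vector of positions along the line.
#' @param sigma Gaussian noise standard deviation.
#' @return matrix `length(t) x 3` of colors in `[0, 1]`.
#' @export
sample_line_color <- function(line, t, sigma = 0) {
  n <- length(t)
  base <- outer(t, line$direction)
  base <- sweep(base, 2, line$centroid, `+`)
  if (sigma > 0) base <- base + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
  pmin(pmax(base, 0), 1)
}

# t-interval over which centroid + t*direction stays inside [0,1]^3
gamut_t_range <- function(line) {
  lo <- -Inf; hi <- Inf
  for (i in 1:3) {
    d <- line$direction[i]; c0 <- line$centroid[i]
    if (abs(d) < 1e-12) next
    bounds <- sort(c((0 - c0) / d, (1 - c0) / d))
    lo <- max(lo, bounds[1]); hi <- min(hi, bounds[2])
  }
  c(lo, hi)
}

#' Rasterize an ellipse into a binary mask
#'
#' @param height,width mask size.
#' @param center numeric (row, col) of the ellipse center.
#' @param a,b semi-major and semi-minor axis lengths in pixels (`a >= b`).
#' @param theta orientation of the major axis, radians, measured in
#'   (row, col) coordinates.
#' @return list with `mask` (0/1 matrix), `foci` (2 x 2 matrix, one focus
#'   per row), `major_axis_length` (2a) and the input parameters.
#' @export
rasterize_ellipse <- function(height, width, center, a, b, theta) {
  stopifnot(a >= b, b > 0)
  u <- c(cos(theta), sin(theta))
  mask <- matrix(0L, height, width)
  r0 <- max(1L, floor(center[1] - a)); r1 <- min(height, ceiling(center[1] + a))
  c0 <- max(1L, floor(center[2] - a)); c1 <- min(width, ceiling(center[2] + a))
  if (r0 <= r1 && c0 <= c1) {
    rr <- r0:r1; cc <- c0:c1
    dr <- matrix(rr - center[1], length(rr), length(cc))
    dc <- matrix(rep(cc - center[2], each = length(rr)), length(rr))
    x <- dr * u[1] + dc * u[2]
    y <- -dr * u[2] + dc * u[1]
    mask[rr, cc] <- as.integer((x / a)^2 + (y / b)^2 <= 1)
  }
  cdist <- sqrt(a^2 - b^2)
  foci <- rbind(center + cdist * u, center - cdist * u)
  colnames(foci) <- c("row", "col")
  list(mask = mask, foci = foci, major_axis_length = 2 * a,
       center = center, a = a, b = b, theta = theta)
}

#' Occlude a fruit with a randomly grown connected blob
#'
#' The occluder starts at a uniformly chosen contour pixel of the fruit
#' and grows one pixel at a time by annexing a random 8-connected frontier
#' pixel (an Eden-type growth, giving compact irregular blobs), stopping
#' the first time the covered fraction of the fruit reaches the target.
#' The achieved fraction is reported exactly; by first-crossing it lies in
#' `[target, target + 1/|fruit|]`.
#'
#' @param full_mask binary matrix of the complete fruit.
#' @param target_fraction desired covered fraction in `[0, 1)`.
#' @param domain optional logical/binary matrix restricting where the blob
#'   may grow (it must contain the fruit); by default the whole image.
#'   The scene generator confines each occluder to its own fruit's
#'   neighborhood so one fruit's occluder cannot drift onto another fruit.
#' @return list with `visible_mask`, `achieved_fraction`, `occluder_mask`.
#'   Uses the current RNG state.
#' @export
occlude_fruit <- function(full_mask, target_fraction, domain = NULL) {
  if (target_fraction < 0 || target_fraction >= 1) {
    stop("occlusion target must lie in [0, 1)")
  }
  m <- mask_to_logical(full_mask)
  h <- nrow(m); w <- ncol(m)
  fruit_area <- sum(m)
  occ <- matrix(FALSE, h, w)
  dom <- if (is.null(domain)) matrix(TRUE, h, w) else mask_to_logical(domain)
  if (any(m & !dom)) stop("the growth domain must contain the fruit")
  if (target_fraction > 0 && fruit_area > 0) {
    contour <- extract_contour(m)
    seed_pt <- contour[sample.int(nrow(contour), 1), ]
    seed_idx <- (seed_pt[2] - 1) * h + seed_pt[1]
    in_blob <- occ
    in_frontier <- matrix(FALSE, h, w)
    frontier <- as.integer(seed_idx)
    in_frontier[seed_idx] <- TRUE
    covered <- 0L
    need <- target_fraction * fruit_area
    dr8 <- c(-1L, -1L, -1L, 0L, 0L, 1L, 1L, 1L)
    dc8 <- c(-1L, 0L, 1L, -1L, 1L, -1L, 0L, 1L)
    while (covered < need && length(frontier) > 0) {
      k <- sample.int(length(frontier), 1)
      idx <- frontier[k]
      frontier[k] <- frontier[length(frontier)]
      length(frontier) <- length(frontier) - 1L
      in_frontier[idx] <- FALSE
      in_blob[idx] <- TRUE
      if (m[idx]) covered <- covered + 1L
      r <- (idx - 1L) %% h + 1L
      cc <- (idx - 1L) %/% h + 1L
      nr <- r + dr8; nc <- cc + dc8
      ok <- nr >= 1L & nr <= h & nc >= 1L & nc <= w
      nidx <- (nc[ok] - 1L) * h + nr[ok]
      nidx <- nidx[!in_blob[nidx] & !in_frontier[nidx] & dom[nidx]]
      if (length(nidx)) {
        frontier <- c(frontier, nidx)
        in_frontier[nidx] <- TRUE
      }
    }
    occ <- in_blob
  }
  visible <- m & !occ
  list(visible_mask = matrix(as.integer(visible), h, w),
       achieved_fraction = 1 - sum(visible) / fruit_area,
       occluder_mask = matrix(as.integer(occ), h, w))
}

#' Generate a synthetic orchard scene
#'
#' Deterministic for a given `config$seed`. The background is tiled with
#' coherent leaf/branch cells; fruits are rasterized rotated ellipses
#' colored along the peach line with a smooth illumination gradient plus
#' noise; occluders are leaf-colored blobs grown over each fruit to its
#' target fraction.
#'
#' @param config a [scene_config()].
#' @return list of class `synthetic_scene` with `image`
#'   (`height x width x 3` array) and `truth`, a ground-truth list:
#'   `full_masks`, `visible_masks` (per fruit), `occluder_mask` (union),
#'   `achieved_occlusion`, `foci` (list of 2 x 2 matrices), `two_a`,
#'   `centers`, `class_map` (character matrix over
#'   `"peach"/"leaf"/"branch"`), and the echoed `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  if (!is.null(config$seed)) {
    return(withr::with_seed(as.integer(config$seed),
                            generate_scene_impl(config)))
  }
  generate_scene_impl(config)
}

generate_scene_impl <- function(config) {
  h <- config$height; w <- config$width
  lines <- config$colors
  max_a <- config$semi_major_range[2]
  if (config$n_fruits > 0 && (2 * (max_a + 2) > min(h, w))) {
    stop("infeasible scene: fruit semi-major axis too large for the image")
  }

  # --- background: coherent leaf/branch cells -------------------------------
  cell <- config$background_cell
  nrc <- ceiling(h / cell); ncc <- ceiling(w / cell)
  cell_class <- matrix(ifelse(stats::runif(nrc * ncc) < config$branch_fraction,
                              "branch", "leaf"), nrc, ncc)
  cell_t <- matrix(NA_real_, nrc, ncc)
  for (cl in c("leaf", "branch")) {
    sel <- cell_class == cl
    tr <- lines[[cl]]$t_range
    cell_t[sel] <- stats::runif(sum(sel), tr[1], tr[2])
  }
  row_cell <- pmin((seq_len(h) - 1L) %/% cell + 1L, nrc)
  col_cell <- pmin((seq_len(w) - 1L) %/% cell + 1L, ncc)
  pix_class <- cell_class[cbind(rep(row_cell, times = w),
                                rep(col_cell, each = h))]
  pix_t <- cell_t[cbind(rep(row_cell, times = w), rep(col_cell, each = h))]
  img_flat <- matrix(0, h * w, 3)
  for (cl in c("leaf", "branch")) {
    sel <- pix_class == cl
    if (any(sel)) {
      img_flat[sel, ] <- sample_line_color(lines[[cl]], pix_t[sel],
                                           config$noise_sigma)
    }
  }
  class_map <- matrix(pix_class, h, w)

  # --- fruits: non-overlapping rotated ellipses -----------------------------
  n <- config$n_fruits
  full_masks <- vector("list", n)
  foci <- vector("list", n)
  two_a <- numeric(n)
  centers <- matrix(NA_real_, n, 2, dimnames = list(NULL, c("row", "col")))
  radii <- numeric(n)
  peach_gamut <- if (config$saturation_clip) lines$peach$t_range
                 else range_intersect(lines$peach$t_range,
                                      gamut_t_range(lines$peach))
  for (i in seq_len(n)) {
    a <- stats::runif(1, config$semi_major_range[1], config$semi_major_range[2])
    ratio <- stats::runif(1, config$flattening_range[1],
                          config$flattening_range[2])
    b <- ratio * a
    theta <- stats::runif(1, 0, pi)
    placed <- FALSE
    for (try in 1:500) {
      ctr <- c(stats::runif(1, a + 2, h - a - 1),
               stats::runif(1, a + 2, w - a - 1))
      # wide spacing so each fruit's occluder neighborhood stays private
      if (i == 1 || all(sqrt(rowSums(sweep(centers[seq_len(i - 1), ,
                                                   drop = FALSE],
                                           2, ctr)^2)) >
                        1.5 * (radii[seq_len(i - 1)] + a) + 4)) {
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("infeasible scene: could not place ", n,
           " non-overlapping fruit in a ", h, " x ", w, " image")
    }
    ell <- rasterize_ellipse(h, w, ctr, a, b, theta)
    full_masks[[i]] <- ell$mask
    foci[[i]] <- ell$foci
    two_a[i] <- ell$major_axis_length
    centers[i, ] <- ctr
    radii[i] <- a

    # illumination gradient across the fruit along a random direction
    idx <- which(ell$mask == 1L)
    pr <- (idx - 1L) %% h + 1L
    pc <- (idx - 1L) %/% h + 1L
    g <- stats::runif(1, 0, 2 * pi)
    proj <- ((pr - ctr[1]) * cos(g) + (pc - ctr[2]) * sin(g)) / a  # [-1, 1]
    t_mid <- stats::runif(1, peach_gamut[1] + 0.35 * diff(peach_gamut),
                          peach_gamut[1] + 0.65 * diff(peach_gamut))
    t_amp <- 0.45 * diff(peach_gamut)
    t_pix <- pmin(pmax(t_mid + t_amp * proj, peach_gamut[1]), peach_gamut[2])
    img_flat[idx, ] <- sample_line_color(lines$peach, t_pix,
                                         config$noise_sigma)
    class_map[idx] <- "peach"
  }

  # --- occluders: leaf-colored blobs over each fruit ------------------------
  occluder <- matrix(0L, h, w)
  for (i in seq_len(n)) {
    tgt <- config$occlusion_targets[i]
    if (tgt > 0) {
      # confine the blob to a box around its own fruit
      half <- 1.45 * radii[i]
      dom <- matrix(FALSE, h, w)
      rr <- max(1, floor(centers[i, 1] - half)):min(h, ceiling(centers[i, 1] + half))
      cc <- max(1, floor(centers[i, 2] - half)):min(w, ceiling(centers[i, 2] + half))
      dom[rr, cc] <- TRUE
      occ <- occlude_fruit(full_masks[[i]], tgt, domain = dom)
      occluder <- pmax(occluder, occ$occluder_mask)
    }
  }
  occ_idx <- which(occluder == 1L)
  if (length(occ_idx) > 0) {
    tr <- lines$leaf$t_range
    t0 <- stats::runif(1, tr[1], tr[2])
    t_occ <- pmin(pmax(t0 + stats::rnorm(length(occ_idx), 0, 0.03), tr[1]),
                  tr[2])
    img_flat[occ_idx, ] <- sample_line_color(lines$leaf, t_occ,
                                             config$noise_sigma)
    class_map[occ_idx] <- "leaf"
  }
  visible_masks <- lapply(full_masks, function(fm) {
    matrix(as.integer(fm == 1L & occluder == 0L), h, w)
  })
  achieved <- vapply(seq_len(n), function(i) {
    1 - sum(visible_masks[[i]]) / sum(full_masks[[i]])
  }, numeric(1))

  image <- array(img_flat, dim = c(h, w, 3))
  structure(list(image = image,
                 truth = list(full_masks = full_masks,
                              visible_masks = visible_masks,
                              occluder_mask = occluder,
                              achieved_occlusion = achieved,
                              foci = foci, two_a = two_a, centers = centers,
                              class_map = class_map),
                 config = config),
            class = "synthetic_scene")
}

range_intersect <- function(a, b) c(max(a[1], b[1]), min(a[2], b[2]))

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene %d x %d, %d fruit>\n",
              dim(x$image)[1], dim(x$image)[2],
              length(x$truth$full_masks)))
  if (length(x$truth$two_a)) {
    cat(sprintf("  true 2a: %s px\n",
                paste(sprintf("%.1f", x$truth$two_a), collapse = ", ")))
    cat(sprintf("  achieved occlusion: %s\n",
                paste(sprintf("%.3f", x$truth$achieved_occlusion),
                      collapse = ", ")))
  }
  invisible(x)
}

#' Sample ground-truth pixels of one class from a scene
#'
#' Draws colors from pixels the generator labeled with the given class --
#' the synthetic stand-in for an operator selecting small pure regions of
#' a known object.
#'
#' @param scene a `synthetic_scene`.
#' @param class_name `"peach"`, `"leaf"` or `"branch"`.
#' @param n number of pixels to draw (without replacement if possible).
#' @return matrix `n x 3` of colors. Uses the current RNG state.
#' @export
sample_class_pixels <- function(scene, class_name, n = 1000) {
  idx <- which(scene$truth$class_map == class_name)
  if (length(idx) == 0) stop("scene has no pixels of class '", class_name, "'")
  pick <- idx[sample.int(length(idx), min(n, length(idx)))]
  flat <- matrix(scene$image, ncol = 3)
  flat[pick, , drop = FALSE]
}

#' Fit classification models from a scene's ground-truth classes
#'
#' Fits one linear color model per class from ground-truth pixels; peach
#' pixels with a color component at the saturation ceiling are split into
#' a second peach model (mirroring the separate models an operator defines
#' for shaded and sun-saturated skin) when there are enough of them.
#'
#' @param scene a `synthetic_scene`.
#' @param n_per_class pixels sampled per class.
#' @param split_saturated split saturated peach pixels into their own
#'   model when at least 50 are present (default `TRUE`).
#' @return a `color_model_set`. Uses the current RNG state.
#' @export
fit_scene_models <- function(scene, n_per_class = 2000,
                             split_saturated = TRUE) {
  peach <- sample_class_pixels(scene, "peach", n_per_class)
  leaf <- sample_class_pixels(scene, "leaf", n_per_class)
  branch <- sample_class_pixels(scene, "branch", n_per_class)
  models <- list()
  sat <- apply(peach, 1, max) >= 1 - 1e-6
  if (split_saturated && sum(sat) >= 50 && sum(!sat) >= 50) {
    models <- c(models,
                list(fit_linear_color_model(peach[!sat, ], "P1", "Peach"),
                     fit_linear_color_model(peach[sat, ], "P2", "Peach")))
  } else {
    models <- c(models, list(fit_linear_color_model(peach, "P1", "Peach")))
  }
  models <- c(models,
              list(fit_linear_color_model(leaf, "L1", "Leaf"),
                   fit_linear_color_model(branch, "B1", "Branch")))
  color_model_set(models, provenance = "fitted from synthetic ground truth")
}

#' Write a scene bundle to a directory
#'
#' Writes `image.png`, per-fruit `fruit_NN_full.png` and
#' `fruit_NN_visible.png` masks, `ground_truth.json` (true foci, 2a,
#' achieved occlusion, per-fruit areas) and `config.yaml` (an echo of the
#' generating configuration).
#'
#' @param scene a `synthetic_scene`.
#' @param dir output directory (created if missing).
#' @export
write_scene_bundle <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_rgb_png(scene$image, file.path(dir, "image.png"))
  n <- length(scene$truth$full_masks)
  for (i in seq_len(n)) {
    write_mask_png(scene$truth$full_masks[[i]],
                   file.path(dir, sprintf("fruit_%02d_full.png", i)))
    write_mask_png(scene$truth$visible_masks[[i]],
                   file.path(dir, sprintf("fruit_%02d_visible.png", i)))
  }
  gt <- lapply(seq_len(n), function(i) {
    list(fruit = i,
         foci = apply(scene$truth$foci[[i]], 1, as.numeric, simplify = FALSE),
         major_axis_length = scene$truth$two_a[i],
         center = as.numeric(scene$truth$centers[i, ]),
         achieved_occlusion = scene$truth$achieved_occlusion[i],
         full_area = sum(scene$truth$full_masks[[i]]),
         visible_area = sum(scene$truth$visible_masks[[i]]))
  })
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  cfg <- scene$config
  cfg$colors <- lapply(cfg$colors, function(l) {
    l$centroid <- as.numeric(l$centroid)
    l$direction <- as.numeric(l$direction)
    l$t_range <- as.numeric(l$t_range)
    l
  })
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
  invisible(dir)
}

#' Read a scene configuration from YAML
#'
#' @param path YAML file with any subset of the [scene_config()] fields.
#' @return a `scene_config`.
#' @export
read_scene_config <- function(path) {
  doc <- yaml::read_yaml(path)
  known <- names(formals(scene_config))
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    stop("unknown scene config fields: ", paste(extra, collapse = ", "))
  }
  if (!is.null(doc$colors)) {
    doc$colors <- lapply(doc$colors, function(l) {
      l$centroid <- as.numeric(unlist(l$centroid))
      l$direction <- as.numeric(unlist(l$direction))
      l$t_range <- as.numeric(unlist(l$t_range))
      l
    })
  }
  do.call(scene_config, doc)
}
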