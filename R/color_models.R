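#' Linear color models in the RGB vector color space
#'
#' The color of one object class under slowly varying illumination traces an
#' approximately straight line in the normalized RGB cube: dimming or
#' brightening moves a pixel's (R, G, B) triple along a common direction.
#' A *linear color model* captures one such trajectory as a 3-D line
#' (centroid plus unit direction) fitted to sampled pixels by total least
#' squares, labeled with the object class it represents (`"Peach"`,
#' `"Leaf"` or `"Branch"`). Pixel classification then reduces to assigning
#' each pixel to the model whose line is nearest in Euclidean distance.
#'
#' @name color_models
NULL

PEACH_CLASSES <- "Peach"
VALID_CLASSES <- c("Peach", "Leaf", "Branch")

#' Fit a linear color model to sampled pixel colors
#'
#' Fits the total-least-squares line through a cloud of RGB color points:
#' the centroid is the componentwise mean and the direction is the first
#' principal axis of the centered cloud, i.e. the direction minimizing the
#' summed squared *orthogonal* distances from the samples to the line.
#' This orthogonal formulation is symmetric in R, G and B and matches the
#' point-to-line distance later used for classification. The direction sign
#' is canonicalized (first nonzero component nonnegative) so that fits are
#' byte-for-byte reproducible.
#'
#' @param samples numeric matrix with one row per pixel and columns
#'   (r, g, b), all values in `[0, 1]` (8-bit intensities divided by 255).
#' @param label short model identifier, e.g. `"P1"`.
#' @param class_name object class, one of `"Peach"`, `"Leaf"`, `"Branch"`.
#' @return an object of class `linear_color_model` with fields `label`,
#'   `class_name`, `centroid` (length-3), `direction` (unit length-3) and
#'   `n_samples`.
#' @examples
#' pts <- cbind(r = c(0, .5, 1), g = c(0, .5, 1), b = c(0, .5, 1))
#' m <- fit_linear_color_model(pts, "P1", "Peach")
#' m$direction  # (1,1,1)/sqrt(3)
#' @export
fit_linear_color_model <- function(samples, label, class_name) {
  samples <- as_color_matrix(samples)
  if (nrow(samples) < 2) {
    stop("degenerate fit for model '", label,
         "': at least 2 sample pixels are required", call. = FALSE)
  }
  centroid <- colMeans(samples)
  centered <- sweep(samples, 2, centroid)
  if (all(abs(centered) < 1e-12)) {
    stop("degenerate fit for model '", label,
         "': all sample pixels are identical", call. = FALSE)
  }
  # principal axis of the centered cloud = leading right singular vector
  direction <- svd(centered, nu = 0, nv = 3)$v[, 1]
  direction <- canonicalize_direction(direction)
  new_linear_color_model(label, class_name, centroid, direction,
                         nrow(samples))
}

new_linear_color_model <- function(label, class_name, centroid, direction,
                                   n_samples) {
  class_name <- match.arg(class_name, VALID_CLASSES)
  stopifnot(length(centroid) == 3, length(direction) == 3,
            abs(sqrt(sum(direction^2)) - 1) < 1e-9,
            all(centroid >= -1e-9 & centroid <= 1 + 1e-9))
  structure(
    list(label = as.character(label), class_name = class_name,
         centroid = as.numeric(centroid),
         direction = as.numeric(direction),
         n_samples = as.integer(n_samples)),
    class = "linear_color_model")
}

canonicalize_direction <- function(d) {
  d <- d / sqrt(sum(d^2))
  nz <- which(abs(d) > 1e-12)
  if (length(nz) && d[nz[1]] < 0) d <- -d
  d
}

as_color_matrix <- function(samples) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) stop("color samples must have 3 columns (r, g, b)")
  storage.mode(samples) <- "double"
  if (any(samples < -1e-9 | samples > 1 + 1e-9)) {
    stop("color components must lie in [0, 1] (normalized 8-bit intensities)")
  }
  samples
}

#' @export
print.linear_color_model <- function(x, ...) {
  cat(sprintf("<linear_color_model %s (%s)>\n", x$label, x$class_name))
  cat(sprintf("  centroid : (%.4f, %.4f, %.4f)\n", x$centroid[1],
              x$centroid[2], x$centroid[3]))
  cat(sprintf("  direction: (%.4f, %.4f, %.4f)\n", x$direction[1],
              x$direction[2], x$direction[3]))
  cat(sprintf("  fitted on %d pixels\n", x$n_samples))
  invisible(x)
}

#' Euclidean distance from a color point to a linear color model
#'
#' Distance from `p` to the *infinite* line `centroid + t * direction`:
#' the norm of the component of `p - centroid` orthogonal to the direction.
#' The distance is invariant to the direction's sign and to sliding the
#' centroid along the line.
#'
#' @param p numeric length-3 color point (r, g, b) in `[0, 1]`, or a matrix
#'   with one point per row.
#' @param model a `linear_color_model`.
#' @return nonnegative distance(s), one per input point.
#' @export
point_to_model_distance <- function(p, model) {
  if (is.null(dim(p))) p <- matrix(p, nrow = 1)
  v <- sweep(p, 2, model$centroid)
  proj <- as.vector(v %*% model$direction)
  d2 <- rowSums(v^2) - proj^2
  sqrt(pmax(d2, 0))
}

#' Build an ordered set of linear color models
#'
#' The order of the models is significant: classification ties are broken
#' in favor of the earliest model in the set.
#'
#' @param models list of `linear_color_model` objects with unique labels;
#'   at least one must have class `"Peach"`.
#' @param provenance free-text note recording where the models came from.
#' @return an object of class `color_model_set`.
#' @export
color_model_set <- function(models, provenance = "") {
  stopifnot(length(models) >= 1)
  lapply(models, function(m) stopifnot(inherits(m, "linear_color_model")))
  labels <- vapply(models, `[[`, "", "label")
  if (anyDuplicated(labels)) stop("model labels must be unique")
  classes <- vapply(models, `[[`, "", "class_name")
  if (!any(classes %in% PEACH_CLASSES)) {
    stop("a color model set must contain at least one Peach-class model")
  }
  structure(list(models = models, provenance = as.character(provenance)),
            class = "color_model_set")
}

#' @export
length.color_model_set <- function(x) length(x$models)

#' @export
print.color_model_set <- function(x, ...) {
  cat(sprintf("<color_model_set: %d models>\n", length(x$models)))
  for (m in x$models) {
    cat(sprintf("  %-4s %-7s centroid (%.3f, %.3f, %.3f)  n = %d\n",
                m$label, m$class_name, m$centroid[1], m$centroid[2],
                m$centroid[3], m$n_samples))
  }
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

model_labels <- function(set) vapply(set$models, `[[`, "", "label")
model_classes <- function(set) vapply(set$models, `[[`, "", "class_name")

#' Fit color models from annotated image regions
#'
#' Realizes the empirical model-determination workflow: an operator marks
#' small rectangles of known objects; each annotation's rectangles are
#' pooled and a linear color model is fitted to the pooled pixel colors.
#'
#' @param image numeric array `height x width x 3` with values in `[0, 1]`
#'   (as returned by [read_rgb_png()]).
#' @param annotations list of region annotations, each a list with fields
#'   `label`, `class`, and `rects`, where `rects` is a list/matrix of
#'   1-based inclusive rectangles `(row0, col0, row1, col1)`
#'   (see [read_annotations()] for the on-disk 0-based half-open format).
#' @return a `color_model_set`, one model per annotation, in input order.
#' @export
fit_models_from_image <- function(image, annotations) {
  check_rgb_image(image)
  if (length(annotations) == 0) stop("at least one region annotation is required")
  models <- lapply(annotations, function(ann) {
    px <- do.call(rbind, lapply(rect_list(ann$rects),
                                function(r) rect_pixels(image, r)))
    fit_linear_color_model(px, ann$label, ann$class)
  })
  color_model_set(models, provenance = "fitted from annotated image regions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rect_list <- function(rects) {
  if (is.matrix(rects)) lapply(seq_len(nrow(rects)), function(i) rects[i, ])
  else rects
}

rect_pixels <- function(image, r) {
  stopifnot(length(r) == 4)
  r <- as.integer(r)
  if (r[1] < 1 || r[2] < 1 || r[3] > dim(image)[1] || r[4] > dim(image)[2] ||
      r[1] > r[3] || r[2] > r[4]) {
    stop("annotation rectangle out of image bounds or empty")
  }
  sub <- image[r[1]:r[3], r[2]:r[4], , drop = FALSE]
  matrix(sub, ncol = 3, dimnames = list(NULL, c("r", "g", "b")))
}

check_rgb_image <- function(image) {
  if (!(is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)) {
    stop("image must be a height x width x 3 numeric array")
  }
  if (any(image < -1e-9 | image > 1 + 1e-9)) {
    stop("image intensities must be normalized to [0, 1]")
  }
  invisible(image)
}

# ---- model / annotation file formats ---------------------------------------

#' Write a color model set to JSON
#'
#' Top-level key `"models"`; each entry carries `label`, `class`,
#' `centroid`, `direction` and `n_samples`, with floats serialized at
#' full precision (well beyond 12 significant digits).
#'
#' @param set a `color_model_set`.
#' @param path output JSON path.
#' @export
write_color_models <- function(set, path) {
  stopifnot(inherits(set, "color_model_set"))
  entries <- lapply(set$models, function(m) {
    list(label = m$label, class = m$class_name, centroid = m$centroid,
         direction = m$direction, n_samples = m$n_samples)
  })
  jsonlite::write_json(list(models = entries, provenance = set$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a color model set from JSON
#'
#' @param path JSON file written by [write_color_models()].
#' @return a `color_model_set`.
#' @export
read_color_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$models) || length(doc$models) == 0) {
    stop("model file '", path, "' contains no models")
  }
  models <- lapply(doc$models, function(e) {
    new_linear_color_model(e$label, e$class,
                           as.numeric(unlist(e$centroid)),
                           as.numeric(unlist(e$direction)),
                           e$n_samples)
  })
  color_model_set(models, provenance = doc$provenance %||% "")
}

#' Read region annotations from JSON
#'
#' The on-disk format is a JSON list of
#' `{"label", "class", "rects": [[row0, col0, row1, col1], ...]}` with
#' 0-based, half-open rectangles (`row0 <= r < row1`). On read, rectangles
#' are converted to the 1-based inclusive convention used in R.
#'
#' @param path annotation JSON path.
#' @param image optional image array; when given, rectangles are checked
#'   against its bounds.
#' @return list of annotations with fields `label`, `class`, `rects`
#'   (matrix of 1-based inclusive rows `(row0, col0, row1, col1)`).
#' @export
read_annotations <- function(path, image = NULL) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(doc) == 0) stop("annotation file '", path, "' is empty")
  anns <- lapply(doc, function(e) {
    rects <- do.call(rbind, lapply(e$rects, function(r) as.integer(unlist(r))))
    if (is.null(rects) || ncol(rects) != 4) {
      stop("annotation '", e$label, "' has malformed rectangles")
    }
    if (any(rects[, 3] <= rects[, 1]) || any(rects[, 4] <= rects[, 2])) {
      stop("annotation '", e$label, "' has an empty half-open rectangle")
    }
    # 0-based half-open -> 1-based inclusive
    rects_r <- cbind(rects[, 1] + 1L, rects[, 2] + 1L, rects[, 3], rects[, 4])
    list(label = e$label, class = e$class, rects = rects_r)
  })
  if (!is.null(image)) {
    for (a in anns) {
      if (any(a$rects[, 1] < 1) || any(a$rects[, 2] < 1) ||
          any(a$rects[, 3] > dim(image)[1]) ||
          any(a$rects[, 4] > dim(image)[2])) {
        stop("annotation '", a$label, "' lies outside the image")
      }
    }
  }
  anns
}
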