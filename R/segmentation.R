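#' Pixel classification and peach-mask extraction
#'
#' Every pixel is assigned to the nearest linear color model (Euclidean
#' distance to the model's line in the RGB cube); no extra thresholds or
#' decision surfaces are needed because the decision boundaries between
#' lines are taken to be equidistant. Pixels whose winning model carries
#' the Peach class form the binary fruit mask, which is then cleaned by
#' removing small components and filling enclosed holes.
#'
#' @name segmentation
NULL

#' Classify every pixel to its nearest linear color model
#'
#' @param image numeric `height x width x 3` array, intensities in `[0, 1]`.
#' @param models a `color_model_set`.
#' @return a `label_map`: integer matrix of 1-based model indices with
#'   attributes `labels` and `classes` (parallel character vectors over the
#'   model set). Ties are broken in favor of the lowest model index.
#' @export
classify_image <- function(image, models) {
  check_rgb_image(image)
  stopifnot(inherits(models, "color_model_set"), length(models) >= 1)
  h <- dim(image)[1]; w <- dim(image)[2]
  pts <- matrix(image, ncol = 3)
  d2 <- vapply(models$models, function(m) {
    v <- sweep(pts, 2, m$centroid)
    proj <- as.vector(v %*% m$direction)
    pmax(rowSums(v^2) - proj^2, 0)
  }, numeric(nrow(pts)))
  d2 <- matrix(d2, nrow = nrow(pts))   # vapply drops dims for 1-pixel images
  idx <- max.col(-d2, ties.method = "first")
  structure(matrix(as.integer(idx), h, w),
            labels = model_labels(models),
            classes = model_classes(models),
            class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  tab <- table(factor(attr(x, "labels")[x], levels = attr(x, "labels")))
  cat(sprintf("<label_map %d x %d>\n", nrow(x), ncol(x)))
  print(tab)
  invisible(x)
}

#' Binarize a label map to the peach mask
#'
#' A pixel is foreground (1) exactly when its assigned model has class
#' `"Peach"`; any Peach-class model counts, so several peach models
#' (e.g. shaded and sun-saturated skin) pool into one mask.
#'
#' @param labelmap a `label_map` from [classify_image()], or a plain
#'   integer matrix of model indices.
#' @param models the `color_model_set` the labels refer to.
#' @return integer matrix of 0/1 values.
#' @export
peach_mask <- function(labelmap, models) {
  stopifnot(inherits(models, "color_model_set"))
  idx <- unclass(labelmap)
  attributes(idx) <- list(dim = dim(labelmap))
  if (any(idx < 1L) || any(idx > length(models))) {
    stop("label map refers to model indices absent from the model set")
  }
  is_peach <- model_classes(models) %in% PEACH_CLASSES
  mask <- matrix(as.integer(is_peach[idx]), nrow(idx), ncol(idx))
  mask
}

#' Label connected components of a binary mask
#'
#' Foreground pixels become vertices of an adjacency graph (edges between
#' neighboring foreground pixels under the chosen connectivity) whose
#' connected components are computed with \pkg{igraph}; components are
#' numbered 1..k by the row-major position of each component's first pixel.
#'
#' @param mask binary matrix (0/1 or logical).
#' @param connectivity 8 (default; includes diagonals) or 4.
#' @return integer matrix; 0 = background, components numbered from 1.
#' @export
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  m <- mask_to_logical(mask)
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0L, h, w)
  fg <- which(m)                       # column-major linear indices
  if (length(fg) == 0) return(out)
  node <- matrix(0L, h, w)
  node[fg] <- seq_along(fg)
  # one shift per unordered neighbor direction
  shifts <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) shifts <- c(shifts, list(c(1, 1), c(1, -1)))
  edges <- lapply(shifts, function(s) {
    nb <- shift_matrix(node, s[1], s[2], fill = 0L)
    both <- node > 0L & nb > 0L
    cbind(node[both], nb[both])
  })
  edges <- do.call(rbind, edges)
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (nrow(edges) > 0) g <- igraph::add_edges(g, t(edges))
  memb <- igraph::components(g)$membership
  # renumber components by their first pixel in row-major scan order
  rmaj <- (row(m)[fg] - 1) * w + col(m)[fg]
  first <- tapply(rmaj, memb, min)
  renum <- integer(length(first))
  renum[order(first)] <- seq_along(first)
  out[fg] <- renum[memb]
  out
}

shift_matrix <- function(x, dr, dc, fill = 0) {
  h <- nrow(x); w <- ncol(x)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  out[rs, cs] <- x[rs - dr, cs - dc]
  out
}

mask_to_logical <- function(mask) {
  m <- as.matrix(mask)
  if (is.numeric(m) && !all(m %in% c(0, 1))) {
    stop("mask must be binary (0/1)")
  }
  matrix(as.logical(m), nrow(m), ncol(m))
}

#' Clean a binary peach mask
#'
#' Removes isolated noise by deleting 8-connected foreground components
#' with fewer than `min_size` pixels (strictly fewer: a component of
#' exactly `min_size` pixels survives), then fills enclosed holes --
#' background regions (4-connected) that do not touch the image border.
#' The operation is idempotent.
#'
#' @param mask binary matrix.
#' @param min_size minimum surviving component size in pixels (default 50).
#' @return cleaned 0/1 integer matrix.
#' @export
clean_mask <- function(mask, min_size = 50) {
  m <- mask_to_logical(mask)
  if (any(m)) {
    lab <- label_components(m, connectivity = 8)
    sizes <- tabulate(lab[lab > 0])
    keep <- which(sizes >= min_size)
    m <- matrix(lab %in% keep, nrow(m), ncol(m))
  }
  if (any(m)) {
    bg <- label_components(!m, connectivity = 4)
    border_ids <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
    border_ids <- border_ids[border_ids > 0]
    hole <- bg > 0 & !(bg %in% border_ids)
    m <- m | hole
  }
  matrix(as.integer(m), nrow(m), ncol(m))
}

#' Split a cleaned mask into per-fruit masks
#'
#' @param mask binary matrix (typically from [clean_mask()]).
#' @return list of 0/1 matrices, one per 8-connected component, ordered by
#'   each component's top-left-most pixel in row-major scan order; the
#'   masks are disjoint and their union is the input.
#' @export
extract_components <- function(mask) {
  lab <- label_components(mask, connectivity = 8)
  k <- max(lab)
  if (k == 0) return(list())
  lapply(seq_len(k), function(i) {
    matrix(as.integer(lab == i), nrow(lab), ncol(lab))
  })
}

# ---- image and mask I/O ----------------------------------------------------

#' Read an 8-bit RGB PNG image
#'
#' @param path PNG file path.
#' @return numeric `height x width x 3` array with intensities in `[0, 1]`.
#' @export
read_rgb_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) {
    stop("'", path, "' is a grayscale image; an RGB image is required")
  }
  if (dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]  # drop alpha
  check_rgb_image(img)
  img
}

#' Write an RGB image array to PNG
#' @param image numeric `height x width x 3` array in `[0, 1]`.
#' @param path output path.
#' @export
write_rgb_png <- function(image, path) {
  check_rgb_image(image)
  png::writePNG(pmin(pmax(image, 0), 1), path)
  invisible(path)
}

#' Read a binary mask from a single-channel PNG
#'
#' Foreground is any nonzero pixel (the writer uses 255).
#' @param path PNG path.
#' @return 0/1 integer matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  matrix(as.integer(img > 0), nrow(img), ncol(img))
}

#' Write a binary mask to a single-channel PNG (0 background, 255 foreground)
#' @param mask 0/1 matrix.
#' @param path output path.
#' @export
write_mask_png <- function(mask, path) {
  m <- mask_to_logical(mask)
  png::writePNG(matrix(as.numeric(m), nrow(m), ncol(m)), path)
  invisible(path)
}

#' Write a label map as PNG plus JSON sidecar
#'
#' The PNG stores the model *index* per pixel (0-based in the file, so up
#' to 256 models); the sidecar maps each index to its model label and
#' class.
#'
#' @param labelmap a `label_map`.
#' @param path output PNG path; the sidecar is written at `<path>.json`.
#' @export
write_label_map <- function(labelmap, path) {
  idx <- unclass(labelmap)
  attributes(idx) <- list(dim = dim(labelmap))
  if (max(idx) > 256) stop("label map PNG supports at most 256 models")
  png::writePNG(matrix((idx - 1L) / 255, nrow(idx), ncol(idx)), path)
  sidecar <- lapply(seq_along(attr(labelmap, "labels")), function(i) {
    list(index = i - 1L, label = attr(labelmap, "labels")[i],
         class = attr(labelmap, "classes")[i])
  })
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a label map written by [write_label_map()]
#' @param path PNG path with `<path>.json` sidecar alongside.
#' @return a `label_map`.
#' @export
read_label_map <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  sidecar <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = FALSE)
  idx <- matrix(as.integer(round(img * 255)) + 1L, nrow(img), ncol(img))
  structure(idx,
            labels = vapply(sidecar, `[[`, "", "label"),
            classes = vapply(sidecar, `[[`, "", "class"),
            class = "label_map")
}
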