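# Shared fixture builders: parametric ellipses, bitten contours, random
# color lines. All randomness is driven by the caller's seed.

ellipse_points <- function(n, a, b, ctr = c(0, 0), ang = 0) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(th); y <- b * sin(th)
  cbind(row = ctr[1] + x * cos(ang) - y * sin(ang),
        col = ctr[2] + x * sin(ang) + y * cos(ang))
}

# ellipse contour with `frac` of its arc replaced by the straight chord
# joining the bite endpoints; points spaced ~`spacing` units apart along
# both the remaining arc and the chord (like contour pixels). Returns the
# points, the chord-point indices and the true 2a.
bitten_ellipse <- function(a, ratio, ctr, ang, frac, start, spacing = 1) {
  b <- ratio * a
  dense <- ellipse_points(2000, a, b, ctr, ang)
  n <- nrow(dense)
  i0 <- round(start * n) + 1
  k <- round(frac * n)
  bite_idx <- ((i0:(i0 + k - 1)) %% n) + 1
  arc <- dense[setdiff(seq_len(n), bite_idx), , drop = FALSE]
  seg <- sqrt(rowSums((arc - rbind(arc[-1, ], arc[1, ]))^2))
  cum <- cumsum(seg)
  pick <- vapply(seq(0, max(cum) - spacing, by = spacing),
                 function(s) which.min(abs(cum - s)), integer(1))
  arc_pts <- arc[unique(pick), , drop = FALSE]
  p1 <- dense[bite_idx[1], ]; p2 <- dense[bite_idx[k], ]
  clen <- sqrt(sum((p2 - p1)^2))
  tt <- seq(0, 1, length.out = max(2, round(clen / spacing)))
  chord_pts <- cbind(p1[1] + tt * (p2[1] - p1[1]),
                     p1[2] + tt * (p2[2] - p1[2]))
  list(pts = rbind(arc_pts, chord_pts),
       bite = nrow(arc_pts) + seq_len(nrow(chord_pts)),
       true_2a = 2 * a)
}

rand_unit3 <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# random color line safely inside the unit cube for noise sigma ~ 0.01
rand_color_line <- function() {
  list(centroid = stats::runif(3, 0.35, 0.65),
       direction = rand_unit3(),
       t_range = c(-0.25, 0.25))
}

# evenly spaced positions along the line: the sample mean then estimates
# the line centroid itself rather than a randomly shifted point on the line
sample_noisy_line <- function(line, n, sigma) {
  t <- seq(line$t_range[1], line$t_range[2], length.out = n)
  pts <- outer(t, line$direction)
  pts <- sweep(pts, 2, line$centroid, `+`)
  pts + matrix(stats::rnorm(3 * n, 0, sigma), n, 3)
}

angle_deg <- function(u, v) {
  cosv <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(cosv, 1)) * 180 / pi
}

# brute-force per-pixel classification (scalar loops, no shared code path)
classify_loop_oracle <- function(image, models) {
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(0L, h, w)
  for (r in seq_len(h)) {
    for (cc in seq_len(w)) {
      p <- image[r, cc, ]
      best <- Inf; besti <- 0L
      for (i in seq_along(models$models)) {
        m <- models$models[[i]]
        v <- p - m$centroid
        rej <- v - sum(v * m$direction) * m$direction
        d <- sqrt(sum(rej^2))
        if (d < best) { best <- d; besti <- i }
      }
      out[r, cc] <- besti
    }
  }
  out
}

random_model_set <- function(k) {
  models <- lapply(seq_len(k), function(i) {
    line <- rand_color_line()
    cls <- c("Peach", "Leaf", "Branch")[(i - 1) %% 3 + 1]
    pts <- sample_noisy_line(line, 50, 0.005)
    pts <- pmin(pmax(pts, 0), 1)
    fit_linear_color_model(pts, paste0("M", i), cls)
  })
  color_model_set(models)
}

random_rgb_image <- function(h, w) {
  array(stats::runif(h * w * 3), dim = c(h, w, 3))
}
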