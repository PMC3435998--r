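test_that("total-least-squares line fit recovers exact and axis-aligned clouds", {
  m <- fit_linear_color_model(rbind(c(0, 0, 0), c(.5, .5, .5), c(1, 1, 1)),
                              "P1", "Peach")
  expect_equal(m$centroid, c(.5, .5, .5))
  expect_equal(m$direction, rep(1, 3) / sqrt(3), tolerance = 1e-12)
  expect_identical(m$n_samples, 3L)

  m2 <- fit_linear_color_model(rbind(c(.2, .1, .1), c(.8, .1, .1)),
                               "P2", "Peach")
  expect_equal(m2$centroid, c(.5, .1, .1))
  expect_equal(m2$direction, c(1, 0, 0), tolerance = 1e-12)
})

test_that("line fit errors on degenerate input, naming the model", {
  expect_error(fit_linear_color_model(rbind(c(.5, .5, .5)), "P9", "Peach"),
               "P9")
  expect_error(
    fit_linear_color_model(rbind(c(.3, .3, .3), c(.3, .3, .3)), "L7", "Leaf"),
    "identical")
})

test_that("noisy line fit recovers direction within 1 degree and centroid within 0.01", {
  set.seed(101)
  line <- rand_color_line()
  pts <- sample_noisy_line(line, 500, 0.01)
  m <- fit_linear_color_model(pmin(pmax(pts, 0), 1), "X", "Peach")
  expect_lt(angle_deg(m$direction, line$direction), 1)
  expect_true(all(abs(m$centroid - colMeans(pts)) < 1e-12))
  expect_true(all(abs(m$centroid - line$centroid) < 0.01))
})

test_that("line fit parameter recovery holds over 50 random lines", {
  set.seed(202)
  worst <- 0
  for (i in 1:50) {
    line <- rand_color_line()
    pts <- pmin(pmax(sample_noisy_line(line, 500, 0.01), 0), 1)
    m <- fit_linear_color_model(pts, "X", "Peach")
    worst <- max(worst, angle_deg(m$direction, line$direction))
    expect_true(all(abs(m$centroid - line$centroid) < 0.01))
  }
  expect_lt(worst, 2)
})

test_that("fitted line beats randomly perturbed lines on orthogonal SSR", {
  set.seed(303)
  line <- rand_color_line()
  pts <- pmin(pmax(sample_noisy_line(line, 200, 0.02), 0), 1)
  m <- fit_linear_color_model(pts, "X", "Peach")
  ssr <- function(c0, d0) sum(point_to_model_distance(
    pts, list(centroid = c0, direction = d0 / sqrt(sum(d0^2))))^2)
  best <- ssr(m$centroid, m$direction)
  for (i in 1:1000) {
    d0 <- m$direction + rnorm(3, 0, 0.2)
    c0 <- m$centroid + rnorm(3, 0, 0.05)
    expect_gte(ssr(c0, d0), best)
  }
})

test_that("point-to-line distance matches hand cases and a dense-sampling oracle", {
  m <- list(centroid = c(.2, .2, .2), direction = c(1, 1, 1) / sqrt(3))
  on_line <- c(.2, .2, .2) + 0.3 * m$direction
  expect_equal(point_to_model_distance(on_line, m), 0, tolerance = 1e-12)

  mz <- list(centroid = c(0, 0, 0), direction = c(0, 0, 1))
  expect_equal(point_to_model_distance(c(1, 0, 0), mz), 1)

  set.seed(404)
  m3 <- list(centroid = runif(3, .3, .7), direction = rand_unit3())
  p <- runif(3)
  d <- point_to_model_distance(p, m3)
  tgrid <- seq(-3, 3, length.out = 1e6)
  oracle <- sqrt(min((p[1] - (m3$centroid[1] + tgrid * m3$direction[1]))^2 +
                     (p[2] - (m3$centroid[2] + tgrid * m3$direction[2]))^2 +
                     (p[3] - (m3$centroid[3] + tgrid * m3$direction[3]))^2))
  expect_equal(d, oracle, tolerance = 1e-4)
})

test_that("distance is invariant to direction sign and centroid sliding", {
  set.seed(505)
  for (i in 1:20) {
    c0 <- runif(3); d0 <- rand_unit3(); p <- runif(3); t0 <- rnorm(1, 0, 2)
    d1 <- point_to_model_distance(p, list(centroid = c0, direction = d0))
    d2 <- point_to_model_distance(
      p, list(centroid = c0 + t0 * d0, direction = -d0))
    expect_equal(d1, d2, tolerance = 1e-9)
  }
})

test_that("fit_models_from_image recovers a known gradient patch and preserves order", {
  set.seed(606)
  img <- array(0.5, dim = c(40, 60, 3))
  line <- rand_color_line()
  # paint a rectangle with a color gradient along the line
  for (r in 5:24) for (cc in 10:29) {
    t <- ((r - 5) * 20 + (cc - 10)) / 400 * 0.4 - 0.2
    img[r, cc, ] <- line$centroid + t * line$direction
  }
  img[26:35, 10:19, 1] <- 0.9  # second, red-ish constant+jitter patch
  img[26:35, 10:19, 2] <- seq(0.1, 0.3, length.out = 10)
  anns <- list(list(label = "P1", class = "Peach",
                    rects = rbind(c(5, 10, 24, 29))),
               list(label = "L1", class = "Leaf",
                    rects = rbind(c(26, 10, 35, 19))))
  set <- fit_models_from_image(img, anns)
  expect_s3_class(set, "color_model_set")
  expect_identical(model_labels <- vapply(set$models, `[[`, "", "label"),
                   c("P1", "L1"))
  expect_lt(angle_deg(set$models[[1]]$direction, line$direction), 1)

  tiny <- list(list(label = "B1", class = "Branch",
                    rects = rbind(c(1, 1, 1, 1))))
  expect_error(fit_models_from_image(img, tiny), "B1")
  expect_error(fit_models_from_image(img, list()), "annotation")
})

test_that("model sets round-trip through JSON at full double precision", {
  set.seed(707)
  set <- random_model_set(4)
  path <- withr::local_tempfile(fileext = ".json")
  write_color_models(set, path)
  back <- read_color_models(path)
  for (i in seq_along(set$models)) {
    expect_equal(back$models[[i]]$centroid, set$models[[i]]$centroid,
                 tolerance = 1e-14)
    expect_equal(back$models[[i]]$direction, set$models[[i]]$direction,
                 tolerance = 1e-14)
    expect_identical(back$models[[i]]$label, set$models[[i]]$label)
    expect_identical(back$models[[i]]$n_samples, set$models[[i]]$n_samples)
  }
})

test_that("annotation files convert 0-based half-open rects to 1-based inclusive", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(list(label = "P1", class = "Peach",
                                 rects = list(c(0, 0, 10, 20)))),
                       path, auto_unbox = TRUE)
  anns <- read_annotations(path)
  expect_equal(unname(anns[[1]]$rects[1, ]), c(1, 1, 10, 20))
  img <- array(0.5, dim = c(5, 5, 3))
  expect_error(read_annotations(path, image = img), "outside")
})

test_that("color model set enforces unique labels and a Peach class", {
  set.seed(808)
  m1 <- fit_linear_color_model(rbind(c(0,0,0), c(1,1,1)), "A", "Leaf")
  m2 <- fit_linear_color_model(rbind(c(0,0,0), c(1,0,0)), "B", "Peach")
  expect_error(color_model_set(list(m1, m1)), "unique|Peach")
  expect_error(color_model_set(list(m1)), "Peach")
  expect_silent(color_model_set(list(m1, m2)))
})
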