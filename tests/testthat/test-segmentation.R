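axis_models <- function() {
  # lines along the R and G axes through the origin
  r_axis <- fit_linear_color_model(rbind(c(0, 0, 0), c(1, 0, 0)), "R", "Peach")
  g_axis <- fit_linear_color_model(rbind(c(0, 0, 0), c(0, 1, 0)), "G", "Leaf")
  color_model_set(list(r_axis, g_axis))
}

test_that("pixels land on their own zero-distance line", {
  img <- array(0, dim = c(1, 2, 3))
  img[1, 1, ] <- c(1, 0, 0)
  img[1, 2, ] <- c(0, 1, 0)
  lm <- classify_image(img, axis_models())
  expect_equal(as.integer(lm), c(1L, 2L))
  expect_identical(attr(lm, "labels"), c("R", "G"))
})

test_that("equidistant pixels break ties toward the earlier model", {
  img <- array(0, dim = c(1, 1, 3))
  img[1, 1, ] <- c(0.5, 0.5, 0)  # same distance to R-axis and G-axis lines
  lm <- classify_image(img, axis_models())
  expect_equal(as.integer(lm), 1L)
})

test_that("classification matches the per-pixel loop oracle and is deterministic", {
  set.seed(11)
  models <- random_model_set(5)
  img <- random_rgb_image(32, 32)
  lm1 <- classify_image(img, models)
  lm2 <- classify_image(img, models)
  expect_identical(unclass(lm1)[, ], unclass(lm2)[, ])
  oracle <- classify_loop_oracle(img, models)
  expect_identical(matrix(as.integer(lm1), 32, 32), oracle)
})

test_that("peach mask is 1 exactly on Peach-class labels", {
  models <- axis_models()
  lm <- matrix(c(1L, 2L, 2L, 1L), 2, 2)
  expect_equal(peach_mask(lm, models), matrix(c(1L, 0L, 0L, 1L), 2, 2))
  expect_equal(sum(peach_mask(matrix(2L, 3, 3), models)), 0)
  expect_error(peach_mask(matrix(3L, 2, 2), models), "indices")

  # several Peach models pool into one mask
  set.seed(12)
  p1 <- fit_linear_color_model(rbind(c(0,0,0), c(1,0,0)), "P1", "Peach")
  p2 <- fit_linear_color_model(rbind(c(0,0,0), c(1,.2,0)), "P2", "Peach")
  l1 <- fit_linear_color_model(rbind(c(0,0,0), c(0,1,0)), "L1", "Leaf")
  ms <- color_model_set(list(p1, p2, l1))
  lm2 <- matrix(sample(1:3, 25, replace = TRUE), 5, 5)
  mk <- peach_mask(lm2, ms)
  for (i in 1:5) for (j in 1:5) {
    expect_identical(mk[i, j], as.integer(lm2[i, j] %in% c(1L, 2L)))
  }
})

test_that("component labeling respects 8- vs 4-connectivity", {
  m <- matrix(0L, 5, 5)
  m[1, 1] <- 1L; m[2, 2] <- 1L; m[4, 4] <- 1L
  expect_equal(max(label_components(m, 8)), 2)  # diagonals join
  expect_equal(max(label_components(m, 4)), 3)  # diagonals split
})

test_that("cleanup removes sub-threshold components, keeps 50-px ones, fills donuts", {
  m <- matrix(0L, 40, 80)
  m[2:8, 2:8] <- 1L          # 49 pixels -> removed
  m[2:11, 20:24] <- 1L       # 50 pixels -> kept
  m[20:34, 40:54] <- 1L      # donut, outer 15x15
  m[25:29, 45:49] <- 0L      # hole
  cleaned <- clean_mask(m, min_size = 50)
  expect_equal(sum(cleaned[2:8, 2:8]), 0)
  expect_equal(sum(cleaned[2:11, 20:24]), 50)
  expect_equal(sum(cleaned[20:34, 40:54]), 225)  # hole filled
  expect_identical(clean_mask(cleaned, 50), cleaned)  # idempotent
  expect_equal(sum(clean_mask(matrix(0L, 5, 5))), 0)
})

test_that("cleanup only fills holes and only deletes whole small components", {
  set.seed(13)
  for (rep in 1:5) {
    m <- matrix(as.integer(runif(60 * 60) < 0.35), 60, 60)
    cleaned <- clean_mask(m, min_size = 50)
    lab <- label_components(m, 8)
    sizes <- tabulate(lab[lab > 0])
    surviving <- which(sizes >= 50)
    # every pixel of a surviving component is retained
    expect_true(all(cleaned[lab %in% surviving] == 1L))
    # added pixels are holes: not 4-connected to the border background
    added <- cleaned == 1L & m == 0L
    if (any(added)) {
      bg <- label_components(1L - m, 4)  # background of original
      border <- unique(c(bg[1, ], bg[60, ], bg[, 1], bg[, 60]))
      expect_true(all(!(bg[added] %in% border[border > 0])))
    }
  }
})

test_that("extract_components splits blobs in row-major order and partitions the mask", {
  m <- matrix(0L, 20, 20)
  m[2:5, 2:5] <- 1L
  m[10:14, 8:12] <- 1L
  comps <- extract_components(m)
  expect_length(comps, 2)
  expect_equal(comps[[1]] + comps[[2]], m)          # union, disjoint
  expect_equal(sum(comps[[1]] * comps[[2]]), 0)
  expect_equal(which(comps[[1]] == 1L)[1] < which(comps[[2]] == 1L)[1], TRUE)

  single <- extract_components(comps[[1]])
  expect_length(single, 1)
  expect_equal(single[[1]], comps[[1]])
  expect_length(extract_components(matrix(0L, 4, 4)), 0)
})

test_that("component counts agree with a flood-fill loop oracle on random scatter", {
  flood_count <- function(m) {
    h <- nrow(m); w <- ncol(m); seen <- matrix(FALSE, h, w); k <- 0
    for (r in 1:h) for (cc in 1:w) {
      if (m[r, cc] == 1L && !seen[r, cc]) {
        k <- k + 1
        stack <- list(c(r, cc)); seen[r, cc] <- TRUE
        while (length(stack)) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            nr <- p[1] + dr; nc <- p[2] + dc
            if (nr >= 1 && nr <= h && nc >= 1 && nc <= w &&
                m[nr, nc] == 1L && !seen[nr, nc]) {
              seen[nr, nc] <- TRUE
              stack[[length(stack) + 1]] <- c(nr, nc)
            }
          }
        }
      }
    }
    k
  }
  set.seed(14)
  for (rep in 1:5) {
    m <- matrix(as.integer(runif(30 * 30) < 0.3), 30, 30)
    expect_equal(length(extract_components(m)), flood_count(m))
  }
})

test_that("masks and label maps round-trip through PNG", {
  set.seed(15)
  m <- matrix(as.integer(runif(25 * 30) < 0.4), 25, 30)
  p <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, p)
  expect_identical(read_mask_png(p), m)

  models <- random_model_set(3)
  img <- random_rgb_image(10, 12)
  lm <- classify_image(img, models)
  lp <- withr::local_tempfile(fileext = ".png")
  write_label_map(lm, lp)
  back <- read_label_map(lp)
  expect_identical(matrix(as.integer(back), 10, 12),
                   matrix(as.integer(lm), 10, 12))
  expect_identical(attr(back, "labels"), attr(lm, "labels"))
})
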