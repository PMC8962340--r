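test_that("manual mask files are taken as-is and shape-checked", {
  cube <- ramp_cube()
  m <- matrix(1L, 6, 5)
  msk <- segment_mask(cube, "manual-file", m)
  expect_true(all(msk$mask))
  p <- file.path(withr::local_tempdir(), "m.pgm")
  write_pgm(m, p)
  expect_true(all(segment_mask(cube, "manual-file", p)$mask))
  expect_error(segment_mask(cube, "manual-file", matrix(1L, 3, 3)), "shape")
})

test_that("automatic segmentation recovers the synthetic kidney", {
  scene <- reduced_scene(time_points = 1L)
  kid <- generate_kidney(3L, reduced_templates(scene), scene, seed = 5L)
  refl <- correct_reflectance(kid$cubes[[1]], kid$refs)
  msk <- segment_mask(refl, "threshold-auto", 0.06)
  expect_gt(sum(msk$mask & kid$mask) / sum(kid$mask), 0.95)
  expect_error(segment_mask(refl, "threshold-auto", max(refl$values) + 1), "empty")
})

test_that("region split cuts the bounding box into three equal slabs", {
  m <- matrix(FALSE, 100, 40)
  m[6:95, 5:30] <- TRUE                      # 90 rows tall, 26 wide -> split on y
  part <- split_regions(m)
  expect_identical(part$axis, "y")
  sizes <- table(factor(part$labels[part$labels > 0], levels = 1:3))
  expect_equal(as.integer(sizes), rep(30L * 26L, 3L))

  m2 <- matrix(FALSE, 100, 40)
  m2[3:93, 5:30] <- TRUE                     # 91 rows: remainder to the upper slab
  sizes2 <- tapply(rep(1, sum(m2)), split_regions(m2)$labels[m2], sum)
  expect_equal(as.integer(sizes2), c(31L, 30L, 30L) * 26L)
})

test_that("region split conserves foreground pixels on irregular masks", {
  set.seed(3)
  for (i in 1:5) {
    m <- matrix(runif(60 * 50) > 0.4, 60, 50)
    part <- split_regions(m)
    expect_identical(part$labels > 0, m)      # union = foreground, disjoint by construction
  }
  expect_error(split_regions(matrix(FALSE, 4, 4)), "empty")
})

test_that("homogeneity of a constant window is zero and a hand case checks out", {
  h0 <- homogeneity_map(matrix(5, 10, 10), matrix(TRUE, 10, 10), k = 4, l = 4)
  expect_true(all(h0$H[h0$valid] == 0))

  # 2x2 window, columns (0,0) and (1,1): two unit x-differences, no y-difference
  h2 <- homogeneity_map(matrix(c(0, 0, 1, 1), 2, 2), matrix(TRUE, 2, 2), k = 2, l = 2)
  expect_equal(h2$H[1, 1], 0.5)
  expect_true(all(h0$H[h0$valid] >= 0))
})

test_that("homogeneity map equals the brute-force oracle on random instances", {
  set.seed(101)
  for (rep in 1:50) {
    nr <- sample(10:20, 1); nc <- sample(10:20, 1)
    k <- sample(3:5, 1); l <- sample(3:5, 1)
    img <- matrix(rnorm(nr * nc), nr, nc)
    mask <- matrix(runif(nr * nc) > 0.15, nr, nc)
    hm <- suppressWarnings(homogeneity_map(img, mask, k = k, l = l))
    valid_ref <- matrix(FALSE, nr, nc)
    dev <- 0
    for (y0 in seq_len(nr - l + 1)) for (x0 in seq_len(nc - k + 1)) {
      window_inside <- all(mask[y0:(y0 + l - 1), x0:(x0 + k - 1)])
      valid_ref[y0, x0] <- window_inside
      if (window_inside) {
        dev <- max(dev, abs(hm$H[y0, x0] - brute_homogeneity(img, y0, x0, k, l)))
      }
    }
    expect_identical(hm$valid, valid_ref)
    expect_lte(dev, 1e-12)
  }
})

test_that("selection returns four ROIs per region on a large homogeneous organ", {
  m <- matrix(TRUE, 120, 160)
  img <- matrix(0, 120, 160)
  part <- split_regions(m)
  hm <- homogeneity_map(img, m, k = 20, l = 20)
  rois <- select_rois(hm, part, n_per_region = 4L)
  expect_identical(nrow(rois), 12L)
  expect_equal(as.integer(table(factor(rois$region, c("upper", "middle", "lower")))),
               c(4L, 4L, 4L))
  # tie-break on the constant map: first pick of each region is its
  # lexicographically smallest (y0, x0) valid anchor
  first_upper <- rois[rois$region == "upper", ][1, ]
  expect_identical(c(first_upper$y0, first_upper$x0), c(0L, 0L))
})

test_that("planted minima are picked first in each region", {
  set.seed(9)
  m <- matrix(TRUE, 90, 150)                  # split along x: slabs of 50 columns
  img <- matrix(rnorm(90 * 150, sd = 1), 90, 150)
  plant <- data.frame(x = c(10, 60, 110), y = c(30, 40, 20))
  for (i in 1:3) {
    img[plant$y[i]:(plant$y[i] + 9), plant$x[i]:(plant$x[i] + 9)] <- 0  # flat patch
  }
  hm <- homogeneity_map(img, m, k = 10, l = 10)
  rois <- select_rois(hm, split_regions(m), n_per_region = 1L)
  for (i in 1:3) {
    expect_true(any(rois$x0 == plant$x[i] - 1 & rois$y0 == plant$y[i] - 1))
  }
})

test_that("selected ROIs respect the overlap and containment constraints", {
  set.seed(23)
  for (rep in 1:5) {
    img <- matrix(rnorm(100 * 140), 100, 140)
    m <- matrix(TRUE, 100, 140)
    hm <- homogeneity_map(img, m, k = 16, l = 16)
    rois <- select_rois(hm, split_regions(m), n_per_region = 4L)
    expect_identical(nrow(rois), 12L)
    for (i in seq_len(nrow(rois))) {
      for (j in seq_len(i - 1L)) {
        ox <- max(0, min(rois$x0[i] + 16, rois$x0[j] + 16) - max(rois$x0[i], rois$x0[j]))
        oy <- max(0, min(rois$y0[i] + 16, rois$y0[j] + 16) - max(rois$y0[i], rois$y0[j]))
        expect_lt(ox * oy, 0.5 * 16 * 16)
      }
      expect_true(rois$x0[i] >= 0 && rois$x0[i] + 16 <= 140)
      expect_true(rois$y0[i] >= 0 && rois$y0[i] + 16 <= 100)
    }
  }
})

test_that("an organ smaller than the window yields zero ROIs and a warning", {
  m <- matrix(FALSE, 30, 30)
  m[10:15, 10:15] <- TRUE                     # 6x6 organ, 10x10 window
  img <- matrix(rnorm(900), 30, 30)
  expect_warning(hm <- homogeneity_map(img, m, k = 10, l = 10), "no valid")
  warns <- testthat::capture_warnings(rois <- select_rois(hm, split_regions(m)))
  expect_length(warns, 3L)                    # one shortfall warning per region
  expect_match(warns, "0 of 4", all = TRUE)
  expect_identical(nrow(rois), 0L)
})

test_that("ROI extraction slices the source cube exactly", {
  cube <- ramp_cube(20, 20, 3)
  rois <- data.frame(x0 = 0L, y0 = 0L, k = 4L, l = 5L, region = "upper",
                     H = 0.1, stringsAsFactors = FALSE)
  s <- extract_roi_samples(cube, rois, label = 2L)
  expect_length(s, 1L)
  expect_equal(s[[1]]$values, cube$values[1:5, 1:4, , drop = FALSE])
  expect_identical(s[[1]]$label, 2L)
  expect_identical(s[[1]]$region, "upper")

  expect_length(extract_roi_samples(cube, rois[0, ]), 0L)
  bad <- data.frame(x0 = 18L, y0 = 0L, k = 4L, l = 4L, region = "upper", H = 0)
  expect_error(extract_roi_samples(cube, bad), "bounds")
})

test_that("ROI tables round-trip through CSV with 0-based coordinates", {
  rois <- data.frame(x0 = c(0L, 12L), y0 = c(3L, 7L), k = 10L, l = 10L,
                     region = c("upper", "middle"), H = c(0.2, 0.4))
  p <- file.path(withr::local_tempdir(), "rois.csv")
  write_roi_csv(rois, p, kidney_id = "K01", time_point = 2L)
  back <- read.csv(p)
  expect_identical(back$x0, c(0L, 12L))
  expect_identical(back$kidney, c("K01", "K01"))
})
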