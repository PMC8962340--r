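test_that("class templates are positive, separable and collapse at separation 0", {
  wl <- seq(500, 995, by = 5)
  tpl <- class_templates(wl)
  expect_true(all(tpl$means > 0))
  expect_gt(tpl$separation_l2, 3 * tpl$intra_sd)       # default separable regime

  flat <- class_templates(wl, separation = 0)
  expect_equal(flat$means[1, ], flat$means[2, ], tolerance = 1e-12)
  expect_equal(flat$means[2, ], flat$means[3, ], tolerance = 1e-12)
  expect_equal(flat$separation_l2, 0, tolerance = 1e-12)
})

test_that("scene validation rejects kidneys that cannot fit with an ROI margin", {
  expect_error(scene_spec(width = 100, height = 100, roi_size = 50), "margin")
  sc <- reduced_scene()
  expect_gte(sc$ellipse$a, sc$roi_size)
  expect_gte(sc$ellipse$b, sc$roi_size)
})

test_that("generation is bit-deterministic given the seed", {
  scene <- reduced_scene(time_points = 2L)
  tpl <- reduced_templates(scene)
  k1 <- generate_kidney(2L, tpl, scene, seed = 42L)
  k2 <- generate_kidney(2L, tpl, scene, seed = 42L)
  expect_identical(k1$cubes[[1]]$values, k2$cubes[[1]]$values)
  expect_identical(k1$cubes[[2]]$values, k2$cubes[[2]]$values)
  expect_identical(k1$refs$white$values, k2$refs$white$values)
  expect_identical(k1$highlights, k2$highlights)
  k3 <- generate_kidney(2L, tpl, scene, seed = 43L)
  expect_false(identical(k1$cubes[[1]]$values, k3$cubes[[1]]$values))
})

test_that("raw counts sit strictly between dark and white references", {
  scene <- reduced_scene(time_points = 2L)
  kid <- generate_kidney(1L, reduced_templates(scene), scene, seed = 3L)
  for (cube in kid$cubes) {
    expect_true(all(cube$values > kid$refs$dark$values))
    expect_true(all(cube$values < kid$refs$white$values))
  }
})

test_that("the correction chain recovers the generated absorbance within 2%", {
  scene <- reduced_scene(time_points = 3L)
  tpl <- reduced_templates(scene)
  for (cl in 1:3) {
    kid <- generate_kidney(cl, tpl, scene, seed = 20L + cl)
    # exclude planted highlights and a guard ring around them
    for (t in c(1L, 3L)) {
      excl <- matrix(FALSE, scene$height, scene$width)
      hl <- kid$highlights[kid$highlights$time_point == t, ]
      for (i in seq_len(nrow(hl))) {
        ys <- pmax(1, hl$y[i] - 4):pmin(scene$height, hl$y[i] + 6)
        xs <- pmax(1, hl$x[i] - 4):pmin(scene$width, hl$x[i] + 6)
        excl[ys, xs] <- TRUE
      }
      use <- kid$mask & !excl
      ab <- to_absorbance(correct_reflectance(kid$cubes[[t]], kid$refs))
      rec <- apply(ab$values, 3, function(p) mean(p[use]))
      expect_lt(max(abs(rec - kid$expected_abs[t, ]) / kid$expected_abs[t, ]), 0.02)
    }
  }
})

test_that("specular highlights are never inside selected ROIs", {
  scene <- reduced_scene(time_points = 2L)
  kid <- generate_kidney(3L, reduced_templates(scene), scene, seed = 15L)
  mask <- segment_mask(kid$cubes[[1]], "manual-file", kid$mask * 1L)
  part <- split_regions(mask)
  for (t in 1:2) {
    refl <- correct_reflectance(kid$cubes[[t]], kid$refs)
    origin <- select_wavelengths(to_absorbance(refl), 550, 995)
    band <- origin$values[, , nearest_band(origin$wavelengths, 805)]
    hm <- homogeneity_map(band, mask, k = 12, l = 12)
    rois <- select_rois(hm, part)
    hl <- kid$highlights[kid$highlights$time_point == t, ]
    for (i in seq_len(nrow(rois))) {
      inside <- hl$x >= rois$x0[i] & hl$x < rois$x0[i] + 12 &
                hl$y >= rois$y0[i] & hl$y < rois$y0[i] + 12
      expect_false(any(inside))
    }
  }
})

test_that("dataset generation writes cubes, masks and metadata to disk", {
  dir <- withr::local_tempdir()
  scene <- reduced_scene(time_points = 2L)
  ds <- generate_dataset(c(1L, 1L, 1L), reduced_templates(scene), scene,
                         seed = 1L, dir = dir, roi_size = 12L)
  expect_length(list.files(dir, pattern = "_t\\d+\\.bin$"), 6L)  # 3 kidneys x 2 tp
  expect_length(list.files(dir, pattern = "_mask\\.pgm$"), 3L)
  expect_length(list.files(dir, pattern = "_(dark|white)\\.bin$"), 6L)
  meta <- read.csv(file.path(dir, "metadata.csv"))
  expect_identical(nrow(meta), 6L)
  expect_setequal(unique(meta$class), 1:3)

  back <- read_cube(file.path(dir, meta$cube[1]))
  expect_identical(back$kind, "raw")
  expect_identical(dim(back$values)[1:2], c(scene$height, scene$width))
})

test_that("class means separate more between classes than within", {
  ds <- reduced_dataset(seed = 0L)
  sigs <- lapply(ds$kidneys, function(k) roi_signature(k$samples)$mean)
  labels <- ds$labels
  within <- c(); between <- c()
  for (i in seq_along(sigs)) for (j in seq_len(i - 1L)) {
    r <- pearson_r(sigs[[i]], sigs[[j]])
    if (labels[i] == labels[j]) within <- c(within, r) else between <- c(between, r)
  }
  expect_gt(min(within), max(between))
  expect_gt(min(within), 0.9)                  # low intra-class variation
})
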