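test_that("ENVI round trip preserves values, wavelengths and metadata", {
  set.seed(11)
  for (interleave in c("bsq", "bil")) {
    cube <- hsi_cube(array(runif(4 * 4 * 3, 0, 4000), c(4, 4, 3)),
                     c(500, 505, 510), "raw", kidney_id = "K01", time_point = 3L)
    base <- file.path(withr::local_tempdir(), "cube")
    write_cube(cube, base, interleave = interleave)
    back <- read_cube(base)
    expect_identical(back$values, cube$values)
    expect_equal(as.numeric(back$wavelengths), as.numeric(cube$wavelengths))
    expect_identical(back$kind, "raw")
    expect_identical(back$kidney_id, "K01")
    expect_identical(back$time_point, 3L)
  }
})

test_that("reflectance and absorbance kinds survive the ENVI round trip", {
  cube <- hsi_cube(array(runif(12), c(2, 2, 3)), c(600, 605, 610), "reflectance")
  base <- file.path(withr::local_tempdir(), "refl")
  write_cube(cube, base)
  expect_identical(read_cube(base)$kind, "reflectance")
})

test_that("inconsistent header fields raise format errors naming the field", {
  cube <- ramp_cube()
  base <- file.path(withr::local_tempdir(), "cube")
  write_cube(cube, base)

  hdr <- readLines(paste0(base, ".hdr"))
  bad <- sub("^bands = 4", "bands = 90", hdr)
  writeLines(bad, paste0(base, ".hdr"))
  expect_error(read_cube(base), "wavelength")

  writeLines(hdr[!grepl("^wavelength =", hdr)], paste0(base, ".hdr"))
  expect_error(read_cube(base), "wavelength")

  writeLines(sub("^interleave = bsq", "interleave = bip", hdr), paste0(base, ".hdr"))
  expect_error(read_cube(base), "interleave")

  expect_error(read_cube(file.path(tempdir(), "nonexistent")), "header")
})

test_that("a 64x48x90 cube spanning 550-995 nm reads back with 90 bands", {
  wl <- seq(550, 995, by = 5)
  expect_length(wl, 90L)
  cube <- hsi_cube(array(runif(48 * 64 * 90), c(48, 64, 90)), wl, "raw")
  base <- file.path(withr::local_tempdir(), "fix")
  write_cube(cube, base)
  back <- read_cube(base)
  expect_identical(dim(back$values), c(48L, 64L, 90L))
  expect_equal(range(as.numeric(back$wavelengths)), c(550, 995))
})

test_that("reflectance correction reproduces its defining identities", {
  cube <- ramp_cube()
  refs <- flat_refs(cube)
  d <- dim(cube$values)

  white_like <- hsi_cube(array(1100, d), cube$wavelengths, "raw")
  expect_equal(correct_reflectance(white_like, refs)$values, array(1, d))

  dark_like <- hsi_cube(array(100, d), cube$wavelengths, "raw")
  expect_equal(correct_reflectance(dark_like, refs)$values, array(0, d))

  one <- hsi_cube(array(600, d), cube$wavelengths, "raw")
  expect_equal(correct_reflectance(one, refs)$values[1, 1, 1], 0.5)
  expect_identical(correct_reflectance(one, refs)$kind, "reflectance")
})

test_that("degenerate references are repaired with a warning, never divided through", {
  cube <- ramp_cube()
  d <- dim(cube$values)
  dark <- array(100, d)
  white <- array(1100, d)
  white[1, 1, 1] <- 100                      # zero dynamic range at one element
  refs <- reference_cubes(hsi_cube(dark, cube$wavelengths, "raw"),
                          hsi_cube(white, cube$wavelengths, "raw"))
  expect_warning(out <- correct_reflectance(cube, refs), "repaired")
  expect_true(all(is.finite(out$values)))
  expect_true(all(out$values >= 0 & out$values <= 2))
})

test_that("shape mismatches between cube and references are rejected", {
  cube <- ramp_cube()
  small <- hsi_cube(array(1, c(3, 3, 4)), cube$wavelengths, "raw")
  expect_error(correct_reflectance(cube, reference_cubes(small, small)), "mismatch")
})

test_that("absorbance is the negative decadic log with a floor", {
  wl <- c(500, 505, 510)
  refl <- hsi_cube(array(rep(c(1, 0.1, 0.5), each = 4), c(2, 2, 3)), wl, "reflectance")
  ab <- to_absorbance(refl)
  expect_identical(ab$kind, "absorbance")
  expect_equal(ab$values[, , 1], matrix(0, 2, 2))
  expect_equal(ab$values[, , 2], matrix(1, 2, 2))
  expect_equal(ab$values[1, 1, 3], 0.30103, tolerance = 1e-5)

  zero <- hsi_cube(array(0, c(2, 2, 3)), wl, "reflectance")
  expect_true(all(is.finite(to_absorbance(zero)$values)))
  expect_error(to_absorbance(ramp_cube()), "reflectance")
})

test_that("wavelength selection keeps exactly the in-range bands", {
  wl <- seq(500, 995, by = 5)
  cube <- hsi_cube(array(runif(2 * 2 * length(wl)), c(2, 2, length(wl))), wl, "raw")
  sel <- select_wavelengths(cube, 550, 995)
  expect_identical(dim(sel$values)[3], 90L)
  expect_equal(range(as.numeric(sel$wavelengths)), c(550, 995))

  full <- select_wavelengths(cube, 500, 995)
  expect_equal(full$values, cube$values)

  again <- select_wavelengths(sel, 550, 995)
  expect_equal(again$values, sel$values)      # idempotent for the same bounds

  expect_error(select_wavelengths(cube, 1200, 1300), "no bands")
  expect_error(select_wavelengths(cube, 900, 600))
})

test_that("correction then absorbance is monotone decreasing in raw intensity", {
  set.seed(7)
  wl <- c(700, 705)
  refs <- flat_refs(hsi_cube(array(0, c(1, 1, 2)), wl, "raw"))
  raws <- sort(runif(25, 150, 1050))
  abs_vals <- vapply(raws, function(r) {
    cube <- hsi_cube(array(r, c(1, 1, 2)), wl, "raw")
    to_absorbance(correct_reflectance(cube, refs))$values[1, 1, 1]
  }, numeric(1))
  expect_true(all(diff(abs_vals) < 0))
})

test_that("PGM masks round-trip", {
  m <- matrix(sample(0:1, 35, replace = TRUE), 5, 7)
  p <- file.path(withr::local_tempdir(), "m.pgm")
  write_pgm(m, p)
  expect_identical(read_pgm(p), m)
})
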