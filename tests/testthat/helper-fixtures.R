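# Shared fixtures, all generated in code. Heavy objects are cached for the
# duration of one test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Reduced desk-scale scene used by training and generator tests: 120 x 90 px,
# 12 bands (500-995 nm at 45 nm), 12 px ROIs, 4 time points.
reduced_scene <- function(time_points = 4L) {
  scene_spec(width = 120L, height = 90L, wl_step = 45, time_points = time_points,
             roi_size = 12L, highlight_count = 2L, highlight_radius = 2L)
}

reduced_templates <- function(scene = reduced_scene(), separation = 1) {
  class_templates(scene$wavelengths, separation = separation)
}

# Fully processed 3/3/3-kidney dataset on the reduced scene.
reduced_dataset <- function(seed = 0L, separation = 1) {
  cached(sprintf("ds_%d_%s", seed, separation), {
    scene <- reduced_scene()
    tpl <- reduced_templates(scene, separation)
    suppressWarnings(
      generate_dataset(c(3L, 3L, 3L), tpl, scene, seed = seed, roi_size = 12L))
  })
}

# Training configuration matched to the reduced scene.
reduced_train_config <- function(seed = 0L, ...) {
  args <- list(...)
  defaults <- list(dropout_rate = 0.5, lr_decay = 0.11, base_lr = 4e-3,
                   batch_size = 16L, max_epochs = 5L, patience = 2L,
                   seed = seed, block_channels = c(4L, 8L, 16L, 32L))
  defaults[names(args)] <- args
  do.call(train_config, defaults)
}

# Small raw cube with a linear ramp, plus matched flat references.
ramp_cube <- function(ny = 6L, nx = 5L, nb = 4L, wl = seq(500, by = 5, length.out = nb)) {
  vals <- array(seq_len(ny * nx * nb), c(ny, nx, nb))
  hsi_cube(vals, wl, "raw")
}

flat_refs <- function(cube, dark = 100, white = 1100) {
  d <- dim(cube$values)
  reference_cubes(
    hsi_cube(array(dark, d), cube$wavelengths, "raw"),
    hsi_cube(array(white, d), cube$wavelengths, "raw"))
}

# Tiny labelled ROI samples with class-dependent mean patterns (no imaging
# chain), for classifier unit tests: class c has mean c/10 in band c.
toy_samples <- function(n_per_class = 8L, side = 8L, nb = 5L, sd = 0.01,
                        seed = 42L) {
  set.seed(seed)
  wl <- seq(500, by = 5, length.out = nb)
  out <- list()
  for (cl in 1:3) {
    for (i in seq_len(n_per_class)) {
      v <- array(stats::rnorm(side * side * nb, 0, sd), c(side, side, nb))
      v[, , cl] <- v[, , cl] + cl / 10
      out[[length(out) + 1L]] <- list(values = v, wavelengths = wl,
                                      kidney_id = sprintf("T%d_%d", cl, i),
                                      time_point = 1L, region = "middle",
                                      label = cl)
    }
  }
  out
}

# Brute-force homogeneity oracle: explicit double loop over window pixels.
brute_homogeneity <- function(img, y0, x0, k, l) {
  w <- img[y0:(y0 + l - 1L), x0:(x0 + k - 1L)]
  sx <- 0
  for (j in 1:l) for (i in 1:(k - 1L)) sx <- sx + (w[j, i] - w[j, i + 1L])^2
  sy <- 0
  for (j in 1:(l - 1L)) for (i in 1:k) sy <- sy + (w[j, i] - w[j + 1L, i])^2
  (sx + sy) / (k * l)
}

# Oracle "classifier" backends: read the true label off each sample.
oracle_train <- function(train_samples, val_samples, cfg) {
  structure(list(stopping_epoch = cfg$max_epochs, cfg = cfg),
            class = "oracle_fit")
}
oracle_predict <- function(fit, samples) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1L))
  scores <- matrix(0, length(labels), 3L)
  scores[cbind(seq_along(labels), labels)] <- 1
  list(labels = labels, scores = scores)
}
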