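# Synthetic normothermic-perfusion HSI scenes: labelled kidneys with
# class-dependent absorbance signatures, per-kidney random effects, smooth
# spatial illumination structure, slow per-time-point drift, pixel noise and
# small specular highlights, converted to raw camera counts by inverting the
# reference correction against generated dark/white cubes. The generator's
# defaults define the study conditions the pipeline is tested under.

gaussian_band <- function(wl, center, width) exp(-0.5 * ((wl - center) / width)^2)

#' Class-dependent spectral templates
#'
#' Phenomenological mean absorbance spectra of the three functional classes:
#' smooth baselines with hemoglobin-like absorption bands near 560 and 760 nm
#' and a water-like band near 970 nm. Classes differ in overall level and in
#' relative band depth (so the differences survive per-pixel vector
#' normalization), with class 1 (nonfunctional) the most blood-congested.
#' The `separation` factor scales all class differences around the grand
#' mean: 1 = default separable regime, 0 = identical classes (negative
#' control).
#'
#' @param wavelengths Wavelength grid (nm).
#' @param separation Inter-class separation multiplier (default 1).
#' @param intra_sd Scale of the smooth per-kidney random effect in absorbance
#'   units (default 0.02).
#' @param pixel_sd Per-pixel/band Gaussian noise in absorbance units
#'   (default 0.01).
#' @return Object of class `"class_template"` with the 3 x bands `means`
#'   matrix and `separation_l2`, the minimum pairwise L2 distance between
#'   class means.
#' @export
class_templates <- function(wavelengths, separation = 1, intra_sd = 0.02,
                            pixel_sd = 0.01) {
  wl <- as.numeric(wavelengths)
  b560 <- gaussian_band(wl, 560, 28)
  b760 <- gaussian_band(wl, 760, 35)
  b970 <- gaussian_band(wl, 970, 45)
  means <- rbind(
    `1` = 0.90 + 0.55 * b560 + 0.12 * b760 + 0.10 * b970,  # nonfunctional: congested
    `2` = 0.65 + 0.33 * b560 + 0.24 * b760 + 0.18 * b970,  # limited
    `3` = 0.45 + 0.14 * b560 + 0.10 * b760 + 0.30 * b970   # functional: well perfused
  )
  grand <- colMeans(means)
  means <- sweep(means, 2L, grand) * separation +
    matrix(grand, 3L, length(wl), byrow = TRUE)
  d12 <- sqrt(sum((means[1L, ] - means[2L, ])^2))
  d13 <- sqrt(sum((means[1L, ] - means[3L, ])^2))
  d23 <- sqrt(sum((means[2L, ] - means[3L, ])^2))
  structure(list(wavelengths = wavelength_grid(wl), means = means,
                 separation = separation, separation_l2 = min(d12, d13, d23),
                 intra_sd = intra_sd, pixel_sd = pixel_sd),
            class = "class_template")
}

#' Synthetic acquisition scene
#'
#' Geometry and nuisance structure of one pushbroom acquisition: image size,
#' band grid, elliptical kidney-shaped foreground on a dark background,
#' specular highlights and acquisition time points. The default scene is a
#' 480 x 360 px reduction of the camera's 1280 x 960 frame — the smallest
#' frame in the same aspect ratio whose poles still admit four 50 px ROIs
#' under the overlap rules; the ellipse leaves a margin of at least
#' `roi_size` to every image border.
#'
#' @param width,height Image size in px (samples x lines).
#' @param wl_from,wl_to,wl_step Band grid in nm (default 500-995 at 5 nm).
#' @param time_points Acquisitions per kidney (default 14: before perfusion
#'   plus regular intervals).
#' @param roi_size ROI side the scene must accommodate (default 50 px).
#' @param background_absorbance Apparent absorbance of the dark background.
#' @param highlight_count,highlight_radius Specular highlights per
#'   acquisition and their radius in px (small relative to `roi_size`, as
#'   real glare spots are).
#' @param drift_scale Amplitude of the monotone per-time-point band-depth
#'   drift (absorbance units; kept below the inter-class separation so labels
#'   stay time-invariant).
#' @param spatial_scale Amplitude of the smooth spatial intensity field.
#' @param white_level Mean white-reference count level.
#' @return Object of class `"scene_spec"`.
#' @export
scene_spec <- function(width = 480L, height = 360L, wl_from = 500, wl_to = 995,
                       wl_step = 5, time_points = 14L, roi_size = 50L,
                       background_absorbance = 1.6, highlight_count = 3L,
                       highlight_radius = 4L, drift_scale = 0.02,
                       spatial_scale = 0.015, white_level = 3000) {
  wl <- seq(wl_from, wl_to, by = wl_step)
  if (length(wl) < 2L) stop("band grid needs at least 2 bands", call. = FALSE)
  a <- width / 2 - roi_size
  b <- height / 2 - roi_size
  if (a < roi_size || b < roi_size) {
    stop("scene too small: kidney cannot fit with a margin of one ROI size", call. = FALSE)
  }
  structure(list(width = as.integer(width), height = as.integer(height),
                 wavelengths = wavelength_grid(wl),
                 time_points = as.integer(time_points),
                 roi_size = as.integer(roi_size),
                 ellipse = list(cx = (width + 1) / 2, cy = (height + 1) / 2,
                                a = a, b = b),
                 background_absorbance = background_absorbance,
                 highlight_count = as.integer(highlight_count),
                 highlight_radius = as.integer(highlight_radius),
                 drift_scale = drift_scale, spatial_scale = spatial_scale,
                 white_level = white_level),
            class = "scene_spec")
}

ellipse_mask <- function(scene) {
  x <- matrix(seq_len(scene$width), scene$height, scene$width, byrow = TRUE)
  y <- matrix(seq_len(scene$height), scene$height, scene$width)
  ((x - scene$ellipse$cx) / scene$ellipse$a)^2 +
    ((y - scene$ellipse$cy) / scene$ellipse$b)^2 <= 1
}

#' Generate one synthetic kidney
#'
#' Per time point, pixel absorbance is built as class mean + smooth
#' per-kidney random effect + smooth spatial field + monotone time drift +
#' pixel noise, then converted to raw integer counts by inverting the
#' reflectance correction against generated dark and white reference cubes.
#' Specular highlights are inserted as small near-white discs. Deterministic
#' given `seed`.
#'
#' @param class_label Functional class 1, 2 or 3.
#' @param template A [class_templates()] object.
#' @param scene A [scene_spec()].
#' @param seed Integer seed.
#' @param kidney_id Identifier carried in cube metadata.
#' @return List with `cubes` (list of `time_points` raw [hsi_cube()]s),
#'   `refs` ([reference_cubes()]), ground-truth logical `mask`, `highlights`
#'   table (time_point, x, y; 0-based centers), `expected_abs` (time_points x
#'   bands matrix: the kidney's expected mean absorbance inside the mask,
#'   i.e. class mean + kidney random effect + time drift + spatial-field mask
#'   mean — the ground truth a round trip through the correction chain should
#'   recover), `label` and `kidney_id`.
#' @export
generate_kidney <- function(class_label, template, scene, seed = 0L,
                            kidney_id = sprintf("K%02d", seed)) {
  stopifnot(class_label %in% 1:3, inherits(template, "class_template"),
            inherits(scene, "scene_spec"))
  if (!isTRUE(all.equal(as.numeric(template$wavelengths),
                        as.numeric(scene$wavelengths)))) {
    stop("template and scene band grids differ", call. = FALSE)
  }
  set.seed(as.integer(seed))
  wl <- as.numeric(scene$wavelengths)
  nb <- length(wl)
  H <- scene$height; W <- scene$width
  mask <- ellipse_mask(scene)

  # per-kidney smooth spectral random effect: dominated by a level shift
  # (removed downstream by vector normalization) plus smaller tilt and
  # band-depth components, keeping intra-class *shape* variation well below
  # the inter-class shape differences
  z <- (wl - mean(wl)) / (diff(range(wl)) / 2)
  re <- stats::rnorm(1L, 0, template$intra_sd) +
    stats::rnorm(1L, 0, 0.3 * template$intra_sd) * z +
    stats::rnorm(1L, 0, 0.5 * template$intra_sd) * gaussian_band(wl, 560, 28)
  mean_abs <- template$means[class_label, ] + re

  # smooth spatial field (removed later by vector normalization; emulates
  # residual illumination structure)
  px <- matrix(seq_len(W), H, W, byrow = TRUE) / W
  py <- matrix(seq_len(H), H, W) / H
  fx <- stats::runif(1L, 0.5, 1.5); fy <- stats::runif(1L, 0.5, 1.5)
  ph1 <- stats::runif(1L, 0, 2 * pi); ph2 <- stats::runif(1L, 0, 2 * pi)
  sfield <- scene$spatial_scale * cos(2 * pi * fx * px + ph1) *
    cos(2 * pi * fy * py + ph2)

  # references shared by all time points of this kidney
  lamp <- 0.85 + 0.3 * gaussian_band(wl, 780, 260)
  falloff <- 1 - 0.12 * ((px - 0.5)^2 + (py - 0.5)^2) / 0.5
  dark_v <- array(round(100 + stats::rnorm(H * W * nb, 0, 2)), c(H, W, nb))
  dark_v[dark_v < 0] <- 0
  white_v <- array(0, c(H, W, nb))
  for (bnd in seq_len(nb)) {
    white_v[, , bnd] <- scene$white_level * lamp[bnd] * falloff
  }
  white_v <- round(white_v + stats::rnorm(length(white_v), 0, 3))
  refs <- reference_cubes(
    hsi_cube(dark_v, scene$wavelengths, "raw"),
    hsi_cube(white_v, scene$wavelengths, "raw"))

  drift_shape <- gaussian_band(wl, 560, 28)
  sfield_mean <- mean(sfield[mask])
  expected_abs <- matrix(0, scene$time_points, nb)
  cubes <- vector("list", scene$time_points)
  hl <- list()
  for (t in seq_len(scene$time_points)) {
    drift <- if (scene$time_points > 1L) {
      scene$drift_scale * (t - 1L) / (scene$time_points - 1L) * drift_shape
    } else rep(0, nb)
    expected_abs[t, ] <- mean_abs + drift + sfield_mean
    A <- array(0, c(H, W, nb))
    for (bnd in seq_len(nb)) {
      plane <- matrix(scene$background_absorbance, H, W)
      plane[mask] <- mean_abs[bnd] + drift[bnd] + sfield[mask]
      A[, , bnd] <- plane
    }
    A <- A + stats::rnorm(length(A), 0, template$pixel_sd)
    A[A < 0.02] <- 0.02

    R <- 10^(-A)
    # specular highlights: small near-white discs well inside the kidney
    n_hl <- scene$highlight_count
    if (n_hl > 0L) {
      placed <- 0L
      while (placed < n_hl) {
        hx <- stats::runif(1L, -0.7, 0.7); hy <- stats::runif(1L, -0.7, 0.7)
        if (hx^2 + hy^2 > 0.7^2) next
        cx <- round(scene$ellipse$cx + hx * scene$ellipse$a)
        cy <- round(scene$ellipse$cy + hy * scene$ellipse$b)
        rr <- scene$highlight_radius
        ys <- max(1L, cy - rr):min(H, cy + rr)
        xs <- max(1L, cx - rr):min(W, cx + rr)
        disc <- outer((ys - cy)^2, (xs - cx)^2, `+`) <= rr^2
        for (bnd in seq_len(nb)) {
          plane <- R[ys, xs, bnd]
          plane[disc] <- 0.97
          R[ys, xs, bnd] <- plane
        }
        hl[[length(hl) + 1L]] <- data.frame(time_point = t, x = cx - 1L, y = cy - 1L)
        placed <- placed + 1L
      }
    }
    R[R < 0.005] <- 0.005
    R[R > 0.995] <- 0.995
    raw <- round(dark_v + R * (white_v - dark_v))
    cubes[[t]] <- hsi_cube(raw, scene$wavelengths, "raw",
                           kidney_id = kidney_id, time_point = t)
  }
  list(cubes = cubes, refs = refs, mask = mask,
       highlights = if (length(hl)) do.call(rbind, hl) else
         data.frame(time_point = integer(0), x = integer(0), y = integer(0)),
       expected_abs = expected_abs,
       label = as.integer(class_label), kidney_id = kidney_id)
}

#' Run one kidney through correction, ROI selection and preprocessing
#'
#' The per-kidney pipeline: reflectance correction, optional conversion to
#' absorbance (`data_origin`), wavelength-range selection, homogeneity-map
#' ROI selection on the band nearest the isosbestic point of the chosen data
#' origin, ROI extraction and chemometric preprocessing.
#'
#' @param kid A [generate_kidney()] result (or an equivalent list with raw
#'   `cubes`, `refs`, `mask`, `label`, `kidney_id`).
#' @param data_origin `"absorbance"` (default) or `"reflectance"`.
#' @param wl_lo,wl_hi Retained wavelength range in nm.
#' @param roi_size,n_per_region,max_overlap,stride ROI-selection settings.
#' @param isosbestic_nm Homogeneity-map band.
#' @param savgol_window,savgol_order Smoothing parameters.
#' @return List of preprocessed, labelled ROI samples (pooled over time
#'   points).
#' @export
kidney_samples <- function(kid, data_origin = c("absorbance", "reflectance"),
                           wl_lo = 550, wl_hi = 995, roi_size = 50L,
                           n_per_region = 4L, max_overlap = 0.5, stride = 1L,
                           isosbestic_nm = 805, savgol_window = 9L,
                           savgol_order = 3L) {
  data_origin <- match.arg(data_origin)
  mask <- structure(list(mask = kid$mask, source = "manual-file"), class = "organ_mask")
  partition <- split_regions(mask)
  samples <- list()
  for (cube in kid$cubes) {
    refl <- correct_reflectance(cube, kid$refs)
    origin <- if (data_origin == "absorbance") to_absorbance(refl) else refl
    origin <- select_wavelengths(origin, wl_lo, wl_hi)
    band <- origin$values[, , nearest_band(origin$wavelengths, isosbestic_nm)]
    hmap <- homogeneity_map(band, mask, k = roi_size, l = roi_size)
    rois <- select_rois(hmap, partition, n_per_region = n_per_region,
                        max_overlap = max_overlap, stride = stride)
    samples <- c(samples, extract_roi_samples(origin, rois, label = kid$label))
  }
  preprocess_samples(samples, window = savgol_window, order = savgol_order)
}

#' Generate a complete labelled dataset
#'
#' Generates `n_per_class` kidneys per class (default 4/10/12, the class
#' sizes of the emulated cohort), runs each through the full preprocessing
#' pipeline and assembles a [kidney_dataset()]. Per-kidney seeds are derived
#' deterministically from `seed`.
#'
#' @param n_per_class Integer vector of length 3.
#' @param template A [class_templates()] (band grids must match `scene`).
#' @param scene A [scene_spec()].
#' @param seed Master seed.
#' @param dir Optional directory: when given, raw cubes (ENVI), references,
#'   ground-truth masks (PGM) and a `metadata.csv` are written there.
#' @param ... Passed to [kidney_samples()] (ROI and preprocessing settings).
#' @return A [kidney_dataset()].
#' @export
generate_dataset <- function(n_per_class = c(4L, 10L, 12L), template, scene,
                             seed = 0L, dir = NULL, ...) {
  stopifnot(length(n_per_class) == 3L, all(n_per_class >= 1L))
  if (!is.null(dir) && !dir.exists(dir)) dir.create(dir, recursive = TRUE)
  kidneys <- list()
  meta <- list()
  idx <- 0L
  for (cl in 1:3) {
    for (i in seq_len(n_per_class[cl])) {
      idx <- idx + 1L
      kid_seed <- as.integer(seed) * 1000L + idx
      id <- sprintf("K%02d", idx)
      kid <- generate_kidney(cl, template, scene, seed = kid_seed, kidney_id = id)
      if (!is.null(dir)) {
        write_pgm(kid$mask, file.path(dir, sprintf("%s_mask.pgm", id)))
        write_cube(kid$refs$dark, file.path(dir, sprintf("%s_dark", id)), data_type = 4L)
        write_cube(kid$refs$white, file.path(dir, sprintf("%s_white", id)), data_type = 4L)
        for (t in seq_along(kid$cubes)) {
          write_cube(kid$cubes[[t]], file.path(dir, sprintf("%s_t%02d", id, t)),
                     data_type = 4L)
          meta[[length(meta) + 1L]] <- data.frame(
            kidney_id = id, class = cl, time_point = t,
            cube = sprintf("%s_t%02d", id, t), mask = sprintf("%s_mask.pgm", id),
            dark = sprintf("%s_dark", id), white = sprintf("%s_white", id),
            stringsAsFactors = FALSE)
        }
      }
      kidneys[[idx]] <- list(id = id, label = cl,
                             samples = kidney_samples(kid, ...))
    }
  }
  if (!is.null(dir)) {
    utils::write.csv(do.call(rbind, meta), file.path(dir, "metadata.csv"),
                     row.names = FALSE)
  }
  kidney_dataset(kidneys)
}
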