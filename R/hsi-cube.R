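# Internal array convention shared by every module: cube$values is a numeric
# array of dim (lines, samples, bands) = (y, x, band).  Externally reported
# coordinates (ROI tables, masks) use 0-based indices with x = column and
# y = row.

#' Construct a wavelength grid
#'
#' Band-center wavelengths of a hyperspectral cube. The grid must be strictly
#' increasing and uniformly spaced (the pushbroom camera emulated here samples
#' every 5 nm between 500 and 995 nm).
#'
#' @param centers Numeric vector of band centers in nm, length >= 2.
#' @return A numeric vector of class `"wavelength_grid"`.
#' @export
wavelength_grid <- function(centers) {
  centers <- as.numeric(centers)
  if (length(centers) < 2L) {
    stop("wavelength grid needs at least 2 bands", call. = FALSE)
  }
  d <- diff(centers)
  if (any(d <= 0)) {
    stop("wavelengths must be strictly increasing", call. = FALSE)
  }
  if (diff(range(d)) > 1e-6 * mean(d)) {
    stop("wavelengths must be uniformly spaced", call. = FALSE)
  }
  structure(centers, class = "wavelength_grid")
}

#' Construct a hyperspectral cube
#'
#' @param values Numeric array of dim (lines, samples, bands), i.e. (y, x,
#'   band). Values must be non-negative for raw and reflectance cubes.
#' @param wavelengths A [wavelength_grid()] (or numeric vector coerced to one)
#'   whose length equals the band dimension.
#' @param kind One of `"raw"`, `"reflectance"`, `"absorbance"`.
#' @param kidney_id,time_point Optional acquisition metadata carried along the
#'   pipeline.
#' @return An object of class `"hsi_cube"`.
#' @export
hsi_cube <- function(values, wavelengths, kind = c("raw", "reflectance", "absorbance"),
                     kidney_id = NA_character_, time_point = NA_integer_) {
  kind <- match.arg(kind)
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("cube values must be a 3-D array (lines, samples, bands)", call. = FALSE)
  }
  if (!inherits(wavelengths, "wavelength_grid")) {
    wavelengths <- wavelength_grid(wavelengths)
  }
  if (dim(values)[3L] != length(wavelengths)) {
    stop(sprintf("band dimension (%d) does not match wavelength count (%d)",
                 dim(values)[3L], length(wavelengths)), call. = FALSE)
  }
  if (kind %in% c("raw", "reflectance") && any(values < 0, na.rm = TRUE)) {
    stop(sprintf("%s cube must be non-negative", kind), call. = FALSE)
  }
  structure(
    list(values = values, wavelengths = wavelengths, kind = kind,
         kidney_id = kidney_id, time_point = time_point),
    class = "hsi_cube"
  )
}

#' @export
print.hsi_cube <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<hsi_cube> %s: %d x %d px, %d bands (%g-%g nm)",
              x$kind, d[2L], d[1L], d[3L],
              min(x$wavelengths), max(x$wavelengths)))
  if (!is.na(x$kidney_id)) cat(sprintf(" [kidney %s, t%s]", x$kidney_id, x$time_point))
  cat("\n")
  invisible(x)
}

#' @export
dim.hsi_cube <- function(x) dim(x$values)

#' Bundle dark-current and white-reference cubes
#'
#' The dark cube is acquired with the lens capped, the white cube against a
#' uniform high-reflectance board. Both must match the raw cube they correct
#' in shape and wavelengths.
#'
#' @param dark,white `hsi_cube` objects of kind `"raw"`.
#' @return An object of class `"reference_cubes"`.
#' @export
reference_cubes <- function(dark, white) {
  stopifnot(inherits(dark, "hsi_cube"), inherits(white, "hsi_cube"))
  if (dark$kind != "raw" || white$kind != "raw") {
    stop("reference cubes must be of kind 'raw'", call. = FALSE)
  }
  if (!identical(dim(dark$values), dim(white$values)) ||
      !isTRUE(all.equal(as.numeric(dark$wavelengths), as.numeric(white$wavelengths)))) {
    stop("dark and white references must share shape and wavelengths", call. = FALSE)
  }
  structure(list(dark = dark, white = white), class = "reference_cubes")
}

check_same_geometry <- function(a, b, what) {
  if (!identical(dim(a$values), dim(b$values))) {
    stop(sprintf("dimension mismatch between cube and %s", what), call. = FALSE)
  }
  if (!isTRUE(all.equal(as.numeric(a$wavelengths), as.numeric(b$wavelengths)))) {
    stop(sprintf("wavelength mismatch between cube and %s", what), call. = FALSE)
  }
  invisible(TRUE)
}

#' Convert a raw intensity cube to reflectance
#'
#' Applies the standard flat-field correction
#' \deqn{I_{REFL} = (I_{RAW} - I_{DARK}) / (I_{WHITE} - I_{DARK})}
#' per pixel and band. Where the reference dynamic range `white - dark` falls
#' below an epsilon (1e-6 of the white dynamic range) the denominator is
#' repaired to that epsilon and a warning reports the count; the quotient is
#' then clipped to `[0, clip_max]` so that the subsequent logarithm stays
#' bounded when sensor noise pushes raw counts below dark or above white.
#'
#' @param raw An `hsi_cube` of kind `"raw"`.
#' @param refs A [reference_cubes()] object matching `raw` in geometry.
#' @param clip_max Upper clip for reflectance (default 2).
#' @return An `hsi_cube` of kind `"reflectance"`.
#' @export
correct_reflectance <- function(raw, refs, clip_max = 2) {
  stopifnot(inherits(raw, "hsi_cube"), inherits(refs, "reference_cubes"))
  if (raw$kind != "raw") stop("input cube must be of kind 'raw'", call. = FALSE)
  check_same_geometry(raw, refs$dark, "dark reference")
  check_same_geometry(raw, refs$white, "white reference")

  denom <- refs$white$values - refs$dark$values
  eps <- 1e-6 * max(refs$white$values)
  if (eps <= 0) eps <- 1e-6
  bad <- denom < eps
  nbad <- sum(bad)
  if (nbad > 0L) {
    warning(sprintf("white - dark below epsilon at %d element(s); denominator repaired", nbad),
            call. = FALSE)
    denom[bad] <- eps
  }
  refl <- (raw$values - refs$dark$values) / denom
  refl[refl < 0] <- 0
  refl[refl > clip_max] <- clip_max
  hsi_cube(refl, raw$wavelengths, "reflectance",
           kidney_id = raw$kidney_id, time_point = raw$time_point)
}

#' Convert a reflectance cube to absorbance
#'
#' Negative decadic logarithm \eqn{I_{ABS} = -\log_{10} I_{REFL}}. Reflectance
#' below `floor` is raised to `floor` first so the logarithm stays finite.
#'
#' @param refl An `hsi_cube` of kind `"reflectance"`.
#' @param floor Reflectance floor applied before the logarithm (default 1e-6).
#' @return An `hsi_cube` of kind `"absorbance"`.
#' @export
to_absorbance <- function(refl, floor = 1e-6) {
  stopifnot(inherits(refl, "hsi_cube"))
  if (refl$kind != "reflectance") {
    stop("to_absorbance() expects a reflectance cube", call. = FALSE)
  }
  v <- refl$values
  v[v < floor] <- floor
  hsi_cube(-log10(v), refl$wavelengths, "absorbance",
           kidney_id = refl$kidney_id, time_point = refl$time_point)
}

#' Restrict a cube to a wavelength range
#'
#' Retains bands whose centers satisfy `lo <= center <= hi` (the analysis
#' window for perfused tissue is 550-995 nm, dropping the noisy blue end).
#'
#' @param cube An `hsi_cube`.
#' @param lo,hi Range bounds in nm, `lo < hi`.
#' @return An `hsi_cube` with the retained bands.
#' @export
select_wavelengths <- function(cube, lo = 550, hi = 995) {
  stopifnot(inherits(cube, "hsi_cube"))
  if (!(lo < hi)) stop("need lo < hi", call. = FALSE)
  keep <- which(cube$wavelengths >= lo & cube$wavelengths <= hi)
  if (length(keep) == 0L) {
    stop(sprintf("no bands in [%g, %g] nm", lo, hi), call. = FALSE)
  }
  if (length(keep) < 2L) {
    stop("wavelength selection would leave fewer than 2 bands", call. = FALSE)
  }
  hsi_cube(cube$values[, , keep, drop = FALSE],
           wavelength_grid(as.numeric(cube$wavelengths)[keep]),
           cube$kind, kidney_id = cube$kidney_id, time_point = cube$time_point)
}

#' Index of the band nearest a target wavelength
#'
#' @param wavelengths A wavelength grid or numeric vector in nm.
#' @param nm Target wavelength in nm (default the 805 nm hemoglobin isosbestic
#'   point, where intensity is insensitive to oxygenation).
#' @return Integer band index.
#' @export
nearest_band <- function(wavelengths, nm = 805) {
  which.min(abs(as.numeric(wavelengths) - nm))
}
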