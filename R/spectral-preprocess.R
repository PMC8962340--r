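# Chemometric preprocessing of ROI spectra and spectrum comparison.
# Fixed preprocessing order: ROI extraction -> vector normalization ->
# Savitzky-Golay smoothing.

#' Construct a spectrum
#'
#' @param wavelengths Wavelength grid (nm).
#' @param values Per-band values (absorbance a.u. or reflectance), finite,
#'   same length as `wavelengths`.
#' @return Object of class `"hsi_spectrum"`.
#' @export
hsi_spectrum <- function(wavelengths, values) {
  if (!inherits(wavelengths, "wavelength_grid")) wavelengths <- wavelength_grid(wavelengths)
  values <- as.numeric(values)
  if (length(values) != length(wavelengths)) {
    stop("spectrum length does not match wavelength grid", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("spectrum values must be finite", call. = FALSE)
  structure(list(wavelengths = wavelengths, values = values), class = "hsi_spectrum")
}

as_values <- function(x) if (inherits(x, "hsi_spectrum")) x$values else as.numeric(x)

#' L2 (vector) normalization of a spectrum
#'
#' Divides the value vector by its Euclidean norm across bands, the standard
#' chemometric normalization that removes overall intensity scaling between
#' pixels while preserving band shape.
#'
#' @param x An `hsi_spectrum` or numeric vector.
#' @return Same type as the input, with unit Euclidean norm.
#' @export
vector_normalize <- function(x) {
  v <- as_values(x)
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) stop("cannot vector-normalize an all-zero spectrum", call. = FALSE)
  out <- v / nrm
  if (inherits(x, "hsi_spectrum")) hsi_spectrum(x$wavelengths, out) else out
}

# Savitzky-Golay smoothing matrix (n x n bands): interior rows apply the
# central least-squares filter, the first/last (window-1)/2 rows the
# asymmetric endpoint filters, exactly as signal::sgolayfilt does.
sgolay_matrix <- function(n_bands, window = 9L, order = 3L) {
  if (window %% 2L != 1L) stop("Savitzky-Golay window must be odd", call. = FALSE)
  if (order >= window) stop("polynomial order must be < window", call. = FALSE)
  if (window > n_bands) stop("Savitzky-Golay window exceeds band count", call. = FALSE)
  FM <- signal::sgolay(p = order, n = window)
  FM <- unclass(FM)
  h <- (window - 1L) %/% 2L
  S <- matrix(0, n_bands, n_bands)
  for (i in seq_len(h)) S[i, 1:window] <- FM[i, ]
  mid <- FM[h + 1L, ]
  for (i in (h + 1L):(n_bands - h)) S[i, (i - h):(i + h)] <- mid
  for (j in seq_len(h)) S[n_bands - h + j, (n_bands - window + 1L):n_bands] <- FM[h + 1L + j, ]
  S
}

#' Savitzky-Golay smoothing of a spectrum
#'
#' Least-squares polynomial convolution smoothing along the spectral axis.
#' Window and polynomial order are exposed because they control the
#' bias/variance trade-off of the filter; the defaults (window 9 bands = 40 nm
#' at 5 nm spacing, cubic) follow common visible/NIR tissue-spectroscopy
#' practice.
#'
#' @param x An `hsi_spectrum` or numeric vector.
#' @param window Odd filter length in bands (default 9).
#' @param order Polynomial degree, `< window` (default 3).
#' @return Smoothed spectrum, same type and length as the input.
#' @export
savgol_smooth <- function(x, window = 9L, order = 3L) {
  v <- as_values(x)
  if (window %% 2L != 1L) stop("Savitzky-Golay window must be odd", call. = FALSE)
  if (order >= window) stop("polynomial order must be < window", call. = FALSE)
  if (window > length(v)) stop("Savitzky-Golay window exceeds band count", call. = FALSE)
  out <- signal::sgolayfilt(v, p = order, n = window)
  if (inherits(x, "hsi_spectrum")) hsi_spectrum(x$wavelengths, out) else out
}

#' Preprocess ROI samples for classification
#'
#' Applies, per pixel spectrum, L2 vector normalization followed by
#' Savitzky-Golay smoothing (in that order). Operates on the flattened pixel
#' matrix with a precomputed smoothing matrix, so large sample lists stay
#' fast; per-spectrum results are identical to
#' `savgol_smooth(vector_normalize(s))`.
#'
#' @param samples List of ROI samples from [extract_roi_samples()].
#' @param window,order Savitzky-Golay parameters.
#' @return The sample list with preprocessed `values`.
#' @export
preprocess_samples <- function(samples, window = 9L, order = 3L) {
  if (length(samples) == 0L) return(samples)
  nb <- dim(samples[[1L]]$values)[3L]
  S <- t(sgolay_matrix(nb, window, order))   # right-multiplication form
  lapply(samples, function(s) {
    d <- dim(s$values)
    if (d[3L] != nb) stop("mixed band counts across samples", call. = FALSE)
    px <- matrix(s$values, d[1L] * d[2L], d[3L])
    nrm <- sqrt(rowSums(px^2))
    if (any(nrm == 0)) stop("cannot vector-normalize an all-zero pixel spectrum", call. = FALSE)
    px <- (px / nrm) %*% S
    s$values <- array(px, d)
    s
  })
}

#' Mean spectral signature of a set of ROIs
#'
#' Per-band mean and standard deviation over all pixels of all ROI samples
#' (after preprocessing), the per-kidney summary used to inspect intra- and
#' inter-class spectral variation.
#'
#' @param samples List of ROI samples sharing one wavelength grid.
#' @return Object of class `"spectral_signature"`: `mean` (an
#'   `hsi_spectrum`), `sd` per band, and pixel-spectrum count `n`.
#' @export
roi_signature <- function(samples) {
  if (length(samples) == 0L) stop("need at least one ROI sample", call. = FALSE)
  wl <- samples[[1L]]$wavelengths
  for (s in samples) {
    if (!isTRUE(all.equal(as.numeric(s$wavelengths), as.numeric(wl)))) {
      stop("samples carry different wavelength grids", call. = FALSE)
    }
  }
  px <- do.call(rbind, lapply(samples, function(s) {
    d <- dim(s$values)
    matrix(s$values, d[1L] * d[2L], d[3L])
  }))
  mu <- colMeans(px)
  sdv <- apply(px, 2L, stats::sd)
  if (nrow(px) == 1L) sdv <- rep(0, ncol(px))
  structure(list(mean = hsi_spectrum(wl, mu), sd = sdv, n = nrow(px)),
            class = "spectral_signature")
}

#' Pearson correlation between two spectra
#'
#' Standard Pearson coefficient between the two value vectors at matched
#' wavelengths, used to quantify how similar two (mean) tissue spectra are.
#'
#' @param a,b `hsi_spectrum` objects (or numeric vectors) on the same grid.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson_r <- function(a, b) {
  if (inherits(a, "hsi_spectrum") && inherits(b, "hsi_spectrum") &&
      !isTRUE(all.equal(as.numeric(a$wavelengths), as.numeric(b$wavelengths)))) {
    stop("spectra are on different wavelength grids", call. = FALSE)
  }
  va <- as_values(a); vb <- as_values(b)
  if (length(va) != length(vb)) stop("spectra have different lengths", call. = FALSE)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) {
    stop("Pearson correlation undefined for a constant spectrum", call. = FALSE)
  }
  stats::cor(va, vb)
}

#' Interpret a correlation coefficient
#'
#' Bins `|r|` into negligible / low / moderate / high / very high with the
#' sign appended (except for negligible). Bins are half-open `[lo, hi)` with
#' 1.0 included in the top bin.
#'
#' @param r Correlation in `[-1, 1]`.
#' @return Character label, e.g. `"very high positive"`.
#' @export
interpret_r <- function(r) {
  if (!is.numeric(r) || length(r) != 1L || is.na(r) || r < -1 || r > 1) {
    stop("r must be a single value in [-1, 1]", call. = FALSE)
  }
  a <- abs(r)
  bin <- if (a < 0.3) "negligible" else if (a < 0.5) "low" else if (a < 0.7)
    "moderate" else if (a < 0.9) "high" else "very high"
  if (bin == "negligible") return(bin)
  paste(bin, if (r >= 0) "positive" else "negative")
}

#' Write a spectrum (or signature) to CSV
#'
#' @param x An `hsi_spectrum` or `spectral_signature`.
#' @param path Output path; columns `wavelength_nm`, `value` and, for
#'   signatures, `sd`.
#' @return `path`, invisibly.
#' @export
write_spectrum_csv <- function(x, path) {
  if (inherits(x, "spectral_signature")) {
    df <- data.frame(wavelength_nm = as.numeric(x$mean$wavelengths),
                     value = x$mean$values, sd = x$sd)
  } else if (inherits(x, "hsi_spectrum")) {
    df <- data.frame(wavelength_nm = as.numeric(x$wavelengths), value = x$values)
  } else stop("unsupported object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a spectrum from CSV
#'
#' @param path CSV with columns `wavelength_nm` and `value`.
#' @return An `hsi_spectrum`.
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  hsi_spectrum(df$wavelength_nm, df$value)
}
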