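# Minimal ENVI header/binary I/O. Supported: interleave bsq/bil, data types
# 2 (int16), 4 (float32), 5 (float64), byte order 0/1. The header carries the
# wavelength list plus user fields "cube kind", "kidney id", "time point".

ENVI_SIZES <- c(`2` = 2L, `4` = 4L, `5` = 8L)

envi_paths <- function(path) {
  base <- sub("\\.hdr$", "", path)
  hdr <- paste0(base, ".hdr")
  bin <- paste0(base, ".bin")
  list(hdr = hdr, bin = bin, base = base)
}

parse_envi_header <- function(hdr_file) {
  txt <- readLines(hdr_file, warn = FALSE)
  if (length(txt) == 0L || !grepl("^ENVI", txt[1L])) {
    stop("not an ENVI header (missing ENVI magic line): ", hdr_file, call. = FALSE)
  }
  fields <- list()
  # walk lines, re-joining values that continue across lines inside braces
  lines <- txt[-1L]
  buf <- character(0)
  open <- FALSE
  for (ln in lines) {
    buf <- c(buf, ln)
    n_open <- lengths(regmatches(ln, gregexpr("\\{", ln)))
    n_close <- lengths(regmatches(ln, gregexpr("\\}", ln)))
    open <- open || n_open > n_close
    if (open && n_close >= 1L) open <- FALSE
    if (!open) {
      entry <- paste(buf, collapse = " ")
      buf <- character(0)
      if (grepl("=", entry)) {
        key <- tolower(trimws(sub("=.*", "", entry)))
        val <- trimws(sub("^[^=]*=", "", entry))
        fields[[key]] <- val
      }
    }
  }
  fields
}

envi_field_num <- function(fields, key) {
  if (is.null(fields[[key]])) {
    stop("ENVI header missing required field '", key, "'", call. = FALSE)
  }
  as.numeric(fields[[key]])
}

envi_field_list <- function(fields, key) {
  v <- fields[[key]]
  if (is.null(v)) return(NULL)
  v <- gsub("[{}]", "", v)
  as.numeric(trimws(strsplit(v, ",")[[1L]]))
}

#' Read a hyperspectral cube from an ENVI header/binary pair
#'
#' Expects `<base>.hdr` alongside `<base>.bin`. Wavelengths are taken from the
#' header's `wavelength` list; the cube kind from the user field `cube kind`
#' (defaulting to `"raw"`).
#'
#' @param path Path to the header, the binary, or their common base name.
#' @return An [hsi_cube()].
#' @export
read_cube <- function(path) {
  p <- envi_paths(sub("\\.bin$", "", path))
  if (!file.exists(p$hdr)) stop("missing ENVI header: ", p$hdr, call. = FALSE)
  if (!file.exists(p$bin)) stop("missing ENVI binary: ", p$bin, call. = FALSE)
  f <- parse_envi_header(p$hdr)

  samples <- as.integer(envi_field_num(f, "samples"))
  lines_n <- as.integer(envi_field_num(f, "lines"))
  bands <- as.integer(envi_field_num(f, "bands"))
  dtype <- as.character(as.integer(envi_field_num(f, "data type")))
  if (!dtype %in% names(ENVI_SIZES)) {
    stop("unsupported ENVI field 'data type' = ", dtype, call. = FALSE)
  }
  interleave <- tolower(if (is.null(f[["interleave"]])) "bsq" else f[["interleave"]])
  if (!interleave %in% c("bsq", "bil")) {
    stop("unsupported ENVI field 'interleave' = ", interleave, call. = FALSE)
  }
  byte_order <- if (is.null(f[["byte order"]])) 0L else as.integer(f[["byte order"]])
  endian <- if (byte_order == 0L) "little" else "big"

  wl <- envi_field_list(f, "wavelength")
  if (is.null(wl)) stop("ENVI header missing required field 'wavelength'", call. = FALSE)
  if (length(wl) != bands) {
    stop(sprintf("ENVI field mismatch: bands = %d but wavelength list has %d entries",
                 bands, length(wl)), call. = FALSE)
  }

  n <- samples * lines_n * bands
  size <- ENVI_SIZES[[dtype]]
  expected <- as.numeric(n) * size
  if (file.info(p$bin)$size != expected) {
    stop(sprintf("ENVI binary size mismatch: expected %.0f bytes from field 'samples/lines/bands', found %.0f",
                 expected, file.info(p$bin)$size), call. = FALSE)
  }
  con <- file(p$bin, "rb")
  on.exit(close(con))
  what <- if (dtype == "2") integer() else numeric()
  v <- readBin(con, what, n = n, size = size, endian = endian)
  v <- as.numeric(v)

  # BSQ: sample fastest, then line, then band -> array (samples, lines, bands)
  # BIL: sample, band, line -> array (samples, bands, lines)
  if (interleave == "bsq") {
    arr <- aperm(array(v, dim = c(samples, lines_n, bands)), c(2L, 1L, 3L))
  } else {
    arr <- aperm(array(v, dim = c(samples, bands, lines_n)), c(3L, 1L, 2L))
  }

  kind <- if (is.null(f[["cube kind"]])) "raw" else tolower(trimws(f[["cube kind"]]))
  if (!kind %in% c("raw", "reflectance", "absorbance")) kind <- "raw"
  kid <- if (is.null(f[["kidney id"]])) NA_character_ else trimws(f[["kidney id"]])
  tp <- if (is.null(f[["time point"]])) NA_integer_ else as.integer(f[["time point"]])

  hsi_cube(arr, wavelength_grid(wl), kind, kidney_id = kid, time_point = tp)
}

#' Write a hyperspectral cube as an ENVI header/binary pair
#'
#' @param cube An [hsi_cube()].
#' @param path Base path (or `.hdr`/`.bin` path); `<base>.hdr` and
#'   `<base>.bin` are written.
#' @param interleave `"bsq"` (default) or `"bil"`.
#' @param data_type ENVI data type code: 5 = float64 (default, lossless for R
#'   doubles), 4 = float32, 2 = int16.
#' @return The base path, invisibly.
#' @export
write_cube <- function(cube, path, interleave = c("bsq", "bil"), data_type = 5L) {
  stopifnot(inherits(cube, "hsi_cube"))
  interleave <- match.arg(interleave)
  dtype <- as.character(as.integer(data_type))
  if (!dtype %in% names(ENVI_SIZES)) stop("unsupported data type code ", dtype, call. = FALSE)
  p <- envi_paths(sub("\\.bin$", "", path))
  d <- dim(cube$values)

  hdr <- c(
    "ENVI",
    "description = { kidneyhsi cube }",
    sprintf("samples = %d", d[2L]),
    sprintf("lines = %d", d[1L]),
    sprintf("bands = %d", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %s", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = nm",
    sprintf("wavelength = { %s }",
            paste(format(as.numeric(cube$wavelengths), trim = TRUE), collapse = ", ")),
    sprintf("cube kind = %s", cube$kind)
  )
  if (!is.na(cube$kidney_id)) hdr <- c(hdr, sprintf("kidney id = %s", cube$kidney_id))
  if (!is.na(cube$time_point)) hdr <- c(hdr, sprintf("time point = %d", cube$time_point))
  writeLines(hdr, p$hdr)

  if (interleave == "bsq") {
    v <- as.vector(aperm(cube$values, c(2L, 1L, 3L)))
  } else {
    v <- as.vector(aperm(cube$values, c(2L, 3L, 1L)))
  }
  con <- file(p$bin, "wb")
  on.exit(close(con))
  if (dtype == "2") {
    writeBin(as.integer(round(v)), con, size = 2L, endian = "little")
  } else {
    writeBin(as.numeric(v), con, size = ENVI_SIZES[[dtype]], endian = "little")
  }
  invisible(p$base)
}

#' Read a PGM (P2, ASCII) mask image
#'
#' @param path Path to a P2 portable graymap.
#' @return Integer matrix (rows = lines, cols = samples).
#' @export
read_pgm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE, comment.char = "#")
  if (length(toks) < 4L || toks[1L] != "P2") {
    stop("not an ASCII PGM (P2) file: ", path, call. = FALSE)
  }
  w <- as.integer(toks[2L]); h <- as.integer(toks[3L])
  vals <- as.integer(toks[-(1:4)])
  if (length(vals) != w * h) {
    stop("PGM pixel count does not match its declared size", call. = FALSE)
  }
  matrix(vals, nrow = h, ncol = w, byrow = TRUE)
}

#' Write a matrix as a PGM (P2, ASCII) image
#'
#' @param m Numeric/integer/logical matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(m, path) {
  m <- matrix(as.integer(m), nrow = nrow(m))
  maxv <- max(1L, max(m))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", sprintf("%d %d", ncol(m), nrow(m)), as.character(maxv)), con)
  write(t(m), file = con, ncolumns = min(ncol(m), 32L))
  invisible(path)
}
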