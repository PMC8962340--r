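# ROI selection: segment the kidney, split it into the three physiological
# regions (upper pole / middle / lower pole), compute the homogeneity map of
# a single band (805 nm isosbestic by default), and greedily pick the most
# homogeneous, overlap-constrained square ROIs.

#' Segment the organ from the background
#'
#' Manual mode loads a mask image of matching shape (any non-zero pixel is
#' foreground). Automatic mode thresholds the band nearest 805 nm and keeps
#' the largest connected foreground component; it exists so that synthetic
#' scenes can be processed end-to-end without hand-drawn masks.
#'
#' @param cube An [hsi_cube()].
#' @param mode `"manual-file"` or `"threshold-auto"`.
#' @param arg For `"manual-file"`: path to a PGM/single-band ENVI mask, or a
#'   logical/numeric matrix. For `"threshold-auto"`: scalar threshold applied
#'   to the 805 nm band (pixels strictly above it are foreground).
#' @param isosbestic_nm Band used by the automatic mode (default 805).
#' @return An object of class `"organ_mask"`: logical matrix `mask` plus the
#'   `source` mode.
#' @export
segment_mask <- function(cube, mode = c("manual-file", "threshold-auto"), arg,
                         isosbestic_nm = 805) {
  stopifnot(inherits(cube, "hsi_cube"))
  mode <- match.arg(mode)
  d <- dim(cube$values)
  if (mode == "manual-file") {
    if (is.character(arg)) {
      m <- if (grepl("\\.pgm$", arg, ignore.case = TRUE)) {
        read_pgm(arg)
      } else {
        mc <- read_cube(arg)
        mc$values[, , 1L]
      }
    } else if (is.matrix(arg)) {
      m <- arg
    } else {
      stop("manual-file mode needs a path or a matrix", call. = FALSE)
    }
    if (!identical(dim(m)[1:2], d[1:2])) {
      stop("mask shape does not match cube spatial shape", call. = FALSE)
    }
    mask <- m > 0
  } else {
    if (!is.numeric(arg) || length(arg) != 1L) {
      stop("threshold-auto mode needs a scalar threshold", call. = FALSE)
    }
    band <- cube$values[, , nearest_band(cube$wavelengths, isosbestic_nm)]
    fg <- band > arg
    if (!any(fg)) stop("segmentation produced an empty mask", call. = FALSE)
    lab <- EBImage::bwlabel(fg)
    tab <- tabulate(lab[lab > 0])
    mask <- lab == which.max(tab)
  }
  if (!any(mask)) stop("segmentation produced an empty mask", call. = FALSE)
  structure(list(mask = mask, source = mode), class = "organ_mask")
}

#' Partition the organ mask into upper, middle and lower regions
#'
#' The foreground bounding box is cut into three equal slabs perpendicular to
#' its longer axis; a remainder of 1-2 pixel rows/columns is assigned to the
#' first (upper) slab. Slabs are labelled in axis order `upper`, `middle`,
#' `lower`.
#'
#' @param mask An `organ_mask` (or logical matrix).
#' @return An object of class `"region_partition"`: integer matrix `labels`
#'   with 0 = outside, 1 = upper, 2 = middle, 3 = lower, plus the split
#'   `axis` (`"x"` or `"y"`).
#' @export
split_regions <- function(mask) {
  m <- if (inherits(mask, "organ_mask")) mask$mask else mask
  stopifnot(is.matrix(m))
  if (!any(m)) stop("cannot partition an empty mask", call. = FALSE)
  rows <- range(which(rowSums(m) > 0))
  cols <- range(which(colSums(m) > 0))
  h <- rows[2L] - rows[1L] + 1L
  w <- cols[2L] - cols[1L] + 1L
  axis <- if (w >= h) "x" else "y"
  extent <- if (axis == "x") w else h
  if (extent < 3L) stop("bounding box too small to split into three regions", call. = FALSE)

  base <- extent %/% 3L
  first <- base + (extent - 3L * base)   # remainder goes to the upper slab
  sizes <- c(first, base, base)
  starts <- cumsum(c(0L, sizes[1:2]))

  labels <- matrix(0L, nrow(m), ncol(m))
  idx <- if (axis == "x") col(m) - cols[1L] else row(m) - rows[1L]
  for (r in 1:3) {
    sel <- m & idx >= starts[r] & idx < starts[r] + sizes[r]
    labels[sel] <- r
  }
  structure(list(labels = labels, axis = axis), class = "region_partition")
}

#' Homogeneity (gradient) map of a band image
#'
#' For every anchor pixel where the full `k x l` window lies inside the organ
#' mask, computes the window homogeneity score: the sum of squared intensity
#' differences between horizontally neighbouring pixels (k-1 by l pairs) and
#' vertically neighbouring pixels (k by l-1 pairs), divided by `k*l`. Small
#' values mean homogeneous tissue; the score is written at the window's
#' upper-left pixel. Implemented with summed-area tables, so cost is linear in
#' image size.
#'
#' @param band_image Numeric matrix (rows = y, cols = x).
#' @param mask An `organ_mask` or logical matrix of the same shape.
#' @param k,l Window width (x) and height (y) in px, both >= 2.
#' @return An object of class `"homogeneity_map"`: numeric matrix `H` (NA
#'   where invalid), logical matrix `valid`, and `k`, `l`.
#' @export
homogeneity_map <- function(band_image, mask, k = 50, l = 50) {
  m <- if (inherits(mask, "organ_mask")) mask$mask else mask
  stopifnot(is.matrix(band_image), is.matrix(m))
  if (!identical(dim(band_image), dim(m))) {
    stop("band image and mask shapes differ", call. = FALSE)
  }
  if (k < 2L || l < 2L) stop("window sides must be >= 2 px", call. = FALSE)
  nr <- nrow(band_image); nc <- ncol(band_image)

  H <- matrix(NA_real_, nr, nc)
  valid <- matrix(FALSE, nr, nc)
  if (nr >= l && nc >= k) {
    # squared neighbour differences
    dx <- (band_image[, -1L, drop = FALSE] - band_image[, -nc, drop = FALSE])^2
    dy <- (band_image[-1L, , drop = FALSE] - band_image[-nr, , drop = FALSE])^2

    sum_dx <- window_sums(dx, l, k - 1L)            # (nr-l+1) x (nc-k+1)
    sum_dy <- window_sums(dy, l - 1L, k)
    cnt <- window_sums(matrix(as.numeric(m), nr, nc), l, k)

    anchors_r <- 1:(nr - l + 1L)
    anchors_c <- 1:(nc - k + 1L)
    ok <- abs(cnt - k * l) < 0.5                    # window fully inside mask
    vals <- (sum_dx + sum_dy) / (k * l)
    vals[!ok] <- NA_real_
    H[anchors_r, anchors_c] <- vals
    valid[anchors_r, anchors_c] <- ok
  }
  if (!any(valid)) {
    warning("no valid ROI anchor: no full window fits inside the mask", call. = FALSE)
  }
  structure(list(H = H, valid = valid, k = as.integer(k), l = as.integer(l)),
            class = "homogeneity_map")
}

# Sums of all h x w windows of a matrix via a padded 2-D cumulative sum.
window_sums <- function(x, h, w) {
  nr <- nrow(x); nc <- ncol(x)
  cs <- apply(x, 2L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)      # single-row input
  cs <- apply(cs, 1L, cumsum)
  if (is.null(dim(cs))) cs <- matrix(cs, nrow = 1L)      # single-column input
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- t(cs)
  rr <- 1:(nr - h + 1L); cc <- 1:(nc - w + 1L)
  S[rr + h, cc + w, drop = FALSE] - S[rr, cc + w, drop = FALSE] -
    S[rr + h, cc, drop = FALSE] + S[rr, cc, drop = FALSE]
}

#' Select homogeneous, overlap-constrained ROIs per region
#'
#' Greedy selection: within each region, valid anchors are visited in
#' ascending homogeneity score (ties broken by row-major anchor order, so the
#' result is deterministic and seed-free). A candidate is accepted when (a)
#' its rectangle shares strictly less than `max_overlap` of its area with
#' every previously accepted ROI and (b) at least `1 - max_overlap` of its
#' area lies inside the region that contains its anchor. If a region cannot
#' supply `n_per_region` acceptable candidates the shortfall is returned and
#' a warning raised; ROIs are never fabricated.
#'
#' @param hmap A [homogeneity_map()].
#' @param partition A [split_regions()] result.
#' @param n_per_region ROIs requested per region (default 4, giving 12 per
#'   acquisition).
#' @param max_overlap Maximum tolerated pairwise area overlap fraction
#'   (default 0.5).
#' @param stride Anchor grid stride in px (default 1 = every valid pixel).
#' @return A data frame of class `"roi_set"` with 0-based `x0`, `y0`, sides
#'   `k`, `l`, `region` (`upper`/`middle`/`lower`) and homogeneity `H`.
#' @export
select_rois <- function(hmap, partition, n_per_region = 4L, max_overlap = 0.5,
                        stride = 1L) {
  stopifnot(inherits(hmap, "homogeneity_map"), inherits(partition, "region_partition"))
  if (max_overlap <= 0 || max_overlap > 1) stop("max_overlap must be in (0, 1]", call. = FALSE)
  k <- hmap$k; l <- hmap$l
  region_names <- c("upper", "middle", "lower")
  lab <- partition$labels
  if (!identical(dim(lab), dim(hmap$H))) {
    stop("partition and homogeneity map shapes differ", call. = FALSE)
  }

  out <- list()
  accepted_x <- integer(0); accepted_y <- integer(0)
  max_shared <- max_overlap * k * l
  min_inside <- (1 - max_overlap) * k * l

  for (r in 1:3) {
    cand <- which(hmap$valid & lab == r, arr.ind = TRUE)
    if (stride > 1L && nrow(cand) > 0L) {
      keep <- (cand[, 1L] - 1L) %% stride == 0L & (cand[, 2L] - 1L) %% stride == 0L
      cand <- cand[keep, , drop = FALSE]
    }
    n_got <- 0L
    if (nrow(cand) > 0L) {
      hv <- hmap$H[cand]
      ord <- order(hv, cand[, 1L], cand[, 2L])       # ascending H, then (y0, x0)
      cand <- cand[ord, , drop = FALSE]
      hv <- hv[ord]
      for (i in seq_len(nrow(cand))) {
        if (n_got >= n_per_region) break
        y <- cand[i, 1L]; x <- cand[i, 2L]
        # (a) pairwise overlap with every accepted ROI
        if (length(accepted_x) > 0L) {
          ox <- pmax(0L, pmin(x + k, accepted_x + k) - pmax(x, accepted_x))
          oy <- pmax(0L, pmin(y + l, accepted_y + l) - pmax(y, accepted_y))
          if (any(ox * oy >= max_shared)) next
        }
        # (b) membership of own region
        inside <- sum(lab[y:(y + l - 1L), x:(x + k - 1L)] == r)
        if (inside < min_inside) next
        accepted_x <- c(accepted_x, x); accepted_y <- c(accepted_y, y)
        n_got <- n_got + 1L
        out[[length(out) + 1L]] <- data.frame(
          x0 = x - 1L, y0 = y - 1L, k = k, l = l,
          region = region_names[r], H = hv[i], stringsAsFactors = FALSE)
      }
    }
    if (n_got < n_per_region) {
      warning(sprintf("region '%s': only %d of %d ROIs selectable", region_names[r],
                      n_got, n_per_region), call. = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(x0 = integer(0), y0 = integer(0), k = integer(0), l = integer(0),
               region = character(0), H = numeric(0), stringsAsFactors = FALSE)
  class(res) <- c("roi_set", "data.frame")
  res
}

#' Extract ROI sub-cubes with metadata
#'
#' @param cube An [hsi_cube()].
#' @param rois An ROI table from [select_rois()] (0-based `x0`, `y0`).
#' @param label Optional class label (1/2/3) attached to every sample.
#' @return A list of ROI samples; each is a list with `values` (l x k x bands
#'   array), `wavelengths`, `kidney_id`, `time_point`, `region`, `label`.
#' @export
extract_roi_samples <- function(cube, rois, label = NA_integer_) {
  stopifnot(inherits(cube, "hsi_cube"), is.data.frame(rois))
  d <- dim(cube$values)
  samples <- vector("list", nrow(rois))
  for (i in seq_len(nrow(rois))) {
    x0 <- rois$x0[i]; y0 <- rois$y0[i]; k <- rois$k[i]; l <- rois$l[i]
    if (x0 < 0L || y0 < 0L || x0 + k > d[2L] || y0 + l > d[1L]) {
      stop(sprintf("ROI %d out of cube bounds", i), call. = FALSE)
    }
    samples[[i]] <- list(
      values = cube$values[(y0 + 1L):(y0 + l), (x0 + 1L):(x0 + k), , drop = FALSE],
      wavelengths = cube$wavelengths,
      kidney_id = cube$kidney_id,
      time_point = cube$time_point,
      region = rois$region[i],
      x0 = x0, y0 = y0, k = k, l = l,
      H = if (!is.null(rois$H)) rois$H[i] else NA_real_,
      label = label
    )
  }
  samples
}

#' Write an ROI table to CSV
#'
#' Columns: kidney, timepoint, region, x0, y0, k, l, H (coordinates 0-based).
#'
#' @param rois An ROI table, optionally with `kidney`/`timepoint` columns.
#' @param path Output CSV path.
#' @param kidney_id,time_point Metadata used when the table has none.
#' @return `path`, invisibly.
#' @export
write_roi_csv <- function(rois, path, kidney_id = NA_character_, time_point = NA_integer_) {
  df <- as.data.frame(rois)
  if (is.null(df$kidney)) df$kidney <- kidney_id
  if (is.null(df$timepoint)) df$timepoint <- time_point
  utils::write.csv(df[, c("kidney", "timepoint", "region", "x0", "y0", "k", "l", "H")],
                   path, row.names = FALSE)
  invisible(path)
}
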