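# Separable Gaussian blur of a matrix (reflective edges), used for the
# detection image only.
.gauss_blur <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  r <- max(1, ceiling(3 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  pad_conv <- function(v) {
    n <- length(v)
    vp <- c(rev(v[seq_len(min(r, n))]), v,
            rev(v[seq.int(max(1, n - r + 1), n)]))
    stats::filter(vp, k, sides = 2)[(r + 1):(r + n)]
  }
  out <- apply(img, 2, pad_conv)
  t(apply(out, 1, pad_conv))
}

#' Detect nuclear ROIs in a plane series
#'
#' A lightweight detector for nuclear-localised indicators: the temporal
#' mean image is Gaussian-smoothed, local maxima exceeding
#' `background + threshold * SD` are kept with a minimum separation of one
#' cell diameter, and each surviving maximum seeds a disk ROI of radius half
#' a cell diameter. Pixels claimed by several disks are assigned to the
#' nearest centroid, so ROIs on a plane never share pixels. Maxima closer
#' than the minimum separation merge into the brighter one (a logged
#' consequence of the separation rule, mirroring how overlapping somata
#' cannot be split at this resolution).
#'
#' @param series A `plane_series` (see [deinterleave()]) or array
#'   `y` x `x` x `t`.
#' @param cell_diameter Typical cell diameter in um (default 6).
#' @param pixel_pitch um per pixel; scalar or `(x, y)` pair.
#' @param threshold Detection threshold in SD units above the smoothed
#'   image's background (median); default 2.
#' @param smooth_sigma Smoothing sigma in um (default `cell_diameter / 4`).
#' @return Object of class `roi_table`: data frame `(roi_id, plane, x, y,
#'   area)` (px coordinates, 1-based centroids) with attribute `pixels`, a
#'   list of linear pixel-index vectors per ROI, and attribute `img_dim`, the
#'   image size. Zero detections give a zero-row table.
#' @export
detect_rois <- function(series, cell_diameter = 6, pixel_pitch = 1,
                        threshold = 2, smooth_sigma = cell_diameter / 4) {
  plane_index <- 0L
  if (inherits(series, "plane_series")) {
    plane_index <- series$plane_index
    frames <- series$frames
  } else frames <- series
  stopifnot(length(dim(frames)) == 3, cell_diameter > 0)
  if (length(pixel_pitch) == 1) pixel_pitch <- rep(pixel_pitch, 2)
  mean_img <- apply(frames, c(1, 2), mean)
  img <- .gauss_blur(mean_img, smooth_sigma / mean(pixel_pitch))
  bg <- stats::median(img)
  cut <- bg + threshold * stats::sd(img)
  d <- dim(img)
  min_sep_px <- cell_diameter / mean(pixel_pitch)
  # local maxima over a 3x3 neighbourhood, above the threshold
  is_max <- img > cut
  if (any(is_max)) {
    padded <- matrix(-Inf, d[1] + 2, d[2] + 2)
    padded[2:(d[1] + 1), 2:(d[2] + 1)] <- img
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      nb <- padded[2:(d[1] + 1) + dr, 2:(d[2] + 1) + dc]
      is_max <- is_max & (img >= nb)
    }
  }
  idx <- which(is_max)
  empty <- data.frame(roi_id = integer(0), plane = integer(0),
                      x = numeric(0), y = numeric(0), area = integer(0))
  if (length(idx) == 0) {
    attr(empty, "pixels") <- list()
    attr(empty, "img_dim") <- d
    class(empty) <- c("roi_table", class(empty))
    return(empty)
  }
  pk <- arrayInd(idx, d)
  ord <- order(-img[idx])
  pk <- pk[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(pk))
  merged <- 0L
  for (i in seq_len(nrow(pk))) {
    if (!keep[i]) next
    if (i < nrow(pk)) {
      later <- (i + 1):nrow(pk)
      dd <- sqrt((pk[later, 1] - pk[i, 1])^2 + (pk[later, 2] - pk[i, 2])^2)
      drop_these <- later[keep[later] & dd < min_sep_px]
      merged <- merged + length(drop_these)
      keep[drop_these] <- FALSE
    }
  }
  if (merged > 0)
    message(sprintf("detect_rois: merged %d maxima closer than %0.1f px",
                    merged, min_sep_px))
  pk <- pk[keep, , drop = FALSE]
  n_roi <- nrow(pk)
  radius_px <- cell_diameter / 2 / mean(pixel_pitch)
  # assign disk pixels; contested pixels go to the nearest centroid
  owner <- matrix(0L, d[1], d[2])
  best_d2 <- matrix(Inf, d[1], d[2])
  r_int <- ceiling(radius_px)
  for (i in seq_len(n_roi)) {
    rows <- max(1, pk[i, 1] - r_int):min(d[1], pk[i, 1] + r_int)
    cols <- max(1, pk[i, 2] - r_int):min(d[2], pk[i, 2] + r_int)
    d2 <- outer((rows - pk[i, 1])^2, (cols - pk[i, 2])^2, "+")
    inside <- d2 <= radius_px^2
    sub_best <- best_d2[rows, cols]
    take <- inside & (d2 < sub_best)
    ow <- owner[rows, cols]
    ow[take] <- i
    owner[rows, cols] <- ow
    sub_best[take] <- d2[take]
    best_d2[rows, cols] <- sub_best
  }
  pixels <- lapply(seq_len(n_roi), function(i) which(owner == i))
  tab <- data.frame(roi_id = seq_len(n_roi),
                    plane = rep(plane_index, n_roi),
                    x = pk[, 2], y = pk[, 1],
                    area = vapply(pixels, length, integer(1)))
  attr(tab, "pixels") <- pixels
  attr(tab, "img_dim") <- d
  class(tab) <- c("roi_table", class(tab))
  tab
}

#' Extract per-ROI fluorescence traces
#'
#' Mean intensity over each ROI's pixel set, per frame.
#'
#' @param series A `plane_series` or array `y` x `x` x `t` (same plane as
#'   the ROI table).
#' @param rois A [detect_rois()] table (attribute `pixels` required).
#' @return A [trace_matrix()] (ROIs x time); rate taken from the series'
#'   timestamps when available, else 1.
#' @export
extract_traces <- function(series, rois) {
  frames <- if (inherits(series, "plane_series")) series$frames else series
  stopifnot(length(dim(frames)) == 3)
  pixels <- attr(rois, "pixels")
  if (is.null(pixels)) stop("roi table carries no pixel sets")
  if (any(vapply(pixels, length, integer(1)) == 0))
    stop("empty ROI pixel set")
  d <- dim(frames)
  flat <- matrix(frames, nrow = d[1] * d[2])
  traces <- t(vapply(pixels, function(px) colMeans(flat[px, , drop = FALSE]),
                     numeric(d[3])))
  if (length(pixels) == 1) traces <- matrix(traces, nrow = 1)
  rate <- 1
  if (inherits(series, "plane_series") && length(series$timestamps) > 1)
    rate <- 1 / mean(diff(series$timestamps))
  trace_matrix(traces, rate = rate,
               t0 = if (inherits(series, "plane_series"))
                 series$timestamps[1] else 0)
}

#' Read / write ROI tables as CSV
#'
#' The CSV path is the import route for externally produced segmentations
#' (e.g. suite2p exports converted to `roi_id, plane, x, y, area`); pixel
#' sets are reconstructed as disks of `cell_diameter / 2` when absent.
#'
#' @param rois A `roi_table`.
#' @param path CSV file.
#' @export
write_rois <- function(rois, path) {
  utils::write.csv(as.data.frame(rois)[, c("roi_id", "plane", "x", "y", "area")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rois
#' @param dim Image dimensions `(n_y, n_x)` used to rebuild pixel sets.
#' @param cell_diameter Cell diameter in px for rebuilt disk ROIs.
#' @export
read_rois <- function(path, dim, cell_diameter = 8) {
  tab <- utils::read.csv(path)
  radius <- cell_diameter / 2
  pixels <- lapply(seq_len(nrow(tab)), function(i) {
    rows <- max(1, round(tab$y[i] - radius)):min(dim[1], round(tab$y[i] + radius))
    cols <- max(1, round(tab$x[i] - radius)):min(dim[2], round(tab$x[i] + radius))
    g <- expand.grid(r = rows, c = cols)
    g <- g[(g$r - tab$y[i])^2 + (g$c - tab$x[i])^2 <= radius^2, ]
    (g$c - 1) * dim[1] + g$r
  })
  attr(tab, "pixels") <- pixels
  attr(tab, "img_dim") <- dim
  class(tab) <- c("roi_table", class(tab))
  tab
}
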