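#' De-interleave a frame stream into per-plane series
#'
#' In a ramping acquisition, consecutive frames sample consecutive planes:
#' frame `k` (0-based) belongs to plane `k mod n_planes`. Incomplete trailing
#' volumes are dropped, as are all frames in the first `discard_initial`
#' seconds (the lens drifts thermally early in a session).
#'
#' @param stream A `frame_stream` (see [render_acquisition()]) or a plain
#'   array `y` x `x` x `frames`.
#' @param n_planes Planes per volume (taken from the stream's geometry when
#'   available).
#' @param discard_initial Seconds to drop from the start (whole volumes;
#'   default 0 — pipeline configurations typically use 60).
#' @param frame_rate Frame rate, Hz; required for a plain array when
#'   `discard_initial > 0`.
#' @return A list of `plane_series` objects, one per plane: each a list with
#'   `plane_index` (0-based), `frames` (`y` x `x` x `t`), `timestamps` (s)
#'   and `applied_shifts` (NULL until motion corrected). Attribute
#'   `dropped_frames` records how many trailing frames were discarded.
#' @export
deinterleave <- function(stream, n_planes = NULL, discard_initial = 0,
                         frame_rate = NULL) {
  if (inherits(stream, "frame_stream")) {
    if (is.null(n_planes)) n_planes <- stream$geometry$n_planes
    if (is.null(frame_rate)) frame_rate <- stream$geometry$frame_rate
    frames <- stream$frames
  } else {
    frames <- stream
  }
  if (is.null(n_planes) || n_planes <= 0) stop("n_planes must be positive")
  stopifnot(length(dim(frames)) == 3)
  n_frames <- dim(frames)[3]
  if (n_frames < n_planes) stop("stream shorter than one volume")
  if (discard_initial > 0) {
    if (is.null(frame_rate)) stop("frame_rate needed to discard by time")
    n_drop_vol <- floor(discard_initial * frame_rate / n_planes)
  } else n_drop_vol <- 0L
  n_vol <- floor(n_frames / n_planes)
  dropped_tail <- n_frames - n_vol * n_planes
  if (n_drop_vol >= n_vol) stop("discard_initial leaves no complete volume")
  vols <- (n_drop_vol + 1):n_vol
  if (is.null(frame_rate)) frame_rate <- n_planes  # 1 volume/s nominal
  out <- vector("list", n_planes)
  for (p in seq_len(n_planes)) {
    idx <- (vols - 1) * n_planes + p
    ps <- list(plane_index = p - 1L,
               frames = frames[, , idx, drop = FALSE],
               timestamps = (idx - 1) / frame_rate,
               applied_shifts = NULL)
    class(ps) <- "plane_series"
    out[[p]] <- ps
  }
  attr(out, "dropped_frames") <- dropped_tail
  attr(out, "dropped_volumes") <- n_drop_vol
  out
}

#' Re-interleave per-plane series into a single frame array
#'
#' Inverse of [deinterleave()] for the retained frames; useful for
#' round-trip checks and export.
#'
#' @param planes List of `plane_series` from [deinterleave()].
#' @return Array `y` x `x` x `frames` in acquisition order.
#' @export
reinterleave <- function(planes) {
  n_planes <- length(planes)
  n_vol <- dim(planes[[1]]$frames)[3]
  d <- dim(planes[[1]]$frames)
  out <- array(NA_real_, dim = c(d[1], d[2], n_planes * n_vol))
  for (p in seq_len(n_planes))
    out[, , seq(p, by = n_planes, length.out = n_vol)] <- planes[[p]]$frames
  out
}

# --- phase cross-correlation ------------------------------------------------

# 2D FFT wrappers (stats::fft handles n-d arrays)
.fft2 <- function(x) stats::fft(x)
.ifft2 <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# Upsampled cross-correlation in a small neighbourhood of an offset, via
# matrix-multiply DFT (Guizar-Sicairos style local upsampling).
.dft_ups <- function(cross_f, shift0, ups) {
  d <- dim(cross_f)
  nr <- d[1]; nc <- d[2]
  half <- ceiling(1.5 * ups)
  rows <- (round(shift0[1] * ups) + (-half:half)) / ups
  cols <- (round(shift0[2] * ups) + (-half:half)) / ups
  fr <- c(0:floor((nr - 1) / 2), -(ceiling((nr - 1) / 2):1)) / nr
  fc <- c(0:floor((nc - 1) / 2), -(ceiling((nc - 1) / 2):1)) / nc
  Er <- exp(2i * pi * outer(rows, fr))        # length(rows) x nr
  Ec <- exp(2i * pi * outer(fc, cols))        # nc x length(cols)
  cc <- Re(Er %*% cross_f %*% Ec)
  peak <- arrayInd(which.max(cc), dim(cc))
  c(rows[peak[1]], cols[peak[2]])
}

#' Estimate a rigid shift between two frames by phase cross-correlation
#'
#' Integer-pixel estimate from the phase-correlation peak, refined to
#' subpixel precision by locally upsampling the cross-correlation with a
#' matrix-multiply DFT.
#'
#' @param reference,frame Numeric matrices of equal size.
#' @param upsample Subpixel refinement factor (default 10; 1 = integer only).
#' @return Numeric `(dy, dx)`: the shift that, applied to `reference`,
#'   produces `frame` (equivalently, subtract it from `frame` to align).
#' @export
phase_shift <- function(reference, frame, upsample = 10) {
  stopifnot(all(dim(reference) == dim(frame)))
  F1 <- .fft2(reference)
  F2 <- .fft2(frame)
  cross <- F2 * Conj(F1)
  denom <- Mod(cross)
  cross_n <- cross / ifelse(denom > 1e-12, denom, 1)
  cc <- Re(.ifft2(cross_n))
  d <- dim(cc)
  peak <- arrayInd(which.max(cc), d) - 1L
  # wrap to signed shifts
  shift <- ifelse(peak > d / 2, peak - d, peak)
  if (upsample > 1)
    shift <- .dft_ups(cross_n, shift, upsample)
  shift
}

#' Shift an image by a (possibly subpixel) rigid translation
#'
#' Integer shifts are applied by index rolling (exact); fractional shifts
#' use the Fourier shift theorem.
#'
#' @param img Numeric matrix.
#' @param shift Numeric `(dy, dx)` in px.
#' @return Shifted matrix (circular boundary).
#' @export
shift_image <- function(img, shift) {
  if (all(shift == round(shift))) {
    d <- dim(img)
    r <- (seq_len(d[1]) - 1 - shift[1]) %% d[1] + 1
    c <- (seq_len(d[2]) - 1 - shift[2]) %% d[2] + 1
    return(img[r, c, drop = FALSE])
  }
  d <- dim(img)
  fr <- c(0:floor((d[1] - 1) / 2), -(ceiling((d[1] - 1) / 2):1)) / d[1]
  fc <- c(0:floor((d[2] - 1) / 2), -(ceiling((d[2] - 1) / 2):1)) / d[2]
  ph <- exp(-2i * pi * (outer(fr * shift[1], rep(1, d[2])) +
                          outer(rep(1, d[1]), fc * shift[2])))
  Re(.ifft2(.fft2(img) * ph))
}

#' Rigid motion correction of a plane series
#'
#' Estimates a per-frame rigid (dx, dy) shift against a reference image by
#' phase cross-correlation with subpixel (default x10 upsampled) precision,
#' and applies the correcting shift to each frame. Shifts are recorded in
#' `applied_shifts`.
#'
#' @param series A `plane_series` (from [deinterleave()]) or a plain array
#'   `y` x `x` x `t` with >= 2 frames.
#' @param reference `"mean"` (default; temporal mean image) or `"first"`.
#' @param upsample Subpixel upsampling factor (default 10).
#' @return The corrected `plane_series` with `applied_shifts` set to an
#'   `t` x 2 matrix of estimated `(dx, dy)` per frame (the motion that was
#'   removed).
#' @export
motion_correct <- function(series, reference = c("mean", "first"),
                           upsample = 10) {
  reference <- match.arg(reference)
  plain <- !inherits(series, "plane_series")
  frames <- if (plain) series else series$frames
  stopifnot(length(dim(frames)) == 3)
  n_t <- dim(frames)[3]
  if (n_t < 2) stop("need at least 2 frames")
  if (any(!is.finite(frames))) stop("frames contain non-finite values")
  ref <- if (reference == "mean") apply(frames, c(1, 2), mean) else
    frames[, , 1]
  shifts <- matrix(0, n_t, 2, dimnames = list(NULL, c("dx", "dy")))
  for (k in seq_len(n_t)) {
    s <- phase_shift(ref, frames[, , k], upsample = upsample)  # (dy, dx)
    shifts[k, ] <- c(s[2], s[1])
    frames[, , k] <- shift_image(frames[, , k], -s)
  }
  if (plain) {
    attr(frames, "applied_shifts") <- shifts
    return(frames)
  }
  series$frames <- frames
  series$applied_shifts <- shifts
  series
}

#' Running-average temporal smoothing
#'
#' Centred moving mean of odd window length along time. Edges use shrunken
#' (truncated) windows so the output has the same length and the overall
#' mean is conserved up to edge effects of order window/length.
#'
#' @param x A `plane_series`, [trace_matrix()] (smoothed along rows'
#'   columns), numeric vector, or array `y` x `x` x `t`.
#' @param window Odd window length in frames (default 3). `window = 1` is
#'   the identity.
#' @return Same shape/class as the input, smoothed along time.
#' @export
running_average <- function(x, window = 3) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  if (window == 1) return(x)
  half <- (window - 1) / 2
  smooth_vec <- function(v) {
    n <- length(v)
    cs <- cumsum(c(0, v))
    lo <- pmax(seq_len(n) - half, 1)
    hi <- pmin(seq_len(n) + half, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  }
  if (inherits(x, "plane_series")) {
    d <- dim(x$frames)
    m <- matrix(x$frames, nrow = d[1] * d[2])
    m <- t(apply(m, 1, smooth_vec))
    x$frames <- array(m, dim = d)
    return(x)
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1, smooth_vec))
    attributes(out) <- attributes(x)
    return(out)
  }
  if (is.array(x) && length(dim(x)) == 3) {
    d <- dim(x)
    m <- matrix(x, nrow = d[1] * d[2])
    m <- t(apply(m, 1, smooth_vec))
    return(array(m, dim = d))
  }
  smooth_vec(as.numeric(x))
}

#' Noise-floor estimate from pre-stimulus segments
#'
#' The mean over segments of the per-segment sample standard deviation,
#' following the convention of estimating the noise floor from (by default
#' 16) pre-stimulus stretches of the trace.
#'
#' @param trace Numeric vector.
#' @param segments List of integer index vectors, one per segment; each must
#'   have >= 2 samples and lie within the trace.
#' @return Scalar noise-floor estimate (same units as the trace).
#' @seealso [pre_stimulus_segments()]
#' @export
noise_floor <- function(trace, segments) {
  if (!is.list(segments) || length(segments) < 1)
    stop("segments must be a non-empty list of index vectors")
  sds <- vapply(segments, function(idx) {
    if (length(idx) < 2) stop("each segment needs >= 2 samples")
    if (any(idx < 1 | idx > length(trace))) stop("segment outside trace")
    stats::sd(trace[idx])
  }, numeric(1))
  mean(sds)
}

#' Build pre-stimulus baseline segments from a protocol
#'
#' One segment per presentation (up to `n_segments`), ending at the sample
#' before the onset.
#'
#' @param protocol A [stimulus_protocol()].
#' @param rate Sampling rate, Hz.
#' @param segment_length Segment length in samples (default 20).
#' @param n_segments Maximum number of segments (default 16).
#' @return List of integer index vectors (1-based sample indices).
#' @export
pre_stimulus_segments <- function(protocol, rate, segment_length = 20,
                                  n_segments = 16) {
  onsets <- protocol$presentations$onset
  segs <- list()
  for (on in onsets) {
    end <- floor(on * rate)           # sample before onset (1-based grid)
    start <- end - segment_length + 1
    if (start >= 1) segs[[length(segs) + 1]] <- start:end
    if (length(segs) >= n_segments) break
  }
  segs
}
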