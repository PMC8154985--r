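#' Place synthetic nuclei in a scan volume with known ground truth
#'
#' Cells are placed by rejection sampling under a hard minimum-distance rule
#' (nuclei do not overlap; default minimum equals the typical 6 um cell
#' diameter). A configurable fraction of cells is flagged as
#' stimulus-responsive and assigned one of `n_motifs` response motifs and a
#' per-cell response amplitude.
#'
#' @param geometry An [acquisition_geometry()] giving the volume extent.
#' @param n_cells Number of cells to place (>= 0).
#' @param seed Integer seed; the same seed reproduces the brain exactly.
#' @param min_distance Minimum pairwise centre distance in um (default 6).
#' @param responsive_fraction Fraction of cells flagged responsive
#'   (default 0.05, the top-quantile used downstream).
#' @param n_motifs Number of response motifs among responsive cells
#'   (default 4).
#' @param amplitude_meanlog,amplitude_sdlog Log-normal parameters of the
#'   per-cell response amplitude (dF/F scale); defaults give amplitudes
#'   around 1.5 (strongly stimulus-driven cells) with ~25% spread.
#' @return An object of class `ground_truth`: list with `cell_positions`
#'   (n x 3 matrix, um), `responsive` (logical), `motif` (integer, `NA` for
#'   non-responsive cells), `amplitude` (numeric, `NA` for non-responsive),
#'   `min_distance`, `geometry`, `seed`.
#' @examples
#' geom <- acquisition_geometry(fov_x = 100, fov_y = 100, z_range = 50)
#' gt <- generate_brain(geom, 50, seed = 1)
#' min(dist(gt$cell_positions)) >= 6
#' @export
generate_brain <- function(geometry, n_cells, seed,
                           min_distance = 6,
                           responsive_fraction = 0.05,
                           n_motifs = 4,
                           amplitude_meanlog = log(1.5), amplitude_sdlog = 0.25) {
  stopifnot(inherits(geometry, "acquisition_geometry"), n_cells >= 0)
  set.seed(as.integer(seed))
  ext <- c(geometry$fov_x, geometry$fov_y, geometry$z_range)
  pos <- matrix(numeric(0), ncol = 3,
                dimnames = list(NULL, c("x", "y", "z")))
  if (n_cells > 0) {
    pos <- matrix(NA_real_, nrow = n_cells, ncol = 3,
                  dimnames = list(NULL, c("x", "y", "z")))
    placed <- 0L
    attempts <- 0L
    max_attempts <- 200L * n_cells
    d2min <- min_distance^2
    while (placed < n_cells && attempts < max_attempts) {
      attempts <- attempts + 1L
      cand <- stats::runif(3) * ext
      ok <- TRUE
      if (placed > 0L) {
        d2 <- (pos[seq_len(placed), 1] - cand[1])^2 +
              (pos[seq_len(placed), 2] - cand[2])^2 +
              (pos[seq_len(placed), 3] - cand[3])^2
        ok <- all(d2 >= d2min)
      }
      if (ok) {
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
    }
    if (placed < n_cells)
      stop(sprintf(
        "could not place %d cells at min distance %g um in %g x %g x %g um; achieved %d",
        n_cells, min_distance, ext[1], ext[2], ext[3], placed))
  }
  n_resp <- ceiling(responsive_fraction * n_cells)
  responsive <- rep(FALSE, n_cells)
  if (n_resp > 0) responsive[sample.int(n_cells, n_resp)] <- TRUE
  motif <- rep(NA_integer_, n_cells)
  amplitude <- rep(NA_real_, n_cells)
  if (n_resp > 0) {
    motif[responsive] <- sample.int(n_motifs, n_resp, replace = TRUE)
    amplitude[responsive] <- stats::rlnorm(n_resp, amplitude_meanlog,
                                           amplitude_sdlog)
  }
  out <- list(cell_positions = pos, responsive = responsive, motif = motif,
              amplitude = amplitude, min_distance = min_distance,
              geometry = geometry, seed = as.integer(seed))
  class(out) <- "ground_truth"
  out
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("Synthetic brain: %d cells (%d responsive, %d motifs), min distance %g um\n",
              nrow(x$cell_positions), sum(x$responsive),
              length(unique(stats::na.omit(x$motif))), x$min_distance))
  invisible(x)
}

#' Calcium-reporter activity model parameters
#'
#' Forward model of nuclear-localised GCaMP6s fluorescence: spikes are
#' convolved with a single-exponential decay kernel of time constant
#' `tau_decay` (the reporter's characteristic response decay, 3.5-4.1 s for
#' H2B-GCaMP6s), scaled by `photon_gain` on top of a baseline `baseline_F0`,
#' with Poisson (photon-counting) or Gaussian noise.
#'
#' @param tau_decay Reporter decay time constant in seconds (default 3.5).
#' @param baseline_rate Spontaneous event rate per cell, events/s
#'   (default 0.01, about 0.6 transients per minute).
#' @param stim_response_prob Probability that a responsive cell fires on a
#'   given stimulus presentation (default 0.8).
#' @param photon_gain Fluorescence counts per unit dF/F (default 100).
#' @param baseline_F0 Baseline fluorescence counts (default 20).
#' @param spont_amplitude dF/F-scale amplitude of spontaneous events
#'   (default 0.5; stimulus-evoked responses in looming-selective cells are
#'   strong relative to spontaneous transients).
#' @param noise `"poisson"` (default), `"gaussian"`, or `"none"`.
#' @param gaussian_sd SD of Gaussian noise when `noise = "gaussian"`.
#' @return An object of class `activity_model`.
#' @export
activity_model <- function(tau_decay = 3.5, baseline_rate = 0.01,
                           stim_response_prob = 0.8, photon_gain = 100,
                           baseline_F0 = 20, spont_amplitude = 0.5,
                           noise = c("poisson", "gaussian", "none"),
                           gaussian_sd = 1) {
  stopifnot(tau_decay > 0, baseline_rate >= 0,
            stim_response_prob >= 0, stim_response_prob <= 1,
            photon_gain > 0, baseline_F0 >= 0, spont_amplitude >= 0)
  out <- list(tau_decay = tau_decay, baseline_rate = baseline_rate,
              stim_response_prob = stim_response_prob,
              photon_gain = photon_gain, baseline_F0 = baseline_F0,
              spont_amplitude = spont_amplitude,
              noise = match.arg(noise), gaussian_sd = gaussian_sd)
  class(out) <- "activity_model"
  out
}

#' Default library of stimulus-response motifs
#'
#' Four kinetically distinct motifs, mirroring the main groups seen in
#' looming-responsive populations: a fast-adapting onset burst (spikes of
#' decreasing amplitude early in the epoch), a sustained response spread
#' over the stimulus epoch, a slow-rising response peaking late in the
#' epoch, and a habituating onset burst whose amplitude decays across
#' presentations. Each motif is a list of
#' `offsets_frac` (event times as fractions of the stimulus epoch),
#' `rel_amp` (per-event relative amplitudes) and `habituation` (per-trial
#' multiplicative decay, 1 = none). Event amplitudes are further scaled by
#' the per-cell amplitude from the ground truth.
#'
#' @return A list of 4 motif definitions.
#' @export
default_motifs <- function() {
  list(
    fast_adapting = list(offsets_frac = c(0.05, 0.2, 0.35, 0.5),
                         rel_amp = c(0.55, 0.4, 0.3, 0.2), habituation = 1.0),
    sustained = list(offsets_frac = c(0.05, 0.275, 0.5, 0.725, 0.95),
                     rel_amp = rep(0.35, 5), habituation = 1.0),
    slow_rising = list(offsets_frac = c(0.6, 0.8, 1.0),
                       rel_amp = rep(0.45, 3), habituation = 1.0),
    habituating = list(offsets_frac = c(0.05, 0.2, 0.35, 0.5),
                       rel_amp = c(0.65, 0.45, 0.35, 0.25), habituation = 0.85)
  )
}

#' Simulate fluorescence traces for a synthetic brain
#'
#' Per cell, `F(t) = F0 + gain * (spike train (*) exp(-t / tau)) + noise`.
#' Every cell fires spontaneous events as a Poisson process at
#' `model$baseline_rate`; responsive cells additionally receive
#' stimulus-locked events on each presentation with probability
#' `model$stim_response_prob`, with times and amplitudes set by their motif.
#' The exponential kernel has unit peak, so an event of amplitude `a`
#' produces a fluorescence transient of `a * photon_gain` counts.
#'
#' @param truth A [generate_brain()] ground truth.
#' @param protocol A [stimulus_protocol()].
#' @param model An [activity_model()].
#' @param duration Recording duration in seconds; must cover the protocol.
#' @param rate Sampling rate in samples/s (volume rate for volumetric data).
#' @param seed Integer seed.
#' @param motifs Motif library; default [default_motifs()]. Motif labels in
#'   `truth` index into this list (recycled modulo its length).
#' @return A [trace_matrix()] (cells x time) with attribute `events`: a list
#'   (one element per cell) of data frames `(time, amplitude)` of the
#'   planted events, the recovery oracle for downstream tests.
#' @export
generate_activity <- function(truth, protocol, model, duration, rate, seed,
                              motifs = default_motifs()) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(protocol, "stimulus_protocol"),
            inherits(model, "activity_model"), rate > 0)
  if (nrow(protocol$presentations) > 0 &&
      max(protocol$presentations$offset) > duration)
    stop("duration does not cover the stimulus protocol")
  set.seed(as.integer(seed))
  n_cells <- nrow(truth$cell_positions)
  n_t <- round(duration * rate)
  kern <- exp(-(seq_len(ceiling(8 * model$tau_decay * rate)) - 1) /
                (model$tau_decay * rate))
  traces <- matrix(model$baseline_F0, nrow = n_cells, ncol = n_t)
  events <- vector("list", n_cells)
  pres <- protocol$presentations
  for (i in seq_len(n_cells)) {
    ev_t <- numeric(0)
    ev_a <- numeric(0)
    n_spont <- stats::rpois(1, model$baseline_rate * duration)
    if (n_spont > 0) {
      ev_t <- stats::runif(n_spont, 0, duration)
      ev_a <- rep(model$spont_amplitude %||% 1, n_spont)
    }
    if (isTRUE(truth$responsive[i]) && nrow(pres) > 0) {
      m <- motifs[[(truth$motif[i] - 1L) %% length(motifs) + 1L]]
      for (trial in seq_len(nrow(pres))) {
        if (stats::runif(1) <= model$stim_response_prob) {
          epoch <- pres$offset[trial] - pres$onset[trial]
          ev_t <- c(ev_t, pres$onset[trial] + m$offsets_frac * epoch)
          ev_a <- c(ev_a, truth$amplitude[i] * m$rel_amp *
                      m$habituation^(trial - 1))
        }
      }
    }
    if (length(ev_t) > 0) {
      o <- order(ev_t)
      ev_t <- ev_t[o]; ev_a <- ev_a[o]
      deltas <- numeric(n_t)
      idx <- pmin(n_t, floor(ev_t * rate) + 1)
      for (j in seq_along(idx)) deltas[idx[j]] <- deltas[idx[j]] + ev_a[j]
      clean <- .causal_conv(deltas, kern)
      traces[i, ] <- traces[i, ] + model$photon_gain * clean
    }
    events[[i]] <- data.frame(time = ev_t, amplitude = ev_a)
  }
  if (model$noise == "poisson") {
    traces[] <- stats::rpois(length(traces), pmax(traces, 0))
  } else if (model$noise == "gaussian") {
    traces <- traces + stats::rnorm(length(traces), 0, model$gaussian_sd)
  }
  tm <- trace_matrix(traces, rate = rate)
  attr(tm, "events") <- events
  tm
}

# causal convolution of x with kernel k, truncated to length(x)
.causal_conv <- function(x, k) {
  n <- length(x)
  out <- stats::convolve(x, rev(k), type = "open")[seq_len(n)]
  out
}

#' ROI- or pixel-by-time fluorescence trace container
#'
#' A plain numeric matrix (traces in rows, time in columns) carrying its
#' sampling rate and time origin as attributes, with class `trace_matrix`.
#'
#' @param data Numeric matrix, traces x time.
#' @param rate Sampling rate, samples/s.
#' @param t0 Time of the first sample in seconds (default 0).
#' @return The matrix with class `trace_matrix` and attributes `rate`, `t0`.
#' @export
trace_matrix <- function(data, rate, t0 = 0) {
  data <- as.matrix(data)
  stopifnot(rate > 0)
  attr(data, "rate") <- rate
  attr(data, "t0") <- t0
  class(data) <- c("trace_matrix", class(data))
  data
}

#' Time axis of a trace matrix
#' @param traces A [trace_matrix()].
#' @return Numeric vector of sample times in seconds.
#' @export
trace_times <- function(traces) {
  attr(traces, "t0") + (seq_len(ncol(traces)) - 1) / attr(traces, "rate")
}

#' Render a synthetic interleaved acquisition stream
#'
#' Forward model of the ramping acquisition: frames are generated in
#' plane-major order within each volume cycle, and each frame's rows sample
#' the depth given by [row_z()]. Every cell contributes a 2D Gaussian spot
#' of lateral width `optics$sigma_xy` centred on its (x, y) position,
#' weighted axially by `exp(-dz^2 / (2 sigma_z^2))` where `dz` is the cell's
#' distance from the focus at its row. Optional rigid in-plane motion shifts
#' each frame; optional Poisson noise models photon counting.
#'
#' @param truth A [generate_brain()] ground truth.
#' @param geometry An [acquisition_geometry()].
#' @param traces A [trace_matrix()] of per-cell fluorescence, sampled at or
#'   above the volume rate (counts scale).
#' @param optics List with `sigma_xy` and `sigma_z` in um: either scalars or
#'   functions of depth z (um) to emulate z-dependent PSF broadening.
#' @param seed Integer seed (noise only).
#' @param n_volumes Number of volume cycles to render; default as many as
#'   the traces cover.
#' @param motion Optional per-frame integer or subpixel shifts: matrix
#'   (n_frames x 2) of (dx, dy) in px, applied to the scene before sampling.
#' @param background Background intensity in counts (default 0).
#' @param poisson_noise Apply Poisson noise to each frame (default FALSE;
#'   the trace simulation may already carry noise).
#' @return An object of class `frame_stream`: list with `frames` (array
#'   `n_y` x `n_x` x `n_frames`, acquisition order), `geometry`, `motion`,
#'   `timestamps` (frame start times, s).
#' @export
render_acquisition <- function(truth, geometry, traces, optics, seed = 1,
                               n_volumes = NULL, motion = NULL,
                               background = 0, poisson_noise = FALSE) {
  stopifnot(inherits(truth, "ground_truth"),
            inherits(geometry, "acquisition_geometry"),
            inherits(traces, "trace_matrix"))
  rate <- attr(traces, "rate")
  if (rate < geometry$volume_rate - 1e-9)
    stop("traces must be sampled at >= the volume rate")
  sxy_f <- if (is.function(optics$sigma_xy)) optics$sigma_xy else
    function(z) rep(optics$sigma_xy, length(z))
  sz_f <- if (is.function(optics$sigma_z)) optics$sigma_z else
    function(z) rep(optics$sigma_z, length(z))
  if (any(sxy_f(c(0, geometry$z_range)) <= 0) ||
      any(sz_f(c(0, geometry$z_range)) <= 0))
    stop("optics sigma values must be positive")
  if (is.null(n_volumes))
    n_volumes <- floor(ncol(traces) / rate * geometry$volume_rate)
  n_frames <- n_volumes * geometry$n_planes
  if (is.null(motion)) motion <- matrix(0, n_frames, 2)
  stopifnot(nrow(motion) >= n_frames)
  set.seed(as.integer(seed))
  pos <- truth$cell_positions
  n_cells <- nrow(pos)
  ny <- geometry$n_y; nx <- geometry$n_x
  # pixel centre coordinates in um (pixel i spans [(i-1), i] * pitch)
  px_x <- (pos[, "x"] / geometry$pixel_pitch_x) + 0.5
  px_y <- (pos[, "y"] / geometry$pixel_pitch_y) + 0.5
  frames <- array(background, dim = c(ny, nx, n_frames))
  timestamps <- (seq_len(n_frames) - 1) / geometry$frame_rate
  for (f in seq_len(n_frames)) {
    plane <- (f - 1) %% geometry$n_planes
    t_frame <- timestamps[f]
    ti <- min(ncol(traces), floor(t_frame * rate) + 1)
    for (i in seq_len(n_cells)) {
      cy <- px_y[i] + motion[f, 2]
      cx <- px_x[i] + motion[f, 1]
      row_near <- min(max(round(cy), 1), ny)
      z_focus <- row_z(geometry, plane, row_near - 1)
      sz <- sz_f(pos[i, "z"])
      dz <- pos[i, "z"] - z_focus
      if (abs(dz) > 4 * sz) next
      axial <- exp(-dz^2 / (2 * sz^2))
      amp <- traces[i, ti] * axial
      if (amp <= 0) next
      sxy <- sxy_f(pos[i, "z"])
      s_px_x <- sxy / geometry$pixel_pitch_x
      s_px_y <- sxy / geometry$pixel_pitch_y
      rx <- ceiling(4 * s_px_x); ry <- ceiling(4 * s_px_y)
      xs <- max(1, floor(cx - rx)):min(nx, ceiling(cx + rx))
      ys <- max(1, floor(cy - ry)):min(ny, ceiling(cy + ry))
      if (length(xs) == 0 || length(ys) == 0) next
      gx <- exp(-(xs - cx)^2 / (2 * s_px_x^2))
      gy <- exp(-(ys - cy)^2 / (2 * s_px_y^2))
      frames[ys, xs, f] <- frames[ys, xs, f] + amp * outer(gy, gx)
    }
  }
  if (poisson_noise)
    frames[] <- stats::rpois(length(frames), pmax(frames, 0))
  out <- list(frames = frames, geometry = geometry,
              motion = motion[seq_len(n_frames), , drop = FALSE],
              timestamps = timestamps)
  class(out) <- "frame_stream"
  out
}

#' @export
print.frame_stream <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("Frame stream: %d frames of %d x %d px (%d planes, %g Hz)\n",
              d[3], d[2], d[1], x$geometry$n_planes, x$geometry$frame_rate))
  invisible(x)
}

#' Generate a synthetic fluorescent-bead z-stack
#'
#' Point-like beads (diameter << PSF) are rendered as 3D Gaussian spots at
#' random positions, emulating a PSF-metrology stack of sub-diffraction
#' polystyrene beads. Beads are kept away from the stack border so that the
#' profile crop window fits.
#'
#' @param sigma_xy,sigma_z Lateral and axial Gaussian sigma of the rendered
#'   spot, in um; scalars or functions of depth z for a depth-dependent PSF.
#' @param voxel_size Numeric length-3, (dx, dy, dz) um per voxel.
#' @param extent Numeric length-3, stack extent (X, Y, Z) in um.
#' @param n_beads Number of beads.
#' @param seed Integer seed.
#' @param amplitude Peak intensity per bead (counts).
#' @param background Constant background (counts).
#' @param noise `"none"` (default), `"poisson"`, or `"gaussian"`.
#' @param gaussian_sd SD for Gaussian noise.
#' @param margin_sigmas Border margin in units of sigma (default 7; wide enough for a 6-sigma profile crop window).
#' @return List with `stack` (array `n_y` x `n_x` x `n_z`), `voxel_size`,
#'   `truth` (data frame x, y, z, sigma_xy, sigma_z, amplitude; um).
#' @export
generate_bead_stack <- function(sigma_xy, sigma_z,
                                voxel_size = c(0.1, 0.1, 0.5),
                                extent = c(15, 15, 40),
                                n_beads = 1, seed = 1,
                                amplitude = 1000, background = 0,
                                noise = c("none", "poisson", "gaussian"),
                                gaussian_sd = 1, margin_sigmas = 7) {
  noise <- match.arg(noise)
  sxy_f <- if (is.function(sigma_xy)) sigma_xy else function(z) rep(sigma_xy, length(z))
  sz_f <- if (is.function(sigma_z)) sigma_z else function(z) rep(sigma_z, length(z))
  if (any(sxy_f(c(0, extent[3])) <= 0) || any(sz_f(c(0, extent[3])) <= 0))
    stop("sigma values must be positive")
  set.seed(as.integer(seed))
  n <- pmax(3L, as.integer(round(extent / voxel_size)))
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  stack <- array(background, dim = c(ny, nx, nz))
  xs_um <- (seq_len(nx) - 0.5) * voxel_size[1]
  ys_um <- (seq_len(ny) - 0.5) * voxel_size[2]
  zs_um <- (seq_len(nz) - 0.5) * voxel_size[3]
  truth <- data.frame(x = numeric(n_beads), y = numeric(n_beads),
                      z = numeric(n_beads), sigma_xy = numeric(n_beads),
                      sigma_z = numeric(n_beads),
                      amplitude = rep(amplitude, n_beads))
  for (b in seq_len(n_beads)) {
    # draw z first: the margins depend on the local sigma
    z0 <- stats::runif(1, 0.25 * extent[3], 0.75 * extent[3])
    sxy <- sxy_f(z0); sz <- sz_f(z0)
    mx <- margin_sigmas * sxy; mz <- margin_sigmas * sz
    if (2 * mx >= extent[1] || 2 * mx >= extent[2] || 2 * mz >= extent[3])
      stop("stack extent too small for the requested sigma and margin")
    x0 <- stats::runif(1, mx, extent[1] - mx)
    y0 <- stats::runif(1, mx, extent[2] - mx)
    z0 <- min(max(z0, mz), extent[3] - mz)
    gx <- exp(-(xs_um - x0)^2 / (2 * sxy^2))
    gy <- exp(-(ys_um - y0)^2 / (2 * sxy^2))
    gz <- exp(-(zs_um - z0)^2 / (2 * sz^2))
    spot <- outer(gy, gx)
    for (k in which(gz > 1e-6))
      stack[, , k] <- stack[, , k] + amplitude * gz[k] * spot
    truth[b, c("x", "y", "z", "sigma_xy", "sigma_z")] <-
      c(x0, y0, z0, sxy, sz)
  }
  if (noise == "poisson") {
    stack[] <- stats::rpois(length(stack), pmax(stack, 0))
  } else if (noise == "gaussian") {
    stack <- stack + stats::rnorm(length(stack), 0, gaussian_sd)
  }
  list(stack = stack, voxel_size = voxel_size, truth = truth)
}

#' A smooth monotone reference current-to-depth calibration curve
#'
#' Mildly nonlinear mapping from focal depth (um) to ETL drive current (mA),
#' used as the default "true" hardware curve for synthetic calibration point
#' sets. Monotone increasing over 0-233 um, spanning roughly 40-230 mA.
#'
#' @param z Depth(s) in um.
#' @return Drive current(s) in mA.
#' @export
default_etl_curve <- function(z) 40 + 0.75 * z + 2.2e-4 * z^2

#' Sample a synthetic ETL calibration point set
#'
#' Emulates the calibration procedure: the same field of view is imaged at a
#' series of drive currents and the objective travel needed to restore focus
#' measures the focal shift, yielding (I, z) pairs with measurement noise on
#' the current.
#'
#' @param true_curve Monotone function mapping z (um) to current (mA);
#'   default [default_etl_curve()].
#' @param z_range Length-2 depth range in um (default `c(0, 233)`).
#' @param n_points Number of calibration points (>= 7; a degree-5 fit needs
#'   6 and one more leaves a residual check). Default 8.
#' @param noise_sd Additive Gaussian noise SD on the current, mA (default 0).
#' @param seed Integer seed.
#' @return Data frame with columns `I` (mA) and `z` (um).
#' @export
generate_lut_points <- function(true_curve = default_etl_curve,
                                z_range = c(0, 233), n_points = 8,
                                noise_sd = 0, seed = 1) {
  if (n_points < 7)
    stop("n_points must be >= 7 (degree-5 fit needs 6 plus one for residual)")
  set.seed(as.integer(seed))
  z <- seq(z_range[1], z_range[2], length.out = n_points)
  I <- true_curve(z) + stats::rnorm(n_points, 0, noise_sd)
  data.frame(I = I, z = z)
}

#' Generate smooth rigid in-plane motion shifts
#'
#' A clipped Gaussian random walk per axis, emulating slow drift plus jitter
#' of an embedded larva.
#'
#' @param n_frames Number of frames.
#' @param step_sd Per-frame random-walk step SD in px (default 0.1).
#' @param max_shift Clip magnitude in px (default 3).
#' @param integer_shifts Round shifts to whole pixels (default FALSE).
#' @param seed Integer seed.
#' @return Matrix n_frames x 2 of (dx, dy) shifts in px; frame 1 is (0, 0).
#' @export
generate_motion <- function(n_frames, step_sd = 0.1, max_shift = 3,
                            integer_shifts = FALSE, seed = 1) {
  set.seed(as.integer(seed))
  steps <- matrix(stats::rnorm(2 * n_frames, 0, step_sd), ncol = 2)
  steps[1, ] <- 0
  shifts <- apply(steps, 2, cumsum)
  shifts <- pmin(pmax(shifts, -max_shift), max_shift)
  if (integer_shifts) shifts <- round(shifts)
  shifts
}
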