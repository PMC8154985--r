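#' Fit an ETL look-up-table calibration polynomial
#'
#' An electrically tunable lens (ETL) shifts the focal plane as a nonlinear
#' function of its drive current. Calibration measures a set of
#' (current, focal shift) pairs; depths are remapped to a normalised
#' coordinate `z* = (z - z_min) / (z_max - z_min)` in `[0, 1]` and the drive
#' current is modelled as a degree-5 polynomial
#' `I(z*) = p0 + p1 z* + ... + p5 z*^5`, fitted by unconstrained least
#' squares. Endpoints are not forced: `I(0) ~ I_min` and `I(1) ~ I_max` hold
#' up to the fit residual, which is retained as a quality metric.
#'
#' @param points A data frame (or matrix) with columns `I` (drive current,
#'   mA) and `z` (measured focal shift, um). At least 7 points are required
#'   (a degree-5 fit needs 6; one extra leaves a residual degree of freedom).
#' @param degree Polynomial degree, default 5.
#' @return An object of class `lut_calibration`: list with `points`,
#'   `z_min`, `z_max`, `I_min`, `I_max`, `coefficients` (named `p0`..`p5`),
#'   `degree` and `residual_rms` (mA). A warning is issued if the fitted
#'   polynomial is not monotone on `[0, 1]` despite monotone input points.
#' @examples
#' pts <- data.frame(z = seq(0, 233, length.out = 8),
#'                   I = 40 + 0.9 * seq(0, 233, length.out = 8))
#' cal <- fit_lut(pts)
#' current_at(cal, c(0, 0.5, 1))
#' @seealso [current_at()], [generate_sawtooth()], [generate_lut_points()]
#' @export
fit_lut <- function(points, degree = 5) {
  points <- as.data.frame(points)
  stopifnot(all(c("I", "z") %in% names(points)), degree >= 1)
  if (nrow(points) < degree + 2)
    stop(sprintf("need at least %d calibration points for a degree-%d fit",
                 degree + 2, degree))
  z <- points$z
  I <- points$I
  if (diff(range(z)) <= 0) stop("z values are all equal; cannot normalise")
  z_star <- (z - min(z)) / (max(z) - min(z))
  dup <- duplicated(z_star)
  if (any(dup)) {
    if (sum(!dup) < degree + 1)
      stop("rank-deficient design: duplicated z* at z = ",
           paste(unique(z[z_star %in% z_star[dup]]), collapse = ", "))
  }
  X <- stats::poly(z_star, degree = degree, raw = TRUE)
  fit <- stats::lm.fit(cbind(1, X), I)
  coefs <- stats::setNames(fit$coefficients, paste0("p", 0:degree))
  rss <- sum(fit$residuals^2)
  cal <- list(
    points = data.frame(I = I, z = z, z_star = z_star),
    z_min = min(z), z_max = max(z),
    I_min = I[which.min(z)], I_max = I[which.max(z)],
    coefficients = coefs, degree = degree,
    residual_rms = sqrt(rss / length(I))
  )
  class(cal) <- "lut_calibration"
  # monotone input points should give a monotone drive curve; a wiggly fit
  # would make the focal sweep non-monotone in time
  if (!is.unsorted(I[order(z)]) || !is.unsorted(rev(I[order(z)]))) {
    grid <- .eval_poly(coefs, seq(0, 1, length.out = 201))
    if (is.unsorted(grid) && is.unsorted(rev(grid)))
      warning("fitted LUT polynomial is not monotone on [0, 1]")
  }
  cal
}

.eval_poly <- function(coefs, x) {
  out <- rep(0, length(x))
  for (i in rev(seq_along(coefs))) out <- out * x + coefs[[i]]
  out
}

#' @export
print.lut_calibration <- function(x, ...) {
  cat(sprintf("ETL LUT calibration: %d points, z in [%g, %g] um, I in [%g, %g] mA\n",
              nrow(x$points), x$z_min, x$z_max, x$I_min, x$I_max))
  cat(sprintf("  degree-%d fit, residual RMS %.3g mA\n", x$degree, x$residual_rms))
  cat(sprintf("  I(z*=0) = %.4g mA, I(z*=1) = %.4g mA\n",
              current_at(x, 0), current_at(x, 1)))
  invisible(x)
}

#' Evaluate the calibrated drive current at a normalised depth
#'
#' @param cal A [fit_lut()] calibration.
#' @param z_star Normalised depth(s) in `[0, 1]`. Values outside the
#'   calibrated range are an error: the polynomial is a fit, not an
#'   extrapolator.
#' @return Drive current(s) in mA.
#' @export
current_at <- function(cal, z_star) {
  stopifnot(inherits(cal, "lut_calibration"))
  if (any(z_star < 0 | z_star > 1))
    stop("z_star must lie in [0, 1]; no extrapolation outside the calibrated range")
  .eval_poly(cal$coefficients, z_star)
}

#' Generate one cycle of the sawtooth focus-ramp drive schedule
#'
#' The remote focus sweeps the volume once per cycle: the normalised depth
#' ramps linearly, `z*(t) = t / cycle_duration`, over `frames_per_cycle`
#' counted frames, then resets instantaneously to 0. The drive current is
#' updated every `update_interval` seconds from the LUT polynomial. The
#' schedule clock starts on a counted frame trigger (t = 0 is a frame start).
#'
#' @param cal A [fit_lut()] calibration.
#' @param frames_per_cycle Frames per volume cycle (e.g. 30).
#' @param frame_rate Frame rate in Hz (e.g. 30).
#' @param update_interval Current-update cadence in seconds (default 0.003,
#'   the fastest the lens driver accepts commands).
#' @param settling_dead_time If `TRUE`, mark samples falling in the first
#'   frame of the cycle as `settling` (the lens needs 6-12 ms to settle
#'   after the reset step); default `FALSE` models the reset as instantaneous.
#' @return An object of class `sawtooth_schedule`: list with
#'   `frames_per_cycle`, `frame_rate`, `update_interval`, `cycle_duration`
#'   and `samples`, a data frame of `(t, z_star, I_mA)` (plus `settling` if
#'   requested) with `floor(cycle_duration / update_interval)` rows.
#' @examples
#' cal <- fit_lut(data.frame(z = seq(0, 233, length.out = 8),
#'                           I = seq(40, 250, length.out = 8)))
#' sched <- generate_sawtooth(cal, 30, 30)   # 1 s cycle, 333 samples
#' nrow(sched$samples)
#' @export
generate_sawtooth <- function(cal, frames_per_cycle, frame_rate,
                              update_interval = 0.003,
                              settling_dead_time = FALSE) {
  stopifnot(inherits(cal, "lut_calibration"),
            frames_per_cycle >= 1, frame_rate > 0, update_interval > 0)
  cycle <- frames_per_cycle / frame_rate
  if (update_interval >= cycle)
    stop("update_interval must be shorter than the cycle duration")
  n <- floor(cycle / update_interval)
  t <- (seq_len(n) - 1) * update_interval
  z_star <- t / cycle
  samples <- data.frame(t = t, z_star = z_star, I_mA = current_at(cal, z_star))
  if (settling_dead_time)
    samples$settling <- t < 1 / frame_rate
  out <- list(frames_per_cycle = as.integer(frames_per_cycle),
              frame_rate = frame_rate, update_interval = update_interval,
              cycle_duration = cycle, samples = samples)
  class(out) <- "sawtooth_schedule"
  out
}

#' @export
print.sawtooth_schedule <- function(x, ...) {
  cat(sprintf("Sawtooth schedule: %d frames at %g Hz -> %g s cycle, %d samples every %g ms\n",
              x$frames_per_cycle, x$frame_rate, x$cycle_duration,
              nrow(x$samples), 1000 * x$update_interval))
  invisible(x)
}

#' Write / read an ETL calibration as JSON
#'
#' @param cal A `lut_calibration`.
#' @param path Output file.
#' @return `write_lut` returns `path` invisibly; `read_lut` returns the
#'   `lut_calibration`.
#' @export
write_lut <- function(cal, path) {
  stopifnot(inherits(cal, "lut_calibration"))
  jsonlite::write_json(
    list(points = cal$points[, c("I", "z")],
         z_range = c(cal$z_min, cal$z_max),
         degree = cal$degree,
         coefficients = as.list(cal$coefficients),
         residual_rms = cal$residual_rms),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_lut
#' @export
read_lut <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_lut(obj$points, degree = obj$degree)
}

#' Export a sawtooth schedule as CSV
#'
#' Columns `t`, `z_star`, `I_mA` (one row per driver update).
#' @param schedule A `sawtooth_schedule`.
#' @param path Output file.
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "sawtooth_schedule"))
  utils::write.csv(schedule$samples, path, row.names = FALSE)
  invisible(path)
}
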