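#' Intensity profile of a bead along one axis
#'
#' Reslices a crop of the stack around the bead along the chosen axis and
#' average-projects over the two remaining axes, yielding a 1D intensity
#' profile with physical coordinates — the standard reslice / average
#' projection / plot-profile procedure of bead-based PSF metrology.
#'
#' @param stack 3D numeric array `y` x `x` x `z`.
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param bead_center Integer voxel `(x, y, z)` (1-based) of the bead.
#' @param voxel_size Numeric length-3 `(dx, dy, dz)` in um/voxel.
#' @param window Crop size in voxels along each axis (odd; default 21).
#'   Scalar or length-3 `(wx, wy, wz)`; axial PSFs are elongated, so a
#'   larger z window is often needed.
#' @return Data frame `position` (um, relative to crop start) and
#'   `intensity`; attribute `axis`.
#' @export
profile_from_stack <- function(stack, axis = c("x", "y", "z"), bead_center,
                               voxel_size = c(1, 1, 1), window = 21) {
  axis <- match.arg(axis)
  stopifnot(length(dim(stack)) == 3, length(bead_center) == 3)
  if (length(window) == 1) window <- rep(window, 3)
  if (any(window %% 2 == 0)) stop("window must be odd")
  d <- dim(stack)                     # (ny, nx, nz)
  sizes <- c(d[2], d[1], d[3])        # in (x, y, z) order
  half <- (window - 1) / 2
  lo <- bead_center - half
  hi <- bead_center + half
  if (any(lo < 1) || any(hi > sizes))
    stop("bead too close to the stack border for the crop window; ",
         "use a larger stack padding or a smaller window")
  crop <- stack[lo[2]:hi[2], lo[1]:hi[1], lo[3]:hi[3], drop = FALSE]
  prof <- switch(axis,
                 x = apply(crop, 2, mean),
                 y = apply(crop, 1, mean),
                 z = apply(crop, 3, mean))
  step <- switch(axis, x = voxel_size[1], y = voxel_size[2],
                 z = voxel_size[3])
  out <- data.frame(position = (seq_along(prof) - 1) * step,
                    intensity = prof)
  attr(out, "axis") <- axis
  out
}

#' FWHM of a fluorescence profile
#'
#' The profile width is summarised as `FWHM = 2 * sqrt(2 * ln 2) * sigma`,
#' where `sigma` is the standard deviation of the bead's fluorescence
#' profile. By default sigma is the background-subtracted intensity-weighted
#' standard deviation of position (moment method); a Gaussian least-squares
#' fit is available as a cross-check.
#'
#' @param profile Data frame from [profile_from_stack()] (columns
#'   `position`, `intensity`), or a numeric vector of intensities with unit
#'   spacing.
#' @param method `"moment"` (default) or `"gaussfit"`.
#' @param background `"tails"` (default; median of the outer 20% of samples
#'   on each side) or a numeric background level to subtract.
#' @return Object of class `psf_measurement`: list with `sigma`, `fwhm`
#'   (same units as `position`), `center`, `background`, `method`, and the
#'   `profile`.
#' @export
measure_fwhm <- function(profile, method = c("moment", "gaussfit"),
                         background = "tails") {
  method <- match.arg(method)
  if (!is.data.frame(profile))
    profile <- data.frame(position = seq_along(profile) - 1,
                          intensity = as.numeric(profile))
  x <- profile$position
  y <- profile$intensity
  if (length(unique(y)) < 2) stop("profile is constant; no peak to measure")
  n <- length(y)
  k <- max(1, floor(0.2 * n))
  tails <- c(y[seq_len(k)], y[(n - k + 1):n])
  if (identical(background, "tails")) {
    bg <- stats::median(tails)
  } else {
    bg <- as.numeric(background)
  }
  # noise floor of the profile, for tail suppression in the moment method
  noise_sd <- stats::mad(tails)
  w <- pmax(y - bg, 0)
  if (sum(w) <= 0) stop("profile has no intensity above background")
  if (method == "moment") {
    # suppress rectified noise in the tails: keep only samples above twice
    # the noise floor, then undo the resulting truncation of the Gaussian
    # analytically (variance of a normal truncated at +-u sigma)
    thr <- 2 * noise_sd
    if (thr > 0 && max(w) > 2 * thr) {
      # support = the contiguous run of above-threshold samples around the
      # peak, so isolated far-tail noise spikes cannot enter the moments
      above <- w >= thr
      pk <- which.max(w)
      lo <- pk; while (lo > 1 && above[lo - 1]) lo <- lo - 1
      hi <- pk; while (hi < length(w) && above[hi + 1]) hi <- hi + 1
      w[-(lo:hi)] <- 0
      w[w < thr] <- 0
    }
    mu <- sum(w * x) / sum(w)
    sigma <- sqrt(sum(w * (x - mu)^2) / sum(w))
    if (thr > 0 && max(w) > 2 * thr) {
      u <- sqrt(-2 * log(thr / max(w)))
      trunc_var <- 1 - 2 * u * stats::dnorm(u) / (2 * stats::pnorm(u) - 1)
      sigma <- sigma / sqrt(trunc_var)
    }
  } else {
    mu0 <- x[which.max(w)]
    sigma0 <- max(sqrt(sum(w * (x - mu0)^2) / sum(w)), 1e-6)
    ss <- function(p) sum((y - (p[1] + p[2] *
                                  exp(-(x - p[3])^2 / (2 * exp(2 * p[4])))))^2)
    fit <- stats::optim(c(bg, max(w), mu0, log(sigma0)), ss,
                        method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    mu <- fit$par[3]; sigma <- exp(fit$par[4]); bg <- fit$par[1]
  }
  if (sigma <= 0) stop("degenerate profile: sigma is zero")
  out <- list(sigma = sigma, fwhm = 2 * sqrt(2 * log(2)) * sigma,
              center = mu, background = bg, method = method,
              profile = profile)
  class(out) <- "psf_measurement"
  out
}

#' @export
print.psf_measurement <- function(x, ...) {
  cat(sprintf("PSF profile (%s): sigma = %.3g, FWHM = %.3g (centre %.3g)\n",
              x$method, x$sigma, x$fwhm, x$center))
  invisible(x)
}

#' Measure all beads of a stack along one axis
#'
#' Convenience wrapper: profiles and measures each bead of a synthetic (or
#' annotated) stack.
#'
#' @param beads A [generate_bead_stack()] result, or a list with `stack`,
#'   `voxel_size` and `truth` (data frame with `x`, `y`, `z` in um).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param window Crop window (see [profile_from_stack()]); default chosen
#'   from the voxel grid to span ~8 sigma when truth carries sigma values.
#' @param method Passed to [measure_fwhm()].
#' @return Data frame `(bead, axis, sigma, fwhm)`.
#' @export
measure_beads <- function(beads, axis = c("x", "y", "z"), window = NULL,
                          method = "moment") {
  axis <- match.arg(axis)
  vs <- beads$voxel_size
  res <- lapply(seq_len(nrow(beads$truth)), function(b) {
    tr <- beads$truth[b, ]
    ctr <- c(round(tr$x / vs[1] + 0.5), round(tr$y / vs[2] + 0.5),
             round(tr$z / vs[3] + 0.5))
    if (is.null(window)) {
      # +-6 sigma crop: the outer-20% background tails are then essentially
      # flat, keeping the moment-method bias well below 1%
      win <- c(2 * ceiling(6 * tr$sigma_xy / vs[1]) + 1,
               2 * ceiling(6 * tr$sigma_xy / vs[2]) + 1,
               2 * ceiling(6 * tr$sigma_z / vs[3]) + 1)
    } else win <- window
    prof <- profile_from_stack(beads$stack, axis, ctr, vs, window = win)
    m <- measure_fwhm(prof, method = method)
    data.frame(bead = b, axis = axis, sigma = m$sigma, fwhm = m$fwhm)
  })
  do.call(rbind, res)
}

#' Field-of-view extent from bead-translation records
#'
#' The FOV is measured by translating a bead with a calibrated stage and
#' recording its pixel position: a linear fit of stage travel against pixel
#' position, extrapolated over the full pixel range, gives the FOV extent
#' in micrometres.
#'
#' @param shift_record Data frame with columns `travel_um` (stage travel)
#'   and `pixel` (bead position in px); >= 2 distinct positions.
#' @param n_pixels Number of pixels along the axis.
#' @return FOV extent in um (um-per-px slope times `n_pixels`).
#' @examples
#' rec <- data.frame(travel_um = c(0, 78.1), pixel = c(100, 200))
#' measure_fov(rec, 1024)   # ~ 800 um
#' @export
measure_fov <- function(shift_record, n_pixels) {
  shift_record <- as.data.frame(shift_record)
  stopifnot(all(c("travel_um", "pixel") %in% names(shift_record)),
            n_pixels > 0)
  if (nrow(shift_record) < 2 ||
      length(unique(shift_record$pixel)) < 2)
    stop("need >= 2 distinct bead positions to measure the FOV")
  fit <- stats::lm(travel_um ~ pixel, data = shift_record)
  abs(stats::coef(fit)[["pixel"]]) * n_pixels
}
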