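#' Visual angle subtended by a looming dot
#'
#' Full visual angle of a disk of diameter `diameter` on a screen at
#' `screen_distance` from the eye: `2 * atan((diameter / 2) / distance)`,
#' in degrees. A 5 mm dot at 30 mm subtends 9.5 degrees; a 50 mm dot at
#' 30 mm subtends about 79.6 degrees.
#'
#' @param diameter Dot diameter, mm (vectorised; >= 0).
#' @param screen_distance Eye-to-screen distance, mm (> 0).
#' @return Full angle(s) in degrees.
#' @export
loom_angle <- function(diameter, screen_distance) {
  if (any(screen_distance <= 0)) stop("screen_distance must be positive")
  if (any(diameter < 0)) stop("diameter must be non-negative")
  2 * atan((diameter / 2) / screen_distance) * 180 / pi
}

#' Mean angular expansion rate of a looming stimulus
#'
#' The final visual angle divided by the expansion duration, in degrees/s.
#' For a dot growing from 0 to 5 mm in 2 s at 30 mm, the mean rate is about
#' 4.8 deg/s (commonly quoted to one digit as 4.7).
#'
#' @param final_diameter Final dot diameter, mm.
#' @param screen_distance Eye-to-screen distance, mm.
#' @param duration Expansion duration, s (> 0).
#' @return Mean expansion rate, degrees/s.
#' @export
loom_expansion_rate <- function(final_diameter, screen_distance, duration) {
  if (any(duration <= 0)) stop("duration must be positive")
  loom_angle(final_diameter, screen_distance) / duration
}

#' Looming-dot angular trajectory
#'
#' Angle over time for a dot expanding linearly in diameter from 0 to
#' `final_diameter` over `duration` seconds.
#'
#' @param t Time(s) since expansion onset, s (clamped to `[0, duration]`).
#' @param final_diameter Final dot diameter, mm.
#' @param screen_distance Eye-to-screen distance, mm.
#' @param duration Expansion duration, s.
#' @return Angle(s) in degrees.
#' @export
loom_angle_at <- function(t, final_diameter, screen_distance, duration) {
  tt <- pmin(pmax(t, 0), duration)
  loom_angle(final_diameter * tt / duration, screen_distance)
}

#' Stimulus presentation protocol
#'
#' A sorted set of non-overlapping stimulus epochs plus the looming-dot
#' geometry needed to derive visual angles.
#'
#' @param onsets Presentation onset times, s.
#' @param stim_duration Duration of each presentation, s (scalar or vector).
#' @param dot_diameter Final dot diameter, mm (default 50).
#' @param screen_distance Eye-to-screen distance, mm (default 30).
#' @param size_to_speed Size-to-speed ratio |l/v| of the looming stimulus, s
#'   (metadata; default `NA`).
#' @return Object of class `stimulus_protocol`: list with `presentations`
#'   (data frame `onset`, `offset`), `dot_diameter`, `screen_distance`,
#'   `size_to_speed`, `final_angle` (deg).
#' @examples
#' # whole-brain protocol: 10 looming dots every 150 s after a 5 min baseline
#' p <- looming_protocol()
#' nrow(p$presentations)
#' @export
stimulus_protocol <- function(onsets, stim_duration, dot_diameter = 50,
                              screen_distance = 30, size_to_speed = NA_real_) {
  stopifnot(length(onsets) == 0 || all(stim_duration > 0))
  onsets <- sort(as.numeric(onsets))
  offsets <- onsets + stim_duration
  if (length(onsets) > 1 && any(onsets[-1] < offsets[-length(offsets)]))
    stop("presentations overlap")
  out <- list(
    presentations = data.frame(onset = onsets, offset = offsets),
    dot_diameter = dot_diameter, screen_distance = screen_distance,
    size_to_speed = size_to_speed,
    final_angle = loom_angle(dot_diameter, screen_distance)
  )
  class(out) <- "stimulus_protocol"
  out
}

#' @export
print.stimulus_protocol <- function(x, ...) {
  cat(sprintf("Stimulus protocol: %d presentations, final angle %.1f deg\n",
              nrow(x$presentations), x$final_angle))
  invisible(x)
}

#' Standard whole-brain looming protocol
#'
#' Ten presentations of a looming dot (0 to 50 mm in 17 s at 30 mm from the
#' eye) at 150 s intervals, after a 300 s spontaneous-activity baseline.
#'
#' @param n_presentations Number of presentations (default 10).
#' @param interval Inter-presentation interval, s (default 150).
#' @param first_onset Onset of the first presentation, s (default 300).
#' @param stim_duration Expansion duration, s (default 17).
#' @param dot_diameter,screen_distance Looming geometry, mm (defaults 50, 30).
#' @return A [stimulus_protocol()].
#' @export
looming_protocol <- function(n_presentations = 10, interval = 150,
                             first_onset = 300, stim_duration = 17,
                             dot_diameter = 50, screen_distance = 30) {
  stimulus_protocol(
    onsets = first_onset + (seq_len(n_presentations) - 1) * interval,
    stim_duration = stim_duration,
    dot_diameter = dot_diameter, screen_distance = screen_distance,
    size_to_speed = 8.3)
}

#' Build stimulus regressors with calcium-reporter kinetics
#'
#' Each presentation epoch becomes a binary waveform (1 during the epoch, 0
#' elsewhere) sampled at `rate`; disjoint epochs give mutually orthogonal
#' waveforms. Each waveform is causally convolved with a normalised
#' exponentially decaying kernel `h[k] proportional to exp(-k / (tau * rate))`
#' modelling the reporter response, and an intercept column is appended. In
#' `"pooled"` mode all presentations are merged into one regressor gathering
#' all the stimulation; `"per_presentation"` keeps one regressor per epoch.
#'
#' @param protocol A [stimulus_protocol()].
#' @param duration Length of the sampled interval, s.
#' @param rate Sampling rate, Hz.
#' @param tau Reporter decay time constant, s (default 3.5).
#' @param mode `"pooled"` (default) or `"per_presentation"`.
#' @param kernel_norm `"sum"` (default; kernel sums to 1, so convolution
#'   preserves the waveform's area) or `"peak"` (kernel peak is 1).
#' @return Object of class `regressor_basis`: list with `design` (time x
#'   (n_regressors + 1) matrix, intercept last, column `"intercept"`),
#'   `binary` (pre-convolution waveforms), `kernel`, `rate`, `tau`, `mode`.
#' @export
build_regressors <- function(protocol, duration, rate, tau = 3.5,
                             mode = c("pooled", "per_presentation"),
                             kernel_norm = c("sum", "peak")) {
  stopifnot(inherits(protocol, "stimulus_protocol"), rate > 0, tau > 0)
  mode <- match.arg(mode)
  kernel_norm <- match.arg(kernel_norm)
  n_t <- round(duration * rate)
  pres <- protocol$presentations
  if (nrow(pres) > 0 && (min(pres$onset) < 0 || max(pres$offset) > duration))
    stop("presentations fall outside the sampled interval")
  kern <- exp(-(seq_len(max(2, ceiling(10 * tau * rate))) - 1) / (tau * rate))
  if (kernel_norm == "sum") kern <- kern / sum(kern)
  tgrid <- (seq_len(n_t) - 1) / rate
  make_wave <- function(rows) {
    w <- numeric(n_t)
    for (r in rows)
      w[tgrid >= pres$onset[r] & tgrid < pres$offset[r]] <- 1
    w
  }
  if (nrow(pres) == 0) {
    binary <- matrix(numeric(0), nrow = n_t, ncol = 0)
  } else if (mode == "pooled") {
    binary <- matrix(make_wave(seq_len(nrow(pres))), ncol = 1,
                     dimnames = list(NULL, "stim"))
  } else {
    binary <- vapply(seq_len(nrow(pres)), make_wave, numeric(n_t))
    colnames(binary) <- sprintf("stim_%02d", seq_len(nrow(pres)))
  }
  conv <- apply(binary, 2, .causal_conv, k = kern)
  if (length(conv) == 0) conv <- matrix(numeric(0), nrow = n_t, ncol = 0)
  design <- cbind(conv, intercept = 1)
  out <- list(design = design, binary = binary, kernel = kern,
              rate = rate, tau = tau, mode = mode, kernel_norm = kernel_norm)
  class(out) <- "regressor_basis"
  out
}

#' Fit traces against a regressor basis and score responsiveness
#'
#' Ordinary least squares per trace against the design matrix (stimulus
#' regressors plus intercept). The responsiveness score of a trace is its
#' stimulus coefficient divided by the mean squared residual of the fit
#' (`beta / MSE`): large when the trace follows the regressor strongly and
#' cleanly. With several stimulus regressors, per-regressor scores
#' `beta_j / MSE` are pooled by their maximum. A perfect noiseless fit
#' (MSE = 0) scores `+Inf` and is always selected.
#'
#' @param traces A [trace_matrix()] (traces x time).
#' @param basis A [build_regressors()] basis with matching time length.
#' @return Object of class `score_table`: data frame with one row per trace
#'   (`trace`, `beta` = pooled stimulus coefficient, `intercept`, `mse`,
#'   `score`), plus attribute `coefficients` (full coefficient matrix,
#'   traces x regressors).
#' @export
fit_traces <- function(traces, basis) {
  stopifnot(inherits(basis, "regressor_basis"))
  traces <- as.matrix(traces)
  X <- basis$design
  if (ncol(traces) != nrow(X))
    stop("traces and design matrix have different time lengths")
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("rank-deficient design matrix")
  Y <- t(traces)                       # time x traces
  coef <- qr.coef(qrX, Y)              # regressors x traces
  resid <- Y - X %*% coef
  mse <- colMeans(resid^2)
  # an exact (noiseless) fit leaves only rounding residue; report it as 0 so
  # the score becomes the documented +Inf sentinel
  mse[mse < 1e-20 * pmax(colMeans(Y^2), .Machine$double.xmin)] <- 0
  n_stim <- ncol(X) - 1
  if (n_stim >= 1) {
    b_stim <- coef[seq_len(n_stim), , drop = FALSE]
    ratio <- sweep(b_stim, 2, mse, "/")
    ratio[, mse == 0] <- ifelse(b_stim[, mse == 0, drop = FALSE] != 0, Inf, 0)
    score <- apply(ratio, 2, max)
    beta <- b_stim[cbind(apply(ratio, 2, which.max), seq_len(ncol(b_stim)))]
  } else {
    beta <- rep(NA_real_, nrow(traces))
    score <- rep(NA_real_, nrow(traces))
  }
  out <- data.frame(trace = seq_len(nrow(traces)), beta = beta,
                    intercept = coef[ncol(X), ], mse = mse, score = score,
                    row.names = NULL)
  attr(out, "coefficients") <- t(coef)
  class(out) <- c("score_table", class(out))
  out
}

#' Select the top-scoring fraction of traces as responsive
#'
#' Flags the `ceiling(fraction * N)` highest-scoring traces. Ties at the cut
#' are broken deterministically by trace index (lower index wins).
#'
#' @param scores A [fit_traces()] score table.
#' @param fraction Top quantile to select, in (0, 1); default 0.05.
#' @return The score table with a logical `responsive` column added;
#'   attribute `n_selected` records the count.
#' @examples
#' # top 5% of 1000 scores selects 50 traces
#' @export
select_responsive <- function(scores, fraction = 0.05) {
  stopifnot(fraction > 0, fraction < 1, nrow(scores) >= 1)
  n_sel <- ceiling(fraction * nrow(scores))
  ord <- order(-scores$score, scores$trace)
  scores$responsive <- FALSE
  scores$responsive[ord[seq_len(n_sel)]] <- TRUE
  attr(scores, "n_selected") <- n_sel
  scores
}

#' Detect fluorescence events exceeding a z-score threshold
#'
#' Each trace is z-scored against its baseline windows
#' (`z(t) = (F(t) - baseline mean) / baseline SD`) and local maxima with
#' `z > threshold` are reported as events.
#'
#' @param traces A [trace_matrix()].
#' @param baseline_windows Integer vector of sample indices defining the
#'   baseline (shared across traces), or a list of index vectors (one per
#'   trace).
#' @param threshold z-score threshold (default 5).
#' @return Object of class `event_table`: data frame `(trace, time, sample,
#'   z)` of detected events, sorted by trace then time; attribute
#'   `threshold`.
#' @export
zscore_events <- function(traces, baseline_windows, threshold = 5) {
  traces <- as.matrix(traces)
  rate <- attr(traces, "rate")
  if (is.null(rate)) rate <- 1
  if (!is.list(baseline_windows))
    baseline_windows <- rep(list(baseline_windows), nrow(traces))
  stopifnot(length(baseline_windows) == nrow(traces))
  res <- vector("list", nrow(traces))
  for (i in seq_len(nrow(traces))) {
    w <- baseline_windows[[i]]
    if (any(w < 1 | w > ncol(traces))) stop("baseline window outside trace")
    mu <- mean(traces[i, w])
    sdv <- stats::sd(traces[i, w])
    if (!is.finite(sdv) || sdv == 0) {
      # a fully constant trace trivially has no events; a flat baseline on a
      # varying trace makes the z-score undefined
      if (all(traces[i, ] == mu)) {
        res[[i]] <- data.frame(trace = integer(0), time = numeric(0),
                               sample = integer(0), z = numeric(0))
        next
      }
      stop("zero baseline SD in trace ", i)
    }
    z <- (traces[i, ] - mu) / sdv
    n <- length(z)
    is_peak <- z > threshold &
      z >= c(-Inf, z[-n]) & z > c(z[-1], -Inf)
    idx <- which(is_peak)
    res[[i]] <- data.frame(trace = rep(i, length(idx)),
                           time = (idx - 1) / rate, sample = idx,
                           z = z[idx])
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    out <- data.frame(trace = integer(0), time = numeric(0),
                      sample = integer(0), z = numeric(0))
  attr(out, "threshold") <- threshold
  class(out) <- c("event_table", class(out))
  out
}
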