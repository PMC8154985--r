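#' Acquisition geometry of a continuously ramping volume scan
#'
#' Describes the physical extent and sampling grid of a volume acquired with
#' a resonant scanner in XY and a continuously ramping remote focus in Z.
#' Because the focus ramps *during* each frame, every "plane" is a shallow
#' incline along the slow (Y) axis; see [row_z()].
#'
#' @param fov_x,fov_y Lateral field of view in micrometres. Defaults match a
#'   whole-brain larval zebrafish configuration (800 x 400 um).
#' @param z_range Axial extent of the scanned volume in micrometres.
#' @param n_x,n_y Frame size in pixels (fast x slow axis).
#' @param n_planes Number of frames per volume (one sawtooth cycle).
#' @param frame_rate Frame rate in Hz.
#'
#' @return An object of class `acquisition_geometry`: a list with the inputs
#'   plus the derived `volume_rate` (Hz), `pixel_pitch_x` and `pixel_pitch_y`
#'   (um/px).
#' @examples
#' geom <- acquisition_geometry()
#' geom$volume_rate        # 1 volume per second
#' @export
acquisition_geometry <- function(fov_x = 800, fov_y = 400, z_range = 180,
                                 n_x = 1024, n_y = 512, n_planes = 30,
                                 frame_rate = 30) {
  stopifnot(fov_x > 0, fov_y > 0, z_range > 0,
            n_x >= 1, n_y >= 1, n_planes >= 1, frame_rate > 0)
  g <- list(
    fov_x = fov_x, fov_y = fov_y, z_range = z_range,
    n_x = as.integer(n_x), n_y = as.integer(n_y),
    n_planes = as.integer(n_planes), frame_rate = frame_rate,
    volume_rate = frame_rate / n_planes,
    pixel_pitch_x = fov_x / n_x,
    pixel_pitch_y = fov_y / n_y
  )
  class(g) <- "acquisition_geometry"
  g
}

#' @export
print.acquisition_geometry <- function(x, ...) {
  cat(sprintf("Acquisition geometry: %g x %g x %g um, %d x %d px, %d planes\n",
              x$fov_x, x$fov_y, x$z_range, x$n_x, x$n_y, x$n_planes))
  cat(sprintf("  frame rate %g Hz -> %g volumes/s; pixel pitch %.3g x %.3g um\n",
              x$frame_rate, x$volume_rate, x$pixel_pitch_x, x$pixel_pitch_y))
  invisible(x)
}

#' Axial focus position of a scan row in a tilted-plane acquisition
#'
#' With the focus ramping linearly across the whole volume cycle, the row
#' acquired at fraction `row_index / n_y` through frame `frame_index` sits at
#' `z = z_range * (frame_index + row_index / n_y) / n_planes`. Consequently
#' the last row of a frame is deeper than its first row by
#' `z_range / n_planes * (n_y - 1) / n_y` (about 6 um for a 180 um volume in
#' 30 planes of 512 rows).
#'
#' @param geometry An [acquisition_geometry()].
#' @param frame_index Frame index within a volume cycle, 0-based, in
#'   `[0, n_planes)`. Vectorised.
#' @param row_index Row index within the frame (slow axis), 0-based, in
#'   `[0, n_y)`. Vectorised; recycled against `frame_index`.
#' @return Focus depth(s) in micrometres relative to the top of the volume.
#' @examples
#' geom <- acquisition_geometry()
#' row_z(geom, 0, 0)                       # 0
#' row_z(geom, 0, geom$n_y - 1) - row_z(geom, 0, 0)  # ~ 6 um tilt
#' @export
row_z <- function(geometry, frame_index, row_index) {
  stopifnot(inherits(geometry, "acquisition_geometry"))
  if (any(frame_index < 0 | frame_index >= geometry$n_planes))
    stop("frame_index out of range [0, n_planes)")
  if (any(row_index < 0 | row_index >= geometry$n_y))
    stop("row_index out of range [0, n_y)")
  geometry$z_range * (frame_index + row_index / geometry$n_y) / geometry$n_planes
}
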