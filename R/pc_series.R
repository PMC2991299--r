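#' Construct a phase-contrast series
#'
#' A `pc_series` pairs a modulus (magnitude) image stack with the decoded
#' velocity stack for one retrospectively ECG-gated cardiac cycle, together
#' with the timing and geometry metadata the downstream analysis needs.
#' Phase `i` (1-based in R) is acquired at time `(i - 1) * frame_interval`
#' milliseconds after the R-wave.
#'
#' @param modulus numeric array `P x H x W`, arbitrary intensity units.
#' @param velocity numeric array `P x H x W`, through-plane velocity in cm/s
#'   (signed). Must have the same dimensions as `modulus`.
#' @param frame_interval milliseconds per cardiac phase (> 0).
#' @param venc encoding velocity in cm/s; `abs(velocity)` may not exceed it.
#' @param pixel_spacing length-2 numeric, (row, col) pixel spacing in mm.
#' @param series_kind `"flow"` (blood velocities) or `"myocardial"` (tissue).
#' @param cycle_length optional cardiac cycle length in ms; must equal
#'   `P * frame_interval` when supplied, and defaults to it.
#'
#' @return An object of class `pc_series` with fields as above plus
#'   `n_phases`, and per-construction count of velocity samples at the
#'   encoding bound (`n_aliased`, possible aliasing; kept, never unwrapped).
#' @export
pc_series <- function(modulus, velocity, frame_interval, venc, pixel_spacing,
                      series_kind = c("flow", "myocardial"),
                      cycle_length = NULL) {
  series_kind <- match.arg(series_kind)
  if (!is.array(modulus) || length(dim(modulus)) != 3L)
    stop("`modulus` must be a 3-d array (phases x rows x cols)")
  if (!is.array(velocity) || !identical(dim(modulus), dim(velocity)))
    stop("`modulus` and `velocity` must be arrays of identical dimensions")
  P <- dim(velocity)[1]
  if (P < 8L) stop("a PC series needs at least 8 cardiac phases, got ", P)
  if (!is.numeric(frame_interval) || length(frame_interval) != 1L ||
      frame_interval <= 0)
    stop("`frame_interval` must be a single positive number (ms)")
  if (!is.numeric(venc) || length(venc) != 1L || venc <= 0)
    stop("`venc` must be a single positive number (cm/s)")
  if (length(pixel_spacing) == 1L) pixel_spacing <- rep(pixel_spacing, 2L)
  if (length(pixel_spacing) != 2L || any(pixel_spacing <= 0))
    stop("`pixel_spacing` must be one or two positive numbers (mm)")
  if (is.null(cycle_length)) cycle_length <- P * frame_interval
  if (abs(cycle_length - P * frame_interval) > 1e-6)
    stop("cycle_length (", cycle_length, ") must equal P x frame_interval (",
         P * frame_interval, ")")
  over <- abs(velocity) > venc + 1e-9
  if (any(over))
    stop("velocity exceeds venc (", venc, " cm/s) in ",
         sum(over), " pixels; first offending phase: ",
         which(apply(over, 1L, any))[1L])
  n_aliased <- sum(abs(abs(velocity) - venc) <= 1e-9)
  structure(
    list(modulus = modulus, velocity = velocity,
         frame_interval = frame_interval, venc = venc,
         pixel_spacing = as.numeric(pixel_spacing),
         cycle_length = cycle_length, series_kind = series_kind,
         n_phases = P, n_aliased = n_aliased),
    class = "pc_series")
}

#' @export
print.pc_series <- function(x, ...) {
  d <- dim(x$velocity)
  cat(sprintf("pc_series (%s): %d phases of %d x %d pixels\n",
              x$series_kind, d[1], d[2], d[3]))
  cat(sprintf("  frame interval %g ms (cycle %g ms), venc %g cm/s, pixel %g x %g mm\n",
              x$frame_interval, x$cycle_length, x$venc,
              x$pixel_spacing[1], x$pixel_spacing[2]))
  if (x$n_aliased > 0)
    cat(sprintf("  note: %d velocity samples at the encoding bound (possible aliasing)\n",
                x$n_aliased))
  invisible(x)
}

#' Phase acquisition times
#'
#' @param series a [pc_series()].
#' @return numeric vector of phase times in ms, starting at 0 (R-wave).
#' @export
phase_times <- function(series) {
  (seq_len(series$n_phases) - 1) * series$frame_interval
}

#' Decode raw phase values to velocities
#'
#' Phase-difference reconstructions store velocity as a signed integer
#' proportional to the phase shift; full scale maps to the encoding velocity
#' (venc). The decode is linear and sign-preserving:
#' `velocity = raw / raw_fullscale * venc`.
#'
#' @param raw numeric array or vector of raw phase values in
#'   `[-raw_fullscale, raw_fullscale]`.
#' @param venc encoding velocity, cm/s.
#' @param raw_fullscale positive scalar; the raw value that maps to `venc`.
#' @return velocities in cm/s, same shape as `raw`.
#' @export
decode_velocity <- function(raw, venc, raw_fullscale) {
  stopifnot(is.numeric(raw), length(venc) == 1L, venc > 0,
            length(raw_fullscale) == 1L, raw_fullscale > 0)
  bad <- abs(raw) > raw_fullscale
  if (any(bad)) {
    if (is.array(raw) && length(dim(raw)) == 3L) {
      ph <- which(apply(bad, 1L, any))[1L]
      stop("raw phase values outside [-", raw_fullscale, ", ", raw_fullscale,
           "] at phase ", ph)
    }
    stop("raw phase values outside [-", raw_fullscale, ", ", raw_fullscale, "]")
  }
  raw / raw_fullscale * venc
}
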