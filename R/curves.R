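#' Sampled time curve
#'
#' A piecewise-linear curve sampled once per cardiac phase: velocity (cm/s)
#' or flow rate (ml/s) against time (ms). Linear interpolation between
#' samples is the curve's interpolation convention throughout.
#'
#' @param times strictly increasing sample times, ms.
#' @param values curve values, same length as `times`.
#' @param unit unit tag, e.g. `"cm/s"` or `"ml/s"`.
#' @return object of class `time_curve`.
#' @export
time_curve <- function(times, values, unit = "cm/s") {
  stopifnot(length(times) == length(values), all(diff(times) > 0))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 unit = unit),
            class = "time_curve")
}

#' @export
print.time_curve <- function(x, ...) {
  cat(sprintf("time_curve: %d samples over [%g, %g] ms, range [%g, %g] %s\n",
              length(x$times), min(x$times), max(x$times),
              min(x$values), max(x$values), x$unit))
  invisible(x)
}

#' @export
plot.time_curve <- function(x, ...) {
  plot(x$times, x$values, type = "l", xlab = "time (ms)", ylab = x$unit, ...)
  invisible(x)
}

# linear interpolation at time t (vectorized)
.curve_at <- function(curve, t) {
  stats::approx(curve$times, curve$values, xout = t, rule = 2)$y
}

#' Velocity and flow-rate curves from a segmented flow
#'
#' Per cardiac phase, with `w = flow_sign * velocity` restricted to the mask
#' (so the flow of interest is positive):
#' \itemize{
#'   \item `v_max`: average of the pixel velocities greater than 95\% of the
#'     maximal velocity within the segmented region (noise-robust maximum;
#'     0 when the mask is empty);
#'   \item `v_mean`: mean of `w` over the mask;
#'   \item `q`: flow rate, `v_mean` times the segmented area
#'     (`ml/s = cm/s x cm^2`).
#' }
#'
#' @param series a flow [pc_series()].
#' @param seg a `mask_series` from [segment_flow()].
#' @return object of class `flow_curves`: list of three [time_curve()]s
#'   (`v_max`, `v_mean`, `q`) sharing the phase time axis, plus `areas_cm2`.
#' @export
flow_curves <- function(series, seg) {
  stopifnot(inherits(series, "pc_series"), inherits(seg, "mask_series"))
  if (!identical(dim(series$velocity), dim(seg$masks)))
    stop("mask series does not match the PC series dimensions")
  P <- series$n_phases
  px_cm2 <- prod(series$pixel_spacing / 10)
  vmax <- vmean <- q <- numeric(P)
  areas <- numeric(P)
  for (p in seq_len(P)) {
    m <- seg$masks[p, , ]
    if (!any(m)) next
    w <- seg$flow_sign * series$velocity[p, , ][m]
    top <- w[w >= 0.95 * max(w)]
    vmax[p] <- mean(top)
    vmean[p] <- mean(w)
    areas[p] <- sum(m) * px_cm2
    q[p] <- vmean[p] * areas[p]
  }
  tt <- phase_times(series)
  structure(list(v_max = time_curve(tt, vmax, "cm/s"),
                 v_mean = time_curve(tt, vmean, "cm/s"),
                 q = time_curve(tt, q, "ml/s"),
                 areas_cm2 = areas,
                 flow_sign = seg$flow_sign),
            class = "flow_curves")
}

# indices of strict local maxima; a plateau counts once, at its first sample
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  out <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (v[i] > v[i - 1L]) {
      j <- i
      while (j < n && v[j + 1L] == v[j]) j <- j + 1L
      if (j < n && v[j + 1L] < v[j]) out <- c(out, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  out
}

#' Zero-crossing time of a wave limb by 40-70\% linear extrapolation
#'
#' Landmark times (onset and end of a filling wave, end of ejection) are
#' estimated by fitting a least-squares line to the part of the limb whose
#' values lie between 40\% and 70\% of the wave's peak — the most linear part
#' of a velocity or flow-rate limb — and intersecting it with the time axis.
#' The fit uses every sample in the band, augmented by the two exact
#' piecewise-linear crossings of the 40\% and 70\% levels, so that a perfectly
#' triangular limb yields its vertex time exactly.
#'
#' @param curve a [time_curve()].
#' @param peak_index index (1-based) of the wave's peak sample; peak value
#'   must be positive.
#' @param side `"ascending"` (limb before the peak) or `"descending"` (after).
#' @param window optional `c(t0, t1)` ms restricting the analysis.
#' @return the fitted line's zero-crossing time, ms.
#' @export
limb_zero_crossing <- function(curve, peak_index,
                               side = c("ascending", "descending"),
                               window = NULL) {
  side <- match.arg(side)
  stopifnot(inherits(curve, "time_curve"))
  tt <- curve$times; vv <- curve$values
  peak <- vv[peak_index]
  if (!is.finite(peak) || peak <= 0) stop("peak value must be positive")
  lo <- 0.40 * peak; hi <- 0.70 * peak
  dir <- if (side == "ascending") -1L else 1L
  n <- length(vv)
  inw <- function(i) {
    i >= 1L && i <= n && (is.null(window) || (tt[i] >= window[1] && tt[i] <= window[2]))
  }
  # walk away from the peak to the first sample at/below the 40% level
  i <- peak_index
  i40 <- NA_integer_; i70 <- NA_integer_
  while (inw(i + dir)) {
    i <- i + dir
    if (is.na(i70) && vv[i] <= hi) i70 <- i
    if (vv[i] <= lo) { i40 <- i; break }
  }
  if (is.na(i70))
    stop("limb truncated: never descends below 70% of peak")
  crossing <- function(level, j) {
    # exact piecewise-linear crossing on the segment [j-dir, j]
    a <- j - dir
    tt[a] + (level - vv[a]) * (tt[j] - tt[a]) / (vv[j] - vv[a])
  }
  pts_t <- crossing(hi, i70)
  pts_v <- hi
  last <- if (is.na(i40)) i else i40
  band <- seq.int(peak_index + dir, last, by = dir)
  band <- band[vv[band] >= lo & vv[band] <= hi]
  pts_t <- c(pts_t, tt[band]); pts_v <- c(pts_v, vv[band])
  if (!is.na(i40)) { pts_t <- c(pts_t, crossing(lo, i40)); pts_v <- c(pts_v, lo) }
  if (length(pts_t) < 2L)
    stop("limb truncated: not enough samples in the 40-70% band")
  fit <- stats::lm.fit(cbind(1, pts_t), pts_v)
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] == 0) stop("degenerate limb: zero slope")
  unname(-b[1] / b[2])
}

#' End of the ejection phase from the aortic flow-rate curve
#'
#' The aortic flow-rate curve is used only for timing: the end of ejection is
#' the time-axis crossing of the descending limb of its dominant systolic
#' peak (40-70\% extrapolation, [limb_zero_crossing()]).
#'
#' @param aortic_q aortic flow-rate [time_curve()] with the flow of interest
#'   positive.
#' @return end-of-ejection time, ms.
#' @export
end_of_ejection <- function(aortic_q) {
  stopifnot(inherits(aortic_q, "time_curve"))
  half <- aortic_q$times <= max(aortic_q$times) / 2
  if (!any(aortic_q$values[half] > 0))
    stop("no systolic peak on the aortic flow-rate curve")
  peak_index <- which(half)[which.max(aortic_q$values[half])]
  limb_zero_crossing(aortic_q, peak_index, "descending")
}

#' Detect the two highest local peaks in a window
#'
#' Finds the pair of local maxima, separated in time by at least `min_sep`,
#' with the greatest summed amplitude, and orders it by time. On transmitral
#' curves the first peak is the early filling (E-type) wave and the second the
#' atrial (A-type) wave — by time of occurrence, regardless of magnitude. The
#' separation constraint (default one sixth of the cardiac cycle) rejects
#' artifactual bumps next to a true peak.
#'
#' @param curve a [time_curve()].
#' @param window `c(t0, t1)` ms; only local maxima inside it are considered.
#' @param min_sep minimal time separation between the two peaks, ms.
#' @return list with `first = c(t, v)`, `second = c(t, v)` (or `NULL` when
#'   fewer than two admissible maxima exist — then `single = TRUE` and `first`
#'   is the highest peak, or `NULL` when there is none).
#' @export
detect_two_peaks <- function(curve, window, min_sep) {
  stopifnot(inherits(curve, "time_curve"))
  tt <- curve$times; vv <- curve$values
  pk <- .local_maxima(vv)
  pk <- pk[tt[pk] >= window[1] & tt[pk] <= window[2]]
  if (length(pk) == 0L)
    return(list(first = NULL, second = NULL, single = FALSE, none = TRUE))
  if (length(pk) >= 2L) {
    best <- NULL; best_sum <- -Inf
    for (a in seq_len(length(pk) - 1L)) for (b in seq.int(a + 1L, length(pk))) {
      i <- pk[a]; j <- pk[b]
      if (tt[j] - tt[i] < min_sep) next
      s <- vv[i] + vv[j]
      if (s > best_sum) { best_sum <- s; best <- c(i, j) }
    }
    if (!is.null(best))
      return(list(first = c(t = tt[best[1]], v = vv[best[1]]),
                  second = c(t = tt[best[2]], v = vv[best[2]]),
                  single = FALSE, none = FALSE))
  }
  i <- pk[which.max(vv[pk])]
  list(first = c(t = tt[i], v = vv[i]), second = NULL,
       single = TRUE, none = FALSE)
}

# trapezoidal integral of max(curve, 0) between t0 and t1 (ms) -> value * s
.integral_clipped <- function(curve, t0, t1) {
  tt <- curve$times; vv <- pmax(curve$values, 0)
  ts <- sort(unique(c(t0, t1, tt[tt > t0 & tt < t1])))
  ys <- stats::approx(tt, vv, xout = ts, rule = 2)$y
  sum(diff(ts) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2) / 1000
}

#' Extract diastolic flow parameters from transmitral and aortic curves
#'
#' Assembles the full blood-flow diastolic parameter set:
#' \itemize{
#'   \item end of ejection from the aortic flow-rate curve
#'     ([end_of_ejection()]); the diastolic search window is from there to the
#'     end of the cycle;
#'   \item `E`, `A` (cm/s): the two highest local peaks of the transmitral
#'     maximal-velocity curve in the diastolic window (first in time = E);
#'   \item `Ef`, `Af` (ml/s): same detection on the flow-rate curve;
#'   \item filling period: onset = ascending-limb zero crossing of the Ef
#'     wave, end = descending-limb zero crossing of the Af wave (40-70\%
#'     extrapolation);
#'   \item `FV` (ml): area under the (non-negative part of the) flow-rate
#'     curve over the filling period;
#'   \item `DT` (ms): time from the Ef peak to the extrapolated end of the Ef
#'     wave;
#'   \item `IVRT` (ms): filling onset minus end of ejection (0 with a warning
#'     when the onset precedes the ejection end);
#'   \item ratios `E/A`, `Ef/Af` and `Ef/FV` (1/s).
#' }
#' Temporal landmarks are taken from flow-rate waves, which average over the
#' segmented area and are less noise-sensitive than maximal-velocity waves.
#'
#' @param mitral a `flow_curves` object for the transmitral flow.
#' @param aortic_q aortic flow-rate [time_curve()] (flow of interest positive).
#' @param cycle_length cardiac cycle length, ms.
#' @param min_sep minimal E-A peak separation, ms; default one sixth of the
#'   cycle.
#' @return object of class `flow_params`: the parameter list plus a `timings`
#'   sub-list (`t_eject_end`, `t_fill_start`, `t_fill_end`) and `single_peak`
#'   flag. A-dependent fields are `NA` in the single-peak case.
#' @export
compute_flow_parameters <- function(mitral, aortic_q, cycle_length,
                                    min_sep = cycle_length / 6) {
  stopifnot(inherits(mitral, "flow_curves"), inherits(aortic_q, "time_curve"))
  t_ee <- end_of_ejection(aortic_q)
  win <- c(t_ee, cycle_length)
  vmax <- mitral$v_max; q <- mitral$q
  pv <- detect_two_peaks(vmax, win, min_sep)
  pq <- detect_two_peaks(q, win, min_sep)
  if (isTRUE(pv$none) || isTRUE(pq$none))
    stop("no diastolic peak found on the transmitral curves")
  single <- pv$single || pq$single
  if (single) warning("only one admissible diastolic peak; A-dependent parameters undefined")

  idx_at <- function(curve, t) which.min(abs(curve$times - t))
  # Ef wave limbs
  i_Ef <- idx_at(q, pq$first["t"])
  t_fill_start <- limb_zero_crossing(q, i_Ef, "ascending",
                                     window = c(t_ee, cycle_length))
  t_Ef_end <- limb_zero_crossing(q, i_Ef, "descending")
  DT <- t_Ef_end - pq$first[["t"]]
  if (!single) {
    i_Af <- idx_at(q, pq$second["t"])
    t_fill_end <- limb_zero_crossing(q, i_Af, "descending")
  } else {
    t_fill_end <- t_Ef_end
  }
  IVRT <- t_fill_start - t_ee
  if (IVRT < 0) {
    warning("filling onset precedes end of ejection; IVRT reported as 0")
    IVRT <- 0
  }
  FV <- .integral_clipped(q, t_fill_start, min(t_fill_end, cycle_length))

  E <- pv$first[["v"]]; t_E <- pv$first[["t"]]
  Ef <- pq$first[["v"]]; t_Ef <- pq$first[["t"]]
  A <- if (!single) pv$second[["v"]] else NA_real_
  t_A <- if (!single) pv$second[["t"]] else NA_real_
  Af <- if (!single) pq$second[["v"]] else NA_real_
  t_Af <- if (!single) pq$second[["t"]] else NA_real_

  structure(
    list(E = E, A = A, EA_ratio = E / A,
         Ef = Ef, Af = Af, EfAf_ratio = Ef / Af,
         FV = FV, Ef_over_FV = Ef / FV,
         DT = DT, IVRT = IVRT,
         t_E = t_E, t_A = t_A, t_Ef = t_Ef, t_Af = t_Af,
         timings = list(t_eject_end = t_ee, t_fill_start = t_fill_start,
                        t_fill_end = t_fill_end),
         single_peak = single),
    class = "flow_params")
}

#' @export
print.flow_params <- function(x, ...) {
  cat("Transmitral diastolic parameters:\n")
  cat(sprintf("  E = %.1f cm/s (t=%g ms)   A = %.1f cm/s (t=%g ms)   E/A = %.2f\n",
              x$E, x$t_E, x$A, x$t_A, x$EA_ratio))
  cat(sprintf("  Ef = %.1f ml/s  Af = %.1f ml/s  Ef/Af = %.2f\n",
              x$Ef, x$Af, x$EfAf_ratio))
  cat(sprintf("  FV = %.1f ml   Ef/FV = %.2f 1/s\n", x$FV, x$Ef_over_FV))
  cat(sprintf("  DT = %.0f ms   IVRT = %.0f ms\n", x$DT, x$IVRT))
  cat(sprintf("  timings: ejection end %.0f ms, filling %.0f-%.0f ms\n",
              x$timings$t_eject_end, x$timings$t_fill_start,
              x$timings$t_fill_end))
  invisible(x)
}
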