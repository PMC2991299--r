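#' Default phase for drawing the rough ROI
#'
#' The rough ROI is drawn on a single phase: the middle of the cardiac cycle
#' for transmitral flow (the valve is open in diastole) and the beginning of
#' the cycle for aortic flow (ejection starts right after the R-wave).
#'
#' @param series a flow [pc_series()].
#' @param flow_kind `"mitral"` or `"aortic"`.
#' @return 0-based phase index: `floor(P/2)` for mitral, `0` for aortic.
#' @export
default_init_phase <- function(series, flow_kind = c("mitral", "aortic")) {
  flow_kind <- match.arg(flow_kind)
  stopifnot(inherits(series, "pc_series"))
  if (flow_kind == "mitral") series$n_phases %/% 2L else 0L
}

#' Reference phase and flow sign inside a rough ROI
#'
#' Computes the mean-velocity curve within the ROI over the whole cycle and
#' returns the phase at which its absolute value is highest, together with
#' the velocity sign at that phase. This phase initializes the segmentation.
#' Ties go to the earliest phase.
#'
#' @param series a flow [pc_series()].
#' @param x a [roi()] (or a precomputed logical `H x W` mask).
#' @return list with `phase` (0-based index), `sign` (+1/-1) and
#'   `mean_curve` (the per-phase ROI mean velocities, cm/s).
#' @export
reference_phase <- function(series, x) {
  stopifnot(inherits(series, "pc_series"))
  m <- if (inherits(x, "roi")) roi_mask(x, dim(series$velocity)[2:3]) else x
  P <- series$n_phases
  means <- vapply(seq_len(P), function(p) mean(series$velocity[p, , ][m]),
                  numeric(1))
  if (all(means == 0)) stop("no flow detected in ROI")
  p <- which.max(abs(means))  # first maximum on ties
  s <- sign(means[p])
  if (s == 0) stop("ambiguous flow sign at reference phase (mean velocity 0)")
  list(phase = p - 1L, sign = s, mean_curve = means)
}

# 3x3 box mean with edge renormalization
.box3 <- function(m) {
  H <- nrow(m); W <- ncol(m)
  pad <- matrix(0, H + 2, W + 2); pad[2:(H + 1), 2:(W + 1)] <- m
  cnt <- matrix(0, H + 2, W + 2); cnt[2:(H + 1), 2:(W + 1)] <- 1
  s <- matrix(0, H, W); n <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + pad[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    n <- n + cnt[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  s / n
}

# robust per-phase noise floor: scaled MAD of the velocity image about zero
# (flow occupies a small fraction of the field, so the MAD reflects noise)
.noise_sigma <- function(v) 1.4826 * stats::mad(v, center = 0)

#' Segment a through-plane flow pattern across the cardiac cycle
#'
#' Semi-automated delineation of a transmitral or aortic flow pattern on a
#' velocity series, starting from a rough ROI drawn on one phase:
#' \enumerate{
#'   \item the reference phase and flow sign are found from the ROI
#'     mean-velocity curve ([reference_phase()]);
#'   \item on the reference phase, the biggest connected area of that sign
#'     within the (dilated) ROI is detected;
#'   \item its centre of mass is propagated phase-by-phase toward both ends of
#'     the cycle, each step keeping the biggest same-sign component containing
#'     the propagated point.
#' }
#' The centre-of-mass propagation constrains the tracking to the flow of
#' interest. When the propagated point lands outside every candidate
#' component (e.g. the valve has closed), the largest component with a pixel
#' within `point_tol` pixels of the point is accepted; failing that, the
#' phase's mask is empty and the previous centroid is carried forward.
#'
#' The sign of a pixel whose velocity is below the noise floor carries no
#' information, and zero-mean noise makes same-sign pixels percolate under
#' 8-connectivity, so the raw sign field cannot be used directly on noisy
#' data. Components are therefore detected with a hysteresis noise floor:
#' the per-phase noise level \eqn{\hat\sigma} is estimated robustly (scaled
#' MAD of the velocity image about zero), the velocity field is smoothed with
#' a 3x3 box, core components are pixels above `z_hi` and the final mask is
#' the surrounding component above `z_lo` noise standard deviations (of the
#' smoothed field) that contains the selected core. On noise-free data
#' \eqn{\hat\sigma = 0} and the procedure reduces exactly to plain
#' sign-connectivity.
#'
#' @param series a flow [pc_series()].
#' @param x a [roi()].
#' @param flow_kind `"mitral"` or `"aortic"` (recorded; also the default ROI
#'   phase convention).
#' @param roi_dilate pixels of dilation applied to the rough ROI to form the
#'   per-phase search region (tolerates jet motion without leaking to the
#'   other valve).
#' @param min_area components below this pixel count are treated as empty
#'   (noise specks; 4 pixels is below the smallest physiologic orifice at
#'   1.9 mm spacing).
#' @param point_tol acceptance distance (pixels, Euclidean) between the
#'   propagated centre of mass and the nearest pixel of a candidate component.
#' @param z_hi,z_lo hysteresis noise-floor multipliers (in noise standard
#'   deviations of the smoothed field); both 0 on noise-free data.
#' @return object of class `mask_series`: list with `masks` (P x H x W logical
#'   array), `centroids` (P x 2, 0-based (row, col), `NA` for empty phases),
#'   `areas` (pixel counts), `seed_phase` (0-based), `flow_sign`, `flow_kind`.
#' @export
segment_flow <- function(series, x, flow_kind = c("mitral", "aortic"),
                         roi_dilate = 3L, min_area = 4L, point_tol = 2,
                         z_hi = 2, z_lo = 1) {
  flow_kind <- match.arg(flow_kind)
  stopifnot(inherits(series, "pc_series"))
  if (series$series_kind != "flow")
    stop("segment_flow expects a flow series")
  dims <- dim(series$velocity)
  rmask <- roi_mask(x, dims[2:3])
  search <- dilate_mask(rmask, roi_dilate)
  ref <- reference_phase(series, rmask)
  P <- series$n_phases
  masks <- array(FALSE, dims)
  centroids <- matrix(NA_real_, P, 2)

  # per-phase hysteresis component labeling: core labels above the high
  # noise floor, expanded to the enclosing low-floor component
  phase_labels <- function(p) {
    v <- ref$sign * series$velocity[p, , ]
    s0 <- .noise_sigma(series$velocity[p, , ])
    if (s0 > 0) { f <- .box3(v); sn <- s0 / 3 } else { f <- v; sn <- 0 }
    hi <- label_components(search & (f > z_hi * sn))
    tab <- tabulate(hi)
    keep <- which(tab >= min_area)
    hi[!(hi %in% keep)] <- 0L
    lo <- if (z_lo < z_hi && sn > 0)
      label_components(search & (f > z_lo * sn)) else hi
    list(hi = hi, lo = lo, sizes = tab)
  }
  expand <- function(pl, l) {
    lo_l <- unique(pl$lo[pl$hi == l])
    lo_l <- lo_l[lo_l > 0]
    pl$lo == lo_l[1]
  }

  p0 <- ref$phase + 1L
  pl0 <- phase_labels(p0)
  l0 <- .largest_label(pl0$hi)
  if (l0 == 0L) stop("initialization failed: no signed component in ROI")
  masks[p0, , ] <- expand(pl0, l0)
  centroids[p0, ] <- .mask_centroid(masks[p0, , ])

  step <- function(p, prev_centroid) {
    pl <- phase_labels(p)
    lab <- pl$hi
    keep <- setdiff(unique(as.integer(lab)), 0L)
    if (length(keep) == 0L) return(NULL)
    rp <- round(prev_centroid)
    l <- 0L
    if (rp[1] >= 0 && rp[1] < dims[2] && rp[2] >= 0 && rp[2] < dims[3])
      l <- lab[rp[1] + 1L, rp[2] + 1L]
    if (l == 0L) {
      # the point fell outside every core (e.g. valve closed): accept the
      # largest core with a pixel within point_tol of the propagated point
      cand <- integer(0); sizes <- integer(0)
      for (lb in keep) {
        idx <- which(lab == lb)
        r0 <- ((idx - 1L) %% dims[2])
        c0 <- ((idx - 1L) %/% dims[2])
        d <- sqrt((r0 - prev_centroid[1])^2 + (c0 - prev_centroid[2])^2)
        if (min(d) <= point_tol) {
          cand <- c(cand, lb); sizes <- c(sizes, sum(lab == lb))
        }
      }
      if (length(cand) == 0L) return(NULL)
      best <- cand[sizes == max(sizes)]
      if (length(best) > 1L) {
        cent <- t(vapply(best, function(lb) .mask_centroid(lab == lb),
                         numeric(2)))
        best <- best[order(cent[, 1], cent[, 2])]
      }
      l <- best[1L]
    }
    expand(pl, l)
  }

  for (dir in c(1L, -1L)) {
    prev <- centroids[p0, ]
    p <- p0 + dir
    while (p >= 1L && p <= P) {
      m <- step(p, prev)
      if (!is.null(m)) {
        masks[p, , ] <- m
        centroids[p, ] <- .mask_centroid(m)
        prev <- centroids[p, ]
      }
      p <- p + dir
    }
  }
  structure(
    list(masks = masks,
         centroids = centroids,
         areas = apply(masks, 1L, sum),
         seed_phase = ref$phase,
         flow_sign = ref$sign,
         flow_kind = flow_kind),
    class = "mask_series")
}

#' @export
print.mask_series <- function(x, ...) {
  P <- dim(x$masks)[1]
  act <- sum(x$areas > 0)
  cat(sprintf("mask_series (%s, sign %+d): %d phases, %d with flow; areas %d-%d px\n",
              x$flow_kind, x$flow_sign, P, act,
              if (act) min(x$areas[x$areas > 0]) else 0L, max(x$areas)))
  invisible(x)
}
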