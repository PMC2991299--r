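#' Per-pixel velocity time-profiles inside an ROI
#'
#' The myocardium cannot be tracked by sign-connectivity because the annulus
#' reverses direction within the cycle; instead, each fixed pixel's
#' full-cycle velocity time-series is used as a feature vector for
#' clustering.
#'
#' @param series a myocardial [pc_series()].
#' @param x a [roi()] (or logical `H x W` mask).
#' @return list with `profiles` (N pixels x P phases matrix) and `pixels`
#'   (N x 2 matrix of 0-based (row, col) coordinates, row order matching
#'   `profiles`).
#' @export
pixel_velocity_profiles <- function(series, x) {
  stopifnot(inherits(series, "pc_series"))
  dims <- dim(series$velocity)
  m <- if (inherits(x, "roi")) roi_mask(x, dims[2:3]) else x
  idx <- which(m)
  if (length(idx) == 0L) stop("empty ROI")
  H <- dims[2]
  pix <- cbind(row = (idx - 1L) %% H, col = (idx - 1L) %/% H)
  P <- series$n_phases
  prof <- matrix(NA_real_, length(idx), P)
  for (p in seq_len(P)) prof[, p] <- series$velocity[p, , ][idx]
  list(profiles = prof, pixels = pix)
}

#' Cluster pixel velocity time-profiles with k-means
#'
#' k-means (squared-Euclidean distance on the raw, unnormalized profile
#' vectors) partitions the ROI pixels into `k` classes; with `k = 7` this
#' separates pixels that stay within the myocardium for the whole cycle from
#' the LV cavity, the background, and pixels whose longitudinal profile is
#' distorted by radial contraction. Seeded with `restarts` random
#' initializations; the run with the lowest within-cluster sum of squares
#' wins, deterministically for a given seed. The default of 50 restarts is
#' needed in practice: with few restarts k-means can settle in a local
#' optimum that splits the myocardium across two labels, fragmenting the
#' connected component the next stage relies on.
#'
#' @param profiles N x P profile matrix (from [pixel_velocity_profiles()]).
#' @param pixels N x 2 matrix of 0-based (row, col) pixel coordinates.
#' @param dim_hw image dimensions `c(H, W)`.
#' @param k number of clusters (default 7).
#' @param seed RNG seed for the initialization.
#' @param restarts number of random restarts.
#' @return object of class `cluster_result`: `label_map` (`H x W` integer,
#'   0..k-1 inside the ROI, -1 outside), `k`, `seed`, `inertia` (total
#'   within-cluster sum of squares).
#' @export
cluster_profiles <- function(profiles, pixels, dim_hw, k = 7L, seed = 1L,
                             restarts = 50L) {
  stopifnot(is.matrix(profiles), nrow(profiles) == nrow(pixels))
  n_distinct <- nrow(unique(profiles))
  lab_map <- matrix(-1L, dim_hw[1], dim_hw[2])
  lin <- pixels[, 2] * dim_hw[1] + pixels[, 1] + 1L
  if (n_distinct == 1L) {
    warning("all profiles identical; single effective cluster")
    lab_map[lin] <- 0L
    return(structure(list(label_map = lab_map, k = k, seed = seed,
                          inertia = 0),
                     class = "cluster_result"))
  }
  if (nrow(profiles) < k)
    stop("ROI has fewer pixels (", nrow(profiles), ") than clusters (", k, ")")
  keff <- min(k, n_distinct)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  km <- stats::kmeans(profiles, centers = keff, nstart = restarts,
                      iter.max = 100L)
  lab_map[lin] <- km$cluster - 1L
  structure(list(label_map = lab_map, k = k, seed = seed,
                 inertia = km$tot.withinss),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  n <- sum(x$label_map >= 0)
  cat(sprintf("cluster_result: k=%d over %d ROI pixels, inertia %.3g\n",
              x$k, n, x$inertia))
  invisible(x)
}

#' Isolate the myocardial cluster
#'
#' For each cluster label, its largest 8-connected spatial component is
#' found; the myocardial mask is the largest such component over all labels
#' (the biggest connected cluster). Ties break to the smallest (row, col)
#' lexicographic centroid.
#'
#' @param label_map `H x W` integer label map (-1 outside the ROI), e.g. the
#'   `label_map` of a `cluster_result`.
#' @return logical `H x W` myocardial mask (one connected component).
#' @export
myocardial_cluster <- function(label_map) {
  if (inherits(label_map, "cluster_result")) label_map <- label_map$label_map
  stopifnot(is.matrix(label_map))
  labels <- setdiff(unique(as.integer(label_map)), -1L)
  best_mask <- NULL; best_size <- -1L; best_cent <- c(Inf, Inf)
  for (l in sort(labels)) {
    lab <- label_components(label_map == l)
    if (max(lab) == 0L) next
    cl <- .largest_label(lab)
    m <- lab == cl
    sz <- sum(m)
    if (sz > best_size) {
      best_mask <- m; best_size <- sz; best_cent <- .mask_centroid(m)
    } else if (sz == best_size) {
      ce <- .mask_centroid(m)
      if (ce[1] < best_cent[1] ||
          (ce[1] == best_cent[1] && ce[2] < best_cent[2])) {
        best_mask <- m; best_cent <- ce
      }
    }
  }
  if (is.null(best_mask)) stop("no cluster found")
  best_mask
}

# within-mask 3x3 box mean: each mask pixel averaged with its in-mask
# neighbours (myocardium is thin; out-of-mask neighbours are excluded)
.masked_box3 <- function(img, mask) {
  H <- nrow(img); W <- ncol(img)
  vp <- matrix(0, H + 2, W + 2); vp[2:(H + 1), 2:(W + 1)] <- img * mask
  mp <- matrix(0, H + 2, W + 2); mp[2:(H + 1), 2:(W + 1)] <- mask
  s <- matrix(0, H, W); n <- matrix(0, H, W)
  for (dr in -1:1) for (dc in -1:1) {
    s <- s + vp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
    n <- n + mp[(2 + dr):(H + 1 + dr), (2 + dc):(W + 1 + dc)]
  }
  out <- img
  out[mask] <- s[mask] / n[mask]
  out
}

# signed noise-robust maximum of a velocity sample set: the 95% averaging
# rule applied to the dominant-direction velocities, sign retained
.signed_vmax <- function(v) {
  if (length(v) == 0L) return(0)
  s <- sign(v[which.max(abs(v))])
  if (s == 0) return(0)
  w <- s * v
  s * mean(w[w >= 0.95 * max(w)])
}

#' Myocardial velocity curves, global and per segment
#'
#' Builds the maximal and mean longitudinal velocity curves of the whole
#' myocardial cluster, and of four standardized segments (lateral, septal,
#' inferior, anterior) defined as angular quadrants about the cavity centre.
#' The "maximal" value per phase reuses the 95\% noise-averaging rule,
#' applied to the velocity direction of larger magnitude with the sign
#' retained. Because the myocardial velocity field is nearly uniform across
#' the thin wall, the rule would otherwise average the upper tail of the
#' pixel noise; by default each pixel is first averaged with its in-mask
#' 3x3 neighbours (`presmooth = TRUE`), which suppresses that tail bias
#' while leaving a spatially uniform field unchanged in expectation. Set
#' `presmooth = FALSE` for raw pixel values (e.g. with strong transmural
#' velocity gradients).
#'
#' @param series a myocardial [pc_series()].
#' @param myocardial_mask logical `H x W` mask.
#' @param cavity_centre 0-based (row, col) of the LV cavity centre; the mask
#'   centroid when `NULL`.
#' @param reference_angle_deg rotation of the quadrant boundaries
#'   (counter-clockwise from the image column axis); quadrant boundaries sit
#'   at 45, 135, 225, 315 degrees from it.
#' @param segment_labels names of the four quadrants, counter-clockwise from
#'   the reference angle.
#' @return list with `global` (max-velocity [time_curve()]), `global_mean`,
#'   and `segments` (named list of max-velocity curves, `NULL` for empty
#'   segments).
#' @export
myo_velocity_curves <- function(series, myocardial_mask, cavity_centre = NULL,
                                reference_angle_deg = 0,
                                segment_labels = c("lateral", "anterior",
                                                   "septal", "inferior"),
                                presmooth = TRUE) {
  stopifnot(inherits(series, "pc_series"), any(myocardial_mask))
  if (is.null(cavity_centre)) cavity_centre <- .mask_centroid(myocardial_mask)
  idx <- which(myocardial_mask)
  H <- nrow(myocardial_mask)
  r0 <- (idx - 1L) %% H
  c0 <- (idx - 1L) %/% H
  # angle counter-clockwise from the +col axis (display convention: row grows
  # downward, so -row is "up")
  ang <- (atan2(-(r0 - cavity_centre[1]), c0 - cavity_centre[2]) * 180 / pi -
            reference_angle_deg + 45) %% 360
  seg_id <- findInterval(ang, c(0, 90, 180, 270, 360),
                         rightmost.closed = TRUE)
  P <- series$n_phases
  tt <- phase_times(series)
  vmax <- vmean <- numeric(P)
  segv <- matrix(0, P, 4)
  for (p in seq_len(P)) {
    vimg <- series$velocity[p, , ]
    vraw <- vimg[idx]
    v <- if (presmooth) .masked_box3(vimg, myocardial_mask)[idx] else vraw
    vmax[p] <- .signed_vmax(v)
    vmean[p] <- mean(vraw)
    for (s in 1:4) segv[p, s] <- .signed_vmax(v[seg_id == s])
  }
  segs <- stats::setNames(vector("list", 4), segment_labels)
  for (s in 1:4) {
    if (any(seg_id == s)) segs[[s]] <- time_curve(tt, segv[, s], "cm/s")
    else warning("segment '", segment_labels[s], "' has no pixels")
  }
  list(global = time_curve(tt, vmax, "cm/s"),
       global_mean = time_curve(tt, vmean, "cm/s"),
       segments = segs,
       segment_id = seg_id)
}

#' Early diastolic longitudinal velocity E'
#'
#' On the myocardial maximal-velocity curve, E' is the highest local peak
#' occurring first during the filling period: the curve is rectified toward
#' the diastolic motion direction, the admissible peak pair (separation at
#' least `min_sep`, greatest summed amplitude) is found as for transmitral
#' E/A, and E' is the earlier member's magnitude. A single admissible peak
#' is E' on its own.
#'
#' @param myo_curve myocardial maximal-velocity [time_curve()] (signed).
#' @param filling_window `c(t0, t1)` ms. When `NULL`, it is derived from
#'   `mean_curve`: from the last zero-crossing of the global mean-velocity
#'   curve preceding its largest diastolic-direction excursion, to cycle end.
#' @param min_sep minimal peak separation, ms (default: a sixth of the span
#'   of the curve's time axis plus one frame).
#' @param mean_curve global mean-velocity [time_curve()]; used to determine
#'   the diastolic direction (sign of the mean velocity within the filling
#'   window) and, if needed, the filling window itself. Defaults to
#'   `myo_curve`.
#' @return list with `E_prime` (cm/s, magnitude), `t_E_prime` (ms),
#'   `direction` (+1/-1), and the window used; `E_prime = NA` with a warning
#'   when no local maximum lies in the window.
#' @export
detect_e_prime <- function(myo_curve, filling_window = NULL, min_sep = NULL,
                           mean_curve = myo_curve) {
  stopifnot(inherits(myo_curve, "time_curve"))
  tt <- myo_curve$times
  dt <- if (length(tt) > 1) tt[2] - tt[1] else 0
  cyc <- max(tt) + dt
  if (is.null(min_sep)) min_sep <- cyc / 6
  mv <- mean_curve$values
  if (is.null(filling_window)) {
    # diastole: after the dominant early-diastolic excursion's last preceding
    # zero-crossing of the mean curve (the annulus reverses direction there)
    half2 <- which(tt >= cyc / 2)
    i_exc <- half2[which.max(abs(mv[half2]))]
    zc <- which(diff(sign(mv[seq_len(i_exc)])) != 0)
    t0 <- if (length(zc)) tt[zc[length(zc)] + 1L] else cyc / 2
    filling_window <- c(t0, max(tt))
  }
  inw <- tt >= filling_window[1] & tt <= filling_window[2]
  dir_sign <- sign(mean(mv[inw]))
  if (dir_sign == 0) dir_sign <- sign(mv[inw][which.max(abs(mv[inw]))])
  rect <- time_curve(tt, dir_sign * myo_curve$values, myo_curve$unit)
  pk <- detect_two_peaks(rect, filling_window, min_sep)
  if (isTRUE(pk$none)) {
    warning("no local maximum in the filling window; E' undefined")
    return(list(E_prime = NA_real_, t_E_prime = NA_real_,
                direction = dir_sign, window = filling_window))
  }
  list(E_prime = unname(pk$first["v"]), t_E_prime = unname(pk$first["t"]),
       direction = dir_sign, window = filling_window)
}

#' Full myocardial analysis of a tissue-velocity series
#'
#' Convenience pipeline: profile extraction, k-means clustering, myocardial
#' cluster isolation, velocity curves, and E' detection; assembles E/E' when
#' a transmitral E velocity is supplied.
#'
#' @param series a myocardial [pc_series()].
#' @param x a [roi()] drawn around the LV.
#' @param k,seed,restarts clustering controls ([cluster_profiles()]).
#' @param filling_window optional `c(t0, t1)` ms from the flow analysis.
#' @param E_velocity optional transmitral E (cm/s) for the E/E' ratio.
#' @param reference_angle_deg,segment_labels see [myo_velocity_curves()].
#' @return object of class `myo_params`: `E_prime`, `t_E_prime`,
#'   `E_over_Eprime`, the `myocardial_mask`, `cluster` result and `curves`.
#' @export
analyze_myocardium <- function(series, x, k = 7L, seed = 1L, restarts = 50L,
                               filling_window = NULL, E_velocity = NULL,
                               reference_angle_deg = 0,
                               segment_labels = c("lateral", "anterior",
                                                  "septal", "inferior")) {
  pr <- pixel_velocity_profiles(series, x)
  if (nrow(pr$profiles) < k)
    stop("ROI has fewer pixels (", nrow(pr$profiles), ") than clusters (", k, ")")
  dims <- dim(series$velocity)[2:3]
  cl <- cluster_profiles(pr$profiles, pr$pixels, dims, k = k, seed = seed,
                         restarts = restarts)
  mask <- myocardial_cluster(cl$label_map)
  cv <- myo_velocity_curves(series, mask,
                            reference_angle_deg = reference_angle_deg,
                            segment_labels = segment_labels)
  ep <- detect_e_prime(cv$global, filling_window = filling_window,
                       mean_curve = cv$global_mean)
  ratio <- if (!is.null(E_velocity) && is.finite(ep$E_prime))
    E_velocity / ep$E_prime else NA_real_
  structure(list(E_prime = ep$E_prime, t_E_prime = ep$t_E_prime,
                 E_over_Eprime = ratio, direction = ep$direction,
                 filling_window = ep$window,
                 myocardial_mask = mask, cluster = cl, curves = cv),
            class = "myo_params")
}

#' @export
print.myo_params <- function(x, ...) {
  cat(sprintf("Myocardial longitudinal velocities: E' = %.1f cm/s (t=%g ms)\n",
              x$E_prime, x$t_E_prime))
  if (is.finite(x$E_over_Eprime))
    cat(sprintf("  E/E' = %.2f\n", x$E_over_Eprime))
  cat(sprintf("  myocardial cluster: %d pixels\n", sum(x$myocardial_mask)))
  invisible(x)
}
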