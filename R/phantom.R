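#' Phantom configuration
#'
#' Builds the configuration of the synthetic PC-CMR generator. Defaults
#' emulate a typical breath-hold acquisition at 1.5 T in a healthy adult:
#' 15 ms effective temporal resolution and venc 180 cm/s for transmitral
#' flow, 20 ms and venc 20 cm/s for myocardial longitudinal motion, 1.9 mm
#' pixels, a 900 ms cardiac cycle, a biphasic E/A transmitral waveform with
#' a parabolic spatial jet profile, an opposite-sign aortic jet, and a
#' myocardial ring with S'/E'/A' longitudinal motion. Waveform node times
#' are snapped to the frame grid by default so that the triangular-limb
#' landmarks are exactly recoverable; truth values report the snapped
#' waveform actually generated.
#'
#' @param kind `"flow"` or `"myo"`.
#' @param ... overrides of any default listed below.
#' @return a `phantom_config` list.
#' @export
phantom_config <- function(kind = c("flow", "myo"), ...) {
  kind <- match.arg(kind)
  cfg <- if (kind == "flow") list(
    kind = "flow",
    grid = c(128L, 128L),
    n_phases = 60L,
    frame_interval = 15,
    pixel_spacing = 1.9,
    venc = 180,
    # transmitral jet
    mitral_centre = c(80, 64),      # 0-based (row, col) pixels
    mitral_radius_mm = 12,
    E_true = 80, A_true = 60,       # centre velocities, cm/s
    DT_true = 185, IVRT_true = 78,  # ms
    rise_E = 90,                    # ms, E-wave upstroke
    t_A = 810, rise_A = 45, fall_A = 60,
    # aortic jet (opposite sign, timing only)
    aortic_centre = c(40, 64),
    aortic_radius_mm = 10,
    aortic_peak = 100,              # cm/s, magnitude
    eject_start = 30, eject_peak_t = 210, eject_end = 420,
    noise_sd = 2,                   # cm/s
    background_offset = 0,          # cm/s
    snap_to_grid = TRUE,
    waveform_shape = "triangular"   # or "raised_cosine"
  ) else list(
    kind = "myo",
    grid = c(64L, 64L),
    n_phases = 45L,
    frame_interval = 20,
    pixel_spacing = 1.9,
    venc = 20,
    ring_centre = c(32, 32),
    ring_inner_mm = 17, ring_outer_mm = 27,
    # longitudinal annular waveform (cm/s; diastolic direction negative)
    S_prime = 8.5, E_prime_true = 11.3, A_prime = 6,
    t_S = 200, S_support = c(40, 420),
    t_Eprime = 560, Eprime_support = c(500, 660),
    t_Aprime = 800, Aprime_support = c(740, 860),
    cavity_amplitude = 15,          # blood pool, cm/s at cavity centre
    background_gradient = 1.2,      # cm/s across the field (static offset)
    noise_sd = 0.5,
    background_offset = 0,
    snap_to_grid = TRUE,
    waveform_shape = "triangular"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  cfg$cycle_length <- cfg$n_phases * cfg$frame_interval
  structure(cfg, class = "phantom_config")
}

# snap a time (ms) to the phase grid
.snap <- function(t, cfg) {
  if (isTRUE(cfg$snap_to_grid)) round(t / cfg$frame_interval) * cfg$frame_interval
  else t
}

# unit triangular pulse: 0 at t0, 1 at tp, 0 at t1, 0 outside (vectorized)
.tri <- function(t, t0, tp, t1) {
  up <- t > t0 & t <= tp
  dn <- t > tp & t < t1
  out <- numeric(length(t))
  out[up] <- (t[up] - t0) / (tp - t0)
  out[dn] <- (t1 - t[dn]) / (t1 - tp)
  out
}

# raised-cosine pulse on the same support
.rcos <- function(t, t0, tp, t1) {
  out <- numeric(length(t))
  up <- t > t0 & t <= tp
  dn <- t > tp & t < t1
  out[up] <- (1 - cos(pi * (t[up] - t0) / (tp - t0))) / 2
  out[dn] <- (1 + cos(pi * (t[dn] - tp) / (t1 - tp))) / 2
  out
}

.pulse <- function(t, t0, tp, t1, shape) {
  if (shape == "raised_cosine") .rcos(t, t0, tp, t1) else .tri(t, t0, tp, t1)
}

# snapped transmitral waveform node times
.flow_nodes <- function(cfg) {
  t_fs <- .snap(cfg$eject_end + cfg$IVRT_true, cfg)
  t_E <- .snap(t_fs + cfg$rise_E, cfg)
  t_Ee <- .snap(t_E + cfg$DT_true, cfg)
  t_A0 <- .snap(cfg$t_A - cfg$rise_A, cfg)
  t_A <- .snap(cfg$t_A, cfg)
  t_A1 <- .snap(cfg$t_A + cfg$fall_A, cfg)
  if (t_Ee > t_A0) stop("waves overlap: E wave ends after the A wave starts")
  if (t_A1 > cfg$cycle_length) stop("A wave extends past the cycle end")
  list(t_fill_start = t_fs, t_E = t_E, t_E_end = t_Ee,
       t_A_start = t_A0, t_A = t_A, t_A_end = t_A1,
       eject_end = .snap(cfg$eject_end, cfg))
}

#' Transmitral centre-velocity waveform
#'
#' The biphasic filling waveform at the centre of the mitral jet: an E wave
#' rising linearly from the filling onset (ejection end + IVRT) to `E_true`
#' and decaying to zero over the deceleration time, followed by a triangular
#' A wave peaking at `t_A`. Zero elsewhere. Supports may touch but not
#' overlap.
#'
#' @param t time(s), ms (vectorized).
#' @param cfg a flow [phantom_config()].
#' @return centre velocity, cm/s.
#' @export
transmitral_waveform <- function(t, cfg) {
  stopifnot(inherits(cfg, "phantom_config"), cfg$kind == "flow")
  nd <- .flow_nodes(cfg)
  cfg$E_true * .pulse(t, nd$t_fill_start, nd$t_E, nd$t_E_end, cfg$waveform_shape) +
    cfg$A_true * .pulse(t, nd$t_A_start, nd$t_A, nd$t_A_end, cfg$waveform_shape)
}

# parabolic spatial profile of a circular jet: H x W matrix in [0, 1]
.jet_profile <- function(grid, centre, radius_mm, spacing) {
  H <- grid[1]; W <- grid[2]
  r0 <- matrix(rep(0:(H - 1), W), H, W)
  c0 <- matrix(rep(0:(W - 1), each = H), H, W)
  d2 <- ((r0 - centre[1]) * spacing)^2 + ((c0 - centre[2]) * spacing)^2
  p <- 1 - d2 / radius_mm^2
  p[p < 0] <- 0
  p
}

#' Generate a transmitral/aortic flow phantom
#'
#' Synthesizes a flow PC series with exactly known ground truth: a mitral
#' orifice whose pixels carry a parabolic spatial profile scaled by the
#' biphasic E/A waveform ([transmitral_waveform()]), an aortic orifice of
#' opposite sign active during systole, additive Gaussian velocity noise,
#' and an optional constant background offset. Modulus images are a flat
#' background with jet brightening. Truth masks are the pixels with
#' noise-free nonzero velocity at each phase.
#'
#' @param cfg a flow [phantom_config()].
#' @param seed RNG seed for the noise.
#' @return list with `series` (a [pc_series()]) and `truth`: per-phase
#'   `mitral_masks` / `aortic_masks` (P x H x W logical), node times, true
#'   parameters (`E`, `A`, `EA_ratio`, `Ef`, `Af`, `EfAf_ratio`, `FV`,
#'   `Ef_over_FV`, `DT`, `IVRT` of the generated, grid-snapped waveform) and
#'   the `seed`.
#' @export
make_flow_phantom <- function(cfg = phantom_config("flow"), seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"), cfg$kind == "flow")
  if (max(cfg$E_true, cfg$A_true, cfg$aortic_peak) + cfg$background_offset >=
      cfg$venc)
    stop("waveform magnitudes must stay below venc (would alias)")
  nd <- .flow_nodes(cfg)
  P <- cfg$n_phases; H <- cfg$grid[1]; W <- cfg$grid[2]
  tt <- (seq_len(P) - 1) * cfg$frame_interval
  mit_prof <- .jet_profile(cfg$grid, cfg$mitral_centre, cfg$mitral_radius_mm,
                           cfg$pixel_spacing)
  aor_prof <- .jet_profile(cfg$grid, cfg$aortic_centre, cfg$aortic_radius_mm,
                           cfg$pixel_spacing)
  if (any(mit_prof > 0 & aor_prof > 0))
    stop("mitral and aortic orifices overlap")
  w_mit <- transmitral_waveform(tt, cfg)
  w_aor <- -cfg$aortic_peak * .pulse(tt, .snap(cfg$eject_start, cfg),
                                     .snap(cfg$eject_peak_t, cfg),
                                     nd$eject_end, cfg$waveform_shape)
  vel <- array(0, c(P, H, W))
  modulus <- array(100, c(P, H, W))
  mit_masks <- aor_masks <- array(FALSE, c(P, H, W))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (p in seq_len(P)) {
    clean <- w_mit[p] * mit_prof + w_aor[p] * aor_prof
    mit_masks[p, , ] <- w_mit[p] != 0 & mit_prof > 0
    aor_masks[p, , ] <- w_aor[p] != 0 & aor_prof > 0
    v <- clean + cfg$background_offset
    if (cfg$noise_sd > 0) v <- v + stats::rnorm(H * W, 0, cfg$noise_sd)
    vel[p, , ] <- pmin(pmax(v, -cfg$venc), cfg$venc)
    modulus[p, , ] <- 100 + 100 * (abs(clean) > 0)
  }
  px_cm2 <- (cfg$pixel_spacing / 10)^2
  S <- sum(mit_prof[mit_prof > 0]) * px_cm2   # cm^2-weighted profile sum
  area_cm2 <- sum(mit_prof > 0) * px_cm2
  fv_int <- (0.5 * cfg$E_true * (nd$t_E_end - nd$t_fill_start) +
               0.5 * cfg$A_true * (nd$t_A_end - nd$t_A_start)) / 1000
  truth <- list(
    E = cfg$E_true, A = cfg$A_true, EA_ratio = cfg$E_true / cfg$A_true,
    Ef = cfg$E_true * S, Af = cfg$A_true * S,
    EfAf_ratio = cfg$E_true / cfg$A_true,
    FV = S * fv_int, Ef_over_FV = cfg$E_true / fv_int,
    DT = nd$t_E_end - nd$t_E, IVRT = nd$t_fill_start - nd$eject_end,
    t_E = nd$t_E, t_A = nd$t_A,
    t_fill_start = nd$t_fill_start, t_fill_end = nd$t_A_end,
    eject_end = nd$eject_end,
    orifice_area_cm2 = area_cm2, profile_sum_cm2 = S,
    mitral_masks = mit_masks, aortic_masks = aor_masks,
    seed = seed)
  if (cfg$waveform_shape != "triangular")
    truth[c("FV", "Ef_over_FV")] <- list(NA_real_, NA_real_)
  series <- pc_series(modulus, vel, cfg$frame_interval, cfg$venc,
                      cfg$pixel_spacing, "flow")
  list(series = series, truth = truth, config = cfg)
}

#' Generate a myocardial tissue-velocity phantom
#'
#' Synthesizes a myocardial PC series: a ring of pixels (the LV wall) that
#' uniformly carries the S'/E'/A' longitudinal waveform (systolic direction
#' positive, diastolic negative), an LV cavity whose blood pool carries a
#' large-amplitude biphasic profile with a parabolic radial taper (a
#' continuum of distinct time-profiles, as blood presents to the clustering
#' step), a static background offset gradient, and Gaussian noise.
#'
#' @param cfg a myo [phantom_config()].
#' @param seed RNG seed.
#' @return list with `series`, `truth` (the `ring_mask`, true waveform values
#'   per phase, `E_prime`, `t_E_prime`, `filling_window`, `seed`) and `config`.
#' @export
make_myo_phantom <- function(cfg = phantom_config("myo"), seed = 1L) {
  stopifnot(inherits(cfg, "phantom_config"), cfg$kind == "myo")
  if (cfg$ring_inner_mm >= cfg$ring_outer_mm)
    stop("ring radii inverted: inner must be smaller than outer")
  if (max(cfg$S_prime, cfg$E_prime_true, cfg$A_prime, cfg$cavity_amplitude) >=
      cfg$venc)
    stop("waveform magnitudes must stay below venc (would alias)")
  P <- cfg$n_phases; H <- cfg$grid[1]; W <- cfg$grid[2]
  tt <- (seq_len(P) - 1) * cfg$frame_interval
  r0 <- matrix(rep(0:(H - 1), W), H, W)
  c0 <- matrix(rep(0:(W - 1), each = H), H, W)
  d_mm <- sqrt(((r0 - cfg$ring_centre[1]))^2 +
                 ((c0 - cfg$ring_centre[2]))^2) * cfg$pixel_spacing
  ring <- d_mm >= cfg$ring_inner_mm & d_mm <= cfg$ring_outer_mm
  cavity <- d_mm < cfg$ring_inner_mm
  sn <- function(x) .snap(x, cfg)
  w_ring <- cfg$S_prime * .pulse(tt, sn(cfg$S_support[1]), sn(cfg$t_S),
                                 sn(cfg$S_support[2]), cfg$waveform_shape) -
    cfg$E_prime_true * .pulse(tt, sn(cfg$Eprime_support[1]), sn(cfg$t_Eprime),
                              sn(cfg$Eprime_support[2]), cfg$waveform_shape) -
    cfg$A_prime * .pulse(tt, sn(cfg$Aprime_support[1]), sn(cfg$t_Aprime),
                         sn(cfg$Aprime_support[2]), cfg$waveform_shape)
  # blood pool: biphasic diastolic inflow, opposite direction to E'/A' tissue
  w_cav <- .pulse(tt, sn(cfg$Eprime_support[1]), sn(cfg$t_Eprime),
                  sn(cfg$Eprime_support[2]), cfg$waveform_shape) +
    0.6 * .pulse(tt, sn(cfg$Aprime_support[1]), sn(cfg$t_Aprime),
                 sn(cfg$Aprime_support[2]), cfg$waveform_shape) -
    0.8 * .pulse(tt, sn(cfg$S_support[1]), sn(cfg$t_S),
                 sn(cfg$S_support[2]), cfg$waveform_shape)
  cav_amp <- cfg$cavity_amplitude *
    pmax(1 - (d_mm / cfg$ring_inner_mm)^2, 0) * cavity
  bg_field <- cfg$background_offset +
    cfg$background_gradient * ((c0 - cfg$ring_centre[2]) / W) * (!ring & !cavity)
  vel <- array(0, c(P, H, W))
  modulus <- array(100, c(P, H, W))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (p in seq_len(P)) {
    clean <- w_ring[p] * ring + w_cav[p] * cav_amp + bg_field
    v <- clean
    if (cfg$noise_sd > 0) v <- v + stats::rnorm(H * W, 0, cfg$noise_sd)
    vel[p, , ] <- pmin(pmax(v, -cfg$venc), cfg$venc)
    modulus[p, , ] <- 100 + 60 * ring + 30 * cavity
  }
  truth <- list(ring_mask = ring,
                waveform = w_ring,
                E_prime = cfg$E_prime_true,
                t_E_prime = sn(cfg$t_Eprime),
                S_prime = cfg$S_prime, A_prime = cfg$A_prime,
                filling_window = c(sn(cfg$Eprime_support[1]),
                                   cfg$cycle_length),
                seed = seed)
  series <- pc_series(modulus, vel, cfg$frame_interval, cfg$venc,
                      cfg$pixel_spacing, "myocardial")
  list(series = series, truth = truth, config = cfg)
}

#' Jitter an ROI to emulate a second operator
#'
#' The analysis requires only a rough manual initialization; to study its
#' reproducibility, ROI vertices are jittered uniformly within
#' `+/- max_shift_px` pixels (seeded), emulating operator-to-operator
#' differences in the drawn ROI.
#'
#' @param x a [roi()].
#' @param max_shift_px maximal per-coordinate shift in pixels.
#' @param seed RNG seed.
#' @return a jittered [roi()].
#' @export
perturb_roi <- function(x, max_shift_px, seed = 1L) {
  stopifnot(inherits(x, "roi"), max_shift_px >= 0)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  if (x$shape == "polygon") {
    n <- nrow(x$coords)
    jit <- matrix(stats::runif(2 * n, -max_shift_px, max_shift_px), n, 2)
    roi(x$phase_index, x$coords + jit, "polygon")
  } else {
    co <- x$coords
    co$centre <- co$centre + stats::runif(2, -max_shift_px, max_shift_px)
    roi(x$phase_index, co, "ellipse")
  }
}
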