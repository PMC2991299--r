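#' Write / read a PC series container
#'
#' Portable on-disk form of a [pc_series()]: `modulus.nii.gz` and
#' `velocity.nii.gz` (NIfTI, `H x W x P`, float64) plus a `series.json`
#' sidecar with `{venc_cm_s, frame_interval_ms, pixel_spacing_mm,
#' series_kind, n_phases, cycle_length_ms}`. The round-trip is exact at
#' stored precision.
#'
#' @param series a [pc_series()].
#' @param dir directory to write into (created if needed).
#' @param overwrite refuse to clobber an existing container unless `TRUE`.
#' @return `write_pc_series` returns `dir` invisibly; `read_pc_series`
#'   returns the [pc_series()].
#' @export
write_pc_series <- function(series, dir, overwrite = FALSE) {
  stopifnot(inherits(series, "pc_series"))
  if (dir.exists(dir) && file.exists(file.path(dir, "series.json")) &&
      !overwrite)
    stop("container already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # store H x W x P (NIfTI convention: phase along the 3rd axis)
  RNifti::writeNifti(aperm(series$modulus, c(2, 3, 1)),
                     file.path(dir, "modulus.nii.gz"))
  RNifti::writeNifti(aperm(series$velocity, c(2, 3, 1)),
                     file.path(dir, "velocity.nii.gz"))
  jsonlite::write_json(
    list(venc_cm_s = series$venc,
         frame_interval_ms = series$frame_interval,
         pixel_spacing_mm = series$pixel_spacing,
         series_kind = series$series_kind,
         n_phases = series$n_phases,
         cycle_length_ms = series$cycle_length),
    file.path(dir, "series.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_pc_series
#' @export
read_pc_series <- function(dir) {
  sj <- file.path(dir, "series.json")
  if (!file.exists(sj)) stop("no series.json in ", dir)
  meta <- jsonlite::read_json(sj, simplifyVector = TRUE)
  if (is.null(meta$venc_cm_s)) stop("venc missing from series.json; refusing to guess")
  mod <- as.array(RNifti::readNifti(file.path(dir, "modulus.nii.gz")))
  vel <- as.array(RNifti::readNifti(file.path(dir, "velocity.nii.gz")))
  if (!identical(dim(mod), dim(vel)))
    stop("modulus and velocity stacks have different shapes")
  P <- dim(vel)[3]
  if (!is.null(meta$n_phases) && meta$n_phases != P)
    stop("phase count mismatch: sidecar says ", meta$n_phases, ", stack has ", P)
  s <- pc_series(aperm(mod, c(3, 1, 2)), aperm(vel, c(3, 1, 2)),
                 meta$frame_interval_ms, meta$venc_cm_s,
                 meta$pixel_spacing_mm, meta$series_kind,
                 cycle_length = meta$cycle_length_ms)
  s
}

#' Write / read a mask series container
#'
#' `masks.nii.gz` (`H x W x P`, 0/1) plus `masks.json` sidecar (phase count,
#' seed phase, flow sign/kind, provenance).
#'
#' @param seg a `mask_series` ([segment_flow()]).
#' @param dir output directory.
#' @param overwrite refuse to clobber unless `TRUE`.
#' @param extra named list merged into the sidecar (e.g. seed, provenance).
#' @export
write_mask_series <- function(seg, dir, overwrite = FALSE, extra = list()) {
  stopifnot(inherits(seg, "mask_series"))
  if (dir.exists(dir) && file.exists(file.path(dir, "masks.json")) &&
      !overwrite)
    stop("mask container already exists at ", dir, " (use overwrite = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(aperm(seg$masks * 1, c(2, 3, 1)),
                     file.path(dir, "masks.nii.gz"))
  meta <- c(list(n_phases = dim(seg$masks)[1],
                 seed_phase = seg$seed_phase,
                 flow_sign = seg$flow_sign,
                 flow_kind = seg$flow_kind,
                 areas = seg$areas,
                 software = paste0("pcmr ", as.character(utils::packageVersion("pcmr")))),
            extra)
  jsonlite::write_json(meta, file.path(dir, "masks.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_mask_series
#' @export
read_mask_series <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "masks.json"),
                              simplifyVector = TRUE)
  m <- as.array(RNifti::readNifti(file.path(dir, "masks.nii.gz"))) > 0.5
  masks <- aperm(m, c(3, 1, 2))
  P <- dim(masks)[1]
  centroids <- matrix(NA_real_, P, 2)
  for (p in seq_len(P)) {
    ce <- .mask_centroid(masks[p, , ])
    if (!is.null(ce)) centroids[p, ] <- ce
  }
  structure(list(masks = masks, centroids = centroids,
                 areas = apply(masks, 1L, sum),
                 seed_phase = meta$seed_phase, flow_sign = meta$flow_sign,
                 flow_kind = meta$flow_kind),
            class = "mask_series")
}

#' Write analysis results
#'
#' Writes parameters as JSON and a one-row CSV (columns suffixed with their
#' unit, e.g. `E_MR_cm_per_s`), curves as CSV (`time_ms` plus one value
#' column per curve), and optionally mask containers. Partial writes are
#' cleaned up on error; existing files are refused unless `overwrite`.
#'
#' @param params a `flow_params`, `myo_params`, or plain named list of
#'   numbers (may be `NULL`).
#' @param curves named list of [time_curve()]s sharing a time axis (may be
#'   empty: the curves file is then omitted).
#' @param masks optional `mask_series`.
#' @param out_dir output directory.
#' @param overwrite logical.
#' @return invisibly, the paths written.
#' @export
write_results <- function(params, curves = list(), masks = NULL, out_dir,
                          overwrite = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  ok <- FALSE
  on.exit(if (!ok) unlink(written, recursive = TRUE))
  emit <- function(path) {
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite ", path)
    written <<- c(written, path)
    path
  }
  paths <- list()
  if (!is.null(params)) {
    flat <- .flatten_params(params)
    pj <- emit(file.path(out_dir, "parameters.json"))
    jsonlite::write_json(flat, pj, auto_unbox = TRUE, digits = NA)
    pc <- emit(file.path(out_dir, "parameters.csv"))
    utils::write.csv(as.data.frame(flat), pc, row.names = FALSE)
    paths$parameters <- c(pj, pc)
  }
  if (length(curves)) {
    tt <- curves[[1]]$times
    df <- data.frame(time_ms = tt)
    for (nm in names(curves)) df[[nm]] <- curves[[nm]]$values
    cc <- emit(file.path(out_dir, "curves.csv"))
    utils::write.csv(df, cc, row.names = FALSE)
    paths$curves <- cc
  } else message("no curves supplied; curves file omitted")
  if (!is.null(masks)) {
    md <- file.path(out_dir, "masks")
    write_mask_series(masks, md, overwrite = overwrite)
    paths$masks <- md
  }
  ok <- TRUE
  invisible(paths)
}

# flatten a parameter object into a named list of scalars with unit suffixes
.flatten_params <- function(params) {
  if (inherits(params, "flow_params")) {
    with(params, list(
      E_MR_cm_per_s = E, A_MR_cm_per_s = A, E_over_A = EA_ratio,
      Ef_MR_ml_per_s = Ef, Af_MR_ml_per_s = Af, Ef_over_Af = EfAf_ratio,
      FV_MR_ml = FV, Ef_over_FV_per_s = Ef_over_FV,
      DT_MR_ms = DT, IVRT_MR_ms = IVRT,
      t_E_ms = t_E, t_A_ms = t_A, t_Ef_ms = t_Ef, t_Af_ms = t_Af,
      t_eject_end_ms = timings$t_eject_end,
      t_fill_start_ms = timings$t_fill_start,
      t_fill_end_ms = timings$t_fill_end))
  } else if (inherits(params, "myo_params")) {
    list(E_prime_MR_cm_per_s = params$E_prime,
         t_E_prime_ms = params$t_E_prime,
         E_over_E_prime = params$E_over_Eprime)
  } else as.list(params)
}
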