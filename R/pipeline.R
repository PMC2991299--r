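#' Load a PC series
#'
#' @param path container directory (see [write_pc_series()] for the format).
#' @param format input format. `"container"` reads the NIfTI + JSON sidecar
#'   container; `"dicom"` is not supported by this build — convert the
#'   magnitude/phase series to the container (raw phase values can be decoded
#'   with [decode_velocity()]).
#' @return a [pc_series()].
#' @export
load_pc_series <- function(path, format = c("container", "dicom")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  if (format == "dicom")
    stop("DICOM reading is not supported in this build; decode the series ",
         "(decode_velocity) and write the NIfTI+JSON container instead")
  read_pc_series(path)
}

#' Full blood-flow analysis of a transmitral PC series
#'
#' Segments the transmitral and aortic flow patterns ([segment_flow()]),
#' derives velocity and flow-rate curves ([flow_curves()]), and extracts the
#' diastolic parameter set ([compute_flow_parameters()]).
#'
#' @param series a flow [pc_series()].
#' @param mitral_roi,aortic_roi rough [roi()]s around the two jets.
#' @param ... passed to [segment_flow()].
#' @return object of class `flow_analysis`: `params` (`flow_params`),
#'   `mitral` (curves), `aortic` (curves), `mitral_seg`, `aortic_seg`.
#' @export
analyze_flow <- function(series, mitral_roi, aortic_roi, ...) {
  ms <- segment_flow(series, mitral_roi, "mitral", ...)
  as_ <- segment_flow(series, aortic_roi, "aortic", ...)
  mc <- flow_curves(series, ms)
  ac <- flow_curves(series, as_)
  fp <- compute_flow_parameters(mc, ac$q, series$cycle_length)
  structure(list(params = fp, mitral = mc, aortic = ac,
                 mitral_seg = ms, aortic_seg = as_),
            class = "flow_analysis")
}

#' @export
print.flow_analysis <- function(x, ...) {
  print(x$params)
  invisible(x)
}

#' @export
plot.flow_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 1, 1))
  on.exit(graphics::par(op))
  plot(x$mitral$v_max, main = "", ...)
  graphics::abline(v = c(x$params$t_E, x$params$t_A), lty = 3)
  plot(x$mitral$q, ...)
  graphics::lines(x$aortic$q$times, x$aortic$q$values, col = "blue")
  graphics::abline(v = unlist(x$params$timings), lty = 3, col = "grey40")
  invisible(x)
}
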