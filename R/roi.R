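#' Define a rough region of interest
#'
#' The segmentation and clustering stages are initialized from a rough ROI
#' drawn around the flow (or myocardium) on a single cardiac phase. The ROI
#' is a polygon or an ellipse in pixel coordinates.
#'
#' Conventions: pixel coordinates are 0-based `(row, col)` with pixel centres
#' at integer positions, and `phase_index` is 0-based (phase `i` at time
#' `i * frame_interval` ms). A pixel belongs to the ROI when its centre is
#' inside the shape.
#'
#' @param phase_index 0-based cardiac phase the ROI was drawn on.
#' @param coords for `shape = "polygon"`, an `n x 2` matrix of `(row, col)`
#'   vertices (n >= 3); for `shape = "ellipse"`, a list with `centre`
#'   (row, col), `semi_axes` (row, col) and optional `angle_deg` (rotation of
#'   the row semi-axis, counter-clockwise).
#' @param shape `"polygon"` or `"ellipse"`.
#' @return an object of class `roi`.
#' @export
roi <- function(phase_index, coords, shape = c("polygon", "ellipse")) {
  shape <- match.arg(shape)
  stopifnot(length(phase_index) == 1L, phase_index >= 0)
  if (shape == "polygon") {
    coords <- as.matrix(coords)
    if (ncol(coords) != 2L || nrow(coords) < 3L)
      stop("polygon ROI needs an n x 2 (row, col) matrix with n >= 3")
  } else {
    if (!all(c("centre", "semi_axes") %in% names(coords)))
      stop("ellipse ROI needs `centre` and `semi_axes`")
    if (is.null(coords$angle_deg)) coords$angle_deg <- 0
    if (any(coords$semi_axes <= 0)) stop("ellipse semi-axes must be positive")
  }
  structure(list(phase_index = as.integer(phase_index), shape = shape,
                 coords = coords),
            class = "roi")
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("roi (%s) on phase %d\n", x$shape, x$phase_index))
  invisible(x)
}

# Even-odd-rule point-in-polygon test, vectorized over points.
# pts: m x 2 (row, col); poly: n x 2. Points exactly on an edge are
# boundary-rule dependent; callers should place vertices at half-integer
# coordinates so that no pixel centre falls on an edge.
.point_in_polygon <- function(pts, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    yi <- poly[i, 1]; xi <- poly[i, 2]
    yj <- poly[j, 1]; xj <- poly[j, 2]
    crosses <- ((yi > pts[, 1]) != (yj > pts[, 1])) &
      (pts[, 2] < (xj - xi) * (pts[, 1] - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Rasterize an ROI to a binary mask
#'
#' @param x a [roi()].
#' @param dim_hw image dimensions `c(H, W)` in pixels.
#' @return an `H x W` logical matrix; `TRUE` where the pixel centre lies
#'   inside the ROI.
#' @export
roi_mask <- function(x, dim_hw) {
  stopifnot(inherits(x, "roi"), length(dim_hw) == 2L)
  H <- dim_hw[1]; W <- dim_hw[2]
  rows0 <- rep(seq_len(H) - 1L, times = W)
  cols0 <- rep(seq_len(W) - 1L, each = H)
  pts <- cbind(rows0, cols0)
  if (x$shape == "polygon") {
    poly <- x$coords
    if (any(poly[, 1] < -0.5 | poly[, 1] > H - 0.5 |
            poly[, 2] < -0.5 | poly[, 2] > W - 0.5))
      stop("ROI vertices outside image bounds")
    inside <- .point_in_polygon(pts, poly)
  } else {
    ce <- x$coords$centre; ax <- x$coords$semi_axes
    th <- x$coords$angle_deg * pi / 180
    dr <- pts[, 1] - ce[1]; dc <- pts[, 2] - ce[2]
    u <- dr * cos(th) + dc * sin(th)
    v <- -dr * sin(th) + dc * cos(th)
    inside <- (u / ax[1])^2 + (v / ax[2])^2 <= 1
    if (ce[1] - ax[1] < -0.5 || ce[1] + ax[1] > H - 0.5 ||
        ce[2] - ax[2] < -0.5 || ce[2] + ax[2] > W - 0.5)
      stop("ROI vertices outside image bounds")
  }
  m <- matrix(inside, H, W)
  if (sum(m) < 16L)
    stop("ROI encloses fewer than 16 pixels (", sum(m), ")")
  m
}

#' Dilate a binary mask
#'
#' Morphological dilation by `iter` steps of the 3x3 (8-neighbour) structuring
#' element, i.e. by a Chebyshev radius of `iter` pixels.
#'
#' @param mask logical matrix.
#' @param iter number of dilation steps (non-negative integer).
#' @return logical matrix of the same shape.
#' @export
dilate_mask <- function(mask, iter = 1L) {
  stopifnot(is.matrix(mask))
  m <- mask
  H <- nrow(m); W <- ncol(m)
  for (k in seq_len(iter)) {
    out <- m
    out[-1, ] <- out[-1, ] | m[-H, ]
    out[-H, ] <- out[-H, ] | m[-1, ]
    out[, -1] <- out[, -1] | m[, -W]
    out[, -W] <- out[, -W] | m[, -1]
    out[-1, -1] <- out[-1, -1] | m[-H, -W]
    out[-1, -W] <- out[-1, -W] | m[-H, -1]
    out[-H, -1] <- out[-H, -1] | m[-1, -W]
    out[-H, -W] <- out[-H, -W] | m[-1, -1]
    m <- out
  }
  m
}

#' Erode a binary mask (8-neighbour structuring element)
#'
#' @inheritParams dilate_mask
#' @return logical matrix of the same shape.
#' @export
erode_mask <- function(mask, iter = 1L) {
  !dilate_mask(!mask, iter)
}

#' Read / write an ROI as JSON
#'
#' The on-disk format is
#' `{"phase_index": i, "shape": "polygon"|"ellipse", "coordinates": ...}` with
#' 0-based `(row, col)` pixel coordinates.
#'
#' @param x a [roi()].
#' @param path file path.
#' @return `write_roi` returns `path` invisibly; `read_roi` returns a [roi()].
#' @export
write_roi <- function(x, path) {
  stopifnot(inherits(x, "roi"))
  co <- if (x$shape == "polygon") unname(apply(x$coords, 1, as.numeric, simplify = FALSE))
        else x$coords
  jsonlite::write_json(list(phase_index = x$phase_index, shape = x$shape,
                            coordinates = co),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_roi
#' @export
read_roi <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  co <- if (j$shape == "polygon") {
    m <- j$coordinates
    if (is.list(m)) m <- do.call(rbind, m)
    matrix(as.numeric(m), ncol = 2)
  } else {
    list(centre = as.numeric(j$coordinates$centre),
         semi_axes = as.numeric(j$coordinates$semi_axes),
         angle_deg = if (is.null(j$coordinates$angle_deg)) 0
                     else as.numeric(j$coordinates$angle_deg))
  }
  roi(j$phase_index, co, j$shape)
}
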