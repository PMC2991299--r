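#' Label connected components of a binary image
#'
#' 8-connectivity labeling: pixels touching horizontally, vertically or
#' diagonally belong to the same component. Built on the component search of
#' \pkg{igraph} over the pixel adjacency graph.
#'
#' @param mask logical matrix.
#' @return integer matrix of the same shape; 0 for background, components
#'   numbered from 1. Label order is deterministic (first pixel in
#'   column-major order gets the lowest label).
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  idx <- which(mask)
  if (length(idx) == 0L) return(lab)
  pos <- match(seq_len(H * W), idx)      # pixel linear index -> vertex id
  r <- ((idx - 1L) %% H) + 1L
  c <- ((idx - 1L) %/% H) + 1L
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    ok <- r2 >= 1L & r2 <= H & c2 >= 1L & c2 <= W
    nb <- (c2[ok] - 1L) * H + r2[ok]
    v2 <- pos[nb]
    has <- !is.na(v2)
    edges <- c(edges, rbind(which(ok)[has], v2[has]))
  }
  g <- igraph::make_graph(edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # relabel so that labels follow first occurrence in column-major order
  first <- !duplicated(comp)
  relab <- integer(max(comp))
  relab[comp[first]] <- seq_len(sum(first))
  lab[idx] <- relab[comp]
  lab
}

# centre of mass of a mask, 0-based (row, col)
.mask_centroid <- function(mask) {
  idx <- which(mask)
  if (length(idx) == 0L) return(NULL)
  H <- nrow(mask)
  r0 <- ((idx - 1L) %% H)
  c0 <- ((idx - 1L) %/% H)
  c(mean(r0), mean(c0))
}

# pick the largest component label from a label matrix; ties broken by
# smallest (row, col) lexicographic centroid.  Returns 0 when no labels.
.largest_label <- function(lab, labels = NULL) {
  if (is.null(labels)) labels <- setdiff(unique(as.integer(lab)), 0L)
  if (length(labels) == 0L) return(0L)
  sizes <- vapply(labels, function(l) sum(lab == l), integer(1))
  best <- labels[sizes == max(sizes)]
  if (length(best) > 1L) {
    cent <- t(vapply(best, function(l) .mask_centroid(lab == l), numeric(2)))
    best <- best[order(cent[, 1], cent[, 2])]
  }
  best[1L]
}

#' Largest connected area of a given velocity sign
#'
#' Finds the 8-connected components of pixels within a search region whose
#' velocity has the requested sign, and returns the largest one. When
#' `required_point` is given, the largest component containing that pixel is
#' returned instead; an all-`FALSE` mask is a valid result when no component
#' qualifies.
#'
#' @param velocity_image numeric `H x W` velocity map (cm/s, signed).
#' @param sign `+1` or `-1`: the velocity sign of the flow of interest.
#' @param search_region logical `H x W` mask restricting the search.
#' @param required_point optional 0-based `(row, col)` pixel the component
#'   must contain.
#' @param min_area components smaller than this many pixels are ignored.
#' @return logical `H x W` mask (a single connected component, or empty).
#' @export
largest_signed_component <- function(velocity_image, sign, search_region,
                                     required_point = NULL, min_area = 1L) {
  stopifnot(is.matrix(velocity_image), sign %in% c(-1, 1),
            identical(dim(velocity_image), dim(search_region)))
  if (!any(search_region)) stop("empty search region")
  fg <- search_region & (sign * velocity_image > 0)
  lab <- label_components(fg)
  if (min_area > 1L) {
    tab <- tabulate(lab)
    small <- which(tab < min_area)
    if (length(small)) lab[lab %in% small] <- 0L
  }
  if (!is.null(required_point)) {
    rp <- round(required_point)
    l <- 0L
    if (rp[1] >= 0 && rp[1] < nrow(lab) && rp[2] >= 0 && rp[2] < ncol(lab))
      l <- lab[rp[1] + 1L, rp[2] + 1L]
    return(lab == l & l > 0L)
  }
  l <- .largest_label(lab)
  lab == l & l > 0L
}
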