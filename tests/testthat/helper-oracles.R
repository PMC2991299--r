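# Independent brute-force oracles used to validate the package's primitives.
# Each oracle is written from the definition, not from the package code:
# stack-based flood fill for connected components, exhaustive pair
# enumeration for peak detection, pairwise concordance for AUC, and full
# enumeration of the U distribution for the exact Mann-Whitney p-value.

# 8-connected component labeling by explicit flood fill
oracle_label <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  nxt <- 0L
  for (cc in seq_len(W)) for (rr in seq_len(H)) {
    if (!mask[rr, cc] || lab[rr, cc] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(rr, cc))
    lab[rr, cc] <- nxt
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r2 <- p[1] + dr; c2 <- p[2] + dc
        if (r2 >= 1 && r2 <= H && c2 >= 1 && c2 <= W &&
            mask[r2, c2] && lab[r2, c2] == 0L) {
          lab[r2, c2] <- nxt
          stack[[length(stack) + 1L]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# centre of mass, 0-based (row, col), for tie-breaking
oracle_centroid <- function(mask) {
  w <- which(mask, arr.ind = TRUE)
  c(mean(w[, 1]) - 1, mean(w[, 2]) - 1)
}

# largest same-sign 8-connected component from the definition
oracle_largest_signed <- function(v, sgn, search, min_area = 1L) {
  fg <- search & (sgn * v > 0)
  lab <- oracle_label(fg)
  labs <- setdiff(unique(as.integer(lab)), 0L)
  sizes <- vapply(labs, function(l) sum(lab == l), integer(1))
  labs <- labs[sizes >= min_area]; sizes <- sizes[sizes >= min_area]
  if (length(labs) == 0L) return(matrix(FALSE, nrow(v), ncol(v)))
  best <- labs[sizes == max(sizes)]
  if (length(best) > 1L) {
    cent <- t(vapply(best, function(l) oracle_centroid(lab == l), numeric(2)))
    best <- best[order(cent[, 1], cent[, 2])]
  }
  lab == best[1L]
}

# exhaustive two-peak search: all strict local maxima in the window, all
# ordered pairs at least min_sep apart, maximal summed amplitude
oracle_two_peaks <- function(times, values, window, min_sep) {
  n <- length(values)
  is_max <- vapply(2:(n - 1), function(i)
    values[i] > values[i - 1] && values[i] > values[i + 1], logical(1))
  pk <- (2:(n - 1))[is_max]
  pk <- pk[times[pk] >= window[1] & times[pk] <= window[2]]
  if (length(pk) < 2L) return(NULL)
  best <- NULL; best_sum <- -Inf
  for (i in pk) for (j in pk) {
    if (times[j] - times[i] < min_sep) next
    if (values[i] + values[j] > best_sum) {
      best_sum <- values[i] + values[j]; best <- c(i, j)
    }
  }
  best
}

# AUC as the plain pairwise concordance probability
oracle_auc <- function(values, labels, positive_group) {
  vp <- values[labels == positive_group]
  vn <- values[labels != positive_group]
  conc <- 0
  for (a in vp) for (b in vn)
    conc <- conc + (a > b) + 0.5 * (a == b)
  auc_hi <- conc / (length(vp) * length(vn))
  max(auc_hi, 1 - auc_hi)
}

# exact two-sided Mann-Whitney p-value by full enumeration of all
# assignments of the pooled ranks to group A (tie-free data only)
oracle_mw_exact_p <- function(groupA, groupB) {
  nA <- length(groupA); nB <- length(groupB)
  r <- rank(c(groupA, groupB))
  u_obs <- sum(r[seq_len(nA)]) - nA * (nA + 1) / 2
  combos <- utils::combn(nA + nB, nA)
  us <- apply(combos, 2, function(id) sum(id) - nA * (nA + 1) / 2)
  p <- if (u_obs > nA * nB / 2) mean(us >= u_obs) else mean(us <= u_obs)
  min(2 * p, 1)
}

# standard ROIs used on the phantoms throughout the tests
phantom_flow_rois <- function() {
  list(
    mitral = roi(30, rbind(c(69.5, 53.5), c(69.5, 74.5),
                           c(90.5, 74.5), c(90.5, 53.5))),
    aortic = roi(0, rbind(c(30.5, 54.5), c(30.5, 73.5),
                          c(50.5, 73.5), c(50.5, 54.5))))
}

phantom_myo_roi <- function() {
  roi(0, list(centre = c(32, 32), semi_axes = c(17.5, 17.5)), "ellipse")
}
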