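#' Box-counting fractal dimension of a thresholded ROI
#'
#' Binarizes the masked, normalized pixels at `v' >= t * 255`, counts the
#' occupied `s x s` boxes on a dyadic grid anchored at the mask bounding-box
#' origin for `s = 1, 2, 4, ...` up to the bounding-box size, and estimates
#' the fractal dimension as minus the slope of the unweighted least-squares
#' fit of `log N(s)` on `log s`. An empty binary set yields FD 0; with a
#' single usable scale the estimate is 0 and the result is flagged.
#'
#' @param roi a `normalized_roi`.
#' @param threshold binarization threshold `t` in (0, 1), as a fraction of 255.
#' @return list with `threshold`, `sizes`, `counts`, `fd` and `degenerate`
#'   (TRUE when fewer than 2 scales carried information).
#' @export
box_count_fd <- function(roi, threshold = 0.5) {
  stopifnot(inherits(roi, "normalized_roi"),
            threshold > 0, threshold < 1)
  occ <- roi$mask & !is.na(roi$values) & roi$values >= threshold * 255
  midx <- which(roi$mask, arr.ind = TRUE)
  r0 <- min(midx[, 1]); c0 <- min(midx[, 2])
  bh <- max(midx[, 1]) - r0 + 1L; bw <- max(midx[, 2]) - c0 + 1L
  smax <- max(bh, bw)
  sizes <- 1L
  while (utils::tail(sizes, 1) * 2L <= smax) sizes <- c(sizes, utils::tail(sizes, 1) * 2L)
  if (!any(occ)) {
    return(list(threshold = threshold, sizes = sizes,
                counts = rep(0L, length(sizes)), fd = 0, degenerate = TRUE))
  }
  oidx <- which(occ, arr.ind = TRUE)
  counts <- vapply(sizes, function(s) {
    br <- (oidx[, 1] - r0) %/% s
    bc <- (oidx[, 2] - c0) %/% s
    length(unique(br * (bw %/% s + 2L) + bc))
  }, integer(1))
  degenerate <- length(sizes) < 2L
  fd <- if (degenerate) 0 else -stats::coef(stats::lm(log(counts) ~ log(sizes)))[[2]]
  if (!is.finite(fd)) fd <- 0
  list(threshold = threshold, sizes = sizes, counts = counts,
       fd = fd, degenerate = degenerate)
}

# the 15 catalog fractal dimensions
.fractal_all <- function(roi) {
  vapply(stats::setNames(.FD_THRESHOLDS, sprintf("FD_%.3f", .FD_THRESHOLDS)),
         function(t) box_count_fd(roi, t)$fd, numeric(1))
}
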