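# polygon area via the shoelace formula (vertices as x/y columns)
.shoelace <- function(xy) {
  x <- xy[, 1]; y <- xy[, 2]
  i2 <- c(seq_len(nrow(xy))[-1], 1L)
  abs(sum(x * y[i2] - x[i2] * y)) / 2
}

#' Morphological features of a ROI mask
#'
#' Fourteen shape descriptors in physical units (mm / mm^2): area
#' (`F_morph.surface`), boundary perimeter (chain-code contour length),
#' moment-ellipse major/minor axis lengths (`L_major`, `L_minor`),
#' eccentricity, elongation (minor/major), circularity `4*pi*A/P^2`,
#' compactness `A/P^2`, convex hull area, solidity, bounding-box extent,
#' maximum Feret diameter, equivalent disc diameter, and the shift between
#' the intensity-weighted and geometric centroids (which needs the frame).
#'
#' Axis lengths follow the moment-of-inertia ellipse convention
#' (`4 * sqrt(eigenvalue)` of the central second moments, with the 1/12
#' pixel-integration correction), so a solid disc of radius R yields
#' `L_major = L_minor = 2R`. The convex hull is taken over pixel corners so
#' solidity never exceeds 1.
#'
#' @param mask a `roi_mask`.
#' @param spacing length-2 (row, col) pixel spacing, mm.
#' @param frame optional `us_frame` for the centre-of-mass shift; when
#'   omitted the shift is 0.
#' @return named numeric vector of length 14.
#' @export
morphological_features <- function(mask, spacing = c(1, 1), frame = NULL) {
  stopifnot(inherits(mask, "roi_mask"))
  m <- mask$mask
  sr <- spacing[1]; sc <- spacing[2]
  idx <- which(m)
  r <- (idx - 1) %% nrow(m) + 1
  c_ <- (idx - 1) %/% nrow(m) + 1
  npx <- length(idx)
  area <- npx * sr * sc

  # perimeter: chain-code length of the outer contour (EBImage, 0-based x/y)
  oc <- EBImage::ocontour(matrix(as.numeric(m), nrow(m), ncol(m)))[[1]]
  if (nrow(oc) >= 2) {
    nxt <- rbind(oc[-1, , drop = FALSE], oc[1, , drop = FALSE])
    dx <- (nxt[, 1] - oc[, 1]) * sr # contour x follows matrix rows
    dy <- (nxt[, 2] - oc[, 2]) * sc
    perim <- sum(sqrt(dx^2 + dy^2))
  } else {
    perim <- 4 * sqrt(sr * sc) # degenerate single-point contour
  }

  # central second moments of pixel centres (mm) + pixel integration term
  x <- r * sr; y <- c_ * sc
  mx <- mean(x); my <- mean(y)
  cxx <- mean((x - mx)^2) + sr^2 / 12
  cyy <- mean((y - my)^2) + sc^2 / 12
  cxy <- mean((x - mx) * (y - my))
  ev <- eigen(matrix(c(cxx, cxy, cxy, cyy), 2, 2), symmetric = TRUE)$values
  ev <- pmax(ev, 0)
  l_major <- 4 * sqrt(ev[1]); l_minor <- 4 * sqrt(ev[2])
  ecc <- if (ev[1] > 0) sqrt(1 - ev[2] / ev[1]) else 0
  elong <- .sdiv(l_minor, l_major)

  # convex hull over the 4 corners of every pixel (in mm)
  corners <- cbind(c(x - sr / 2, x - sr / 2, x + sr / 2, x + sr / 2),
                   c(y - sc / 2, y + sc / 2, y - sc / 2, y + sc / 2))
  h <- grDevices::chull(corners)
  hull <- corners[h, , drop = FALSE]
  conv_area <- .shoelace(hull)
  feret <- sqrt(max(outer(hull[, 1], hull[, 1], "-")^2 +
                    outer(hull[, 2], hull[, 2], "-")^2))

  bbox_area <- (diff(range(r)) + 1) * sr * (diff(range(c_)) + 1) * sc

  com_shift <- 0
  if (!is.null(frame)) {
    w <- frame$pixels[idx]
    if (sum(w) > 0) {
      wx <- sum(w * x) / sum(w); wy <- sum(w * y) / sum(w)
      com_shift <- sqrt((wx - mx)^2 + (wy - my)^2)
    }
  }

  c(F_morph.surface = area,
    F_morph.perimeter = perim,
    L_major = l_major,
    L_minor = l_minor,
    F_morph.ecc = ecc,
    F_morph.elong = elong,
    F_morph.circ = .sdiv(4 * pi * area, perim^2),
    F_morph.comp = .sdiv(area, perim^2),
    F_morph.conv.area = conv_area,
    F_morph.solidity = .sdiv(area, conv_area),
    F_morph.extent = area / bbox_area,
    F_morph.feret.max = feret,
    F_morph.eq.diam = 2 * sqrt(area / pi),
    F_morph.com.shift = com_shift)
}
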