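#' Single-frame greyscale ultrasound image
#'
#' Lightweight container for a 2D grey image in the 8-bit range together
#' with its pixel spacing and hierarchy tags (machine, patient, ovary side,
#' scan plane).
#'
#' @param pixels numeric matrix, finite, values in `[0, 255]`.
#' @param pixel_spacing length-2 positive numeric (row, col), mm/pixel.
#' @param tags named list: `machine`, `patient_id`, `side`, `plane`.
#' @return object of class `us_frame`.
#' @export
us_frame <- function(pixels, pixel_spacing = c(1, 1), tags = list()) {
  stopifnot(is.matrix(pixels), all(is.finite(pixels)),
            length(pixel_spacing) == 2, all(pixel_spacing > 0))
  structure(list(pixels = pixels, pixel_spacing = as.numeric(pixel_spacing),
                 tags = tags),
            class = "us_frame")
}

#' Binary region-of-interest mask
#'
#' Validates the pipeline's ROI contract: at least 16 foreground pixels and
#' exactly one 4-connected foreground component.
#'
#' @param mask logical (or 0/1 numeric) matrix.
#' @return object of class `roi_mask`.
#' @export
roi_mask <- function(mask) {
  if (!is.logical(mask)) mask <- mask > 0
  stopifnot(is.matrix(mask))
  npx <- sum(mask)
  if (npx == 0) stop("mask error: mask is empty")
  if (npx < 16) stop("mask error: fewer than 16 foreground pixels")
  ncomp <- max(.label4(mask))
  if (ncomp != 1)
    stop("mask error: expected one 4-connected component, found ", ncomp)
  structure(list(mask = mask), class = "roi_mask")
}

#' Read an original/mask DICOM pair
#'
#' Reads the two files of a leaf folder, checks that they share a pixel
#' grid, binarizes the mask at > 0, and validates the ROI contract.
#'
#' @param path_image path to the original DICOM.
#' @param path_mask path to the ROI mask DICOM.
#' @return list with `frame` (`us_frame`) and `mask` (`roi_mask`).
#' @export
read_dicom_pair <- function(path_image, path_mask) {
  img <- read_dicom(path_image)
  msk <- read_dicom(path_mask)
  if (!all(dim(img$pixels) == dim(msk$pixels)))
    stop("pairing error: image and mask pixel grids differ")
  list(frame = us_frame(img$pixels, img$pixel_spacing, img$tags),
       mask = roi_mask(msk$pixels > 0))
}

#' Read a cohort manifest CSV
#'
#' @param path path to a `manifest.csv` written by [make_cohort()].
#' @return data frame with one row per image.
#' @export
read_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "path_image", "path_mask", "machine", "patient_id",
            "side", "plane", "label")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest is missing columns: ", paste(missing, collapse = ", "))
  man
}

#' Min-max rescale the ROI pixels to the 0-255 range
#'
#' `v' = 255 (v - min) / (max - min)` over masked pixels only; a constant
#' ROI maps to all zeros. Geometry (mask and spacing) is retained so texture
#' matrices can be built on the same grid.
#'
#' @param frame a `us_frame`.
#' @param mask a `roi_mask` with the same grid.
#' @return object of class `normalized_roi`: `values` (matrix, `NA` outside
#'   the mask), `mask`, `pixel_spacing`.
#' @export
normalize_roi <- function(frame, mask) {
  stopifnot(inherits(frame, "us_frame"), inherits(mask, "roi_mask"),
            all(dim(frame$pixels) == dim(mask$mask)))
  m <- mask$mask
  v <- frame$pixels[m]
  rng <- range(v)
  out <- matrix(NA_real_, nrow(m), ncol(m))
  out[m] <- if (rng[2] > rng[1]) 255 * (v - rng[1]) / (rng[2] - rng[1]) else 0
  structure(list(values = out, mask = m,
                 pixel_spacing = frame$pixel_spacing),
            class = "normalized_roi")
}

#' Discretize a normalized ROI into Ng grey levels
#'
#' Uniform bin width over `[0, 256)`:
#' `level = min(Ng, floor(v' * Ng / 256) + 1)`, so 0 maps to level 1 and 255
#' to level `Ng`. Pixels outside the mask carry `NA` as the "outside" marker.
#'
#' @param roi a `normalized_roi`.
#' @param Ng number of grey levels, >= 2 (default 32).
#' @return object of class `discretized_roi`: `levels` (integer matrix with
#'   `NA` outside), `Ng`, `mask`, `pixel_spacing`.
#' @export
discretize_roi <- function(roi, Ng = 32L) {
  stopifnot(inherits(roi, "normalized_roi"))
  if (Ng < 2) stop("config error: Ng must be at least 2")
  lev <- floor(roi$values * Ng / 256) + 1
  lev[!is.na(lev) & lev > Ng] <- Ng
  lev <- matrix(as.integer(lev), nrow(lev), ncol(lev))
  structure(list(levels = lev, Ng = as.integer(Ng), mask = roi$mask,
                 pixel_spacing = roi$pixel_spacing),
            class = "discretized_roi")
}
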