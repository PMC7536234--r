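#' Extract the full 232-feature vector from an image/mask pair
#'
#' Runs normalization (min-max rescale to 0-255 over the ROI), grey-level
#' discretization, and the four feature families: 20 first-order, 14
#' morphological, 183 texture (co-occurrence, run-length, size-zone,
#' distance-zone) and 15 box-counting fractal dimensions. Returns exactly
#' the catalog names in catalog order; degenerate textures fall back to
#' fixed values rather than missing entries.
#'
#' @param frame a `us_frame`.
#' @param mask a `roi_mask` on the same grid.
#' @param Ng grey-level count for discretization (default 32).
#' @param families subset of
#'   `c("first_order", "morphology", "texture", "fractal")`; the returned
#'   vector is restricted accordingly (full catalog by default).
#' @return named numeric vector (length 232 for the full catalog).
#' @export
extract_all <- function(frame, mask, Ng = 32L,
                        families = c("first_order", "morphology",
                                     "texture", "fractal")) {
  families <- match.arg(families, several.ok = TRUE)
  roi <- normalize_roi(frame, mask)
  out <- numeric(0)
  if ("first_order" %in% families)
    out <- c(out, first_order_features(roi, Ng = Ng))
  if ("morphology" %in% families)
    out <- c(out, morphological_features(mask, spacing = frame$pixel_spacing,
                                         frame = frame))
  if ("texture" %in% families) {
    disc <- discretize_roi(roi, Ng = Ng)
    szm <- glszm(disc)
    out <- c(out,
             .glcm_all(disc),
             .glrlm_all(disc),
             stats::setNames(szm$features, paste0("F_szm.", .GLSZM_FEATURES)),
             stats::setNames(distance_zone_features(disc),
                             paste0("F_dzm.", .GLDZM_FEATURES)))
  }
  if ("fractal" %in% families)
    out <- c(out, .fractal_all(roi))
  cat_names <- feature_catalog()
  want <- cat_names$name[cat_names$family %in% families]
  stopifnot(setequal(names(out), want))
  out[want]
}

#' Extract features for every image of a cohort
#'
#' Applies [extract_all()] to each image/mask pair of a manifest (reading
#' the DICOM pairs) or of an in-memory simulated cohort, and assembles the
#' feature table the screening and modeling stages consume.
#'
#' @param manifest data frame from [make_cohort()] / [read_manifest()], or a
#'   list as returned by the in-memory simulator.
#' @param Ng grey-level count (default 32).
#' @param families feature families to compute (all by default).
#' @return data frame: `image_id`, `patient_id`, `machine`, `label`, then
#'   one column per catalog feature.
#' @export
extract_cohort <- function(manifest, Ng = 32L,
                           families = c("first_order", "morphology",
                                        "texture", "fractal")) {
  if (is.data.frame(manifest)) {
    pairs <- lapply(seq_len(nrow(manifest)), function(i) {
      read_dicom_pair(manifest$path_image[i], manifest$path_mask[i])
    })
    meta <- manifest[, c("image_id", "patient_id", "machine", "label")]
  } else {
    pairs <- manifest$items
    meta <- manifest$manifest[, c("image_id", "patient_id", "machine", "label")]
  }
  feats <- do.call(rbind, lapply(pairs, function(p)
    extract_all(p$frame, p$mask, Ng = Ng, families = families)))
  cbind(meta, as.data.frame(feats), stringsAsFactors = FALSE)
}
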