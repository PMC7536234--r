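# Feature catalog: the ordered 232-feature registry. Family sizes are
# first-order 20, morphology 14, texture 183 (100 co-occurrence + 64
# run-length + 16 size-zone + 3 distance-zone), fractal 15.

.GLCM_FEATURES <- c("joint.max", "joint.avg", "joint.var", "joint.entr",
                    "diff.avg", "diff.var", "diff.entr",
                    "sum.avg", "sum.var", "sum.entr",
                    "energy", "contrast", "dissimilarity",
                    "inv.diff", "inv.diff.norm", "inv.diff.mom",
                    "inv.diff.mom.norm", "inv.var",
                    "corr", "autocorr",
                    "clust.tend", "clust.shade", "clust.prom",
                    "info.corr.1", "info.corr.2")

.GLRLM_FEATURES <- c("sre", "lre", "lgre", "hgre", "srlge", "srhge",
                     "lrlge", "lrhge", "glnu", "glnu.norm", "rlnu",
                     "rlnu.norm", "run.pct", "gl.var", "rl.var", "rl.entr")

.GLSZM_FEATURES <- c("sze", "lze", "lgze", "hgze", "szlge", "szhge",
                     "lzlge", "lzhge", "glnu", "glnu.norm", "zsnu",
                     "zsnu.norm", "z.pct", "gl.var", "zs.var", "z.entr")

.GLDZM_FEATURES <- c("sde", "lde", "zd.entr")

.FO_FEATURES <- c("mean", "var", "skew", "kurt", "median", "min", "max",
                  "range", "p10", "p90", "iqr", "mad", "rmad", "medad",
                  "cov", "qcod", "energy", "rms", "entropy", "uniformity")

.MORPH_FEATURES <- c("F_morph.surface", "F_morph.perimeter",
                     "L_major", "L_minor",
                     "F_morph.ecc", "F_morph.elong", "F_morph.circ",
                     "F_morph.comp", "F_morph.conv.area", "F_morph.solidity",
                     "F_morph.extent", "F_morph.feret.max",
                     "F_morph.eq.diam", "F_morph.com.shift")

.RLM_DIRECTIONS <- c(0L, 45L, 90L, 135L)
.FD_THRESHOLDS <- seq(0.05, 0.75, by = 0.05)

# GLCM variant naming: distance-1 directional average is the bare name,
# the merged (pooled-matrix) variant carries the 2.5Dmerged tag, and
# distance-2 variants append a d2 tag.
.glcm_variant_names <- function() {
  c(paste0("F_cm.", .GLCM_FEATURES),
    paste0("F_cm.2.5Dmerged.", .GLCM_FEATURES),
    paste0("F_cm.d2.", .GLCM_FEATURES),
    paste0("F_cm.2.5Dmerged.d2.", .GLCM_FEATURES))
}

#' The default 232-feature catalog
#'
#' Ordered registry of feature descriptors: 20 first-order statistics, 14
#' morphological features, 183 texture features (25 co-occurrence features
#' in 4 variants: directional-average and merged matrices at distances 1 and
#' 2; 16 run-length features along each of 4 directions; 16 size-zone
#' features; 3 distance-zone features) and 15 box-counting fractal
#' dimensions at binarization thresholds 0.05 to 0.75.
#'
#' @return data frame with columns `name`, `family`
#'   (`first_order`/`morphology`/`texture`/`fractal`) and `variant`.
#' @export
feature_catalog <- function() {
  fo <- data.frame(name = paste0("F_stat.", .FO_FEATURES),
                   family = "first_order", variant = "")
  mo <- data.frame(name = .MORPH_FEATURES, family = "morphology", variant = "")
  cm <- data.frame(name = .glcm_variant_names(), family = "texture",
                   variant = rep(c("cm.avg.d1", "cm.merged.d1",
                                   "cm.avg.d2", "cm.merged.d2"), each = 25))
  rlm <- data.frame(
    name = as.vector(vapply(.RLM_DIRECTIONS, function(d)
      paste0("F_rlm.", .GLRLM_FEATURES, ".", d), character(16))),
    family = "texture",
    variant = rep(paste0("rlm.", .RLM_DIRECTIONS), each = 16))
  szm <- data.frame(name = paste0("F_szm.", .GLSZM_FEATURES),
                    family = "texture", variant = "szm")
  dzm <- data.frame(name = paste0("F_dzm.", .GLDZM_FEATURES),
                    family = "texture", variant = "dzm")
  fd <- data.frame(name = sprintf("FD_%.3f", .FD_THRESHOLDS),
                   family = "fractal", variant = "")
  out <- rbind(fo, mo, cm, rlm, szm, dzm, fd)
  stopifnot(!anyDuplicated(out$name))
  out
}
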