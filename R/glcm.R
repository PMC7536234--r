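# Grey-level co-occurrence matrices and their 25 features.
# Directions 0/45/90/135 degrees; matrices are symmetric (each pixel pair is
# counted in both orders) and restricted to in-mask pixel pairs.

.GLCM_OFFSETS <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L),
                      `90` = c(-1L, 0L), `135` = c(1L, 1L))

# raw symmetric co-occurrence counts for one offset (dr, dc) * d
.glcm_counts <- function(lev, Ng, offset, d) {
  dr <- offset[1] * d; dc <- offset[2] * d
  nr <- nrow(lev); nc <- ncol(lev)
  r1 <- max(1L, 1L - dr):min(nr, nr - dr)
  c1 <- max(1L, 1L - dc):min(nc, nc - dc)
  if (!length(r1) || !length(c1)) return(matrix(0, Ng, Ng))
  a <- lev[r1, c1, drop = FALSE]
  b <- lev[r1 + dr, c1 + dc, drop = FALSE]
  ok <- !is.na(a) & !is.na(b)
  if (!any(ok)) return(matrix(0, Ng, Ng))
  cnt <- matrix(tabulate((a[ok] - 1L) * Ng + b[ok], nbins = Ng * Ng), Ng, Ng)
  cnt + t(cnt)
}

# the 25 features of one normalized symmetric co-occurrence matrix
.glcm_feature_set <- function(P) {
  Ng <- nrow(P)
  tot <- sum(P)
  if (tot <= 0) {
    out <- stats::setNames(numeric(25), .GLCM_FEATURES)
    out["energy"] <- 1
    return(out)
  }
  P <- P / tot
  I <- row(P); J <- col(P)
  px <- rowSums(P)
  mu <- sum(I * P)
  jvar <- sum((I - mu)^2 * P)
  dvec <- abs(I - J)
  pd <- vapply(0:(Ng - 1), function(k) sum(P[dvec == k]), numeric(1))
  svec <- I + J
  ps <- vapply(2:(2 * Ng), function(k) sum(P[svec == k]), numeric(1))
  da <- sum((0:(Ng - 1)) * pd)
  sa <- sum((2:(2 * Ng)) * ps)
  hxy <- .entropy2(P)
  hx <- .entropy2(px)
  pxy <- outer(px, px)
  sel <- P > 0 & pxy > 0
  hxy1 <- -sum(P[sel] * log2(pxy[sel]))
  hxy2 <- .entropy2(pxy)
  ic2sq <- 1 - exp(-2 * (hxy2 - hxy))
  offdiag <- I != J
  c(joint.max = max(P),
    joint.avg = mu,
    joint.var = jvar,
    joint.entr = hxy,
    diff.avg = da,
    diff.var = sum(((0:(Ng - 1)) - da)^2 * pd),
    diff.entr = .entropy2(pd),
    sum.avg = sa,
    sum.var = sum(((2:(2 * Ng)) - sa)^2 * ps),
    sum.entr = .entropy2(ps),
    energy = sum(P^2),
    contrast = sum((I - J)^2 * P),
    dissimilarity = sum(abs(I - J) * P),
    inv.diff = sum(P / (1 + abs(I - J))),
    inv.diff.norm = sum(P / (1 + abs(I - J) / Ng)),
    inv.diff.mom = sum(P / (1 + (I - J)^2)),
    inv.diff.mom.norm = sum(P / (1 + (I - J)^2 / Ng^2)),
    inv.var = sum(P[offdiag] / (I[offdiag] - J[offdiag])^2),
    corr = .sdiv(sum((I - mu) * (J - mu) * P), jvar),
    autocorr = sum(I * J * P),
    clust.tend = sum((I + J - 2 * mu)^2 * P),
    clust.shade = sum((I + J - 2 * mu)^3 * P),
    clust.prom = sum((I + J - 2 * mu)^4 * P),
    info.corr.1 = .sdiv(hxy - hxy1, hx),
    info.corr.2 = if (ic2sq > 0) sqrt(ic2sq) else 0)
}

#' Grey-level co-occurrence matrix and features
#'
#' Builds symmetric co-occurrence matrices over the four 2D directions at
#' pixel distance `d`, restricted to in-mask pixel pairs, and evaluates 25
#' features. The `"average"` variant computes features per direction and
#' averages them over directions with at least one pair; the `"merged"`
#' variant pools the directional counts into one matrix first (the 2.5D
#' aggregation, which coincides with merged-2D for single-frame input).
#'
#' @param disc a `discretized_roi`.
#' @param d offset distance in pixels (1 or 2).
#' @param variant `"average"` or `"merged"`.
#' @param directions subset of `c("0", "45", "90", "135")`.
#' @return list with `P` (the merged or mean directional probability
#'   matrix) and `features` (named numeric, 25).
#' @export
glcm <- function(disc, d = 1L, variant = c("average", "merged"),
                 directions = names(.GLCM_OFFSETS)) {
  stopifnot(inherits(disc, "discretized_roi"), d %in% c(1L, 2L))
  variant <- match.arg(variant)
  lev <- disc$levels; Ng <- disc$Ng
  counts <- lapply(.GLCM_OFFSETS[directions], .glcm_counts,
                   lev = lev, Ng = Ng, d = d)
  if (variant == "merged") {
    pooled <- Reduce(`+`, counts)
    feats <- .glcm_feature_set(pooled)
    P <- if (sum(pooled) > 0) pooled / sum(pooled) else pooled
  } else {
    have <- vapply(counts, sum, numeric(1)) > 0
    if (!any(have)) {
      feats <- .glcm_feature_set(counts[[1]])
      P <- counts[[1]]
    } else {
      fmat <- vapply(counts[have], .glcm_feature_set, numeric(25))
      feats <- rowMeans(fmat)
      P <- Reduce(`+`, lapply(counts[have], function(x) x / sum(x))) / sum(have)
    }
  }
  list(P = P, features = feats)
}

# all 100 catalog-named co-occurrence features
.glcm_all <- function(disc) {
  out <- c(
    stats::setNames(glcm(disc, 1L, "average")$features,
                    paste0("F_cm.", .GLCM_FEATURES)),
    stats::setNames(glcm(disc, 1L, "merged")$features,
                    paste0("F_cm.2.5Dmerged.", .GLCM_FEATURES)),
    stats::setNames(glcm(disc, 2L, "average")$features,
                    paste0("F_cm.d2.", .GLCM_FEATURES)),
    stats::setNames(glcm(disc, 2L, "merged")$features,
                    paste0("F_cm.2.5Dmerged.d2.", .GLCM_FEATURES)))
  out
}
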