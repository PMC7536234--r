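# Grey-level size-zone and distance-zone matrices. Zones are 4-connected
# sets of equal grey level; zone distance is the city-block distance of a
# zone to the ROI border (border pixels have distance 1).

# per-zone (grey level, size, border distance) table
.zone_table <- function(disc, with_distance = FALSE) {
  lev <- disc$levels; Ng <- disc$Ng
  dmap <- if (with_distance) .chamfer_cityblock(!is.na(lev)) else NULL
  gl <- integer(0); sz <- integer(0); dist <- integer(0)
  for (g in seq_len(Ng)) {
    sel <- !is.na(lev) & lev == g
    if (!any(sel)) next
    lab <- .label4(sel)
    nz <- max(lab)
    sizes <- tabulate(lab[lab > 0], nbins = nz)
    gl <- c(gl, rep(g, nz)); sz <- c(sz, sizes)
    if (with_distance) {
      dmin <- vapply(seq_len(nz), function(k) min(dmap[lab == k]), numeric(1))
      dist <- c(dist, as.integer(dmin))
    }
  }
  list(gl = gl, size = sz, dist = dist, np = sum(!is.na(lev)), Ng = Ng)
}

#' Grey-level size-zone matrix and features
#'
#' Direction-free analogue of the run-length matrix over 4-connected
#' constant-level zones; evaluates the 16 size-zone features.
#'
#' @param disc a `discretized_roi`.
#' @return list with `S` (Ng x Zmax zone-count matrix), `Nz` (total zones)
#'   and `features` (named numeric, 16, bare names).
#' @export
glszm <- function(disc) {
  stopifnot(inherits(disc, "discretized_roi"))
  zt <- .zone_table(disc)
  Ng <- zt$Ng
  zmax <- max(zt$size)
  S <- matrix(tabulate((zt$gl - 1L) * zmax + zt$size, nbins = Ng * zmax),
              Ng, zmax, byrow = TRUE)
  nz <- sum(S)
  i <- row(S); j <- col(S)
  p <- S / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  si <- rowSums(S); sj <- colSums(S)
  feats <- c(
    sze = sum(S / j^2) / nz,
    lze = sum(S * j^2) / nz,
    lgze = sum(S / i^2) / nz,
    hgze = sum(S * i^2) / nz,
    szlge = sum(S / (i^2 * j^2)) / nz,
    szhge = sum(S * i^2 / j^2) / nz,
    lzlge = sum(S * j^2 / i^2) / nz,
    lzhge = sum(S * i^2 * j^2) / nz,
    glnu = sum(si^2) / nz,
    glnu.norm = sum(si^2) / nz^2,
    zsnu = sum(sj^2) / nz,
    zsnu.norm = sum(sj^2) / nz^2,
    z.pct = nz / zt$np,
    gl.var = sum((i - mu_i)^2 * p),
    zs.var = sum((j - mu_j)^2 * p),
    z.entr = .entropy2(p)
  )
  list(S = S, Nz = nz, features = feats)
}

#' Grey-level distance-zone summaries
#'
#' Three summaries of the joint distribution of zone grey level and zone
#' distance to the ROI border (city-block metric, border distance 1): small
#' distance emphasis, large distance emphasis and zone distance entropy.
#'
#' @param disc a `discretized_roi`.
#' @return named numeric vector of length 3 (bare names).
#' @export
distance_zone_features <- function(disc) {
  stopifnot(inherits(disc, "discretized_roi"))
  zt <- .zone_table(disc, with_distance = TRUE)
  nz <- length(zt$gl)
  d <- zt$dist
  key <- paste(zt$gl, d)
  p <- as.vector(table(key)) / nz
  c(sde = sum(1 / d^2) / nz,
    lde = sum(d^2) / nz,
    zd.entr = .entropy2(p))
}
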