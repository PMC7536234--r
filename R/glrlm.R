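# Grey-level run-length matrices: maximal constant-level pixel runs along
# one of the four 2D directions, inside the mask (NA cells break runs).

# line id per matrix cell for a direction; column-major order then gives the
# correct traversal order along every line
.rlm_line_key <- function(nr, nc, direction) {
  r <- matrix(seq_len(nr), nr, nc)
  cc <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  switch(as.character(direction),
         `0` = r,          # along columns
         `90` = cc,        # along rows
         `45` = r + cc,    # anti-diagonals, traversed up-right
         `135` = cc - r,   # diagonals, traversed down-right
         stop("direction must be one of 0, 45, 90, 135"))
}

#' Grey-level run-length matrix and features
#'
#' Counts maximal runs of equal grey level along a direction and evaluates
#' the 16 run-length features (short/long-run and low/high grey-level
#' emphases and their cross terms, grey-level and run-length
#' non-uniformities, run percentage, grey-level/run-length variances and
#' run entropy).
#'
#' @param disc a `discretized_roi`.
#' @param direction one of 0, 45, 90, 135 (degrees).
#' @return list with `R` (Ng x Lmax run-count matrix), `Nr` (total runs)
#'   and `features` (named numeric, 16, bare names).
#' @export
glrlm <- function(disc, direction = 0L) {
  stopifnot(inherits(disc, "discretized_roi"))
  lev <- disc$levels; Ng <- disc$Ng
  key <- .rlm_line_key(nrow(lev), ncol(lev), direction)
  lines <- split(as.vector(lev), as.vector(key))
  glv <- integer(0); lnv <- integer(0)
  for (ln in lines) {
    rl <- rle(ln)
    keep <- !is.na(rl$values)
    if (any(keep)) {
      glv <- c(glv, rl$values[keep])
      lnv <- c(lnv, rl$lengths[keep])
    }
  }
  np <- sum(!is.na(lev))
  if (!length(glv)) { # cannot happen for a valid mask
    R <- matrix(0, Ng, 1)
    return(list(R = R, Nr = 0,
                features = stats::setNames(numeric(16), .GLRLM_FEATURES)))
  }
  lmax <- max(lnv)
  R <- matrix(tabulate((glv - 1L) * lmax + lnv, nbins = Ng * lmax),
              Ng, lmax, byrow = TRUE)
  nr_runs <- sum(R)
  i <- row(R); j <- col(R)
  p <- R / nr_runs
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  ri <- rowSums(R); rj <- colSums(R)
  feats <- c(
    sre = sum(R / j^2) / nr_runs,
    lre = sum(R * j^2) / nr_runs,
    lgre = sum(R / i^2) / nr_runs,
    hgre = sum(R * i^2) / nr_runs,
    srlge = sum(R / (i^2 * j^2)) / nr_runs,
    srhge = sum(R * i^2 / j^2) / nr_runs,
    lrlge = sum(R * j^2 / i^2) / nr_runs,
    lrhge = sum(R * i^2 * j^2) / nr_runs,
    glnu = sum(ri^2) / nr_runs,
    glnu.norm = sum(ri^2) / nr_runs^2,
    rlnu = sum(rj^2) / nr_runs,
    rlnu.norm = sum(rj^2) / nr_runs^2,
    run.pct = nr_runs / np,
    gl.var = sum((i - mu_i)^2 * p),
    rl.var = sum((j - mu_j)^2 * p),
    rl.entr = .entropy2(p)
  )
  list(R = R, Nr = nr_runs, features = feats)
}

# all 64 catalog-named run-length features (16 per direction)
.glrlm_all <- function(disc) {
  unlist(lapply(.RLM_DIRECTIONS, function(d) {
    stats::setNames(glrlm(disc, d)$features,
                    paste0("F_rlm.", .GLRLM_FEATURES, ".", d))
  }))
}
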