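# internal helpers shared across modules

# 0 when the denominator vanishes; degenerate-texture fallback convention
.sdiv <- function(num, den) if (!is.finite(den) || den == 0) 0 else num / den

.entropy2 <- function(p) {
  p <- p[p > 0]
  if (!length(p)) return(0)
  -sum(p * log2(p))
}

.clip255 <- function(x) pmin(pmax(x, 0), 255)

# city-block distance transform inside a logical mask; border foreground
# pixels (adjacent to background or to the image edge) get distance 1.
# padded by one background ring so the image edge counts as border.
.chamfer_cityblock <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(0, nr + 2L, nc + 2L)
  padded[2:(nr + 1), 2:(nc + 1)] <- as.numeric(mask)
  d <- EBImage::imageData(EBImage::distmap(padded, metric = "manhattan"))
  matrix(d[2:(nr + 1), 2:(nc + 1)], nr, nc)
}

# sample from the values of v (not from 1:v when v is scalar)
.resample <- function(v, size, replace = FALSE) {
  v[sample.int(length(v), size, replace = replace)]
}

# 4-connected component labels of a logical matrix (EBImage::bwlabel)
.label4 <- function(mask) {
  EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
}
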