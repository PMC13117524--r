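# Independent naive oracle for flat grayscale morphology: per-pixel window
# extrema over the active structuring-element cells, with edge-clamped
# (replicated) borders. Deliberately written as nested loops, independent of
# the package's offset-shift implementation.

oracleExtremum <- function(m, mask, op) {
  s <- nrow(mask)
  r <- (s - 1L) %/% 2L
  h <- nrow(m); w <- ncol(m)
  out <- matrix(0, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    vals <- numeric(0)
    for (u in seq_len(s)) for (v in seq_len(s)) {
      if (!mask[u, v]) next
      ii <- min(max(i + u - r - 1L, 1L), h)
      jj <- min(max(j + v - r - 1L, 1L), w)
      vals <- c(vals, m[ii, jj])
    }
    out[i, j] <- op(vals)
  }
  out
}

oracleDilate <- function(m, mask) oracleExtremum(m, mask, max)
oracleErode <- function(m, mask) oracleExtremum(m, mask, min)
oracleOpen <- function(m, mask) oracleDilate(oracleErode(m, mask), mask)
oracleClose <- function(m, mask) oracleErode(oracleDilate(m, mask), mask)

randomUint8 <- function(h, w)
  matrix(as.double(sample(0:255, h * w, replace = TRUE)), h, w)
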