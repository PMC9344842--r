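# Independent oracles, deliberately implemented with different algorithms
# than the package internals.

# GF(2^8) multiplication by Russian-peasant shift-and-xor reduction with
# polynomial 0x11D (the package uses exp/log tables instead).
gf_mul_peasant <- function(a, b) {
  r <- 0L
  a <- as.integer(a); b <- as.integer(b)
  while (b > 0L) {
    if (bitwAnd(b, 1L) == 1L) r <- bitwXor(r, a)
    b <- bitwShiftR(b, 1L)
    a <- bitwShiftL(a, 1L)
    if (a > 255L) a <- bitwXor(a, 0x11DL)
  }
  r
}

# Straightforward systematic encoder built on the peasant multiplier:
# parity row j is the GF dot product of Cauchy coefficients with the data
# stripes, computed element by element.
oracle_encode <- function(payload, k, m) {
  L <- ceiling(length(payload) / k)
  padded <- c(as.integer(payload), integer(k * L - length(payload)))
  stripes <- matrix(padded, nrow = k, ncol = L, byrow = TRUE)
  x <- 0:(k - 1L); y <- k:(k + m - 1L)
  # coefficient 1/(x_i xor y_j) via brute-force inverse search
  inv_of <- function(v) which(vapply(1:255, function(c) gf_mul_peasant(v, c), integer(1)) == 1L)
  parity <- matrix(0L, nrow = m, ncol = L)
  for (j in seq_len(m)) {
    for (i in seq_len(k)) {
      coef <- inv_of(bitwXor(x[i], y[j]))
      parity[j, ] <- bitwXor(parity[j, ],
                             vapply(stripes[i, ], gf_mul_peasant, integer(1), b = coef))
    }
  }
  rbind(stripes, parity)
}
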