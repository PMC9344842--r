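## Arithmetic in GF(2^8) with reducing polynomial x^8+x^4+x^3+x^2+1 (0x11D),
## the field underlying the erasure code. Addition is XOR; multiplication
## goes through exponential/logarithm tables built once per session from
## repeated doubling by the primitive element 2.

.gf <- new.env(parent = emptyenv())

gf_tables <- function() {
  if (is.null(.gf$exp)) {
    expt <- integer(510)  # alpha^0 .. alpha^508, doubled to skip the mod 255
    logt <- integer(256)  # log[v + 1] = discrete log of v; v = 0 unused
    v <- 1L
    for (i in 0:254) {
      expt[i + 1L] <- v
      logt[v + 1L] <- i
      v <- bitwShiftL(v, 1L)
      if (v > 255L) v <- bitwXor(v, 0x11DL)
    }
    expt[256:510] <- expt[1:255]
    .gf$exp <- expt
    .gf$log <- logt
  }
  .gf
}

#' Multiply in GF(2^8)
#'
#' Multiplication in the 256-element finite field with reducing polynomial
#' `0x11D`, vectorized over both arguments (recycled). Addition in this
#' field is `bitwXor()`; together they carry the erasure code.
#'
#' @param a,b Integer vectors with elements in `[0, 255]`.
#' @return Integer vector of products in `[0, 255]`.
#' @export
#' @examples
#' gf_mul(7, 1)    # identity
#' gf_mul(129, 0)  # annihilator
gf_mul <- function(a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (anyNA(a) || anyNA(b) || any(a < 0L | a > 255L) || any(b < 0L | b > 255L))
    stop("gf_mul() arguments must be integers in [0, 255]")
  t <- gf_tables()
  out <- t$exp[t$log[a + 1L] + t$log[b + 1L] + 1L]
  out[a == 0L | b == 0L] <- 0L
  out
}

#' Multiplicative inverse in GF(2^8)
#'
#' @param a Integer vector with elements in `[1, 255]`; 0 has no inverse.
#' @return Integer vector of inverses.
#' @export
gf_inv <- function(a) {
  a <- as.integer(a)
  if (anyNA(a) || any(a < 1L | a > 255L))
    stop("gf_inv() arguments must be integers in [1, 255]")
  t <- gf_tables()
  t$exp[(255L - t$log[a + 1L]) %% 255L + 1L]
}

## C[j, i] = 1 / (x_i + y_j) with x_i = i - 1, y_j = k + j - 1: a Cauchy
## matrix, so every square submatrix of rbind(diag(k), C) is invertible for
## N = k + m <= 256 -- the maximum-distance-separable guarantee.
cauchy_matrix <- function(k, m) {
  x <- 0:(k - 1L)
  y <- k:(k + m - 1L)
  C <- matrix(0L, nrow = m, ncol = k)
  for (j in seq_len(m))
    C[j, ] <- gf_inv(bitwXor(x, y[j]))
  C
}

## A (r x k) %*% B (k x L) over GF(2^8)
gf_matmul <- function(A, B) {
  out <- matrix(0L, nrow = nrow(A), ncol = ncol(B))
  for (j in seq_len(nrow(A))) {
    acc <- integer(ncol(B))
    for (i in seq_len(ncol(A)))
      if (A[j, i] != 0L) acc <- bitwXor(acc, gf_mul(A[j, i], B[i, ]))
    out[j, ] <- acc
  }
  out
}

## Solve A X = B over GF(2^8) by Gaussian elimination with partial
## (nonzero) pivoting; A is k x k and invertible for every Cauchy-derived
## system the decoder builds.
gf_solve <- function(A, B) {
  k <- nrow(A)
  A <- A; B <- B
  for (col in seq_len(k)) {
    piv <- which(A[col:k, col] != 0L)[1]
    if (is.na(piv)) stop("singular system over GF(2^8)")
    piv <- piv + col - 1L
    if (piv != col) {
      A[c(col, piv), ] <- A[c(piv, col), ]
      B[c(col, piv), ] <- B[c(piv, col), ]
    }
    inv <- gf_inv(A[col, col])
    A[col, ] <- gf_mul(inv, A[col, ])
    B[col, ] <- gf_mul(inv, B[col, ])
    for (r in seq_len(k)) {
      if (r != col && A[r, col] != 0L) {
        f <- A[r, col]
        A[r, ] <- bitwXor(A[r, ], gf_mul(f, A[col, ]))
        B[r, ] <- bitwXor(B[r, ], gf_mul(f, B[col, ]))
      }
    }
  }
  B
}
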