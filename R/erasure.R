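## Systematic Reed-Solomon-style erasure code: a payload is zero-padded,
## split into k equal stripes (the data shards), and m parity shards are
## produced from a Cauchy-derived generator over GF(2^8). Any k of the
## N = k + m shards reconstruct the payload, so with the default k = m = N/2
## up to half of the storage devices can be lost.

#' Erasure-coding configuration
#'
#' `N = k + m` shards per object, reconstruction threshold `k`. The default
#' takes `k = m = N/2` (N even), giving tolerance of exactly half the
#' storage devices; `k = 1` degenerates to full replication.
#'
#' @param N Total shard count (storage devices used per object).
#' @param k Data shards; defaults to `N/2`.
#' @param m Parity shards; defaults to `N - k`.
#' @return A `storage_config`.
#' @export
storage_config <- function(N = 8L, k = NULL, m = NULL) {
  N <- as.integer(N)
  if (is.null(k) && is.null(m)) {
    if (N < 2L || N %% 2L != 0L)
      stop("default configuration needs an even N >= 2 (k = m = N/2)")
    k <- N %/% 2L
  }
  k <- as.integer(k %||% (N - as.integer(m)))
  m <- as.integer(m %||% (N - k))
  if (k < 1L) stop("k must be >= 1")
  if (m < 0L) stop("m must be >= 0")
  if (k + m != N) stop("N must equal k + m")
  if (N > 256L) stop("at most 256 shards are supported by GF(2^8)")
  structure(list(N = N, k = k, m = m), class = "storage_config")
}

#' @export
print.storage_config <- function(x, ...) {
  cat("<storage_config> N =", x$N, "(k =", x$k, "data +", x$m, "parity)\n")
  invisible(x)
}

new_shard <- function(object_id, shard_index, payload) {
  structure(
    list(object_id = object_id, shard_index = as.integer(shard_index),
         payload = payload, shard_digest = sha256_hex(payload)),
    class = "object_shard")
}

#' Erasure-encode a payload into N shards
#'
#' Systematic encoding: shards `0..k-1` are the zero-padded payload split
#' into k equal stripes; shards `k..N-1` are parity rows from the
#' Cauchy-derived generator. The manifest records the true payload size for
#' unpadding and the digest of every shard for corruption screening; the
#' object id is the SHA-256 of the payload itself (content addressing).
#'
#' @param payload Nonempty raw vector.
#' @param config A [storage_config()].
#' @return List with `shards` (list of N shard objects) and `manifest`
#'   (an `object_manifest`; its `placement` is filled by [put_object()]).
#' @export
encode_object <- function(payload, config = storage_config()) {
  stopifnot(inherits(config, "storage_config"))
  if (!is.raw(payload) || length(payload) == 0L)
    stop("payload must be a nonempty raw vector")
  k <- config$k; m <- config$m; N <- config$N
  L <- ceiling(length(payload) / k)
  padded <- c(as.integer(payload), integer(k * L - length(payload)))
  stripes <- matrix(padded, nrow = k, ncol = L, byrow = TRUE)
  rows <- if (m > 0L) rbind(stripes, gf_matmul(cauchy_matrix(k, m), stripes)) else stripes
  object_id <- sha256_hex(payload)
  shards <- lapply(seq_len(N), function(i)
    new_shard(object_id, i - 1L, as.raw(rows[i, ])))
  manifest <- structure(
    list(object_id = object_id, size = length(payload), config = config,
         shard_digests = vapply(shards, `[[`, character(1), "shard_digest"),
         placement = character(0)),
    class = "object_manifest")
  list(shards = shards, manifest = manifest)
}

#' @export
print.object_manifest <- function(x, ...) {
  cat("<object_manifest> ", substr(x$object_id, 1, 12), "..., ", x$size,
      " bytes, N = ", x$config$N, " (k = ", x$config$k, ")\n", sep = "")
  invisible(x)
}

#' Reconstruct a payload from a subset of its shards
#'
#' Shards whose digest does not match the manifest are excluded (corruption
#' is detected by digest, never trusted) and reported via the
#' `"excluded_shards"` attribute of the result. Reconstruction succeeds iff
#' at least `k` distinct valid shards remain; it solves the k-by-k
#' Cauchy-derived linear system over GF(2^8) by Gaussian elimination and
#' verifies the output digest against the object id.
#'
#' @param shards List of shard objects (any subset, any order).
#' @param manifest The object's `object_manifest`.
#' @return The original payload (raw vector).
#' @export
reconstruct_object <- function(shards, manifest) {
  k <- manifest$config$k
  seen <- integer(0)
  valid <- list()
  excluded <- character(0)
  for (s in shards) {
    if (!identical(s$object_id, manifest$object_id)) next
    idx <- s$shard_index
    if (idx %in% seen) next
    if (!identical(sha256_hex(s$payload), manifest$shard_digests[[idx + 1L]])) {
      excluded <- c(excluded, sprintf("shard %d digest mismatch", idx))
      next
    }
    seen <- c(seen, idx)
    valid[[length(valid) + 1L]] <- s
  }
  if (length(valid) < k)
    stop("insufficient-shards: have ", length(valid), " valid shard(s), need ",
         k, " (missing ", k - length(valid), ")",
         if (length(excluded)) paste0("; excluded: ", paste(excluded, collapse = ", ")))
  use <- valid[seq_len(k)]
  idx <- vapply(use, `[[`, integer(1), "shard_index")
  G <- rbind(diag(1L, k), if (manifest$config$m > 0L) cauchy_matrix(k, manifest$config$m))
  A <- G[idx + 1L, , drop = FALSE]
  B <- do.call(rbind, lapply(use, function(s) as.integer(s$payload)))
  stripes <- gf_solve(A, B)
  payload <- as.raw(as.integer(t(stripes)))[seq_len(manifest$size)]
  if (!identical(sha256_hex(payload), manifest$object_id))
    stop("reconstruction digest mismatch: recovered bytes do not match the object id")
  if (length(excluded)) attr(payload, "excluded_shards") <- excluded
  payload
}
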