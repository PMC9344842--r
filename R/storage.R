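## Simulated distributed object store: storage nodes grouped by
## organization, shards placed round-robin across organizations so that no
## single organization concentrates an object, and a staging namespace used
## by the upload lifecycle (shards are promoted only after the metadata
## commits).

#' Create a storage cluster
#'
#' @param nodes Data frame / tibble with columns `node_id` and `org_id`,
#'   one row per storage node.
#' @return A `storage_cluster` (environment with reference semantics).
#' @export
storage_cluster <- function(nodes) {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  stopifnot(all(c("node_id", "org_id") %in% names(nodes)),
            !anyDuplicated(nodes$node_id))
  cl <- new.env(parent = emptyenv())
  cl$nodes <- stats::setNames(
    lapply(seq_len(nrow(nodes)), function(i)
      list(node_id = nodes$node_id[i], org_id = nodes$org_id[i], status = "online")),
    nodes$node_id)
  cl$shards <- new.env(parent = emptyenv())    # "oid:idx" -> list(shard, node_id, staged)
  cl$manifests <- new.env(parent = emptyenv()) # object_id -> manifest (+ purged flag)
  class(cl) <- "storage_cluster"
  cl
}

#' @export
print.storage_cluster <- function(x, ...) {
  st <- vapply(x$nodes, `[[`, character(1), "status")
  cat("<storage_cluster>", length(x$nodes), "nodes (",
      sum(st == "online"), "online ), ",
      length(ls(x$shards)), "stored shard(s)\n")
  invisible(x)
}

shard_key <- function(object_id, shard_index) paste0(object_id, ":", shard_index)

#' Fail or restore a storage node
#'
#' A failed node serves nothing (its shards become unreachable) but its
#' stored bytes survive a later restore.
#'
#' @param cluster A `storage_cluster`.
#' @param node_id Node to change.
#' @return The cluster, invisibly.
#' @export
fail_storage_node <- function(cluster, node_id) {
  if (is.null(cluster$nodes[[node_id]])) stop("unknown storage node: ", node_id)
  cluster$nodes[[node_id]]$status <- "failed"
  invisible(cluster)
}

#' @rdname fail_storage_node
#' @export
restore_storage_node <- function(cluster, node_id) {
  if (is.null(cluster$nodes[[node_id]])) stop("unknown storage node: ", node_id)
  cluster$nodes[[node_id]]$status <- "online"
  invisible(cluster)
}

online_nodes <- function(cluster) {
  Filter(function(n) n$status == "online", cluster$nodes)
}

## Round-robin placement across organizations: shard i goes to the next
## organization in rotation that still has an unused online node and holds
## fewer than ceiling(N / n_orgs) shards of this object. Injective per
## object by construction.
plan_placement <- function(cluster, N) {
  on <- online_nodes(cluster)
  if (length(on) < N)
    stop("placement infeasible: need ", N, " online storage nodes, have ", length(on))
  orgs <- sort(unique(vapply(on, `[[`, character(1), "org_id")))
  cap <- ceiling(N / length(orgs))
  free <- lapply(orgs, function(o)
    sort(vapply(Filter(function(n) n$org_id == o, on), `[[`, character(1), "node_id")))
  names(free) <- orgs
  used <- stats::setNames(integer(length(orgs)), orgs)
  placement <- character(N)
  oi <- 0L
  for (i in seq_len(N)) {
    placed <- FALSE
    for (step in seq_along(orgs)) {
      o <- orgs[(oi + step - 1L) %% length(orgs) + 1L]
      if (used[[o]] < cap && length(free[[o]]) > 0L) {
        placement[i] <- free[[o]][1L]
        free[[o]] <- free[[o]][-1L]
        used[[o]] <- used[[o]] + 1L
        oi <- (oi + step) %% length(orgs)
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("placement infeasible: organization capacity exhausted")
  }
  stats::setNames(placement, as.character(0:(N - 1L)))
}

#' Store a payload as erasure-coded shards across the cluster
#'
#' Encodes, plans placement and writes one shard per storage node. Storing
#' a payload already present is deduplicated: the existing manifest is
#' returned (promoting it out of staging if needed).
#'
#' @param payload Nonempty raw vector.
#' @param cluster A `storage_cluster`.
#' @param config A [storage_config()].
#' @param staging Write to the staging namespace (not yet visible to
#'   [get_object()]) for later [promote_staging()] / [abort_staging()]?
#' @return The `object_manifest` (placement filled in).
#' @export
put_object <- function(payload, cluster, config = storage_config(), staging = FALSE) {
  object_id <- sha256_hex(payload)
  existing <- cluster$manifests[[object_id]]
  if (!is.null(existing) && !isTRUE(attr(existing, "purged"))) {
    if (!staging && isTRUE(attr(existing, "staged"))) promote_staging(cluster, object_id)
    return(cluster$manifests[[object_id]])
  }
  enc <- encode_object(payload, config)
  manifest <- enc$manifest
  manifest$placement <- plan_placement(cluster, config$N)
  for (s in enc$shards) {
    node_id <- manifest$placement[[as.character(s$shard_index)]]
    assign(shard_key(object_id, s$shard_index),
           list(shard = s, node_id = node_id, staged = staging),
           envir = cluster$shards)
  }
  attr(manifest, "staged") <- staging
  attr(manifest, "purged") <- FALSE
  cluster$manifests[[object_id]] <- manifest
  manifest
}

#' Promote or discard a staged object
#'
#' The upload lifecycle stages shards before the metadata commit and
#' promotes them after it, so a failed commit never leaves live shards.
#'
#' @param cluster A `storage_cluster`.
#' @param object_id Object to promote/discard.
#' @return The cluster, invisibly.
#' @export
promote_staging <- function(cluster, object_id) {
  m <- cluster$manifests[[object_id]]
  if (is.null(m)) stop("unknown object: ", object_id)
  for (i in 0:(m$config$N - 1L)) {
    key <- shard_key(object_id, i)
    ent <- get0(key, envir = cluster$shards)
    if (!is.null(ent)) { ent$staged <- FALSE; assign(key, ent, envir = cluster$shards) }
  }
  attr(m, "staged") <- FALSE
  cluster$manifests[[object_id]] <- m
  invisible(cluster)
}

#' @rdname promote_staging
#' @export
abort_staging <- function(cluster, object_id) {
  m <- cluster$manifests[[object_id]]
  if (is.null(m) || !isTRUE(attr(m, "staged"))) return(invisible(cluster))
  for (i in 0:(m$config$N - 1L))
    if (exists(shard_key(object_id, i), envir = cluster$shards))
      rm(list = shard_key(object_id, i), envir = cluster$shards)
  rm(list = object_id, envir = cluster$manifests)
  invisible(cluster)
}

#' Retrieve a payload from the cluster
#'
#' Gathers shards from online nodes per the manifest placement, screens
#' them against the manifest digests and reconstructs. Fails with a
#' `data-unavailable` error when fewer than `k` valid shards are reachable.
#'
#' @param manifest An `object_manifest`.
#' @param cluster A `storage_cluster`.
#' @return The payload (raw vector), byte-identical to what was stored.
#' @export
get_object <- function(manifest, cluster) {
  avail <- list()
  for (i in 0:(manifest$config$N - 1L)) {
    ent <- get0(shard_key(manifest$object_id, i), envir = cluster$shards)
    if (is.null(ent) || isTRUE(ent$staged)) next
    node <- cluster$nodes[[ent$node_id]]
    if (is.null(node) || node$status != "online") next
    avail[[length(avail) + 1L]] <- ent$shard
  }
  out <- tryCatch(reconstruct_object(avail, manifest), error = function(e) e)
  if (inherits(out, "error"))
    stop("data-unavailable: ", conditionMessage(out))
  attr(out, "excluded_shards") <- NULL
  out
}

#' Delete every shard of an object from every node
#'
#' The ledger (metadata) is untouched by design; after deletion the
#' manifest remains resolvable but is flagged purged, so downloads report
#' missing data rather than an opaque failure. Idempotent.
#'
#' @param cluster A `storage_cluster`.
#' @param object_id Object to purge.
#' @return The cluster, invisibly.
#' @export
purge_object <- function(cluster, object_id) {
  m <- cluster$manifests[[object_id]]
  if (is.null(m)) stop("unknown object: ", object_id)
  for (i in 0:(m$config$N - 1L))
    if (exists(shard_key(object_id, i), envir = cluster$shards))
      rm(list = shard_key(object_id, i), envir = cluster$shards)
  attr(m, "purged") <- TRUE
  cluster$manifests[[object_id]] <- m
  invisible(cluster)
}

#' Count of live (non-staged) shards held by the cluster
#' @param cluster A `storage_cluster`.
#' @param object_id Optional filter to one object.
#' @return Integer shard count.
#' @export
shard_count <- function(cluster, object_id = NULL) {
  keys <- ls(cluster$shards)
  if (!is.null(object_id)) keys <- keys[startsWith(keys, paste0(object_id, ":"))]
  sum(vapply(keys, function(k) !isTRUE(get(k, envir = cluster$shards)$staged), logical(1)))
}

#' Tabulate shard placement by node and organization
#' @param cluster A `storage_cluster`.
#' @return Tibble with `object_id`, `shard_index`, `node_id`, `org_id`, `staged`.
#' @export
shard_map <- function(cluster) {
  keys <- ls(cluster$shards)
  if (!length(keys))
    return(tibble::tibble(object_id = character(), shard_index = integer(),
                          node_id = character(), org_id = character(),
                          staged = logical()))
  rows <- lapply(keys, function(k) {
    ent <- get(k, envir = cluster$shards)
    tibble::tibble(object_id = ent$shard$object_id,
                   shard_index = ent$shard$shard_index,
                   node_id = ent$node_id,
                   org_id = cluster$nodes[[ent$node_id]]$org_id,
                   staged = isTRUE(ent$staged))
  })
  out <- do.call(rbind, rows)
  out[order(out$object_id, out$shard_index), ]
}
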