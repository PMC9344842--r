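## The platform facade ties the lifecycle together. Upload is
## metadata-first with staged storage: shards are written to a staging
## namespace, the transaction is endorsed and committed, and only then is
## staging promoted -- so a rejected or failed submission leaves neither
## ledger entries nor live shards. Download is search -> resolve ->
## reconstruct behind authentication and consortium membership.

#' Create a platform instance
#'
#' Builds the consortium network, the storage cluster and the template
#' registry (the three packaged templates are pre-registered).
#'
#' @param topology A [load_topology()] result; default reference topology.
#' @param config Erasure-coding [storage_config()] used for every payload.
#' @return A `fair_platform` (environment with reference semantics).
#' @export
create_platform <- function(topology = reference_topology(),
                            config = storage_config(8L)) {
  p <- new.env(parent = emptyenv())
  p$network <- build_network(topology)
  storage_nodes <- do.call(rbind, lapply(topology$organizations, function(org) {
    n <- org$storage_nodes %||% 0L
    if (n == 0L) return(NULL)
    data.frame(node_id = sprintf("%s-store%d", org$org_id, seq_len(n)),
               org_id = org$org_id, stringsAsFactors = FALSE)
  }))
  p$cluster <- storage_cluster(storage_nodes)
  p$config <- config
  for (t in c("dublin-core", "manufacture", "measurement"))
    register_template(p$network, builtin_template(t))
  class(p) <- "fair_platform"
  p
}

#' @export
print.fair_platform <- function(x, ...) {
  cat("<fair_platform>\n")
  print(x$network)
  print(x$cluster)
  invisible(x)
}

#' Authenticate a platform user
#'
#' Salted-hash credential check against the user registry.
#'
#' @param platform A `fair_platform`.
#' @param user_id,secret Credentials.
#' @return The user entry, invisibly; errors on failure.
#' @export
authenticate <- function(platform, user_id, secret) {
  u <- platform$network$users[[user_id]]
  if (is.null(u) || !identical(sha256_hex(paste0(u$salt, secret)), u$secret_hash))
    stop("authentication failure for user '", user_id, "'")
  invisible(u)
}

channel_of <- function(platform, channel_id = NULL) {
  channel_id %||% names(platform$network$channels)[1]
}

require_member <- function(platform, user, channel_id) {
  ch <- platform$network$channels[[channel_id]]
  if (!user$org_id %in% ch$member_org_ids)
    stop("permission error: organization '", user$org_id,
         "' is not a member of the consortium channel '", channel_id, "'")
  invisible(ch)
}

## The authoritative read view: the longest verify_chain-consistent replica
## on the channel.
platform_ledger <- function(platform, channel_id = NULL) {
  channel_id <- channel_of(platform, channel_id)
  ch <- platform$network$channels[[channel_id]]
  reps <- lapply(ch$evc_node_ids, function(n) platform$network$replicas[[n]])
  reps <- reps[order(vapply(reps, ledger_length, integer(1)), decreasing = TRUE)]
  for (r in reps) if (verify_chain(r)$consistent) return(r)
  stop("no consistent ledger replica available on channel ", channel_id)
}

#' Upload a (meta)data duple
#'
#' The full lifecycle: authenticate, stage the erasure-coded shards, run
#' the endorsement lifecycle on the version-1 transaction, and promote the
#' staged shards only after the commit. On rejection the staged shards are
#' discarded and the chain is untouched. Identical payloads are
#' deduplicated in storage (one object, many DIDs).
#'
#' @param platform A `fair_platform`.
#' @param user_id,secret Credentials of a consortium member.
#' @param record A `metadata_record`.
#' @param payload Nonempty raw vector (the data the metadata describes).
#' @param channel_id Channel to commit on (default: the first).
#' @return On commit: list with `did`, `version = 1`, `decision`,
#'   `manifest`. On rejection: list with `decision = "reject"`, `reason`
#'   and the `violations` tibble.
#' @export
upload <- function(platform, user_id, secret, record, payload, channel_id = NULL) {
  user <- authenticate(platform, user_id, secret)
  channel_id <- channel_of(platform, channel_id)
  require_member(platform, user, channel_id)
  data_digest <- sha256_hex(payload)
  did <- mint_did(data_digest, record_digest(record))
  pre_existing <- !is.null(platform$cluster$manifests[[data_digest]]) &&
    !isTRUE(attr(platform$cluster$manifests[[data_digest]], "staged"))
  manifest <- put_object(payload, platform$cluster, platform$config, staging = TRUE)
  draft <- ledger_transaction(did, 1L, record, data_digest, user_id)
  res <- tryCatch(submit_proposal(platform$network, draft, channel_id),
                  error = function(e) e)
  if (inherits(res, "error") || res$decision != "commit") {
    if (!pre_existing) abort_staging(platform$cluster, data_digest)
    if (inherits(res, "error")) stop(res)
    return(list(decision = "reject", reason = res$reason,
                violations = res$violations))
  }
  promote_staging(platform$cluster, data_digest)
  list(did = did, version = 1L, decision = "commit",
       manifest = platform$cluster$manifests[[data_digest]])
}

#' Download a (meta)data duple
#'
#' Resolves the requested (default latest) metadata version from the
#' ledger, then gathers and reconstructs the payload from the storage
#' cluster. Purged data is not an opaque failure: the metadata is returned
#' with `data_status = "missing"`.
#'
#' @param platform A `fair_platform`.
#' @param user_id,secret Credentials of a consortium member.
#' @param did The Data ID.
#' @param version Metadata version (default latest).
#' @param channel_id Channel to read (default: the first).
#' @return List: `record`, `payload` (raw or `NULL`), `data_status`
#'   (`"ok"` or `"missing"`), `data_digest`.
#' @export
download <- function(platform, user_id, secret, did, version = NULL,
                     channel_id = NULL) {
  user <- authenticate(platform, user_id, secret)
  channel_id <- channel_of(platform, channel_id)
  require_member(platform, user, channel_id)
  ledger <- platform_ledger(platform, channel_id)
  record <- get_version(ledger, did, version)
  data_digest <- version_history(ledger, did)$data_digest
  manifest <- platform$cluster$manifests[[data_digest]]
  if (is.null(manifest) || isTRUE(attr(manifest, "purged")))
    return(list(record = record, payload = NULL, data_status = "missing",
                data_digest = data_digest))
  payload <- get_object(manifest, platform$cluster)
  list(record = record, payload = payload, data_status = "ok",
       data_digest = data_digest)
}

#' Submit a revised metadata version for an existing DID
#'
#' The revision is re-validated through the full endorsement lifecycle as
#' if it were a new entry; on commit it becomes version n+1 with the DID's
#' unchanged data digest, and every prior version remains retrievable.
#'
#' @param platform A `fair_platform`.
#' @param user_id,secret Credentials of a consortium member.
#' @param did An existing DID.
#' @param new_record The revised `metadata_record`.
#' @param channel_id Channel to commit on (default: the first).
#' @return On commit: list with `did`, `version`. On rejection: list with
#'   `decision = "reject"`, `reason`, `violations`; the chain is unchanged.
#' @export
update_metadata <- function(platform, user_id, secret, did, new_record,
                            channel_id = NULL) {
  user <- authenticate(platform, user_id, secret)
  channel_id <- channel_of(platform, channel_id)
  require_member(platform, user, channel_id)
  ledger <- platform_ledger(platform, channel_id)
  hist <- version_history(ledger, did)
  draft <- ledger_transaction(did, max(hist$entries$version) + 1L, new_record,
                              hist$data_digest, user_id)
  res <- submit_proposal(platform$network, draft, channel_id)
  if (res$decision != "commit")
    return(list(decision = "reject", reason = res$reason,
                violations = res$violations))
  list(did = did, version = max(hist$entries$version) + 1L, decision = "commit")
}

#' @rdname version_history
#' @param platform A `fair_platform` (method for the platform's ledger view).
#' @export
platform_history <- function(platform, did) {
  version_history(platform_ledger(platform), did)
}

#' Purge the data of a DID from every storage node
#'
#' Admin-only. All shards of the underlying object are deleted everywhere;
#' the ledger is untouched, so the metadata keeps resolving and subsequent
#' downloads report the data as missing. Because storage is deduplicated
#' by content, every DID sharing the payload loses its data, and the
#' report lists all of them. Idempotent.
#'
#' @param platform A `fair_platform`.
#' @param user_id,secret Credentials of an admin user.
#' @param did The DID whose data to remove.
#' @return List: `status = "data-removed"`, `object_id`, `affected_dids`.
#' @export
purge_data <- function(platform, user_id, secret, did) {
  user <- authenticate(platform, user_id, secret)
  if (!isTRUE(user$admin))
    stop("permission error: purge requires admin privileges")
  ledger <- platform_ledger(platform)
  hist <- version_history(ledger, did)  # not-found error surfaces here
  txs <- ledger_transactions(ledger)
  affected <- sort(unique(txs$did[txs$data_digest == hist$data_digest]))
  purge_object(platform$cluster, hist$data_digest)
  list(status = "data-removed", object_id = hist$data_digest,
       affected_dids = affected)
}

#' Export selected DIDs to a fresh open ledger
#'
#' Re-packages every committed version of the selected DIDs, in source
#' chain order, into a new chain with a new genesis. Records are not
#' re-validated against templates (that happened at original submission),
#' but all block hashes are recomputed because the block order changes;
#' the result passes [verify_chain()].
#'
#' The open ledger is a distinct deployment: its genesis is stamped with
#' the export instant (not the consortium's shared epoch genesis), so the
#' exported chain carries fresh hashes even when every transaction is
#' exported -- which is exactly why provenance requires verifying the new
#' chain rather than reusing the source's hashes.
#'
#' @param source A `fair_ledger`, or a `fair_platform` (its authoritative
#'   ledger view is exported).
#' @param dids Character vector of DIDs to export; may be empty.
#' @param exported_at ISO 8601 UTC instant stamped on the new genesis;
#'   defaults, deterministically, to one second after the source tip's
#'   timestamp.
#' @return A fresh `fair_ledger` (replica id `"open"`).
#' @export
export_open_ledger <- function(source, dids, exported_at = NULL) {
  ledger <- if (inherits(source, "fair_platform")) platform_ledger(source) else source
  txs <- ledger_transactions(ledger)
  missing <- setdiff(dids, txs$did)
  if (length(missing))
    stop("unknown DID(s): ", paste(missing, collapse = ", "))
  if (is.null(exported_at)) {
    tip_ts <- ledger$blocks[[ledger_length(ledger)]]$timestamp
    exported_at <- utc_instant(as.numeric(as.POSIXct(tip_ts,
      format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) + 1)
  }
  open <- new_ledger(replica_id = "open")
  open$blocks[[1L]] <- new_block(0L, ZERO_DIGEST, exported_at, list())
  keep <- which(txs$did %in% dids)
  clock <- 0L
  for (i in keep) {
    blk <- ledger$blocks[[txs$block[i] + 1L]]
    tx <- blk$transactions[[txs$position[i]]]
    clock <- clock + 1L
    open <- append_block(open, list(tx), utc_instant(clock))
  }
  open
}
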