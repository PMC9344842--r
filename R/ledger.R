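## Append-only hash-chained block store that doubles as the metadata
## database. Blocks chain via SHA-256 over a canonical serialization, so
## every replica of a channel's ledger is byte-identical and any tampering
## surfaces as a localizable inconsistency.

bin2hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")

hex2bin <- function(h) {
  if (!nzchar(h)) return(raw(0))
  as.raw(strtoi(substring(h, seq(1, nchar(h), 2), seq(2, nchar(h), 2)), 16L))
}

#' Construct a ledger transaction
#'
#' One validated metadata version bound to a Data ID (DID): the unit stored
#' in blocks. The metadata digest is always recomputed from the record's
#' canonical bytes; the data digest addresses the immutable payload the
#' metadata describes and must be identical across all versions of a DID.
#'
#' @param did 32-hex-character Data ID (see [mint_did()]).
#' @param version Metadata version, integer >= 1.
#' @param record The committed `metadata_record`.
#' @param data_digest SHA-256 hex digest of the described payload.
#' @param submitter Submitting user id.
#' @param endorsements List of endorsement objects (see [endorse()]).
#' @return A `ledger_transaction`.
#' @export
ledger_transaction <- function(did, version, record, data_digest, submitter,
                               endorsements = list()) {
  stopifnot(inherits(record, "metadata_record"))
  if (!is_hex_digest(did, 32L)) stop("did must be 32 hex characters")
  if (!is_hex_digest(data_digest)) stop("data_digest must be 64 hex characters")
  version <- as.integer(version)
  if (is.na(version) || version < 1L) stop("version must be an integer >= 1")
  structure(
    list(did = did, version = version, record = record,
         metadata_digest = record_digest(record),
         data_digest = data_digest, submitter = submitter,
         template_id = record$template_id, endorsements = endorsements),
    class = "ledger_transaction")
}

serialize_endorsement <- function(e) {
  paste0("{\"node_id\":", json_str(e$node_id),
         ",\"verdict\":", if (isTRUE(e$verdict)) "true" else "false",
         ",\"signature\":", json_str(e$signature), "}")
}

serialize_transaction <- function(tx) {
  ends <- tx$endorsements
  if (length(ends)) {
    ord <- order(vapply(ends, `[[`, character(1), "node_id"), method = "radix")
    ends <- ends[ord]
  }
  paste0("{\"did\":", json_str(tx$did),
         ",\"version\":", tx$version,
         ",\"template_id\":", json_str(tx$template_id),
         ",\"submitter\":", json_str(tx$submitter),
         ",\"metadata_digest\":", json_str(tx$metadata_digest),
         ",\"data_digest\":", json_str(tx$data_digest),
         ",\"record\":", rawToChar(canonical_bytes(tx$record)),
         ",\"endorsements\":[",
         paste(vapply(ends, serialize_endorsement, character(1)), collapse = ","),
         "]}")
}

serialize_transaction_list <- function(transactions) {
  paste0("[", paste(vapply(transactions, serialize_transaction, character(1)),
                    collapse = ","), "]")
}

## payload_serialized: optional precomputed serialize_transaction_list()
## output, so the orderer can serialize once per commit while appending the
## same block to many replicas. verify_chain() always re-serializes.
new_block <- function(index, previous_hash, timestamp, transactions,
                      payload_serialized = NULL) {
  structure(
    list(index = as.integer(index), previous_hash = previous_hash,
         payload_hash = sha256_hex(payload_serialized %||%
                                     serialize_transaction_list(transactions)),
         timestamp = timestamp, transactions = transactions),
    class = "ledger_block")
}

#' Hash of a block's header
#'
#' The chaining function: SHA-256 over the canonical serialization of
#' `(index, previous_hash, payload_hash, timestamp)`. The payload hash in
#' turn covers the canonical serialization of the transaction list, so the
#' block hash commits to the block's entire content.
#'
#' @param block A `ledger_block`.
#' @return A 64-character hex digest.
#' @export
block_hash <- function(block) {
  sha256_hex(paste0("{\"index\":", block$index,
                    ",\"previous_hash\":", json_str(block$previous_hash),
                    ",\"payload_hash\":", json_str(block$payload_hash),
                    ",\"timestamp\":", json_str(block$timestamp), "}"))
}

#' Create an empty ledger (genesis block only)
#'
#' The genesis block has index 0, an all-zero previous hash, a fixed epoch
#' timestamp and no transactions, so independent deployments of the same
#' consortium share a common genesis.
#'
#' @param replica_id Identifier of the node holding this replica.
#' @return A `fair_ledger` of length 1.
#' @export
new_ledger <- function(replica_id = "replica-0") {
  structure(
    list(replica_id = replica_id,
         blocks = list(new_block(0L, ZERO_DIGEST, GENESIS_TIMESTAMP, list()))),
    class = "fair_ledger")
}

#' @export
print.fair_ledger <- function(x, ...) {
  n_tx <- sum(vapply(x$blocks, function(b) length(b$transactions), integer(1)))
  cat("<fair_ledger> replica ", x$replica_id, ": ", length(x$blocks),
      " blocks, ", n_tx, " transactions\n", sep = "")
  invisible(x)
}

#' Number of blocks in a ledger
#' @param ledger A `fair_ledger`.
#' @return Integer block count (genesis included).
#' @export
ledger_length <- function(ledger) length(ledger$blocks)

#' Hash of the ledger's tip block
#' @param ledger A `fair_ledger`.
#' @return A 64-character hex digest.
#' @export
ledger_tip_hash <- function(ledger) block_hash(ledger$blocks[[ledger_length(ledger)]])

## per-DID index of committed versions: list(did = list(max_version, data_digest))
ledger_did_state <- function(ledger) {
  state <- list()
  for (b in ledger$blocks) for (tx in b$transactions) {
    cur <- state[[tx$did]]
    if (is.null(cur)) {
      state[[tx$did]] <- list(max_version = tx$version, data_digest = tx$data_digest)
    } else {
      state[[tx$did]]$max_version <- max(cur$max_version, tx$version)
    }
  }
  state
}

#' Append a block of transactions to a ledger
#'
#' Enforces the version-control invariants before chaining: a version v >= 2
#' transaction requires version v-1 of the same DID already on the chain,
#' and the data digest of a DID can never change (metadata may be revised,
#' the data it points to may not). The block's `previous_hash` is the hash
#' of the current tip, so the chain invariant is preserved by construction.
#'
#' @param ledger A `fair_ledger`.
#' @param transactions Nonempty list of [ledger_transaction()] objects.
#' @param timestamp Orderer-assigned ISO 8601 UTC instant.
#' @param payload_serialized Optional precomputed canonical serialization
#'   of `transactions`, letting the orderer serialize once while appending
#'   one committed block to many replicas. Verification never trusts it.
#' @return The extended `fair_ledger`.
#' @export
append_block <- function(ledger, transactions, timestamp,
                         payload_serialized = NULL) {
  stopifnot(inherits(ledger, "fair_ledger"))
  if (length(transactions) == 0L) stop("cannot append an empty block")
  state <- ledger_did_state(ledger)
  for (tx in transactions) {
    if (!inherits(tx, "ledger_transaction")) stop("transactions must be ledger_transaction objects")
    if (tx$metadata_digest != record_digest(tx$record))
      stop("append rejected: metadata_digest does not match the record for DID ", tx$did)
    cur <- state[[tx$did]]
    if (is.null(cur)) {
      if (tx$version != 1L)
        stop("append rejected: first transaction for DID ", tx$did,
             " must be version 1, got ", tx$version)
      state[[tx$did]] <- list(max_version = tx$version, data_digest = tx$data_digest)
    } else {
      if (tx$version != cur$max_version + 1L)
        stop("append rejected: version gap for DID ", tx$did, " (have ",
             cur$max_version, ", got ", tx$version, ")")
      if (tx$data_digest != cur$data_digest)
        stop("append rejected: data_digest change for DID ", tx$did,
             " (the data a DID points to is immutable)")
      state[[tx$did]]$max_version <- tx$version
    }
  }
  n <- ledger_length(ledger)
  blk <- new_block(n, ledger_tip_hash(ledger), timestamp, transactions,
                   payload_serialized)
  ledger$blocks[[n + 1L]] <- blk
  ledger
}

## -- tamper detection -------------------------------------------------------

new_tamper_report <- function(findings) {
  structure(list(consistent = nrow(findings) == 0L, findings = findings),
            class = "tamper_report")
}

tamper_finding <- function(block, kind, message) {
  tibble::tibble(block = as.integer(block), kind = kind, message = message)
}

no_findings <- function() {
  tibble::tibble(block = integer(), kind = character(), message = character())
}

#' @export
print.tamper_report <- function(x, ...) {
  if (x$consistent) {
    cat("<tamper_report> consistent\n")
  } else {
    cat("<tamper_report> INCONSISTENT:", nrow(x$findings), "finding(s)\n")
    print(x$findings)
  }
  invisible(x)
}

#' @rdname verify_chain
#' @param x,... Report to tidy; unused.
#' @method tidy tamper_report
#' @export
tidy.tamper_report <- function(x, ...) x$findings

#' @method glance tamper_report
#' @export
glance.tamper_report <- function(x, ...) {
  tibble::tibble(consistent = x$consistent, n_findings = nrow(x$findings))
}

#' Verify a ledger's hash chain and localize inconsistencies
#'
#' Recomputes every block's payload hash from its stored transactions and
#' every chain link from the previous block's recomputed hash. Each
#' discrepancy yields a finding naming the earliest block at which it is
#' detectable: `payload-mismatch` (stored transactions no longer match the
#' committed payload hash), `broken-link` (a block's `previous_hash` does
#' not equal the hash of its predecessor, or the tip does not match
#' `tip_hash`), `bad-genesis` and `bad-index`.
#'
#' Corruption of the tip block's timestamp alters only the tip's own hash,
#' which no later block references; supplying the independently known
#' `tip_hash` (as replicas do during resynchronization) closes that gap.
#'
#' @param ledger A `fair_ledger`.
#' @param tip_hash Optional trusted hash of the tip block.
#' @return A `tamper_report`: `consistent` flag plus a tibble of findings
#'   `(block, kind, message)`; consistent iff no findings.
#' @export
verify_chain <- function(ledger, tip_hash = NULL) {
  f <- list()
  blocks <- ledger$blocks
  n <- length(blocks)
  if (n == 0L)
    return(new_tamper_report(tamper_finding(0L, "bad-genesis", "ledger has no blocks")))
  g <- blocks[[1L]]
  if (!identical(g$previous_hash, ZERO_DIGEST))
    f[[length(f) + 1L]] <- tamper_finding(0L, "bad-genesis",
                                          "genesis previous_hash is not all zeros")
  if (length(g$transactions) != 0L)
    f[[length(f) + 1L]] <- tamper_finding(0L, "bad-genesis",
                                          "genesis block carries transactions")
  for (i in seq_len(n)) {
    b <- blocks[[i]]
    if (!identical(as.integer(b$index), i - 1L))
      f[[length(f) + 1L]] <- tamper_finding(i - 1L, "bad-index",
                                            sprintf("block at position %d has index %s", i - 1L, b$index))
    recomputed <- sha256_hex(serialize_transaction_list(b$transactions))
    if (!identical(recomputed, b$payload_hash))
      f[[length(f) + 1L]] <- tamper_finding(i - 1L, "payload-mismatch",
                                            sprintf("block %d payload hash does not match its transactions", i - 1L))
    if (i > 1L && !identical(b$previous_hash, block_hash(blocks[[i - 1L]])))
      f[[length(f) + 1L]] <- tamper_finding(i - 1L, "broken-link",
                                            sprintf("block %d previous_hash does not match block %d", i - 1L, i - 2L))
  }
  if (!is.null(tip_hash) && !identical(block_hash(blocks[[n]]), tip_hash))
    f[[length(f) + 1L]] <- tamper_finding(n - 1L, "broken-link",
                                          "tip block hash does not match the trusted tip digest")
  new_tamper_report(if (length(f)) do.call(rbind, f) else no_findings())
}

## -- search -----------------------------------------------------------------

#' All transactions of a ledger as a tibble
#'
#' @param ledger A `fair_ledger`.
#' @return A tibble with one row per transaction in chain order: `block`,
#'   `position`, `did`, `version`, `template_id`, `submitter`,
#'   `metadata_digest`, `data_digest` and a list-column `record`.
#' @export
ledger_transactions <- function(ledger) {
  rows <- list()
  for (b in ledger$blocks) {
    for (p in seq_along(b$transactions)) {
      tx <- b$transactions[[p]]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        block = b$index, position = p, did = tx$did, version = tx$version,
        template_id = tx$template_id, submitter = tx$submitter,
        metadata_digest = tx$metadata_digest, data_digest = tx$data_digest,
        record = list(tx$record))
    }
  }
  if (!length(rows))
    return(tibble::tibble(block = integer(), position = integer(),
                          did = character(), version = integer(),
                          template_id = character(), submitter = character(),
                          metadata_digest = character(), data_digest = character(),
                          record = list()))
  do.call(rbind, rows)
}

#' @method tidy fair_ledger
#' @export
tidy.fair_ledger <- function(x, ...) ledger_transactions(x)

#' @method glance fair_ledger
#' @export
glance.fair_ledger <- function(x, ...) {
  txs <- ledger_transactions(x)
  tibble::tibble(replica_id = x$replica_id, n_blocks = ledger_length(x),
                 n_transactions = nrow(txs), n_dids = length(unique(txs$did)),
                 tip_hash = ledger_tip_hash(x))
}

#' Search the ledger's metadata database
#'
#' Exact, case-insensitive match of every query pair against the committed
#' record values. The ledger is the authoritative metadata database: the
#' scan runs over the chain itself, in block order.
#'
#' @param ledger A `fair_ledger`.
#' @param query Named list/vector of field = value pairs; an empty query
#'   matches everything.
#' @param latest_only Keep only the highest committed version per DID?
#' @return A tibble in the shape of [ledger_transactions()], ordered by
#'   `(block, position)`.
#' @export
search_ledger <- function(ledger, query = list(), latest_only = FALSE) {
  txs <- ledger_transactions(ledger)
  if (nrow(txs) == 0L) return(txs)
  query <- as.list(query)
  if (length(query)) {
    keep <- vapply(txs$record, function(rec) {
      all(vapply(names(query), function(k) {
        v <- rec$values[[k]]
        !is.null(v) && tolower(as.character(v)) == tolower(as.character(query[[k]]))
      }, logical(1)))
    }, logical(1))
    txs <- txs[keep, , drop = FALSE]
  }
  if (latest_only && nrow(txs) > 0L) {
    latest <- tapply(txs$version, txs$did, max)
    txs <- txs[txs$version == latest[txs$did], , drop = FALSE]
  }
  txs
}

## -- persistence ------------------------------------------------------------

serialize_block <- function(block) {
  paste0("{\"index\":", block$index,
         ",\"previous_hash\":", json_str(block$previous_hash),
         ",\"payload_hash\":", json_str(block$payload_hash),
         ",\"timestamp\":", json_str(block$timestamp),
         ",\"transactions\":", serialize_transaction_list(block$transactions), "}")
}

#' Write a ledger to a JSON Lines file
#'
#' One canonical block object per line; replicas fed the same block
#' sequence produce bit-identical files.
#'
#' @param ledger A `fair_ledger`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ledger <- function(ledger, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (b in ledger$blocks)
    writeLines(serialize_block(b), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

## Rebuild a transaction exactly as stored, without re-validation, so a
## tampered file can still be loaded and then flagged by verify_chain().
deserialize_transaction <- function(d) {
  structure(
    list(did = d$did, version = as.integer(d$version),
         record = metadata_record(d$record$template_id,
                                  lapply(d$record$values, as.character)),
         metadata_digest = d$metadata_digest, data_digest = d$data_digest,
         submitter = d$submitter, template_id = d$template_id,
         endorsements = lapply(d$endorsements, function(e)
           list(node_id = e$node_id, verdict = isTRUE(e$verdict),
                signature = e$signature))),
    class = "ledger_transaction")
}

#' Read a ledger from a JSON Lines file
#'
#' Blocks are loaded exactly as stored (no invariants enforced), so a
#' tampered file can be inspected with [verify_chain()].
#'
#' @param path File written by [write_ledger()].
#' @param replica_id Replica identifier for the in-memory copy.
#' @return A `fair_ledger`.
#' @export
read_ledger <- function(path, replica_id = "loaded") {
  lines <- readLines(path, encoding = "UTF-8")
  blocks <- lapply(lines, function(ln) {
    d <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    structure(
      list(index = as.integer(d$index), previous_hash = d$previous_hash,
           payload_hash = d$payload_hash, timestamp = d$timestamp,
           transactions = lapply(d$transactions, deserialize_transaction)),
      class = "ledger_block")
  })
  structure(list(replica_id = replica_id, blocks = blocks), class = "fair_ledger")
}
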