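## Simulated permissioned consortium: organizations, channels, EVC
## (endorser-validator-committer) nodes holding ledger replicas, and a
## single orderer per channel with a logical clock. Consensus is
## proof-of-authority style: a proposal commits iff a strict majority of
## ALL registered EVC nodes on the channel return signed true verdicts --
## offline nodes count against the quorum, signatures that fail to verify
## are discarded before counting.

#' Load a consortium topology configuration
#'
#' YAML or JSON with keys `consortium_id`, `channels` (each
#' `channel_id` + member `organizations`), `organizations` (each `org_id`,
#' `domain_name`, `evc_nodes`, `storage_nodes`) and `users` (each
#' `user_id`, `org_id`, `secret`, `admin`).
#'
#' @param source Path to a YAML/JSON file, or an equivalent nested list.
#' @return A `topology` object.
#' @export
load_topology <- function(source) {
  cfg <- if (is.list(source)) source
    else if (grepl("\\.json$", source)) jsonlite::fromJSON(source, simplifyVector = FALSE)
    else yaml::read_yaml(source)
  stopifnot(!is.null(cfg$consortium_id), length(cfg$organizations) > 0L,
            length(cfg$channels) > 0L)
  org_ids <- vapply(cfg$organizations, `[[`, character(1), "org_id")
  if (anyDuplicated(org_ids)) stop("duplicate org_id in topology")
  for (ch in cfg$channels) {
    miss <- setdiff(unlist(ch$organizations), org_ids)
    if (length(miss))
      stop("channel ", ch$channel_id, " references unknown organization(s): ",
           paste(miss, collapse = ", "))
  }
  structure(cfg, class = "topology")
}

#' The packaged reference topology
#'
#' Three organizations in a single channel and consortium, two EVC nodes
#' and three storage nodes per organization, one orderer.
#'
#' @return A `topology`.
#' @export
reference_topology <- function() {
  load_topology(system.file("extdata", "topology.yaml",
                            package = "fairledger", mustWork = TRUE))
}

EVC_STATUSES <- c("honest-online", "offline", "malicious")

#' Build an in-process consortium network from a topology
#'
#' Instantiates every EVC node with a fresh Ed25519 keypair and a genesis
#' ledger replica, one orderer (logical clock) per channel, and the user
#' registry with salted credential hashes. The network is an environment:
#' operations like [inject_fault()] and [submit_proposal()] mutate it in
#' place.
#'
#' @param topology A [load_topology()] result (default: the reference
#'   topology).
#' @return An `evc_network`.
#' @export
build_network <- function(topology = reference_topology()) {
  net <- new.env(parent = emptyenv())
  net$topology <- topology
  net$consortium_id <- topology$consortium_id
  net$orgs <- stats::setNames(topology$organizations,
                              vapply(topology$organizations, `[[`, character(1), "org_id"))
  net$evc_nodes <- list()
  net$replicas <- new.env(parent = emptyenv())
  for (org in topology$organizations) {
    for (i in seq_len(org$evc_nodes %||% 1L)) {
      node_id <- sprintf("%s-evc%d", org$org_id, i)
      key <- openssl::ed25519_keygen()
      net$evc_nodes[[node_id]] <- list(
        node_id = node_id, org_id = org$org_id, status = "honest-online",
        key = key, pubkey = key$pubkey)
      net$replicas[[node_id]] <- new_ledger(replica_id = node_id)
    }
  }
  net$channels <- stats::setNames(
    lapply(topology$channels, function(ch) {
      member_orgs <- unlist(ch$organizations)
      list(channel_id = ch$channel_id, member_org_ids = member_orgs,
           evc_node_ids = names(Filter(function(n) n$org_id %in% member_orgs,
                                       net$evc_nodes)))
    }),
    vapply(topology$channels, `[[`, character(1), "channel_id"))
  net$orderers <- new.env(parent = emptyenv())
  for (cid in names(net$channels)) net$orderers[[cid]] <- list(clock = 0L)
  net$users <- list()
  for (u in topology$users %||% list()) {
    salt <- sha256_hex(paste0("salt:", u$user_id))
    net$users[[u$user_id]] <- list(
      user_id = u$user_id, org_id = u$org_id,
      salt = salt, secret_hash = sha256_hex(paste0(salt, u$secret)),
      admin = isTRUE(u$admin))
  }
  net$templates <- list()
  class(net) <- "evc_network"
  net
}

#' @export
print.evc_network <- function(x, ...) {
  cat("<evc_network> consortium ", x$consortium_id, ": ",
      length(x$orgs), " orgs, ", length(x$evc_nodes), " EVC nodes, ",
      length(x$channels), " channel(s)\n", sep = "")
  invisible(x)
}

#' Register a metadata template with every endorser
#'
#' @param network An `evc_network`.
#' @param template A `metadata_template`.
#' @return The network, invisibly.
#' @export
register_template <- function(network, template) {
  network$templates[[template$template_id]] <- template
  invisible(network)
}

#' Network status as a tibble
#' @param network An `evc_network`.
#' @return Tibble with `node_id`, `org_id`, `status`, `replica_blocks`.
#' @export
network_status <- function(network) {
  ids <- names(network$evc_nodes)
  tibble::tibble(
    node_id = ids,
    org_id = unname(vapply(network$evc_nodes, `[[`, character(1), "org_id")),
    status = unname(vapply(network$evc_nodes, `[[`, character(1), "status")),
    replica_blocks = unname(vapply(ids, function(i)
      ledger_length(network$replicas[[i]]), integer(1))))
}

#' Digest an endorsement proposal
#'
#' The canonical digest every endorser signs: SHA-256 over the proposal's
#' identifying fields and the record's canonical bytes.
#'
#' @param draft A `ledger_transaction` draft (endorsements may be empty).
#' @return A 64-character hex digest.
#' @export
proposal_digest <- function(draft) {
  sha256_hex(paste0("{\"did\":", json_str(draft$did),
                    ",\"version\":", draft$version,
                    ",\"template_id\":", json_str(draft$template_id),
                    ",\"submitter\":", json_str(draft$submitter),
                    ",\"metadata_digest\":", json_str(draft$metadata_digest),
                    ",\"data_digest\":", json_str(draft$data_digest), "}"))
}

endorsement_message <- function(digest, verdict) {
  charToRaw(paste0(digest, ":", if (isTRUE(verdict)) "true" else "false"))
}

#' Endorse a transaction proposal
#'
#' The endorsement computation of one EVC node. An offline node returns
#' `NULL` (no endorsement; it counts against the quorum). An honest online
#' node validates the record against the registered templates and signs its
#' verdict; a malicious node signs `TRUE` regardless of validity -- the
#' endorse-everything fault model, caught downstream by the majority rule.
#'
#' @param node An EVC node entry (from `network$evc_nodes`).
#' @param draft A `ledger_transaction` draft.
#' @param templates Named list of registered `metadata_template`s.
#' @return An endorsement (`node_id`, `proposal_digest`, `verdict`,
#'   `signature` hex, `violations` tibble) or `NULL`.
#' @export
endorse <- function(node, draft, templates) {
  if (node$status == "offline") return(NULL)
  digest <- proposal_digest(draft)
  if (node$status == "malicious") {
    verdict <- TRUE
    violations <- no_violations()
  } else {
    report <- validate_record(draft$record, templates)
    ok_digest <- identical(draft$metadata_digest, record_digest(draft$record))
    verdict <- report$valid && ok_digest
    violations <- report$violations
  }
  sig <- openssl::ed25519_sign(endorsement_message(digest, verdict), node$key)
  list(node_id = node$node_id, proposal_digest = digest, verdict = verdict,
       signature = bin2hex(sig), violations = violations)
}

verify_endorsement <- function(e, pubkey) {
  tryCatch(
    openssl::ed25519_verify(endorsement_message(e$proposal_digest, e$verdict),
                            hex2bin(e$signature), pubkey),
    error = function(err) FALSE)
}

#' Majority decision over a set of endorsements
#'
#' Proof-of-authority quorum rule: commit iff the number of
#' signature-verified, verdict-true endorsements is strictly greater than
#' half of ALL registered EVC nodes on the channel. Absent (offline) nodes
#' therefore count against the quorum, and endorsements whose signatures do
#' not verify are discarded before counting -- the system stays live and
#' sound as long as a strict majority of the validators is available and
#' honest.
#'
#' @param endorsements List of endorsements for one proposal digest
#'   (`NULL` entries allowed).
#' @param n_registered Count of registered EVC nodes on the channel.
#' @param pubkeys Named list of node public keys for signature checks.
#' @return List: `decision` (`"commit"`/`"reject"`), `reason`, `n_true`,
#'   `n_registered`.
#' @export
decide <- function(endorsements, n_registered, pubkeys = NULL) {
  n_registered <- as.integer(n_registered)
  if (is.na(n_registered) || n_registered < 1L)
    stop("configuration error: a committing channel needs at least one EVC node")
  endorsements <- Filter(Negate(is.null), endorsements)
  if (length(endorsements)) {
    digests <- unique(vapply(endorsements, `[[`, character(1), "proposal_digest"))
    if (length(digests) > 1L) stop("endorsements span multiple proposals")
  }
  if (!is.null(pubkeys)) {
    endorsements <- Filter(function(e) {
      pk <- pubkeys[[e$node_id]]
      !is.null(pk) && verify_endorsement(e, pk)
    }, endorsements)
  }
  n_true <- sum(vapply(endorsements, function(e) isTRUE(e$verdict), logical(1)))
  commit <- n_true > n_registered / 2
  list(decision = if (commit) "commit" else "reject",
       reason = sprintf("%d of %d registered endorser-validators returned a valid true verdict (need > %s)",
                        n_true, n_registered, format(n_registered / 2)),
       n_true = n_true, n_registered = n_registered)
}

#' Submit a transaction proposal through the ordering service
#'
#' The full endorsement lifecycle: the proposal is broadcast to every EVC
#' node of the channel, endorsements are collected and the majority rule
#' applied; on commit the orderer assigns a logical-clock timestamp,
#' packages one block and appends it to the replica of every non-offline
#' node (offline nodes catch up via [resync()]).
#'
#' @param network An `evc_network`.
#' @param draft A `ledger_transaction` draft (no endorsements).
#' @param channel_id Channel to commit on (default: the first).
#' @return List: `decision`, `reason`, `violations` (tibble from an honest
#'   endorsement when rejected), `block_index` (on commit).
#' @export
submit_proposal <- function(network, draft, channel_id = NULL) {
  channel_id <- channel_id %||% names(network$channels)[1]
  ch <- network$channels[[channel_id]]
  if (is.null(ch)) stop("unknown channel: ", channel_id)
  sub <- network$users[[draft$submitter]]
  if (is.null(sub) || !sub$org_id %in% ch$member_org_ids)
    stop("permission error: submitter '", draft$submitter,
         "' is not a registered user of a member organization")
  ends <- lapply(network$evc_nodes[ch$evc_node_ids], endorse,
                 draft = draft, templates = network$templates)
  pubkeys <- lapply(network$evc_nodes[ch$evc_node_ids], `[[`, "pubkey")
  verdict <- decide(ends, n_registered = length(ch$evc_node_ids), pubkeys = pubkeys)
  if (verdict$decision != "commit") {
    honest <- Filter(function(e) !is.null(e) && nrow(e$violations) > 0L, ends)
    verdict$violations <- if (length(honest)) honest[[1]]$violations else no_violations()
    return(verdict)
  }
  ord <- network$orderers[[channel_id]]
  ord$clock <- ord$clock + 1L
  network$orderers[[channel_id]] <- ord
  tx <- draft
  tx$endorsements <- lapply(Filter(Negate(is.null), ends), function(e)
    list(node_id = e$node_id, verdict = e$verdict, signature = e$signature))
  targets <- ch$evc_node_ids[vapply(ch$evc_node_ids, function(nid)
    network$evc_nodes[[nid]]$status != "offline", logical(1))]
  ts <- utc_instant(ord$clock)
  tx_ser <- serialize_transaction_list(list(tx))
  ## dry-run the chain invariants (version contiguity, immutable data
  ## digest) on the first replica so a bad draft rejects atomically
  first <- tryCatch(append_block(network$replicas[[targets[1]]], list(tx), ts,
                                 payload_serialized = tx_ser),
                    error = function(e) e)
  if (inherits(first, "error")) {
    verdict$decision <- "reject"
    verdict$reason <- conditionMessage(first)
    verdict$violations <- no_violations()
    return(verdict)
  }
  network$replicas[[targets[1]]] <- first
  block_index <- ledger_length(first) - 1L
  for (nid in targets[-1])
    network$replicas[[nid]] <- append_block(network$replicas[[nid]], list(tx), ts,
                                            payload_serialized = tx_ser)
  verdict$violations <- no_violations()
  verdict$block_index <- block_index
  verdict
}

#' Change an EVC node's fault status
#'
#' @param network An `evc_network`.
#' @param node_id Node to change.
#' @param status `"honest-online"`, `"offline"` or `"malicious"`. Idempotent.
#' @return The network, invisibly.
#' @export
inject_fault <- function(network, node_id, status) {
  status <- match.arg(status, EVC_STATUSES)
  if (is.null(network$evc_nodes[[node_id]])) stop("unknown node: ", node_id)
  network$evc_nodes[[node_id]]$status <- status
  invisible(network)
}

#' Resynchronize a returning node's ledger replica
#'
#' Adopts the longest replica among the channel's other non-offline nodes
#' that passes [verify_chain()]; a candidate that fails verification is
#' refused and reported, never silently adopted. A node that missed no
#' blocks is left unchanged.
#'
#' @param network An `evc_network`.
#' @param node_id Node returning from `offline`.
#' @param channel_id Channel whose ledger to adopt (default: the first).
#' @return The adopted `fair_ledger`, invisibly.
#' @export
resync <- function(network, node_id, channel_id = NULL) {
  channel_id <- channel_id %||% names(network$channels)[1]
  ch <- network$channels[[channel_id]]
  if (is.null(network$evc_nodes[[node_id]])) stop("unknown node: ", node_id)
  peers <- setdiff(ch$evc_node_ids, node_id)
  peers <- peers[vapply(peers, function(p)
    network$evc_nodes[[p]]$status != "offline", logical(1))]
  candidates <- lapply(peers, function(p) network$replicas[[p]])
  ord <- order(vapply(candidates, ledger_length, integer(1)), decreasing = TRUE)
  reports <- list()
  for (i in ord) {
    cand <- candidates[[i]]
    rep <- verify_chain(cand)
    if (rep$consistent) {
      if (ledger_length(cand) > ledger_length(network$replicas[[node_id]])) {
        adopted <- cand
        adopted$replica_id <- node_id
        network$replicas[[node_id]] <- adopted
      }
      return(invisible(network$replicas[[node_id]]))
    }
    reports[[peers[i]]] <- rep
  }
  if (length(reports)) {
    msgs <- vapply(names(reports), function(p)
      sprintf("%s: %d finding(s)", p, nrow(reports[[p]]$findings)), character(1))
    stop("resync failure: every candidate replica is inconsistent [",
         paste(msgs, collapse = "; "), "]")
  }
  invisible(network$replicas[[node_id]])
}

#' Sweep consensus liveness across availability levels
#'
#' Builds one channel with `n_nodes` EVC nodes, then for each availability
#' count sets exactly that many nodes honest-online (the rest offline) and
#' submits one valid fixture record, recording whether the proposal
#' commits. With the strict-majority rule the commit boundary sits at the
#' smallest count exceeding half the registered nodes.
#'
#' @param n_nodes Registered EVC nodes on the channel.
#' @param counts Honest-online counts to test (default `0:n_nodes`).
#' @return A `liveness_sweep` tibble: `honest_online`, `pct_online`,
#'   `committed`.
#' @export
liveness_sweep <- function(n_nodes = 100L, counts = NULL) {
  counts <- counts %||% 0:n_nodes
  topo <- list(
    consortium_id = "sweep",
    channels = list(list(channel_id = "main", organizations = list("org1"))),
    organizations = list(list(org_id = "org1", domain_name = "org1.example",
                              evc_nodes = as.integer(n_nodes), storage_nodes = 0L)),
    users = list(list(user_id = "sweeper", org_id = "org1",
                      secret = "s", admin = FALSE)))
  net <- build_network(load_topology(topo))
  register_template(net, builtin_template("manufacture"))
  corpus <- generate_corpus(seed = 1L, n_records = 1L, phases = "manufacture")
  rec <- corpus$record[[1]]
  node_ids <- names(net$evc_nodes)
  out <- lapply(counts, function(a) {
    for (i in seq_along(node_ids))
      inject_fault(net, node_ids[i], if (i <= a) "honest-online" else "offline")
    payload <- charToRaw(sprintf("sweep-%03d", a))
    dd <- sha256_hex(payload)
    draft <- ledger_transaction(mint_did(dd, record_digest(rec)), 1L, rec,
                                dd, "sweeper")
    res <- submit_proposal(net, draft)
    tibble::tibble(honest_online = as.integer(a),
                   pct_online = 100 * a / n_nodes,
                   committed = identical(res$decision, "commit"))
  })
  structure(do.call(rbind, out), class = c("liveness_sweep", class(tibble::tibble())))
}

#' @rdname liveness_sweep
#' @param object A `liveness_sweep` tibble.
#' @param ... Unused.
#' @method autoplot liveness_sweep
#' @export
autoplot.liveness_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$honest_online,
                                       y = as.integer(.data$committed))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "honest-online EVC nodes",
                  y = "proposal commits (0/1)",
                  title = "Proof-of-authority liveness boundary") +
    ggplot2::theme_minimal()
}
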