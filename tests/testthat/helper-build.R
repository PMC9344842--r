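# Builders shared across the suite. Everything is generated in code; no
# stored fixtures.

# A fully populated Dublin Core record (valid against the base template).
base_record <- function(overrides = list(), template_id = "dublin-core") {
  values <- stats::setNames(as.list(paste0("value-", tolower(dublin_core_elements()))),
                            dublin_core_elements())
  values$Date <- "2022-03-15"
  values$Language <- "en"
  values$Identifier <- "rec-001"
  values[names(overrides)] <- overrides
  metadata_record(template_id, values)
}

# Compact records for ledger-structure tests (the chain does not validate
# against templates; schema checks happen at endorsement).
mini_record <- function(i, extra = list()) {
  values <- list(Title = sprintf("entry %02d", i), Creator = "someone",
                 Date = "2022-01-01")
  values[names(extra)] <- extra
  metadata_record("mini", values)
}

mini_tx <- function(i, version = 1L, payload = NULL, record = NULL,
                    endorsements = list()) {
  payload <- payload %||% charToRaw(sprintf("payload-%02d", i))
  record <- record %||% mini_record(i)
  dd <- sha256_hex(payload)
  ledger_transaction(mint_did(dd, record_digest(record)), version, record, dd,
                     submitter = "tester", endorsements = endorsements)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# n_blocks non-genesis blocks, one transaction each, deterministic
# timestamps; optionally a dummy endorsement on every other block so the
# endorsement serialization is swept too.
make_chain <- function(n_blocks, with_endorsements = FALSE) {
  led <- new_ledger("test")
  for (i in seq_len(n_blocks)) {
    ends <- if (with_endorsements && i %% 2L == 0L)
      list(list(node_id = "node-a", verdict = TRUE,
                signature = strrep(sprintf("%02x", i), 8L)))
    else list()
    led <- append_block(led, list(mini_tx(i, endorsements = ends)),
                        utc_instant(i))
  }
  led
}

# Reference topology plus one organization outside the channel (and its
# user), for permission tests.
topology_with_outsider <- function() {
  topo <- unclass(reference_topology())
  topo$organizations <- c(topo$organizations, list(
    list(org_id = "outsider-org", domain_name = "outsider.example",
         evc_nodes = 1L, storage_nodes = 0L)))
  topo$users <- c(topo$users, list(
    list(user_id = "eve", org_id = "outsider-org", secret = "eve-secret",
         admin = FALSE)))
  load_topology(topo)
}

first_evc <- function(platform_or_net) {
  net <- if (inherits(platform_or_net, "fair_platform")) platform_or_net$network
         else platform_or_net
  net$evc_nodes[[1]]
}

valid_manufacture_record <- function(i = 1L) {
  rec <- generate_corpus(seed = 100L + i, n_records = 1L,
                         phases = "manufacture")$record[[1]]
  # manufacture fixtures share their protocol constants; make each helper
  # call a distinct record so DIDs differ across submissions
  rec$values$Identifier <- sprintf("fiber-manufacture-x%03d", i)
  rec$values$Title <- sprintf("Fiber manufacture run x%03d", i)
  rec
}
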