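ref_net <- function() {
  net <- build_network(reference_topology())
  register_template(net, builtin_template("dublin-core"))
  register_template(net, builtin_template("manufacture"))
  register_template(net, builtin_template("measurement"))
  net
}

draft_for <- function(record, submitter = "alice", payload = charToRaw("data")) {
  dd <- sha256_hex(payload)
  ledger_transaction(mint_did(dd, record_digest(record)), 1L, record, dd, submitter)
}

test_that("endorsement verdicts follow node status and validation outcome", {
  net <- ref_net()
  node <- first_evc(net)
  good <- draft_for(valid_manufacture_record())
  e <- endorse(node, good, net$templates)
  expect_true(e$verdict)
  expect_identical(decide(list(e), 1L, list(`uni-london-evc1` = node$pubkey))$decision,
                   "commit")

  bad_rec <- valid_manufacture_record()
  bad_rec$values$Language <- "english"
  bad <- draft_for(bad_rec)
  e_bad <- endorse(node, bad, net$templates)
  expect_false(e_bad$verdict)
  expect_true("bad-language-code" %in% e_bad$violations$kind)

  inject_fault(net, node$node_id, "malicious")
  e_mal <- endorse(net$evc_nodes[[node$node_id]], bad, net$templates)
  expect_true(e_mal$verdict)  # endorse-everything fault model

  inject_fault(net, node$node_id, "offline")
  expect_null(endorse(net$evc_nodes[[node$node_id]], good, net$templates))

  # a proposal naming an unregistered template draws an honest false verdict
  ghost <- draft_for(metadata_record("ghost", list(Title = "x")))
  e_ghost <- endorse(net$evc_nodes$`hospital-oslo-evc1`, ghost, net$templates)
  expect_false(e_ghost$verdict)
  expect_identical(e_ghost$violations$kind, "unknown-template")
})

test_that("the majority rule requires a strict majority of registered nodes", {
  mk <- function(verdicts) lapply(seq_along(verdicts), function(i)
    list(node_id = sprintf("n%d", i), proposal_digest = strrep("a", 64),
         verdict = verdicts[i], signature = ""))
  expect_identical(decide(mk(rep(TRUE, 4)), 6L)$decision, "commit")   # 4 > 3
  expect_identical(decide(mk(rep(TRUE, 3)), 6L)$decision, "reject")   # 3 is not > 3
  expect_identical(decide(mk(TRUE), 1L)$decision, "commit")
  expect_identical(decide(mk(c(TRUE, TRUE, FALSE)), 3L)$decision, "commit")  # 2 > 1.5
  expect_identical(decide(mk(c(TRUE, TRUE)), 4L)$decision, "reject")         # 2 is not > 2
  # absent endorsements count against the quorum
  expect_identical(decide(list(NULL, NULL, mk(TRUE)[[1]]), 3L)$decision, "reject")
  expect_error(decide(list(), 0L), "configuration error")
  two <- c(mk(TRUE), lapply(mk(TRUE), function(e) { e$proposal_digest <- strrep("b", 64); e }))
  expect_error(decide(two, 2L), "multiple proposals")
})

test_that("endorsements with tampered signatures never count toward quorum", {
  net <- ref_net()
  good <- draft_for(valid_manufacture_record())
  ch <- net$channels$main
  ends <- lapply(net$evc_nodes[ch$evc_node_ids], endorse,
                 draft = good, templates = net$templates)
  pubkeys <- lapply(net$evc_nodes[ch$evc_node_ids], `[[`, "pubkey")
  expect_identical(decide(ends, 6L, pubkeys)$decision, "commit")
  # tamper 3 signatures: only 3 verifiable true verdicts remain, not > 3
  for (i in 1:3) ends[[i]]$signature <- strrep("00", 64)
  v <- decide(ends, 6L, pubkeys)
  expect_identical(v$decision, "reject")
  expect_identical(v$n_true, 3L)
  # flipping a verdict after signing also invalidates the endorsement
  ends2 <- lapply(net$evc_nodes[ch$evc_node_ids], endorse,
                  draft = good, templates = net$templates)
  ends2[[1]]$verdict <- FALSE
  expect_identical(decide(ends2, 6L, pubkeys)$n_true, 5L)
})

test_that("committed proposals reach every online replica identically", {
  net <- ref_net()
  res <- submit_proposal(net, draft_for(valid_manufacture_record()))
  expect_identical(res$decision, "commit")
  st <- network_status(net)
  expect_identical(st$replica_blocks, rep(2L, 6))
  files <- vapply(st$node_id, function(n) {
    f <- tempfile(); write_ledger(net$replicas[[n]], f); f
  }, character(1))
  contents <- lapply(files, readLines)
  for (i in 2:6) expect_identical(contents[[i]], contents[[1]])
})

test_that("invalid records leave no trace on any replica", {
  net <- ref_net()
  bad_rec <- valid_manufacture_record()
  bad_rec$values$Language <- "eng"
  res <- submit_proposal(net, draft_for(bad_rec))
  expect_identical(res$decision, "reject")
  expect_true("bad-language-code" %in% res$violations$kind)
  expect_identical(network_status(net)$replica_blocks, rep(1L, 6))
})

test_that("commits resume exactly at the quorum boundary", {
  net <- ref_net()
  ids <- names(net$evc_nodes)
  for (n in ids[1:3]) inject_fault(net, n, "offline")
  expect_identical(submit_proposal(net, draft_for(valid_manufacture_record(1)))$decision,
                   "reject")
  inject_fault(net, ids[1], "honest-online")  # 4 of 6 online: 4 > 3
  expect_identical(submit_proposal(net, draft_for(valid_manufacture_record(2)))$decision,
                   "commit")
})

test_that("fault injection is idempotent and reversible; no quorum when all offline", {
  net <- ref_net()
  n1 <- names(net$evc_nodes)[1]
  inject_fault(net, n1, "offline")
  inject_fault(net, n1, "offline")
  inject_fault(net, n1, "honest-online")
  expect_identical(net$evc_nodes[[n1]]$status, "honest-online")
  expect_error(inject_fault(net, "ghost-node", "offline"), "unknown node")
  for (n in names(net$evc_nodes)) inject_fault(net, n, "offline")
  expect_identical(submit_proposal(net, draft_for(valid_manufacture_record()))$decision,
                   "reject")
})

test_that("a malicious minority cannot push invalid metadata through", {
  net <- ref_net()
  ids <- names(net$evc_nodes)
  for (n in ids[1:2]) inject_fault(net, n, "malicious")  # ceiling(6/2) - 1 = 2
  bad_rec <- valid_manufacture_record()
  bad_rec$values$cell_type <- "NIH3T3"
  res <- submit_proposal(net, draft_for(bad_rec))
  expect_identical(res$decision, "reject")
  expect_identical(res$n_true, 2L)
  expect_identical(network_status(net)$replica_blocks, rep(1L, 6))
})

test_that("with an honest majority no invalid fixture record is ever committed", {
  net <- ref_net()
  inject_fault(net, names(net$evc_nodes)[1], "malicious")
  corpus <- generate_corpus(seed = 77L, n_records = 10L,
                            corruption = c("drop-required", "bad-language",
                                           "off-vocabulary", "bad-date", "bad-number"))
  for (i in seq_len(nrow(corpus))) {
    res <- submit_proposal(net, draft_for(corpus$record[[i]],
                                          payload = corpus$payload[[i]]))
    expect_identical(res$decision, "reject")
  }
  expect_identical(network_status(net)$replica_blocks, rep(1L, 6))
})

test_that("a node offline during commits converges after resync", {
  net <- ref_net()
  ids <- names(net$evc_nodes)
  inject_fault(net, ids[6], "offline")
  for (i in 1:3)
    expect_identical(submit_proposal(net, draft_for(valid_manufacture_record(i)))$decision,
                     "commit")
  expect_identical(ledger_length(net$replicas[[ids[6]]]), 1L)
  inject_fault(net, ids[6], "honest-online")
  resync(net, ids[6])
  expect_identical(ledger_length(net$replicas[[ids[6]]]), 4L)
  fa <- tempfile(); fb <- tempfile()
  write_ledger(net$replicas[[ids[6]]], fa)
  write_ledger(net$replicas[[ids[1]]], fb)
  expect_identical(readLines(fa), readLines(fb))
  # no missed blocks: resync is a no-op
  before <- net$replicas[[ids[6]]]
  resync(net, ids[6])
  expect_identical(net$replicas[[ids[6]]], before)
})

test_that("resync refuses tampered candidate replicas", {
  net <- ref_net()
  ids <- names(net$evc_nodes)
  inject_fault(net, ids[1], "offline")
  submit_proposal(net, draft_for(valid_manufacture_record()))
  # corrupt every peer replica so no candidate verifies
  for (n in ids[-1]) {
    led <- net$replicas[[n]]
    led$blocks[[2]]$transactions[[1]]$record$values$Title <- "forged"
    net$replicas[[n]] <- led
  }
  inject_fault(net, ids[1], "honest-online")
  expect_error(resync(net, ids[1]), "resync failure")
  expect_identical(ledger_length(net$replicas[[ids[1]]]), 1L)
})

test_that("submitters must belong to a member organization", {
  net <- build_network(topology_with_outsider())
  register_template(net, builtin_template("manufacture"))
  expect_error(submit_proposal(net, draft_for(valid_manufacture_record(), submitter = "eve")),
               "permission error")
  expect_error(submit_proposal(net, draft_for(valid_manufacture_record(), submitter = "mallory")),
               "permission error")
})

test_that("the liveness boundary sits at a strict majority on a small channel", {
  sw <- liveness_sweep(10)
  expect_identical(sw$committed, sw$honest_online >= 6L)
  expect_s3_class(autoplot(sw), "ggplot")
})
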