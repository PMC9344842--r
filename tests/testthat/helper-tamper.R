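# Enumerate single-character corruptions of every serialized field of every
# block: character positions of string fields are substituted one at a time
# (with a character guaranteed to differ), integer fields are bumped by one.
# Returns a list of (label, mutated ledger) pairs.

substitute_char <- function(s, pos) {
  ch <- substr(s, pos, pos)
  repl <- if (ch == "0") "1" else "0"
  substr(s, pos, pos) <- repl
  s
}

string_mutations <- function(s) lapply(seq_len(nchar(s)), function(p) substitute_char(s, p))

ledger_mutations <- function(ledger) {
  out <- list()
  add <- function(label, led) out[[length(out) + 1L]] <<- list(label = label, ledger = led)
  for (bi in seq_along(ledger$blocks)) {
    b <- ledger$blocks[[bi]]
    # integer field
    led <- ledger; led$blocks[[bi]]$index <- b$index + 1L
    add(sprintf("block %d index", bi - 1L), led)
    for (field in c("previous_hash", "payload_hash", "timestamp")) {
      for (mut in string_mutations(b[[field]])) {
        led <- ledger; led$blocks[[bi]][[field]] <- mut
        add(sprintf("block %d %s", bi - 1L, field), led)
      }
    }
    for (ti in seq_along(b$transactions)) {
      tx <- b$transactions[[ti]]
      led <- ledger; led$blocks[[bi]]$transactions[[ti]]$version <- tx$version + 1L
      add(sprintf("block %d tx %d version", bi - 1L, ti), led)
      for (field in c("did", "template_id", "submitter", "metadata_digest",
                      "data_digest")) {
        for (mut in string_mutations(tx[[field]])) {
          led <- ledger; led$blocks[[bi]]$transactions[[ti]][[field]] <- mut
          add(sprintf("block %d tx %d %s", bi - 1L, ti, field), led)
        }
      }
      for (vn in names(tx$record$values)) {
        for (mut in string_mutations(tx$record$values[[vn]])) {
          led <- ledger
          led$blocks[[bi]]$transactions[[ti]]$record$values[[vn]] <- mut
          add(sprintf("block %d tx %d record[%s]", bi - 1L, ti, vn), led)
        }
      }
      for (ei in seq_along(tx$endorsements)) {
        for (mut in string_mutations(tx$endorsements[[ei]]$signature)) {
          led <- ledger
          led$blocks[[bi]]$transactions[[ti]]$endorsements[[ei]]$signature <- mut
          add(sprintf("block %d tx %d endorsement %d", bi - 1L, ti, ei), led)
        }
      }
    }
  }
  out
}
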