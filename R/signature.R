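# Signature grammar shared by the simulator truth and the classifier.
#
# A signature is a hyphen-joined token string over
#   {DEL, INS, DUP, INV, INVDUP, DUPn (n >= 3)}
# with tokens in reference order and unchanged flanks omitted, e.g.
# "DEL-INV-DEL". A call is complex (CSV) iff it has more than two
# breakpoints; breakpoint multiplicities per event class are:
#   DEL 2, INS 1, INV 2, tandem DUP (2 copies) 2, DUPn n, INVDUP 3,
#   template switch 4 (two target edges + two donor edges).
# Lone DEL/INS/INV/DUP therefore stay simple while inverted duplications,
# higher-copy duplications, distal template switches and any multi-event
# cluster are complex.

# tokens for one event; `kind` uses the simulator/candidate vocabulary
event_tokens <- function(kind, ref_len = 0L, copies = 2L, min_sv = 50L) {
  switch(kind,
    DEL = "DEL",
    INS = "INS",
    INV = "INV",
    TANDEM_DUP = ,
    DUP = if (copies <= 2L) "DUP" else paste0("DUP", copies),
    INV_DUP = ,
    INVDUP = "INVDUP",
    DISTAL_SWITCH = ,
    TEMPLATE_SWITCH = if (ref_len >= min_sv) c("DEL", "INS") else "INS",
    stop("unknown event kind: ", kind))
}

# breakpoint positions (with multiplicity) for one event
event_breakpoints <- function(kind, start, end, copies = 2L,
                              donor_start = NA_integer_,
                              donor_end = NA_integer_) {
  switch(kind,
    DEL = c(start, end),
    INS = start,
    INV = c(start, end),
    TANDEM_DUP = ,
    DUP = if (copies <= 2L) c(start, end)
          else c(start, end, rep(end, copies - 2L)),
    INV_DUP = ,
    INVDUP = c(start, end, end),
    DISTAL_SWITCH = ,
    TEMPLATE_SWITCH = {
      bp <- c(start, end)
      if (!is.na(donor_start)) bp <- c(bp, donor_start, donor_end)
      bp
    },
    stop("unknown event kind: ", kind))
}

# Breakpoint count of an event cluster: positions shared between events
# (e.g. the boundary between an adjacent deletion and inversion) count once;
# within-event multiplicity (INVDUP's doubled end, DUPn's repeated junction)
# is preserved. `bp_list` is one breakpoint vector per event.
count_breakpoints <- function(bp_list) {
  if (!length(bp_list)) return(list(n = 0L, positions = integer(0)))
  pos <- sort(unique(unlist(bp_list)))
  mult <- vapply(pos, function(p) {
    max(vapply(bp_list, function(b) sum(b == p), integer(1)))
  }, integer(1))
  list(n = sum(mult), positions = pos)
}

#' Canonical signature string from event tokens
#'
#' @param tokens character vector of signature tokens in reference order.
#' @return hyphen-joined canonical signature.
#' @export
signature_string <- function(tokens) {
  tokens <- tokens[nzchar(tokens)]
  if (!length(tokens)) return("")
  paste(tokens, collapse = "-")
}

# Cluster events (rows with start/end footprints, sorted by start) whose
# reference footprints lie within `merge_adjacent` bp of each other.
cluster_events <- function(starts, ends, merge_adjacent) {
  n <- length(starts)
  if (n == 0L) return(integer(0))
  o <- order(starts, ends)
  cl <- integer(n)
  cl[o[1L]] <- 1L
  hi <- ends[o[1L]]
  for (i in seq_len(n - 1L)) {
    j <- o[i + 1L]
    if (starts[j] - hi <= merge_adjacent) {
      cl[j] <- cl[o[i]]
    } else {
      cl[j] <- cl[o[i]] + 1L
    }
    hi <- max(hi, ends[j])
  }
  cl
}
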