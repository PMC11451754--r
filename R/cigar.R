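# CIGAR machinery over the extended ops {=, X, I, D}. All coordinates are
# 0-based half-open; CIGARs are stored in alignment orientation (reference
# forward; query reverse-complemented for minus-strand records).

QUERY_OPS <- c("=", "X", "I")
REF_OPS <- c("=", "X", "D")

cigar_parse <- function(cig) {
  if (is.na(cig) || !nzchar(cig)) {
    return(data.frame(len = integer(0), op = character(0)))
  }
  lens <- as.integer(regmatches(cig, gregexpr("[0-9]+", cig))[[1]])
  ops <- regmatches(cig, gregexpr("[=XIDM]", cig))[[1]]
  if (length(lens) != length(ops)) stop("malformed CIGAR: ", cig)
  data.frame(len = lens, op = ops, stringsAsFactors = FALSE)
}

# Collapse adjacent runs of the same op and drop zero-length runs.
cigar_string <- function(len, op) {
  keep <- len > 0L
  len <- len[keep]; op <- op[keep]
  if (!length(len)) return("")
  r <- rle(op)
  ends <- cumsum(r$lengths)
  starts <- c(1L, head(ends, -1L) + 1L)
  lens <- vapply(seq_along(starts),
                 function(i) sum(as.numeric(len[starts[i]:ends[i]])),
                 numeric(1))
  paste0(lens, r$values, collapse = "")
}

cigar_consumed <- function(cig) {
  p <- cigar_parse(cig)
  list(q = sum(p$len[p$op %in% QUERY_OPS]),
       r = sum(p$len[p$op %in% REF_OPS]),
       match = sum(p$len[p$op == "="]),
       mismatch = sum(p$len[p$op == "X"]),
       gap = sum(p$len[p$op %in% c("I", "D")]))
}

# Emit =/X runs by direct comparison of two equal-length strings.
cigar_compare <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  if (!nchar(a)) return(data.frame(len = integer(0), op = character(0)))
  eq <- utf8ToInt(a) == utf8ToInt(b)
  r <- rle(eq)
  data.frame(len = r$lengths, op = ifelse(r$values, "=", "X"),
             stringsAsFactors = FALSE)
}

# Cut `n` query bases from the left or right (alignment orientation) of a
# parsed CIGAR; returns list(tab, qcut, rcut) with reference bases removed
# alongside. Dangling D runs at the cut edge are removed too.
cigar_cut_aln <- function(tab, n, side = c("left", "right")) {
  side <- match.arg(side)
  if (side == "right") {
    tab <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
  }
  qcut <- 0L; rcut <- 0L; i <- 1L
  while (qcut < n && i <= nrow(tab)) {
    op <- tab$op[i]; len <- tab$len[i]
    if (op %in% QUERY_OPS) {
      take <- min(len, n - qcut)
      qcut <- qcut + take
      if (op %in% REF_OPS) rcut <- rcut + take
      tab$len[i] <- len - take
      if (tab$len[i] > 0L) break
    } else {  # D consumes reference only
      rcut <- rcut + len
      tab$len[i] <- 0L
    }
    i <- i + 1L
  }
  # strip leading zero-length runs and any now-dangling D at the edge
  tab <- tab[tab$len > 0L, , drop = FALSE]
  while (nrow(tab) && tab$op[1L] == "D") {
    rcut <- rcut + tab$len[1L]
    tab <- tab[-1L, , drop = FALSE]
  }
  if (side == "right") {
    tab <- tab[rev(seq_len(nrow(tab))), , drop = FALSE]
  }
  list(tab = tab, qcut = qcut, rcut = rcut)
}

# Needleman-Wunsch global alignment with configurable unit scores, returning
# the CIGAR run table in {=, X, I, D} (I consumes `a`, the query; D consumes
# `b`, the reference) plus the optimal score. Deterministic tie-break:
# diagonal, then D (gap in query), then I.
nw_align <- function(a, b, match = 0L, mismatch = -1L, gap = -1L) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0L && m == 0L) {
    return(list(tab = data.frame(len = integer(0), op = character(0)),
                score = 0))
  }
  if (n == 0L) {
    return(list(tab = data.frame(len = m, op = "D"), score = m * gap))
  }
  if (m == 0L) {
    return(list(tab = data.frame(len = n, op = "I"), score = n * gap))
  }
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  # score matrix rows over b (reference), vectorised over a
  S <- matrix(0, nrow = n + 1L, ncol = m + 1L)
  S[, 1L] <- (0:n) * gap
  S[1L, ] <- (0:m) * gap
  for (j in seq_len(m)) {
    sub <- ifelse(av == bv[j], match, mismatch)
    prev <- S[, j]
    cur <- numeric(n + 1L)
    cur[1L] <- j * gap
    # row-wise dependence on cur[i-1] prevents full vectorisation; do the
    # diagonal/up part vectorised and resolve the left-dependence in a loop
    diag_up <- pmax(prev[1:n] + sub, prev[2:(n + 1L)] + gap)
    for (i in seq_len(n)) {
      cur[i + 1L] <- max(diag_up[i], cur[i] + gap)
    }
    S[, j + 1L] <- cur
  }
  # traceback
  ops <- character(n + m); k <- 0L
  i <- n; j <- m
  while (i > 0L || j > 0L) {
    k <- k + 1L
    if (i > 0L && j > 0L &&
        S[i + 1L, j + 1L] ==
          S[i, j] + (if (av[i] == bv[j]) match else mismatch)) {
      ops[k] <- if (av[i] == bv[j]) "=" else "X"
      i <- i - 1L; j <- j - 1L
    } else if (j > 0L && S[i + 1L, j + 1L] == S[i + 1L, j] + gap) {
      ops[k] <- "D"
      j <- j - 1L
    } else {
      ops[k] <- "I"
      i <- i - 1L
    }
  }
  r <- rle(rev(ops[seq_len(k)]))
  list(tab = data.frame(len = r$lengths, op = r$values,
                        stringsAsFactors = FALSE),
       score = S[n + 1L, m + 1L])
}
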