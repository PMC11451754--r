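# VCF 4.2 output/input for resolved and merged calls. One record per call
# (composite variants stay single records with their signature in INFO);
# POS uses the 1-based anchor-base convention for symbolic alleles.

#' Write calls as VCF 4.2
#'
#' INFO carries SVTYPE, SVLEN, END, SIG (signature string), SEGS (segment
#' tiling `start-end:strand:role`), MIMIC, and — when present — AF and the
#' carrier list.
#'
#' @param calls resolved or merged call data frame.
#' @param ref reference `genome_sequence` (for anchor bases).
#' @param path output path.
#' @export
write_vcf <- function(calls, ref, path) {
  rseq <- as_seq(ref)
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", seq_name(ref, "ref"), nchar(rseq)),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Variant class\">",
    "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"Signed length change\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position (1-based inclusive)\">",
    "##INFO=<ID=SIG,Number=1,Type=String,Description=\"Composite signature\">",
    "##INFO=<ID=NBP,Number=1,Type=Integer,Description=\"Breakpoint count\">",
    "##INFO=<ID=SEGS,Number=1,Type=String,Description=\"Segment tiling start-end:strand:role\">",
    "##INFO=<ID=MIMIC,Number=0,Type=Flag,Description=\"Alignment footprint mimics a simple SV\">",
    "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Allele count\">",
    "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Allele frequency\">",
    "##INFO=<ID=CARRIERS,Number=1,Type=String,Description=\"Carrier haplotypes\">",
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Source sample and haplotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- vapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    anchor0 <- max(0L, call$pos - 1L)
    refbase <- subseq0(rseq, anchor0, anchor0 + 1L)
    if (!nzchar(refbase)) stop("missing reference base at ", call$pos)
    alt <- paste0("<", gsub("-", ":", call$svtype), ">")
    segs <- call$segments[[1L]]
    seg_str <- if (!is.null(segs) && nrow(segs)) {
      paste(sprintf("%s-%s:%s:%s",
                    ifelse(is.na(segs$start), "ins", segs$start),
                    ifelse(is.na(segs$end), nchar(segs$seq), segs$end),
                    segs$strand, segs$role), collapse = ",")
    } else "."
    info <- c(sprintf("SVTYPE=%s", call$svtype),
              sprintf("SVLEN=%d", call$svlen),
              sprintf("END=%d", call$end),
              sprintf("SIG=%s", call$signature),
              sprintf("NBP=%d", call$n_breakpoints),
              sprintf("SEGS=%s", seg_str))
    if (isTRUE(call$mimic)) info <- c(info, "MIMIC")
    if (!is.null(call$allele_count)) {
      info <- c(info, sprintf("AC=%d", call$allele_count))
    }
    if (!is.null(call$af)) info <- c(info, sprintf("AF=%.6g", call$af))
    if (!is.null(call$carriers)) {
      info <- c(info, sprintf("CARRIERS=%s",
                              paste(call$carriers[[1L]], collapse = "|")))
    } else {
      info <- c(info, sprintf("SAMPLE=%s#%d", call$sample, call$hap))
    }
    paste(call$rname, anchor0 + 1L, sprintf("sv%04d", i), refbase, alt,
          ".", "PASS", paste(info, collapse = ";"), sep = "\t")
  }, character(1))
  writeLines(c(hdr, body), path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF path.
#' @return call data frame (0-based half-open `pos`/`end`).
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  get_info <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(?:^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_,
           character(1))
  }
  if (!length(body)) return(empty_calls())
  f <- do.call(rbind, strsplit(body, "\t", fixed = TRUE))
  info <- f[, 8L]
  pos1 <- as.integer(f[, 2L])
  out <- data.frame(
    rname = f[, 1L],
    pos = pos1,  # anchor base is pos1 (1-based) => variant starts at 0-based pos1
    end = as.integer(get_info(info, "END")),
    svtype = get_info(info, "SVTYPE"),
    signature = get_info(info, "SIG"),
    svlen = as.integer(get_info(info, "SVLEN")),
    n_breakpoints = as.integer(get_info(info, "NBP")),
    mimic = grepl("(^|;)MIMIC(;|$)", info),
    stringsAsFactors = FALSE)
  out$complex <- out$n_breakpoints > 2L
  ac <- get_info(info, "AC")
  if (any(!is.na(ac))) out$allele_count <- as.integer(ac)
  af <- get_info(info, "AF")
  if (any(!is.na(af))) out$af <- as.numeric(af)
  carriers <- get_info(info, "CARRIERS")
  if (any(!is.na(carriers))) {
    out$carriers <- lapply(carriers, function(x) {
      if (is.na(x)) character(0) else strsplit(x, "|", fixed = TRUE)[[1]]
    })
  }
  smp <- get_info(info, "SAMPLE")
  if (any(!is.na(smp))) {
    parts <- strsplit(smp, "#", fixed = TRUE)
    out$sample <- vapply(parts, `[`, character(1), 1L)
    out$hap <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  out
}
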