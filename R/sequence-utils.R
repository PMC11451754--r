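#' @importFrom stats setNames quantile median
#' @importFrom utils head tail read.delim write.table
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A/C/G/T/N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  stringi::stri_reverse(chartr("ACGTNacgtn", "TGCANtgcan", x))
}

#' Random DNA sequence
#'
#' Bases are drawn i.i.d.; `gc` sets the total probability of G+C (split
#' evenly between G and C, likewise A and T).
#'
#' @param n sequence length in bp.
#' @param gc GC content in `[0, 1]`; default 0.5 (uniform).
#' @return a single character string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) {
  stopifnot(n >= 0, gc >= 0, gc <= 1)
  if (n == 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# Run code with a fixed RNG state, restoring the caller's stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# 0-based half-open substring.
subseq0 <- function(seq, start, end) {
  if (end <= start) return("")
  substr(seq, start + 1L, end)
}

# All k-mers of a sequence as a character vector (position i -> 0-based i-1).
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  starts <- seq_len(n - k + 1L)
  substring(seq, starts, starts + k - 1L)
}

#' Construct a genome sequence
#'
#' A named DNA sequence over A/C/G/T/N, uppercase and nonempty.
#'
#' @param name sequence identifier.
#' @param seq DNA string.
#' @return an object of class `genome_sequence` with elements `name`, `seq`.
#' @export
genome_sequence <- function(name, seq) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  seq <- toupper(seq)
  if (grepl("[^ACGTN]", seq)) {
    stop("sequence contains characters outside A/C/G/T/N")
  }
  structure(list(name = name, seq = seq), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat(sprintf("<genome_sequence> %s (%d bp)\n", x$name, nchar(x$seq)))
  invisible(x)
}

as_seq <- function(x) {
  if (inherits(x, "genome_sequence")) x$seq else as.character(x)
}

seq_name <- function(x, default = "seq") {
  if (inherits(x, "genome_sequence")) x$name else default
}

#' Read and write FASTA
#'
#' Thin wrappers around Biostrings for plain-text FASTA I/O.
#'
#' @param path file path.
#' @return `read_fasta` returns a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @param seqs named character vector (or list of `genome_sequence`).
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  if (is.list(seqs)) {
    nm <- vapply(seqs, seq_name, character(1))
    seqs <- setNames(vapply(seqs, as_seq, character(1)), nm)
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path, width = 80L)
}
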