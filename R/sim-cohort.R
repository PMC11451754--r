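# Cohort simulation: shared variants implanted at identical reference
# coordinates in a controlled fraction of haplotypes, with a machine-readable
# truth table of carriers. Enables exact allele-frequency recovery tests.

#' Simulate a cohort of haplotypes with target allele frequencies
#'
#' Each element of `af_spec` is a list with a rearrangement `plan` (list of
#' [rearrangement_op()]) and a target allele frequency `af` in (0, 1]. The
#' variant is implanted in `round(af * 2 * n_samples)` haplotypes, chosen by
#' seeded sampling without replacement, at identical reference coordinates.
#' Plans of different spec entries must not overlap on the reference.
#'
#' @param ref reference `genome_sequence`.
#' @param n_samples number of diploid samples (2 * `n_samples` haplotypes).
#' @param seed integer RNG seed controlling carrier assignment.
#' @param af_spec list of `list(plan = ..., af = ...)` entries.
#' @param dir optional directory; when given, one FASTA per haplotype named
#'   `SAMPLE#HAP.fa` and a `truth.tsv` table are written there.
#' @return list with `haplotypes` (named list of `genome_sequence`), `truth`
#'   (per-haplotype event-cluster truth with sample/hap columns), and
#'   `carriers` (per-spec carrier haplotype names and realised AF).
#' @export
simulate_cohort <- function(ref, n_samples, seed, af_spec, dir = NULL) {
  stopifnot(n_samples >= 1)
  n_hap <- 2L * n_samples
  hap_ids <- data.frame(
    sample = rep(sprintf("S%02d", seq_len(n_samples)), each = 2L),
    hap = rep(1:2, n_samples))
  hap_ids$name <- sprintf("%s#%d", hap_ids$sample, hap_ids$hap)

  carriers <- with_seed(seed, {
    lapply(seq_along(af_spec), function(i) {
      spec <- af_spec[[i]]
      stopifnot(is.numeric(spec$af), spec$af > 0, spec$af <= 1)
      k <- round(spec$af * n_hap)
      if (k < 1L) {
        warning("variant ", i, ": AF ", spec$af,
                " yields no carriers in ", n_hap, " haplotypes; dropped")
        return(integer(0))
      }
      sort(sample.int(n_hap, k))
    })
  })

  plans <- vector("list", n_hap)
  for (i in seq_along(af_spec)) {
    for (h in carriers[[i]]) {
      plans[[h]] <- c(plans[[h]], af_spec[[i]]$plan)
    }
  }

  haps <- vector("list", n_hap)
  truth <- list()
  for (h in seq_len(n_hap)) {
    res <- apply_plan(ref, if (is.null(plans[[h]])) list() else plans[[h]],
                      sample = hap_ids$sample[h], hap = hap_ids$hap[h])
    haps[[h]] <- res$hap
    truth[[h]] <- res$truth
  }
  names(haps) <- hap_ids$name
  truth <- do.call(rbind, truth)

  carrier_tab <- do.call(rbind, lapply(seq_along(af_spec), function(i) {
    data.frame(variant = i,
               target_af = af_spec[[i]]$af,
               realised_af = length(carriers[[i]]) / n_hap,
               carriers = paste(hap_ids$name[carriers[[i]]], collapse = ","),
               stringsAsFactors = FALSE)
  }))

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (h in seq_len(n_hap)) {
      write_fasta(list(haps[[h]]),
                  file.path(dir, paste0(sub("#", "_", hap_ids$name[h]), ".fa")))
    }
    write_truth(truth, file.path(dir, "truth.tsv"))
  }

  list(haplotypes = haps, truth = truth, carriers = carrier_tab,
       n_haplotypes = n_hap)
}

#' Write / read a truth table as TSV
#'
#' BED-derived TSV with explicit 0-based half-open coordinates.
#'
#' @param truth truth data frame from [apply_plan()] / [simulate_cohort()].
#' @param path output path.
#' @export
write_truth <- function(truth, path) {
  write.table(truth, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
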