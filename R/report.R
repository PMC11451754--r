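# Reporting layer: interval arithmetic, set overlaps, callset ratios, and
# Phred-style QV conversions used in callset accounting, plus per-sample
# summary reports.

#' Length of a half-open interval
#'
#' @param start,end 0-based half-open bounds (`end >= start`).
#' @return `end - start` in bp.
#' @export
interval_length <- function(start, end) {
  if (any(end < start)) stop("end < start")
  end - start
}

#' Overlap statistics from set cardinalities
#'
#' Given `|A|`, `|B|` and `|A union B|`, returns the intersection size by
#' inclusion-exclusion and the fractions of the union found in both sets or
#' exclusively in one.
#'
#' @param n_a,n_b,n_union set cardinalities.
#' @return list with `intersection`, `frac_both`, `frac_a_only`,
#'   `frac_b_only` (fractions of the union; they sum to 1).
#' @export
set_overlap_from_counts <- function(n_a, n_b, n_union) {
  if (n_union > n_a + n_b || n_union < max(n_a, n_b)) {
    stop("inconsistent counts: union must lie in [max(nA,nB), nA+nB]")
  }
  inter <- n_a + n_b - n_union
  list(intersection = inter,
       frac_both = inter / n_union,
       frac_a_only = (n_a - inter) / n_union,
       frac_b_only = (n_b - inter) / n_union)
}

#' Callset ratio and percent increase
#'
#' @param new,old counts (`old > 0`).
#' @return list with `ratio` (1 decimal) and `percent_increase` (2 decimals).
#' @export
ratio_and_increase <- function(new, old) {
  if (old <= 0) stop("old count must be positive")
  list(ratio = round(new / old, 1),
       percent_increase = round(100 * (new - old) / old, 2))
}

#' Phred QV / error-rate conversions
#'
#' `error = 10^(-qv/10)` (as a fraction; `error_percent` is 100x that) and
#' `qv = -10 log10(error)`. The two directions are inverse to within 1e-9.
#' An error rate of exactly zero maps to the configured cap with a flag.
#'
#' @param qv quality value (>= 0).
#' @param error_rate error fraction in `[0, 1]`.
#' @param cap QV reported for a zero error rate.
#' @return list with `qv`, `error_rate` (fraction), `error_percent`, and
#'   `capped`.
#' @export
qv_conversions <- function(qv = NULL, error_rate = NULL, cap = 99) {
  if (is.null(qv) == is.null(error_rate)) {
    stop("supply exactly one of qv or error_rate")
  }
  if (!is.null(qv)) {
    stopifnot(qv >= 0)
    err <- 10^(-qv / 10)
    list(qv = qv, error_rate = err, error_percent = 100 * err,
         capped = FALSE)
  } else {
    stopifnot(error_rate >= 0, error_rate <= 1)
    if (error_rate == 0) {
      return(list(qv = cap, error_rate = 0, error_percent = 0,
                  capped = TRUE))
    }
    list(qv = -10 * log10(error_rate), error_rate = error_rate,
         error_percent = 100 * error_rate, capped = FALSE)
  }
}

#' Summarise a merged callset per sample
#'
#' @param merged merged variant data frame with `carriers`.
#' @param samples character vector of all cohort samples (so zero-count
#'   samples appear).
#' @return list with `per_sample` (counts by svtype per sample), `complex`
#'   (per-sample complex-call count with mean/median/range), `size_quantiles`
#'   of absolute svlen, and `ins_del_balance`.
#' @export
callset_summary <- function(merged, samples = NULL) {
  if (!nrow(merged)) {
    return(list(per_sample = data.frame(), complex = list(),
                size_quantiles = numeric(0), ins_del_balance = NA_real_))
  }
  expanded <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    cc <- merged$carriers[[i]]
    if (is.null(cc) || !length(cc)) {
      cc <- sprintf("%s#%d", merged$sample[i], merged$hap[i])
    }
    data.frame(sample = sub("#.*$", "", cc),
               svtype = merged$svtype[i],
               complex = merged$complex[i],
               svlen = merged$svlen[i], stringsAsFactors = FALSE)
  }))
  if (is.null(samples)) samples <- sort(unique(expanded$sample))
  per_sample <- as.data.frame.matrix(
    table(factor(expanded$sample, levels = samples), expanded$svtype))
  cx <- vapply(samples, function(s) {
    sum(expanded$complex[expanded$sample == s])
  }, numeric(1))
  n_ins <- sum(expanded$svtype == "INS")
  n_del <- sum(expanded$svtype == "DEL")
  list(per_sample = per_sample,
       complex = list(per_sample = cx, mean = mean(cx),
                      median = median(cx), range = range(cx)),
       size_quantiles = quantile(abs(merged$svlen),
                                 c(0, 0.25, 0.5, 0.75, 1)),
       ins_del_balance = if (n_del > 0) n_ins / n_del else NA_real_)
}
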