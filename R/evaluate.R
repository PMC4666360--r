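# Call-set comparison within coordinate windows and the
# sensitivity/precision/FDR arithmetic, plus cohort summary statistics.

#' Windowed intersection of two call sets
#'
#' A call in `a` hits if any call in `b` on the same chromosome lies
#' within `window` bp (closed: distance equal to `window` counts), and
#' symmetrically.  Each call is counted once regardless of multiplicity.
#'
#' @param a,b data.frames with columns `chrom`, `pos`
#' @param window distance in bp (default 100)
#' @return list with logical vectors `a_hits`, `b_hits`
#' @export
intersect_within <- function(a, b, window = 100L) {
  stopifnot(window >= 0)
  hit <- function(x, y) {
    out <- logical(nrow(x))
    for (cn in unique(x$chrom)) {
      yp <- sort(y$pos[y$chrom == cn])
      xi <- which(x$chrom == cn)
      if (length(yp) == 0L) next
      lo <- findInterval(x$pos[xi] - window - 1L, yp)
      hi <- findInterval(x$pos[xi] + window, yp)
      out[xi] <- hi > lo
    }
    out
  }
  list(a_hits = hit(a, b), b_hits = hit(b, a))
}

#' Performance row from overlap counts
#'
#' `sensitivity = truth_with_overlap / truth_count`,
#' `precision = predicted_with_overlap / predicted_count`,
#' `fdr = 1 - precision`.  Percentages are reported half-up rounded to
#' one decimal alongside the raw fractions.
#'
#' @param n_predicted,n_predicted_hit,n_truth,n_truth_hit the four counts
#' @return data.frame of class `"performance_row"`
#' @export
performance_row <- function(n_predicted, n_predicted_hit, n_truth,
                            n_truth_hit) {
  stopifnot(n_truth > 0)
  flag <- n_predicted == 0
  precision <- if (flag) 0 else n_predicted_hit / n_predicted
  sensitivity <- n_truth_hit / n_truth
  fdr <- 1 - precision
  out <- data.frame(
    predicted = n_predicted, predicted_hit = n_predicted_hit,
    truth = n_truth, truth_hit = n_truth_hit,
    sensitivity = sensitivity, precision = precision, fdr = fdr,
    sensitivity_pct = round_half_up(100 * sensitivity, 1),
    precision_pct = round_half_up(100 * precision, 1),
    fdr_pct = round_half_up(100 * fdr, 1),
    undefined_precision = flag)
  class(out) <- c("performance_row", "data.frame")
  out
}

#' Sensitivity/precision/FDR of a predicted call set against a truth set
#'
#' @param predicted,truth data.frames with `chrom`, `pos`
#' @param window intersection window (default 100)
#' @return a `"performance_row"`
#' @export
performance_metrics <- function(predicted, truth, window = 100L) {
  stopifnot(nrow(truth) > 0)
  hits <- intersect_within(predicted, truth, window)
  performance_row(nrow(predicted), sum(hits$a_hits), nrow(truth),
                  sum(hits$b_hits))
}

#' Cohort summary statistics of breakpoint calls
#'
#' @param calls list of `"breakpoint_call"` objects
#' @return list: insertion-length and TSD-length min/median/max, counts by
#'   genotypable flag and by overlap-vs-deletion class
#' @export
cohort_stats <- function(calls) {
  stopifnot(length(calls) >= 1L)
  ins_len <- vapply(calls, function(x)
    nchar(x$inserted_seq %||% x$element_seq %||% ""), numeric(1))
  tsd_len <- vapply(calls, function(x) x$tsd_len %||% NA_integer_,
                    numeric(1))
  genot <- vapply(calls, function(x) isTRUE(x$genotypable), logical(1))
  cls <- vapply(calls, function(x) {
    if (is.null(x$overlap_len)) return("uncalled")
    if (x$overlap_len > 0L) "overlap"
    else if ((x$target_deletion %||% 0L) > 0L) "deletion" else "blunt"
  }, character(1))
  list(
    insertion_length = c(min = min(ins_len), median = median(ins_len),
                         max = max(ins_len)),
    tsd_length = c(min = min(tsd_len, na.rm = TRUE),
                   median = median(tsd_len, na.rm = TRUE),
                   max = max(tsd_len, na.rm = TRUE)),
    genotypable = table(genot),
    class = table(cls))
}
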