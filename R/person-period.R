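#' Expand a cohort into person-period (discrete-time) format
#'
#' Each subject with follow-up `t` contributes `ceiling(t / period_length)`
#' rows; the death indicator `death_k` equals the subject's `DIED` on the last
#' row and 0 elsewhere, so total deaths are conserved. One-hot period dummies
#' `PER_1..PER_K` mark the interval of each row (all dummies are emitted; the
#' reference is dropped at fit time, not at encoding time).
#'
#' @param cohort a cohort table (see [generate_cohort]).
#' @param period_length interval width in years (default 2).
#' @return a `data.frame` of class `person_period_table` with columns
#'   `source_id`, `period_index`, the period dummies, `death_k`, and every
#'   subject-level covariate copied to each row.
#' @export
to_person_period <- function(cohort, period_length = 2) {
  if (period_length <= 0) stopf("period_length must be > 0")
  if (any(cohort$time <= 0)) {
    stopf("non-positive follow-up time for id(s): %s",
          paste(utils::head(cohort$id[cohort$time <= 0], 5), collapse = ", "))
  }
  nper <- as.integer(ceiling(cohort$time / period_length))
  idx <- rep.int(seq_len(nrow(cohort)), nper)
  period <- sequence(nper)
  last <- period == rep.int(nper, nper)
  covars <- setdiff(names(cohort), c("id", "time", "DIED"))
  out <- data.frame(source_id = cohort$id[idx],
                    period_index = period,
                    stringsAsFactors = FALSE)
  K <- max(nper)
  for (k in seq_len(K)) out[[sprintf("PER_%d", k)]] <- as.integer(period == k)
  out$death_k <- as.integer(last & rep.int(cohort$DIED, nper) == 1L)
  for (cv in covars) out[[cv]] <- cohort[[cv]][idx]
  class(out) <- c("person_period_table", "data.frame")
  attr(out, "period_length") <- period_length
  attr(out, "n_periods") <- K
  out
}

#' Percentile-bin coding of a continuous vector by bin medians
#'
#' Cuts a continuous vector at sample percentile boundaries into `n_bins`
#' bins and replaces each value by the median of its bin. The mapping is
#' monotone non-decreasing; ties at a boundary fall into the lower bin.
#' Duplicate percentile boundaries (heavy ties) collapse bins, with a warning
#' when fewer than `n_bins` remain.
#'
#' @param values numeric vector.
#' @param n_bins number of percentile bins (>= 1; default 10, deciles).
#' @return numeric vector of bin-median codes, same length as `values`.
#' @export
discretize_percentiles <- function(values, n_bins = 10L) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 1L) stopf("n_bins must be >= 1")
  if (!length(values)) return(values)
  if (n_bins == 1L) return(rep(stats::median(values), length(values)))
  probs <- seq_len(n_bins - 1L) / n_bins
  cuts <- unique(stats::quantile(values, probs = probs, names = FALSE,
                                 type = 7))
  cuts <- cuts[cuts > min(values) & cuts < max(values)]
  if (length(cuts) < n_bins - 1L) {
    warning(sprintf("only %d distinct bins available for n_bins = %d",
                    length(cuts) + 1L, n_bins), call. = FALSE)
  }
  if (!length(cuts)) return(rep(stats::median(values), length(values)))
  # values equal to a cut go to the lower bin: intervals (-Inf, c1], (c1, c2]...
  bin <- findInterval(values, cuts, left.open = TRUE) + 1L
  med <- vapply(split(values, bin), stats::median, numeric(1))
  unname(med[as.character(bin)])
}
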