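# Per-tumour-sample over-/under-splicing calls from quantile cutoffs of
# normal-cohort SPLs.

#' Nearest-rank empirical quantile
#'
#' The `ceil(p * n)`-th order statistic of the non-missing values: a
#' deterministic, interpolation-free quantile.
#'
#' @param x numeric vector (`NA` dropped).
#' @param p probability in `(0, 1]`.
#' @return the quantile.
#' @export
nearest_rank_quantile <- function(x, p) {
  x <- sort(x[!is.na(x)])
  if (length(x) == 0) stop("no non-missing values")
  if (p <= 0 || p > 1) stop("p must lie in (0, 1]")
  x[max(1L, ceiling(p * length(x)))]
}

#' Over-/under-splicing quantile cutoffs from two normal references
#'
#' The over-splicing cutoff is the larger of the two groups' `q_high`
#' quantiles (stringent); the under-splicing cutoff is by default the
#' smaller of the two `q_low` quantiles (the symmetric, stringent rule),
#' with `under_rule = "max"` taking the larger.
#'
#' @param normal_spls SPLs of the matched-normal group.
#' @param reference_spls SPLs of the reference-normal group (pass the same
#'   vector when only one normal group exists).
#' @param q_low,q_high quantile probabilities (defaults 0.10 / 0.90).
#' @param under_rule `"min"` (default) or `"max"`.
#' @param min_n minimum non-missing values per group (default 5).
#' @return list with `cutoff_low`, `cutoff_high`.
#' @export
quantile_cutoffs <- function(normal_spls, reference_spls,
                             q_low = 0.10, q_high = 0.90,
                             under_rule = c("min", "max"), min_n = 5L) {
  under_rule <- match.arg(under_rule)
  if (sum(!is.na(normal_spls)) < min_n || sum(!is.na(reference_spls)) < min_n) {
    stop("need at least ", min_n, " non-missing normal SPLs per group")
  }
  hi <- max(nearest_rank_quantile(normal_spls, q_high),
            nearest_rank_quantile(reference_spls, q_high))
  lo_pair <- c(nearest_rank_quantile(normal_spls, q_low),
               nearest_rank_quantile(reference_spls, q_low))
  lo <- if (under_rule == "min") min(lo_pair) else max(lo_pair)
  list(cutoff_low = min(lo, hi), cutoff_high = hi)
}

#' Splice-status call for tumour SPLs
#'
#' `OVER` when SPL is strictly above the high cutoff, `UNDER` when strictly
#' below the low cutoff, `MISSING` for missing SPLs, `NEITHER` otherwise
#' (a value equal to a cutoff is `NEITHER`).
#'
#' @param spl numeric vector of SPLs.
#' @param cutoffs list with `cutoff_low`, `cutoff_high` (from
#'   [quantile_cutoffs()]).
#' @return character vector of statuses.
#' @export
call_status <- function(spl, cutoffs) {
  out <- rep("NEITHER", length(spl))
  out[is.na(spl)] <- "MISSING"
  out[!is.na(spl) & spl > cutoffs$cutoff_high] <- "OVER"
  out[!is.na(spl) & spl < cutoffs$cutoff_low] <- "UNDER"
  out
}

#' Per-sample splice-status calls for a set of events
#'
#' For each event, derives quantile cutoffs from the `NORMAL` and
#' `REFERENCE_NORMAL` cohorts (the matched-normal values are reused when no
#' reference cohort exists) and calls every tumour sample.  Intended for
#' events flagged significant by [differential_cohort()]; pass all events
#' explicitly to override.
#'
#' @param spl_mat an `spl_matrix`.
#' @param event_ids events to call (default: all rows).
#' @inheritParams quantile_cutoffs
#' @return data.frame: `event_id`, `sample_id`, `spl`, `cutoff_low`,
#'   `cutoff_high`, `status`.
#' @export
call_splice_status <- function(spl_mat, event_ids = rownames(spl_mat$spl),
                               q_low = 0.10, q_high = 0.90,
                               under_rule = c("min", "max"), min_n = 5L) {
  under_rule <- match.arg(under_rule)
  tum <- cohort_samples(spl_mat, "TUMOUR")
  nor <- cohort_samples(spl_mat, "NORMAL")
  ref <- cohort_samples(spl_mat, "REFERENCE_NORMAL")
  if (length(ref) == 0) ref <- nor
  if (length(tum) == 0) stop("no TUMOUR samples")
  event_ids <- intersect(event_ids, rownames(spl_mat$spl))
  if (length(event_ids) == 0) {
    return(data.frame(event_id = character(0), sample_id = character(0),
                      spl = numeric(0), cutoff_low = numeric(0),
                      cutoff_high = numeric(0), status = character(0),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(event_ids, function(e) {
    cuts <- quantile_cutoffs(spl_mat$spl[e, nor], spl_mat$spl[e, ref],
                             q_low = q_low, q_high = q_high,
                             under_rule = under_rule, min_n = min_n)
    spl <- spl_mat$spl[e, tum]
    data.frame(
      event_id = e, sample_id = tum, spl = unname(spl),
      cutoff_low = cuts$cutoff_low, cutoff_high = cuts$cutoff_high,
      status = call_status(spl, cuts),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Tabulate over-/under-spliced tumour samples per event
#'
#' @param calls data.frame as from [call_splice_status()] (possibly stacked
#'   across cohorts).
#' @return data.frame: `event_id`, `n_over`, `n_under`, `n_neither`,
#'   `n_missing`, sorted by decreasing `n_over`.
#' @export
tabulate_over_under <- function(calls) {
  if (nrow(calls) == 0) {
    return(data.frame(event_id = character(0), n_over = integer(0),
                      n_under = integer(0), n_neither = integer(0),
                      n_missing = integer(0)))
  }
  lv <- c("OVER", "UNDER", "NEITHER", "MISSING")
  tab <- table(calls$event_id, factor(calls$status, levels = lv))
  out <- data.frame(
    event_id = rownames(tab),
    n_over = as.integer(tab[, "OVER"]),
    n_under = as.integer(tab[, "UNDER"]),
    n_neither = as.integer(tab[, "NEITHER"]),
    n_missing = as.integer(tab[, "MISSING"]),
    stringsAsFactors = FALSE
  )
  out[order(-out$n_over, out$event_id), , drop = FALSE]
}
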