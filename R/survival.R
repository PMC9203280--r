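# Survival association of splicing levels and burden: univariate Cox
# proportional hazards (Efron ties), Kaplan-Meier half-splits and the
# favourable/unfavourable labelling rule (HR < 1 or > 1 at P < 0.05).

#' Read a clinical TSV
#'
#' @param path TSV with header columns `sample_id`, `time_days`, `event`
#'   (1 = death observed, 0 = censored).
#' @return validated data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("sample_id", "time_days", "event")
  if (!all(need %in% names(df))) {
    stop("clinical table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$time_days <= 0)) stop("survival times must be > 0")
  if (!all(df$event %in% c(0, 1))) stop("event indicator must be 0/1")
  df
}

prognosis_label <- function(hr, p, alpha = 0.05) {
  if (is.na(hr) || is.na(p) || p >= alpha) return("NS")
  if (hr > 1) "UNFAVOURABLE" else if (hr < 1) "FAVOURABLE" else "NS"
}

#' Univariate Cox regression of survival on a continuous covariate
#'
#' Fits `Surv(time, event) ~ covariate` (Efron tie handling) and labels the
#' result `UNFAVOURABLE` (HR > 1, P < 0.05), `FAVOURABLE` (HR < 1,
#' P < 0.05) or `NS`.  The covariate is the raw SPL in `[0, 1]`, so the
#' hazard ratio is per full 0 to 1 change.  Degenerate covariates or
#' non-converging fits return `NS` with a diagnostic flag rather than
#' failing.
#'
#' @param spl named numeric covariate vector (names = sample ids).
#' @param clinical data.frame as from [read_clinical()].
#' @param min_n minimum samples with covariate and clinical data
#'   (default 20).
#' @param min_events minimum observed deaths (default 5).
#' @return list: `hazard_ratio`, `ci_low`, `ci_high` (95% Wald CI),
#'   `p_value`, `label`, `km_p`, `n`, `n_events`, `flag` (`""` when clean).
#' @export
cox_per_event <- function(spl, clinical, min_n = 20L, min_events = 5L) {
  i <- match(clinical$sample_id, names(spl))
  keep <- !is.na(i) & !is.na(spl[i])
  x <- spl[i[keep]]
  time <- clinical$time_days[keep]
  ev <- clinical$event[keep]
  ns <- function(flag) list(hazard_ratio = NA_real_, ci_low = NA_real_,
                            ci_high = NA_real_, p_value = NA_real_,
                            label = "NS", km_p = NA_real_,
                            n = length(x), n_events = sum(ev), flag = flag)
  if (length(x) < min_n || sum(ev) < min_events) return(ns("insufficient_data"))
  if (stats::sd(x) == 0) return(ns("degenerate_covariate"))
  fit <- tryCatch(
    survival::coxph(survival::Surv(time, ev) ~ x, ties = "efron"),
    error = function(e) NULL, warning = function(w) {
      suppressWarnings(survival::coxph(survival::Surv(time, ev) ~ x,
                                       ties = "efron"))
    }
  )
  if (is.null(fit) || is.na(stats::coef(fit))) return(ns("no_convergence"))
  sm <- summary(fit)
  hr <- unname(sm$conf.int[1, "exp(coef)"])
  p <- unname(sm$coefficients[1, "Pr(>|z|)"])
  km <- tryCatch(km_half_split(x, time, ev)$km_p, error = function(e) NA_real_)
  list(
    hazard_ratio = hr,
    ci_low = unname(sm$conf.int[1, "lower .95"]),
    ci_high = unname(sm$conf.int[1, "upper .95"]),
    p_value = p,
    label = prognosis_label(hr, p),
    km_p = km,
    n = length(x), n_events = sum(ev), flag = ""
  )
}

#' Kaplan-Meier comparison of top and bottom halves
#'
#' Splits samples at the median of the covariate (values equal to the
#' median go to the low group, so with odd `n` the low group gets the
#' extra sample) and runs a log-rank test.
#'
#' @param x numeric covariate (SPL or burden).
#' @param time,event survival time and status, aligned with `x`.
#' @return list: `km_p` (log-rank p), `group` (factor low/high), `fit`
#'   (a [survival::survfit] object with the two curves).
#' @export
km_half_split <- function(x, time, event) {
  grp <- factor(ifelse(x <= stats::median(x), "low", "high"),
                levels = c("low", "high"))
  if (any(table(grp) == 0)) stop("median split produced an empty group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  km_p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  list(km_p = km_p, group = grp, fit = fit)
}

#' Survival comparison of flagged versus unflagged samples
#'
#' Binary-covariate Cox model plus log-rank test, e.g. tumours with an
#' over-spliced event versus the rest.
#'
#' @param flagged named logical vector (names = sample ids).
#' @param clinical data.frame as from [read_clinical()].
#' @return list: `hazard_ratio`, `ci_low`, `ci_high`, `p_value`, `km_p`,
#'   `n_flagged`, `n_unflagged`.
#' @export
group_survival <- function(flagged, clinical) {
  i <- match(clinical$sample_id, names(flagged))
  keep <- !is.na(i) & !is.na(flagged[i])
  g <- as.numeric(flagged[i[keep]])
  time <- clinical$time_days[keep]
  ev <- clinical$event[keep]
  if (all(g == 1) || all(g == 0)) {
    stop("group comparison needs both flagged and unflagged samples")
  }
  fit <- survival::coxph(survival::Surv(time, ev) ~ g, ties = "efron")
  sm <- summary(fit)
  sd <- survival::survdiff(survival::Surv(time, ev) ~ g)
  list(
    hazard_ratio = unname(sm$conf.int[1, "exp(coef)"]),
    ci_low = unname(sm$conf.int[1, "lower .95"]),
    ci_high = unname(sm$conf.int[1, "upper .95"]),
    p_value = unname(sm$coefficients[1, "Pr(>|z|)"]),
    km_p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
    n_flagged = sum(g == 1), n_unflagged = sum(g == 0)
  )
}

#' Survival association of per-sample 3USP burden
#'
#' [cox_per_event()] with the per-sample 3USP count or normalized burden as
#' the covariate.
#'
#' @param burden named numeric vector (names = sample ids).
#' @inheritParams cox_per_event
#' @return as [cox_per_event()].
#' @export
burden_survival <- function(burden, clinical, min_n = 20L, min_events = 5L) {
  cox_per_event(burden, clinical, min_n = min_n, min_events = min_events)
}

#' Prognosis table across events
#'
#' Runs [cox_per_event()] on every requested event of an SPL matrix using
#' tumour-cohort samples, and adds a BH-adjusted column for transparency
#' (labels themselves follow the unadjusted P < 0.05 rule).
#'
#' @param spl_mat an `spl_matrix`.
#' @param clinical data.frame as from [read_clinical()].
#' @param event_ids events to test (default all).
#' @return data.frame: `event_id`, `hazard_ratio`, `ci_low`, `ci_high`,
#'   `p_value`, `fdr`, `label`, `km_p`, `n`, `n_events`, `flag`.
#' @export
prognosis_table <- function(spl_mat, clinical,
                            event_ids = rownames(spl_mat$spl)) {
  tum <- cohort_samples(spl_mat, "TUMOUR")
  event_ids <- intersect(event_ids, rownames(spl_mat$spl))
  rows <- lapply(event_ids, function(e) {
    r <- cox_per_event(spl_mat$spl[e, tum], clinical)
    data.frame(event_id = e, hazard_ratio = r$hazard_ratio,
               ci_low = r$ci_low, ci_high = r$ci_high, p_value = r$p_value,
               label = r$label, km_p = r$km_p, n = r$n,
               n_events = r$n_events, flag = r$flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- NA_real_
  ok <- !is.na(out$p_value)
  out$fdr[ok] <- bh_adjust(out$p_value[ok])
  out[, c("event_id", "hazard_ratio", "ci_low", "ci_high", "p_value", "fdr",
          "label", "km_p", "n", "n_events", "flag")]
}
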