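# Differential 3' UTR splicing between cohorts: rank tests, BH FDR,
# unidirectionality and effect-size criteria, small-cohort sign-flip
# permutation FDR, and hypergeometric set-overlap tests.

#' Two-sided Mann-Whitney U p-value
#'
#' Exact enumeration when both groups have at most 8 observations and the
#' pooled values carry no ties; normal approximation with tie correction
#' otherwise.
#'
#' @param x,y numeric vectors (no NAs).
#' @return two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  exact <- length(x) <= 8 && length(y) <= 8 && !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = !exact)$p.value
  )
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, via [stats::p.adjust()].
#'
#' @param p numeric vector of p-values in `[0, 1]` (empty allowed).
#' @return q-values, same length.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential splicing between tumour and normal cohorts
#'
#' Per event: a two-sided Mann-Whitney U test of tumour versus normal SPLs
#' (missing values dropped), BH adjustment across all testable events, and
#' the significance rule: `fdr < fdr_cut`, unidirectional median shifts
#' against both normal references, and a median difference strictly above
#' `min_delta` against at least one of them.  When the matrix carries no
#' `REFERENCE_NORMAL` samples the reference criteria are waived and the rule
#' reduces to `fdr < fdr_cut` and `|delta_normal| > min_delta`.
#'
#' Events with fewer than `min_group` non-missing values in any required
#' group are reported untestable (`NA` p) and excluded from the BH family.
#'
#' @param spl_mat an `spl_matrix` with cohort labels `TUMOUR`, `NORMAL` and
#'   optionally `REFERENCE_NORMAL`.
#' @param fdr_cut FDR threshold (default 0.1).
#' @param min_delta minimum absolute median SPL difference, strict
#'   (default 0.05).
#' @param min_group minimum non-missing values per group (default 3).
#' @return data.frame: `event_id`, `p_value`, `fdr`, `median_tumour`,
#'   `median_normal`, `median_reference`, `delta_normal`, `delta_reference`,
#'   `direction` (`UP`/`DOWN`/`NONE`), `significant`, `testable`.
#' @export
differential_cohort <- function(spl_mat, fdr_cut = 0.1, min_delta = 0.05,
                                min_group = 3L) {
  tum <- cohort_samples(spl_mat, "TUMOUR")
  nor <- cohort_samples(spl_mat, "NORMAL")
  ref <- cohort_samples(spl_mat, "REFERENCE_NORMAL")
  if (length(nor) == 0) stop("no NORMAL samples in matrix")
  if (length(tum) == 0) stop("no TUMOUR samples in matrix")
  has_ref <- length(ref) > 0

  S <- spl_mat$spl
  n_ev <- nrow(S)
  res <- data.frame(
    event_id = rownames(S),
    p_value = NA_real_, fdr = NA_real_,
    median_tumour = NA_real_, median_normal = NA_real_,
    median_reference = NA_real_,
    delta_normal = NA_real_, delta_reference = NA_real_,
    direction = "NONE", significant = FALSE, testable = FALSE,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n_ev)) {
    x <- S[i, tum]; x <- x[!is.na(x)]
    y <- S[i, nor]; y <- y[!is.na(y)]
    r <- if (has_ref) { z <- S[i, ref]; z[!is.na(z)] } else numeric(0)
    res$median_tumour[i] <- if (length(x)) stats::median(x) else NA_real_
    res$median_normal[i] <- if (length(y)) stats::median(y) else NA_real_
    res$median_reference[i] <- if (length(r)) stats::median(r) else NA_real_
    ok <- length(x) >= min_group && length(y) >= min_group &&
      (!has_ref || length(r) >= min_group)
    if (!ok) next
    res$testable[i] <- TRUE
    res$p_value[i] <- mann_whitney_p(x, y)
    res$delta_normal[i] <- res$median_tumour[i] - res$median_normal[i]
    if (has_ref) res$delta_reference[i] <- res$median_tumour[i] - res$median_reference[i]
  }
  res$fdr[res$testable] <- bh_adjust(res$p_value[res$testable])

  dn <- res$delta_normal
  dr <- res$delta_reference
  if (has_ref) {
    unidir <- !is.na(dn) & !is.na(dr) & sign(dn) == sign(dr) & sign(dn) != 0
    big <- (abs(dn) > min_delta) | (abs(dr) > min_delta)
  } else {
    unidir <- !is.na(dn) & sign(dn) != 0
    big <- abs(dn) > min_delta
  }
  sig <- res$testable & !is.na(res$fdr) & res$fdr < fdr_cut & unidir & big
  res$significant <- sig
  res$direction[sig] <- ifelse(dn[sig] > 0, "UP", "DOWN")
  res
}

#' Sign-flip permutation FDR for small paired cohorts
#'
#' For matched tumour/normal pairs the per-event statistic is the median of
#' paired SPL differences.  The null is built by sign-flipping the paired
#' differences: all `2^n` flips when that is at most `n_perm`, otherwise
#' `n_perm` flips sampled with the seed.  The per-event FDR is the mean
#' null count of events with `|statistic| >=` the observed value, divided by
#' the observed count, capped at 1.
#'
#' @param diffs events x pairs matrix of paired SPL differences
#'   (tumour - normal).
#' @param n_perm maximum number of sign-flip permutations (default 10000).
#' @param seed integer seed used when flips are sampled.
#' @return data.frame: `event_id`, `statistic`, `fdr`.
#' @export
permutation_fdr_paired <- function(diffs, n_perm = 10000L, seed = 1L) {
  diffs <- as.matrix(diffs)
  n_pairs <- ncol(diffs)
  if (n_pairs < 2) stop("need at least 2 matched pairs")
  n_ev <- nrow(diffs)
  obs <- apply(diffs, 1, stats::median)

  if (2^n_pairs <= n_perm) {
    flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), n_pairs)))
  } else {
    rs <- local({ set.seed(seed); matrix(sample(c(-1, 1), n_perm * n_pairs,
                                                replace = TRUE), n_perm) })
    flips <- rs
  }
  n_flip <- nrow(flips)
  null_abs <- numeric(n_ev * n_flip)
  idx <- 1L
  for (f in seq_len(n_flip)) {
    flipped <- sweep(diffs, 2, flips[f, ], `*`)
    null_abs[idx:(idx + n_ev - 1L)] <- abs(apply(flipped, 1, stats::median))
    idx <- idx + n_ev
  }
  null_sorted <- sort(null_abs)
  obs_abs <- abs(obs)
  obs_sorted <- sort(obs_abs)
  # counts of values >= t via binary search on the sorted vectors
  ge_count <- function(sorted, t) length(sorted) - findInterval(t - 1e-12, sorted)
  fdr <- vapply(obs_abs, function(t) {
    null_ge <- ge_count(null_sorted, t) / n_flip
    obs_ge <- ge_count(obs_sorted, t)
    min(1, null_ge / obs_ge)
  }, numeric(1))
  data.frame(
    event_id = rownames(diffs) %||% as.character(seq_len(n_ev)),
    statistic = obs, fdr = fdr, stringsAsFactors = FALSE
  )
}

#' Hypergeometric overlap test
#'
#' Upper-tail probability `P(X >= k)` for the overlap `k` between a set of
#' size `K` and a set of size `n` drawn from a universe of size `N`.
#'
#' @param k overlap size.
#' @param K first set size.
#' @param n second set size.
#' @param N universe size.
#' @return list with `k`, `K`, `n`, `N`, `p_value`.
#' @export
hypergeom_overlap <- function(k, K, n, N) {
  if (K > N || n > N || k > min(K, n) || k < 0) {
    stop("inconsistent set sizes for hypergeometric overlap")
  }
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p_value = p)
}

#' RBP knockdown screen on one event
#'
#' For each factor, compares the event's SPL between knockdown and control
#' samples with the Mann-Whitney U test and reports the median difference —
#' the machinery behind a knockdown volcano table.
#'
#' @param spl named numeric vector of SPLs for one event across samples.
#' @param factor_of sample -> factor name for knockdown samples (named
#'   character vector; samples absent from it are ignored unless controls).
#' @param controls character vector of control sample ids.
#' @return data.frame: `factor`, `n_kd`, `n_ctrl`, `delta_median`, `p_value`.
#' @export
rbp_screen <- function(spl, factor_of, controls) {
  ctrl <- spl[intersect(names(spl), controls)]
  ctrl <- ctrl[!is.na(ctrl)]
  if (length(ctrl) == 0) stop("no control samples with SPL values")
  facs <- sort(unique(factor_of))
  rows <- lapply(facs, function(fc) {
    kd <- spl[intersect(names(spl), names(factor_of)[factor_of == fc])]
    kd <- kd[!is.na(kd)]
    if (length(kd) == 0) {
      return(data.frame(factor = fc, n_kd = 0L, n_ctrl = length(ctrl),
                        delta_median = NA_real_, p_value = NA_real_))
    }
    data.frame(
      factor = fc, n_kd = length(kd), n_ctrl = length(ctrl),
      delta_median = stats::median(kd) - stats::median(ctrl),
      p_value = mann_whitney_p(kd, ctrl),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
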