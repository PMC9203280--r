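# 3' UTR splicing event (3USP) discovery, common-event calls and support
# annotation.

#' Discover 3' UTR splicing events (3USPs)
#'
#' Keeps junctions that (i) classify as `THREE_UTR_EXCLUSIVE` against the
#' annotation and (ii) in at least one sample are supported by
#' `>= min_reads` junction reads with an SPL strictly greater than
#' `min_spl` (both conditions in the same sample).
#'
#' @param spl_mat an `spl_matrix` from [build_spl_matrix()].
#' @param ann a `genome_annotation` from [parse_gtf()].
#' @param min_reads minimum junction reads (default 2).
#' @param min_spl SPL support threshold, strict (default 0.10).
#' @param stranded_exclusion passed to [classify_introns()].
#' @return data.frame of surviving events: `junction_id`, `chrom`, `start`,
#'   `end`, `strand`, `region`, `gene_ids` (comma-joined ids of same-strand
#'   transcripts whose 3' UTR contains the event).
#' @export
discover_3usps <- function(spl_mat, ann, min_reads = 2L, min_spl = 0.10,
                           stranded_exclusion = FALSE) {
  ev <- spl_mat$events
  region <- classify_introns(ev, ann, stranded_exclusion = stranded_exclusion)
  supported <- spl_mat$out_reads >= min_reads & !is.na(spl_mat$spl) &
    spl_mat$spl > min_spl
  keep <- region == "THREE_UTR_EXCLUSIVE" & rowSums(supported) > 0
  out <- ev[keep, , drop = FALSE]
  out$region <- region[keep]
  out$gene_ids <- event_gene_ids(out, ann)
  rownames(out) <- NULL
  out
}

# comma-joined gene ids of same-strand transcripts whose 3' UTR union
# contains each event
event_gene_ids <- function(events, ann) {
  if (nrow(events) == 0 || length(ann$utr3_flat) == 0) {
    return(rep("", nrow(events)))
  }
  gr <- intervals_to_gr(events)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, ann$utr3_flat, type = "within",
                                ignore.strand = FALSE)
  )
  res <- rep("", nrow(events))
  if (length(hits)) {
    tx <- ann$utr3_flat$transcript_id[S4Vectors::subjectHits(hits)]
    gid <- ann$transcripts$gene_id[match(tx, ann$transcripts$transcript_id)]
    agg <- tapply(gid, S4Vectors::queryHits(hits),
                  function(g) paste(sort(unique(g)), collapse = ","))
    res[as.integer(names(agg))] <- as.character(agg)
  }
  res
}

#' Common-event (c3USP) call for one event within one cohort
#'
#' An event is common when its SPL exceeds `min_spl` (strictly) in strictly
#' more than half of the cohort's samples.  By default missing SPLs count
#' in the denominator (all cohort samples); `denominator = "observed"`
#' restricts it to samples with a value.
#'
#' @param spl numeric vector of SPLs for one event across one cohort
#'   (`NA` = missing).
#' @param min_spl threshold, strict (default 0.10).
#' @param denominator `"all"` (default) or `"observed"`.
#' @return logical.
#' @export
call_c3usp <- function(spl, min_spl = 0.10, denominator = c("all", "observed")) {
  denominator <- match.arg(denominator)
  if (length(spl) == 0) stop("empty cohort")
  n <- if (denominator == "all") length(spl) else sum(!is.na(spl))
  if (n == 0) return(FALSE)
  sum(spl > min_spl, na.rm = TRUE) > n / 2
}

#' c3USP flags for every event of a cohort
#'
#' @param spl_mat an `spl_matrix`.
#' @param cohort cohort label to restrict to (default `"TUMOUR"`).
#' @inheritParams call_c3usp
#' @return named logical vector over events.
#' @export
c3usp_flags <- function(spl_mat, cohort = "TUMOUR", min_spl = 0.10,
                        denominator = c("all", "observed")) {
  denominator <- match.arg(denominator)
  sid <- cohort_samples(spl_mat, cohort)
  if (length(sid) == 0) stop("no samples in cohort ", cohort)
  sub <- spl_mat$spl[, sid, drop = FALSE]
  apply(sub, 1, call_c3usp, min_spl = min_spl, denominator = denominator)
}

#' Normalized 3USP burden
#'
#' Fraction of a sample's splicing events that are 3USPs.
#'
#' @param n_3usp number of 3USPs detected in the sample.
#' @param n_all_splicing number of all splicing events in the sample.
#' @return `n_3usp / n_all_splicing`.
#' @export
normalize_burden <- function(n_3usp, n_all_splicing) {
  if (any(n_all_splicing <= 0)) stop("all-splicing event count must be > 0")
  if (any(n_3usp < 0) || any(n_3usp > n_all_splicing)) {
    stop("need 0 <= n_3usp <= n_all_splicing")
  }
  n_3usp / n_all_splicing
}

#' Per-sample splicing burden table
#'
#' Counts, per sample, the 3USPs and all splicing events passing the same
#' per-sample support rule (`>= min_reads` junction reads and SPL strictly
#' above `min_spl`), the normalized burden, and a low-depth exclusion flag
#' for samples with fewer than `min_depth_junctions` supported junctions.
#'
#' @param spl_mat an `spl_matrix`.
#' @param events_3usp data.frame from [discover_3usps()].
#' @param min_reads,min_spl support thresholds (defaults 2 and 0.10).
#' @param min_depth_junctions low-depth exclusion threshold (default 1000).
#' @return data.frame: `sample_id`, `cohort`, `n_3usp`, `n_all_splicing`,
#'   `burden` (NA when no splicing events), `low_depth`.
#' @export
splice_burden <- function(spl_mat, events_3usp, min_reads = 2L, min_spl = 0.10,
                          min_depth_junctions = 1000L) {
  supported <- spl_mat$out_reads >= min_reads & !is.na(spl_mat$spl) &
    spl_mat$spl > min_spl
  n_all <- colSums(supported)
  is3 <- rownames(spl_mat$spl) %in% events_3usp$junction_id
  n3 <- colSums(supported[is3, , drop = FALSE])
  data.frame(
    sample_id = spl_mat$samples$sample_id,
    cohort = spl_mat$samples$cohort,
    n_3usp = n3,
    n_all_splicing = n_all,
    burden = ifelse(n_all > 0, n3 / n_all, NA_real_),
    low_depth = n_all < min_depth_junctions,
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

# introns (exon gaps) of a GTF/GFF of isoform models, as a junction-id set
isoform_introns <- function(path) {
  gr <- rtracklayer::import(path)
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) return(character(0))
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    s = GenomicRanges::start(gr) - 1L,
    e = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx = gr$transcript_id,
    stringsAsFactors = FALSE
  )
  ids <- character(0)
  for (ti in split(seq_len(nrow(df)), df$tx)) {
    if (length(ti) < 2) next
    g <- iv_gaps(iv_reduce(df$s[ti], df$e[ti]))
    if (nrow(g)) {
      ids <- c(ids, junction_id(df$chrom[ti[1]], g[, 1], g[, 2], df$strand[ti[1]]))
    }
  }
  unique(ids)
}

#' Long-read (PacBio-style) support for events
#'
#' An event is supported when some isoform model contains an intron with
#' identical chromosome, donor and acceptor coordinates.
#'
#' @param events data.frame with `chrom`, `start`, `end`, `strand`.
#' @param isoform_gtf path to an isoform-model GTF/GFF (exon features).
#' @return logical vector over events.
#' @export
match_longread_support <- function(events, isoform_gtf) {
  iso <- isoform_introns(isoform_gtf)
  # strand-insensitive coordinate identity: long-read isoform strand calls
  # can disagree for single-exon-pair models, coordinates cannot
  strip <- function(id) sub(":[+-]$", "", id)
  strip(junction_id(events$chrom, events$start, events$end, events$strand)) %in%
    strip(iso)
}

#' Annotated-intron check for events
#'
#' `TRUE` when the event's boundaries equal an annotated transcript intron
#' of the reference annotation.
#'
#' @param events data.frame with `chrom`, `start`, `end`, `strand`.
#' @param ann a `genome_annotation`.
#' @return logical vector over events.
#' @export
check_annotated <- function(events, ann) {
  if (length(ann$introns) == 0) return(rep(FALSE, nrow(events)))
  d <- gr_to_intervals(ann$introns)
  known <- junction_id(d$chrom, d$start, d$end, d$strand)
  junction_id(events$chrom, events$start, events$end, events$strand) %in% known
}
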