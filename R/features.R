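# Event-level sequence features: exonic distance from the stop codon to the
# 5' splice site, the 50-nt NMD prediction rule, and repeat (Alu) overlap
# of the removed intron.

# vectorized exonic stop-codon -> donor distances; NA for events outside any
# annotated 3' UTR.  One overlap query for all events; per-hit arithmetic on
# the 0-based utr3 table.
stop_distances <- function(events, ann) {
  n <- nrow(events)
  out <- rep(NA_integer_, n)
  if (n == 0 || length(ann$utr3_flat) == 0) return(out)
  gr <- intervals_to_gr(events)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, ann$utr3_flat, type = "within",
                                ignore.strand = FALSE)
  )
  if (length(hits) == 0) return(out)
  q <- S4Vectors::queryHits(hits)
  tx <- ann$utr3_flat$transcript_id[S4Vectors::subjectHits(hits)]
  pairs <- unique(data.frame(q = q, tx = tx, stringsAsFactors = FALSE))
  u3 <- ann$utr3_tab
  u3_by_tx <- split(seq_len(nrow(u3)), u3$transcript_id)
  d <- numeric(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    t1 <- pairs$tx[i]
    ev <- events[pairs$q[i], ]
    b0 <- ann$stop_boundary[[t1]]
    iv <- u3[u3_by_tx[[t1]], , drop = FALSE]
    if (ev$strand == "+") {
      # exonic bases in [b0, donor); containment guarantees donor >= b0
      d[i] <- sum(pmax(0, pmin(iv$e, ev$start) - pmax(iv$s, b0)))
    } else {
      # exonic bases in [donor, b0) with donor = intron end on minus strand
      d[i] <- sum(pmax(0, pmin(iv$e, b0) - pmax(iv$s, ev$end)))
    }
  }
  agg <- tapply(d, pairs$q, min)
  out[as.integer(names(agg))] <- as.integer(agg)
  out
}

#' Exonic distance from the stop codon to an event's 5' splice site
#'
#' Distance in mRNA (exonic) coordinates from the first nucleotide after
#' the stop codon to the intron's donor site, strand-aware.  When the event
#' lies in the 3' UTR of several transcripts the minimum distance is
#' reported (conservative for NMD prediction).
#'
#' @param event one-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand` (0-based half-open).
#' @param ann a `genome_annotation`.
#' @return integer distance in nt (0 when the splice site immediately
#'   follows the stop codon).
#' @export
stop_distance <- function(event, ann) {
  ev <- data.frame(chrom = event$chrom, start = event$start, end = event$end,
                   strand = event$strand, stringsAsFactors = FALSE)
  d <- stop_distances(ev, ann)
  if (is.na(d)) {
    stop("event ", junction_id(event$chrom, event$start, event$end, event$strand),
         " is not contained in any transcript's 3' UTR")
  }
  d
}

#' 50-nt rule NMD prediction
#'
#' An exon-exon junction strictly more than `threshold` nt downstream of
#' the stop codon predicts nonsense-mediated decay; at or below the
#' threshold the transcript is predicted to escape NMD.
#'
#' @param stop_distance_nt non-negative exonic distance(s) in nt.
#' @param threshold canonical boundary, default 50 nt (strict `>`).
#' @return logical: `TRUE` = NMD-predicted.
#' @export
predict_nmd <- function(stop_distance_nt, threshold = 50L) {
  if (any(stop_distance_nt < 0)) stop("distance must be >= 0")
  stop_distance_nt > threshold
}

#' Read RepeatMasker-style repeat intervals from BED
#'
#' Six columns: chrom, start, end, name (repeat family, e.g. `AluYa5`),
#' score, strand.
#'
#' @param path BED path.
#' @return GRanges with a `name` metadata column.
#' @export
read_repeats_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  nf <- vapply(strsplit(lines, "\t", fixed = TRUE), length, integer(1))
  if (any(nf < 4)) {
    stop("malformed BED line ", which(nf < 4)[1], ": expected >= 4 columns")
  }
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name)) gr$name <- ""
  gr
}

# vectorized repeat-union overlap; returns data.frame(fraction, has_alu)
repeat_overlaps <- function(events, repeats) {
  n <- nrow(events)
  res <- data.frame(fraction = rep(0, n), has_alu = rep(FALSE, n))
  if (n == 0 || length(repeats) == 0) return(res)
  gr <- intervals_to_gr(events)
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, repeats, ignore.strand = TRUE)
  )
  if (length(hits) == 0) return(res)
  q <- S4Vectors::queryHits(hits)
  rs <- GenomicRanges::start(repeats)[S4Vectors::subjectHits(hits)] - 1L
  re <- GenomicRanges::end(repeats)[S4Vectors::subjectHits(hits)]
  nm <- as.character(repeats$name)[S4Vectors::subjectHits(hits)]
  for (qi in unique(q)) {
    sel <- q == qi
    ev_s <- events$start[qi]; ev_e <- events$end[qi]
    m <- iv_reduce(pmax(rs[sel], ev_s), pmin(re[sel], ev_e))
    res$fraction[qi] <- sum(m[, 2] - m[, 1]) / (ev_e - ev_s)
    res$has_alu[qi] <- any(startsWith(nm[sel], "Alu"))
  }
  res
}

#' Repeat overlap of an event's intron
#'
#' Fraction of intron bases covered by the union of overlapping repeat
#' intervals, and whether any overlapping repeat is an Alu element (name
#' starting with `"Alu"`).
#'
#' @param event one-row data.frame (or list) with `chrom`, `start`, `end`,
#'   `strand`.
#' @param repeats GRanges from [read_repeats_bed()].
#' @return list: `fraction` in `[0, 1]`, `has_alu`.
#' @export
repeat_overlap <- function(event, repeats) {
  ev <- data.frame(chrom = event$chrom, start = event$start, end = event$end,
                   strand = event$strand, stringsAsFactors = FALSE)
  r <- repeat_overlaps(ev, repeats)
  list(fraction = r$fraction, has_alu = r$has_alu)
}

#' Feature table for a set of events
#'
#' Combines [stop_distance()], [predict_nmd()] and [repeat_overlap()] per
#' event; distances (and hence NMD calls) are `NA` for events outside any
#' annotated 3' UTR.
#'
#' @param events data.frame with `junction_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param ann a `genome_annotation`.
#' @param repeats GRanges of repeats, or `NULL` to skip repeat features.
#' @param nmd_threshold passed to [predict_nmd()].
#' @return data.frame: `event_id`, `stop_distance_nt`, `nmd_predicted`,
#'   `intron_length_nt`, `repeat_overlap_fraction`, `has_alu`.
#' @export
annotate_events <- function(events, ann, repeats = NULL, nmd_threshold = 50L) {
  n <- nrow(events)
  dist <- stop_distances(events, ann)
  if (!is.null(repeats)) {
    ro <- repeat_overlaps(events, repeats)
    frac <- ro$fraction
    alu <- ro$has_alu
  } else {
    frac <- rep(NA_real_, n)
    alu <- rep(NA, n)
  }
  nmd <- rep(NA, n)
  ok <- !is.na(dist)
  nmd[ok] <- predict_nmd(dist[ok], nmd_threshold)
  data.frame(
    event_id = events$junction_id,
    stop_distance_nt = dist,
    nmd_predicted = nmd,
    intron_length_nt = events$end - events$start,
    repeat_overlap_fraction = frac,
    has_alu = alu,
    stringsAsFactors = FALSE
  )
}
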