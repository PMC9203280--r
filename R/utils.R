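# Internal helpers: coordinate conventions and junction identifiers.
#
# All intervals inside the package are 0-based half-open [start, end) on a
# named chromosome with strand "+" or "-".  GTF input (1-based inclusive) is
# converted at parse time; IRanges/GRanges (1-based inclusive) are built on
# the fly for overlap arithmetic via `intervals_to_gr()`.

#' Build a GRanges from a 0-based half-open interval table
#'
#' @param df data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive) and `strand`.
#' @return A [GenomicRanges::GRanges] (1-based inclusive).
#' @keywords internal
#' @noRd
intervals_to_gr <- function(df) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(df)))
  if (any(df$start >= df$end)) {
    stop("invalid interval: start must be < end (0-based half-open)")
  }
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = df$strand
  )
}

gr_to_intervals <- function(gr) {
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE
  )
}

#' Canonical junction identifier
#'
#' Identifiers have the form `chrom:start-end:strand` with the intron in
#' 0-based half-open coordinates, and round-trip through
#' [parse_junction_id()].
#'
#' @param chrom,start,end,strand interval components (vectorised).
#' @return character vector of ids.
#' @export
junction_id <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, as.integer(start), as.integer(end), strand)
}

#' @rdname junction_id
#' @param id character vector of junction ids.
#' @return for `parse_junction_id`, a data.frame with columns
#'   `chrom`, `start`, `end`, `strand`.
#' @export
parse_junction_id <- function(id) {
  m <- regmatches(id, regexec("^(.+):([0-9]+)-([0-9]+):([+-])$", id))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    stop("malformed junction id(s): ", paste(utils::head(id[bad], 3), collapse = ", "))
  }
  data.frame(
    chrom = vapply(m, `[`, character(1), 2L),
    start = as.integer(vapply(m, `[`, character(1), 3L)),
    end = as.integer(vapply(m, `[`, character(1), 4L)),
    strand = vapply(m, `[`, character(1), 5L),
    stringsAsFactors = FALSE
  )
}

# match() that errors on absent keys, listing them
match_strict <- function(x, table, what) {
  i <- match(x, table)
  if (anyNA(i)) {
    stop(what, " not found: ", paste(unique(x[is.na(i)]), collapse = ", "))
  }
  i
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- tiny 0-based half-open interval arithmetic -----------------------------
# Per-transcript exon/CDS sets are a handful of intervals; doing their
# reduce/setdiff in plain R keeps annotation parsing linear in transcript
# count.  Global overlap queries still go through IRanges.

# merge overlapping/adjacent intervals; returns matrix with cols s, e
iv_reduce <- function(s, e) {
  if (length(s) == 0) return(cbind(s = integer(0), e = integer(0)))
  o <- order(s, e)
  s <- s[o]; e <- e[o]
  ks <- s[1]; ke <- e[1]
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_along(s)[-1]) {
    if (s[i] <= ke) {
      ke <- max(ke, e[i])
    } else {
      out_s <- c(out_s, ks); out_e <- c(out_e, ke)
      ks <- s[i]; ke <- e[i]
    }
  }
  cbind(s = c(out_s, ks), e = c(out_e, ke))
}

# bases of (as, ae) not covered by (bs, be); both reduced beforehand
iv_setdiff <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  out_s <- integer(0); out_e <- integer(0)
  for (i in seq_len(nrow(a))) {
    cur_s <- a[i, 1]; cur_e <- a[i, 2]
    for (j in seq_len(nrow(b))) {
      bs <- b[j, 1]; be <- b[j, 2]
      if (be <= cur_s || bs >= cur_e) next
      if (bs > cur_s) { out_s <- c(out_s, cur_s); out_e <- c(out_e, bs) }
      cur_s <- max(cur_s, be)
      if (cur_s >= cur_e) break
    }
    if (cur_s < cur_e) { out_s <- c(out_s, cur_s); out_e <- c(out_e, cur_e) }
  }
  cbind(s = out_s, e = out_e)
}

# gaps between the intervals of a reduced set (annotated introns)
iv_gaps <- function(m) {
  if (nrow(m) < 2) return(cbind(s = integer(0), e = integer(0)))
  cbind(s = m[-nrow(m), 2], e = m[-1, 1])
}
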