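# Junction evidence ingestion and the SPL (splicing level) statistic.
#
# SPL = out / (out + in/2), where `out` counts junction (splicing-out)
# reads that are gapped exactly across the intron and `in` counts reads
# spanning either splice-site boundary contiguously with >= 6 aligned nt on
# both sides (splicing-in), summed over donor and acceptor.  The /2 averages
# the two-site retention evidence so the denominator is commensurate with
# the per-junction out count.

#' Read a STAR SJ.out.tab splice-junction table
#'
#' Columns: chrom, intron start (1-based), intron end (1-based inclusive),
#' strand code (0 undefined, 1 `+`, 2 `-`), motif, annotated flag,
#' unique-mapping reads, multimapping reads, max overhang.  Coordinates are
#' converted to 0-based half-open.  Junctions with strand code 0 are kept on
#' `+` and flagged in the `strand_undefined` column.
#'
#' @param path path to the tab-separated table (no header).
#' @param sample_id sample identifier attached to every row.
#' @param include_multimappers add the multimapping count to `out_reads`
#'   (default `FALSE`).
#' @return data.frame: `junction_id`, `chrom`, `start`, `end`, `strand`,
#'   `strand_undefined`, `sample_id`, `out_reads`.
#' @export
read_sj_table <- function(path, sample_id, include_multimappers = FALSE) {
  cols <- c("chrom", "start1", "end1", "strand_code", "motif", "annotated",
            "unique_reads", "multi_reads", "max_overhang")
  empty <- data.frame(
    junction_id = character(0), chrom = character(0), start = integer(0),
    end = integer(0), strand = character(0), strand_undefined = logical(0),
    sample_id = character(0), out_reads = integer(0), stringsAsFactors = FALSE
  )
  if (file.size(path) == 0) return(empty)
  raw <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(raw) < 9) stop("SJ table ", path, ": expected 9 columns, found ", ncol(raw))
  names(raw)[1:9] <- cols
  for (cc in c("start1", "end1", "strand_code", "unique_reads", "multi_reads")) {
    v <- suppressWarnings(as.integer(raw[[cc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("SJ table ", path, ": non-integer value in column '", cc,
           "' at line ", bad)
    }
    raw[[cc]] <- v
  }
  if (any(raw$strand_code > 2 | raw$strand_code < 0)) {
    stop("SJ table ", path, ": strand code outside {0,1,2}")
  }
  strand <- c("+", "+", "-")[raw$strand_code + 1L]
  out_reads <- raw$unique_reads +
    if (include_multimappers) raw$multi_reads else 0L
  data.frame(
    junction_id = junction_id(raw$chrom, raw$start1 - 1L, raw$end1, strand),
    chrom = raw$chrom,
    start = raw$start1 - 1L,
    end = raw$end1,
    strand = strand,
    strand_undefined = raw$strand_code == 0L,
    sample_id = sample_id,
    out_reads = out_reads,
    stringsAsFactors = FALSE
  )
}

#' Read a splicing-in (spanning-read) count table
#'
#' @param path TSV with header columns `junction_id`, `sample_id`,
#'   `in_reads_total`.
#' @return the validated data.frame.
#' @export
read_in_reads <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("junction_id", "sample_id", "in_reads_total")
  if (!all(need %in% names(df))) {
    stop("in-reads table ", path, " must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$in_reads_total < 0) || any(df$in_reads_total != floor(df$in_reads_total))) {
    stop("in_reads_total must be non-negative integers")
  }
  df
}

#' Splicing level (SPL) of one junction in one sample
#'
#' `SPL = out / (out + in/2)`; `NA` (missing) when there is no evidence at
#' all (`out = 0` and `in = 0`): absence of coverage is not evidence of
#' non-splicing.  Vectorised.
#'
#' @param out_reads non-negative integer(s): junction-spanning (splicing-out)
#'   reads.
#' @param in_reads_total non-negative integer(s): boundary-spanning
#'   (splicing-in) reads summed over donor and acceptor sites.
#' @return numeric in `[0, 1]` or `NA`.
#' @export
compute_spl <- function(out_reads, in_reads_total) {
  if (any(out_reads < 0) || any(in_reads_total < 0)) {
    stop("read counts must be non-negative")
  }
  spl <- out_reads / (out_reads + in_reads_total / 2)
  spl[out_reads == 0 & in_reads_total == 0] <- NA_real_
  spl
}

#' Count splicing-in reads at a junction's boundaries
#'
#' A read contributes 1 at the donor boundary when one of its ungapped
#' aligned blocks covers the boundary with at least `min_overhang` nt on
#' both sides (so a read spliced across this junction, whose blocks stop at
#' the boundary, never counts), and likewise at the acceptor.  A single read
#' spanning both boundaries contributes 2 by default
#' (`dedupe_spanning_reads = TRUE` counts it once).
#'
#' @param blocks data.frame of ungapped aligned blocks with columns
#'   `read_id`, `chrom`, `start`, `end` (0-based half-open).
#' @param junction one-row data.frame (or list) with `chrom`, `start`, `end`.
#' @param min_overhang minimum aligned nt on each side of a boundary
#'   (default 6).
#' @param dedupe_spanning_reads count a doubly-spanning read once.
#' @return integer: `in_reads_total` for the junction.
#' @export
count_in_reads <- function(blocks, junction, min_overhang = 6L,
                           dedupe_spanning_reads = FALSE) {
  if (junction$start < 0) stop("junction outside contig bounds")
  b <- blocks[blocks$chrom == junction$chrom, , drop = FALSE]
  spans <- function(boundary) {
    # block covers [boundary - k, boundary + k) contiguously
    hit <- b$start <= boundary - min_overhang & b$end >= boundary + min_overhang
    unique(b$read_id[hit])
  }
  donor <- spans(junction$start)
  acceptor <- spans(junction$end)
  if (dedupe_spanning_reads) {
    length(unique(c(donor, acceptor)))
  } else {
    length(donor) + length(acceptor)
  }
}

#' Assemble an SPL matrix across samples
#'
#' Takes per-sample junction (splicing-out) counts and splicing-in counts,
#' forms the union of junctions (absent = 0/0, i.e. missing), applies
#' [compute_spl()] elementwise, and attaches cohort labels.
#'
#' @param sj data.frame as returned by [read_sj_table()] (rows from several
#'   samples stacked).
#' @param in_reads data.frame as from [read_in_reads()].
#' @param sample_sheet data.frame with columns `sample_id` and `cohort`
#'   (values `TUMOUR`, `NORMAL`, `REFERENCE_NORMAL`).
#' @return An object of class `spl_matrix`: list with `events` (data.frame:
#'   `junction_id`, `chrom`, `start`, `end`, `strand`), `samples`
#'   (data.frame: `sample_id`, `cohort`), and events x samples matrices
#'   `spl`, `out_reads`, `in_reads`.
#' @export
build_spl_matrix <- function(sj, in_reads, sample_sheet) {
  need <- c("sample_id", "cohort")
  if (!all(need %in% names(sample_sheet))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  bad_cohort <- setdiff(unique(sample_sheet$cohort),
                        c("TUMOUR", "NORMAL", "REFERENCE_NORMAL"))
  if (length(bad_cohort)) stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "))
  seen <- unique(c(sj$sample_id, in_reads$sample_id))
  missing_sheet <- setdiff(seen, sample_sheet$sample_id)
  if (length(missing_sheet)) {
    stop("sample(s) in counts absent from sample sheet: ",
         paste(missing_sheet, collapse = ", "))
  }

  jid <- sort(unique(c(sj$junction_id, in_reads$junction_id)))
  sid <- sample_sheet$sample_id
  out <- matrix(0L, length(jid), length(sid), dimnames = list(jid, sid))
  inn <- out
  if (nrow(sj)) {
    out[cbind(match(sj$junction_id, jid), match(sj$sample_id, sid))] <- sj$out_reads
  }
  if (nrow(in_reads)) {
    inn[cbind(match(in_reads$junction_id, jid),
              match(in_reads$sample_id, sid))] <- as.integer(in_reads$in_reads_total)
  }
  ev <- cbind(junction_id = jid, parse_junction_id(jid))
  spl <- compute_spl(out, inn)
  dim(spl) <- dim(out); dimnames(spl) <- dimnames(out)
  structure(
    list(
      events = ev,
      samples = data.frame(sample_id = sid, cohort = sample_sheet$cohort,
                           stringsAsFactors = FALSE),
      spl = spl, out_reads = out, in_reads = inn
    ),
    class = "spl_matrix"
  )
}

#' @export
print.spl_matrix <- function(x, ...) {
  tab <- table(x$samples$cohort)
  cat("spl_matrix:", nrow(x$events), "events x", nrow(x$samples), "samples (",
      paste(names(tab), tab, collapse = ", "), ")\n")
  invisible(x)
}

#' Serialize / read an SPL matrix as TSV (events as rows, `NA` missing)
#'
#' @param x an `spl_matrix`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_spl_matrix <- function(x, path) {
  df <- data.frame(junction_id = rownames(x$spl),
                   as.data.frame(x$spl, check.names = FALSE),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# cohort-restricted sample ids
cohort_samples <- function(x, cohort) {
  x$samples$sample_id[x$samples$cohort == cohort]
}

#' Build an SPL matrix from precomputed splicing levels
#'
#' Convenience constructor for workflows where SPLs are already computed
#' (or simulated): wraps a values matrix and cohort labels into the
#' `spl_matrix` container used across the package.  Read-count matrices
#' default to placeholders consistent with the values (`NA` cells get
#' 0 out / 0 in; others a nominal depth).
#'
#' @param values events x samples numeric matrix of SPLs in `[0, 1]` with
#'   `NA` for missing; needs row and column names.
#' @param cohort character vector of cohort labels aligned with the
#'   columns.
#' @param out_reads,in_reads optional integer matrices of the same shape.
#' @return an `spl_matrix`.
#' @export
as_spl_matrix <- function(values, cohort, out_reads = NULL, in_reads = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) rownames(values) <- sprintf("ev%04d", seq_len(nrow(values)))
  if (is.null(colnames(values))) colnames(values) <- sprintf("S%04d", seq_len(ncol(values)))
  if (length(cohort) != ncol(values)) stop("cohort labels must match columns")
  if (any(!is.na(values) & (values < 0 | values > 1))) {
    stop("SPL values must lie in [0, 1]")
  }
  if (is.null(out_reads)) {
    out_reads <- matrix(ifelse(is.na(values), 0L, 100L), nrow(values),
                        dimnames = dimnames(values))
  }
  if (is.null(in_reads)) {
    in_reads <- matrix(ifelse(is.na(values), 0L, 100L), nrow(values),
                       dimnames = dimnames(values))
  }
  ids <- rownames(values)
  ev <- tryCatch(cbind(junction_id = ids, parse_junction_id(ids)),
                 error = function(e) data.frame(junction_id = ids,
                                                stringsAsFactors = FALSE))
  structure(
    list(events = ev,
         samples = data.frame(sample_id = colnames(values), cohort = cohort,
                              stringsAsFactors = FALSE),
         spl = values, out_reads = out_reads, in_reads = in_reads),
    class = "spl_matrix"
  )
}
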