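# Gene-annotation parsing and intron region classification.
#
# The classifier implements the 3' UTR exclusivity rule used to nominate
# 3' UTR splicing events: an intron qualifies only when it is fully
# contained in the 3' UTR of at least one same-strand transcript and
# overlaps no CDS and no 5' UTR base of any transcript.

REGION_CLASSES <- c("THREE_UTR_EXCLUSIVE", "FIVE_UTR", "CDS", "NONCODING", "MIXED")

# Light structural validation so parse failures name the offending line.
validate_gtf_lines <- function(path) {
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GTF record at line ", i, ": expected 9 tab-separated fields")
    }
    if (f[3] %in% c("exon", "CDS", "stop_codon") &&
        !grepl("transcript_id", f[9], fixed = TRUE)) {
      stop("malformed GTF attributes at line ", i, ": missing transcript_id")
    }
  }
  invisible(TRUE)
}

#' Parse a GENCODE-style GTF into a genome annotation
#'
#' Reads exon, CDS and stop_codon features, derives 5'/3' UTRs as the exonic
#' regions flanking the CDS (the stop codon is folded into the CDS span, so
#' the 3' UTR begins immediately after it), and builds a region index used
#' by [classify_introns()].  Transcripts without CDS are treated as
#' non-coding.  All internal coordinates are 0-based half-open.
#'
#' @param path path to a GTF file (GTF dialect only; attributes must carry
#'   `transcript_id` and `gene_id`).
#' @return An object of class `genome_annotation`: a list with
#'   \describe{
#'     \item{transcripts}{data.frame of transcript metadata (`transcript_id`,
#'       `gene_id`, `gene_name`, `strand`, `coding`).}
#'     \item{region_index}{named list of GRanges: `FIVE_UTR`, `CDS`,
#'       `THREE_UTR`, `NONCODING_EXON` (stranded).}
#'     \item{utr3_flat}{GRanges of per-transcript reduced 3' UTR intervals
#'       with a `transcript_id` metadata column (containment queries).}
#'     \item{introns}{GRanges of annotated introns (exon gaps) across all
#'       transcripts.}
#'     \item{stop_boundary}{per coding transcript, the 0-based coordinate
#'       where the 3' UTR begins (strand-aware).}
#'   }
#' @export
parse_gtf <- function(path) {
  validate_gtf_lines(path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type %in% c("exon", "CDS", "stop_codon")]
  if (length(gr) == 0) stop("GTF contains no exon/CDS/stop_codon features: ", path)

  # plain 0-based table; per-transcript derivation runs in base R
  feat <- data.frame(
    type = as.character(gr$type),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    s = GenomicRanges::start(gr) - 1L,
    e = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    tx = gr$transcript_id,
    gene = gr$gene_id,
    gname = if (!is.null(gr$gene_name)) gr$gene_name else gr$gene_id,
    stringsAsFactors = FALSE
  )
  exf <- feat[feat$type == "exon", ]
  if (nrow(exf) == 0) stop("GTF contains no exon features: ", path)

  tx_ids <- unique(exf$tx)
  meta_i <- match(tx_ids, exf$tx)
  coding_tx <- unique(feat$tx[feat$type == "CDS"])
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = exf$gene[meta_i],
    gene_name = exf$gname[meta_i],
    strand = exf$strand[meta_i],
    coding = tx_ids %in% coding_tx,
    stringsAsFactors = FALSE
  )

  ex_idx <- split(seq_len(nrow(exf)), exf$tx)
  csf <- feat[feat$type %in% c("CDS", "stop_codon"), ]
  cs_idx <- split(seq_len(nrow(csf)), csf$tx)
  has_stop <- unique(csf$tx[csf$type == "stop_codon"])

  acc <- list(FIVE_UTR = list(), CDS = list(), THREE_UTR = list(),
              NONCODING_EXON = list(), INTRON = list())
  utr3_tx <- list()
  stop_boundary <- numeric(0)
  piece <- function(m, chrom, strand) {
    if (nrow(m) == 0) return(NULL)
    data.frame(chrom = chrom, s = m[, 1], e = m[, 2], strand = strand,
               stringsAsFactors = FALSE)
  }

  for (k in seq_len(nrow(transcripts))) {
    tx <- transcripts$transcript_id[k]
    st <- transcripts$strand[k]
    ei <- ex_idx[[tx]]
    chrom <- exf$chrom[ei[1]]
    ex <- iv_reduce(exf$s[ei], exf$e[ei])
    acc$INTRON[[tx]] <- piece(iv_gaps(ex), chrom, st)
    if (!transcripts$coding[k]) {
      acc$NONCODING_EXON[[tx]] <- piece(ex, chrom, st)
      next
    }
    ci <- cs_idx[[tx]]
    if (!tx %in% has_stop) {
      warning("transcript ", tx,
              " has CDS but no stop_codon; deriving stop from CDS 3' end")
    }
    cdsx <- iv_reduce(csf$s[ci], csf$e[ci]) # stop codon folded into CDS
    span <- c(min(cdsx[, 1]), max(cdsx[, 2]))
    non_cds <- iv_setdiff(ex, cdsx)
    if (st == "+") {
      is_u3 <- non_cds[, 1] >= span[2]
      is_u5 <- non_cds[, 2] <= span[1]
      stop_boundary[tx] <- span[2] # 0-based first base after the stop codon
    } else {
      is_u3 <- non_cds[, 2] <= span[1]
      is_u5 <- non_cds[, 1] >= span[2]
      stop_boundary[tx] <- span[1]
    }
    u3 <- non_cds[is_u3, , drop = FALSE]
    u5 <- non_cds[is_u5, , drop = FALSE]
    # exonic non-CDS pieces sandwiched inside the CDS span (rare) are folded
    # into the CDS index: stringent for the exclusivity rule
    internal <- non_cds[!is_u3 & !is_u5, , drop = FALSE]
    acc$CDS[[tx]] <- piece(rbind(cdsx, internal), chrom, st)
    if (nrow(u5)) acc$FIVE_UTR[[tx]] <- piece(u5, chrom, st)
    if (nrow(u3)) {
      acc$THREE_UTR[[tx]] <- piece(u3, chrom, st)
      utr3_tx[[tx]] <- rep(tx, nrow(u3))
    }
  }

  bind <- function(lst) {
    if (length(lst) == 0) {
      return(data.frame(chrom = character(0), s = integer(0), e = integer(0),
                        strand = character(0), stringsAsFactors = FALSE))
    }
    do.call(rbind, unname(lst))
  }
  to_gr <- function(df) {
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$s + 1L, df$e),
                           strand = df$strand)
  }
  utr3_df <- bind(acc$THREE_UTR)
  utr3_flat <- to_gr(utr3_df)
  if (length(utr3_flat)) {
    S4Vectors::mcols(utr3_flat)$transcript_id <- unlist(utr3_tx, use.names = FALSE)
  }
  utr3_df$transcript_id <- unlist(utr3_tx, use.names = FALSE) %||% character(0)

  ann <- list(
    transcripts = transcripts,
    region_index = list(
      FIVE_UTR = to_gr(bind(acc$FIVE_UTR)),
      CDS = to_gr(bind(acc$CDS)),
      THREE_UTR = GenomicRanges::granges(utr3_flat),
      NONCODING_EXON = to_gr(bind(acc$NONCODING_EXON))
    ),
    utr3_flat = utr3_flat,
    utr3_tab = utr3_df, # 0-based table mirror of utr3_flat, for arithmetic
    introns = to_gr(bind(acc$INTRON)),
    stop_boundary = stop_boundary
  )
  class(ann) <- "genome_annotation"
  ann
}

#' @export
print.genome_annotation <- function(x, ...) {
  cat("genome_annotation:", nrow(x$transcripts), "transcripts (",
      sum(x$transcripts$coding), "coding ),",
      length(x$introns), "annotated introns\n")
  invisible(x)
}

#' Classify introns against UTR/CDS regions
#'
#' Labels each intron as `THREE_UTR_EXCLUSIVE`, `FIVE_UTR`, `CDS`,
#' `NONCODING` or `MIXED`.  An intron is 3' UTR-exclusive iff it is fully
#' contained in the (reduced) 3' UTR of at least one transcript on the same
#' strand and overlaps zero CDS and zero 5' UTR bases.  By default the
#' CDS/5' UTR exclusion considers features on either strand (short-read
#' junction strand is often ambiguous); set `stranded_exclusion = TRUE` to
#' restrict exclusion (and the other label overlaps) to same-strand
#' features.  Introns that overlap a 3' UTR without satisfying containment,
#' or that touch two or more region types, are `MIXED`; introns touching no
#' indexed region (including those on chromosomes absent from the
#' annotation, with a warning) are `NONCODING`.
#'
#' @param introns data.frame with `chrom`, `start`, `end`, `strand`
#'   (0-based half-open).
#' @param ann a `genome_annotation` from [parse_gtf()].
#' @param stranded_exclusion logical; restrict overlaps to the intron strand.
#' @return character vector of region classes, one per intron.
#' @export
classify_introns <- function(introns, ann, stranded_exclusion = FALSE) {
  stopifnot(inherits(ann, "genome_annotation"))
  n <- nrow(introns)
  if (n == 0) return(character(0))
  gr <- intervals_to_gr(introns)

  known <- unique(unlist(lapply(ann$region_index,
                                function(g) as.character(unique(GenomicRanges::seqnames(g))))))
  absent <- setdiff(unique(introns$chrom), known)
  if (length(absent)) {
    warning("chromosome(s) absent from annotation, classified NONCODING: ",
            paste(absent, collapse = ", "))
  }

  ig <- !stranded_exclusion
  cnt <- function(index) {
    suppressWarnings(GenomicRanges::countOverlaps(gr, index, ignore.strand = ig)) > 0
  }
  has_cds <- cnt(ann$region_index$CDS)
  has_u5 <- cnt(ann$region_index$FIVE_UTR)
  has_u3 <- cnt(ann$region_index$THREE_UTR)
  has_nc <- cnt(ann$region_index$NONCODING_EXON)

  # full containment in one same-strand transcript's 3' UTR union
  contained <- rep(FALSE, n)
  if (length(ann$utr3_flat)) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, ann$utr3_flat, ignore.strand = FALSE)
    )
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      w <- GenomicRanges::width(GenomicRanges::pintersect(gr[q], ann$utr3_flat[s]))
      key <- paste(q, ann$utr3_flat$transcript_id[s], sep = "\r")
      covered <- tapply(w, key, sum)
      qi <- as.integer(sub("\r.*", "", names(covered)))
      contained[unique(qi[covered == GenomicRanges::width(gr)[qi]])] <- TRUE
    }
  }

  out <- rep("NONCODING", n)
  nlab <- has_cds + has_u5 + has_u3 + has_nc
  out[nlab >= 2] <- "MIXED"
  out[nlab == 1 & has_cds] <- "CDS"
  out[nlab == 1 & has_u5] <- "FIVE_UTR"
  out[nlab == 1 & has_u3] <- "MIXED"      # 3' UTR touched but not exclusive
  out[contained & !has_cds & !has_u5] <- "THREE_UTR_EXCLUSIVE"
  out
}

#' Export a region index label as 6-column BED
#'
#' @param ann a `genome_annotation`.
#' @param label one of `FIVE_UTR`, `CDS`, `THREE_UTR`, `NONCODING_EXON`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
export_region_bed <- function(ann, label, path) {
  stopifnot(label %in% names(ann$region_index))
  gr <- ann$region_index[[label]]
  df <- gr_to_intervals(gr)
  bed <- data.frame(df$chrom, df$start, df$end, label, 0L, df$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
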