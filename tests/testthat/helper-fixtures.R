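# Shared fixtures and independent oracles.
#
# The annotation oracle works base by base: transcripts are defined as plain
# coordinate lists, UTRs are derived by walking each transcript's exonic
# bases in transcript orientation, and intron classification is decided from
# per-base label membership.  It shares only the *definitions* with the
# package, none of the interval arithmetic.

# 20-transcript fixture on one chromosome, both strands, coding and
# non-coding, with antisense overlaps and spliced-3'UTR isoforms.
# Coordinates are 0-based half-open.
oracle_transcripts <- function() {
  tx <- list(
    # 2-exon coding, CDS ends mid-exon-2
    list(id = "TXP1", gene = "GP1", strand = "+",
         exons = rbind(c(100, 500), c(700, 1400)),
         cds = rbind(c(200, 500), c(700, 900)), stop = c(900, 903)),
    # minus-strand 2-exon coding (stop at the genomic low end of the CDS)
    list(id = "TXM1", gene = "GM1", strand = "-",
         exons = rbind(c(1600, 2300), c(2500, 2900)),
         cds = rbind(c(1900, 2300), c(2600, 2800)), stop = c(1897, 1900)),
    # single-exon coding with a spliced-3'UTR second isoform
    list(id = "TXP2", gene = "GP2", strand = "+",
         exons = rbind(c(3000, 4200)),
         cds = rbind(c(3100, 3600)), stop = c(3600, 3603)),
    list(id = "TXP2B", gene = "GP2", strand = "+",
         exons = rbind(c(3000, 3700), c(3900, 4200)),
         cds = rbind(c(3100, 3600)), stop = c(3600, 3603)),
    # antisense coding gene whose CDS overlaps TXP2's 3' UTR
    list(id = "TXM2", gene = "GM2", strand = "-",
         exons = rbind(c(3800, 4600)),
         cds = rbind(c(3950, 4400)), stop = c(3947, 3950)),
    # noncoding 2-exon
    list(id = "TXN1", gene = "GN1", strand = "+",
         exons = rbind(c(4800, 5200), c(5400, 5800)), cds = NULL, stop = NULL),
    # 5'UTR intron gene
    list(id = "TXP8", gene = "GP8", strand = "+",
         exons = rbind(c(4300, 4500), c(4550, 4750)),
         cds = rbind(c(4600, 4700)), stop = c(4700, 4703)),
    list(id = "TXP3", gene = "GP3", strand = "+",
         exons = rbind(c(6000, 6400), c(6600, 7400)),
         cds = rbind(c(6200, 6400), c(6600, 6800)), stop = c(6800, 6803)),
    # antisense noncoding inside TXP3's 3' UTR
    list(id = "TXN4", gene = "GN4", strand = "-",
         exons = rbind(c(7000, 7300)), cds = NULL, stop = NULL),
    list(id = "TXM3", gene = "GM3", strand = "-",
         exons = rbind(c(7600, 8400)),
         cds = rbind(c(7900, 8200)), stop = c(7897, 7900)),
    # CDS but no stop_codon feature (stop derived from CDS 3' end)
    list(id = "TXP4", gene = "GP4", strand = "+",
         exons = rbind(c(8600, 9200)),
         cds = rbind(c(8700, 9000)), stop = NULL),
    list(id = "TXN2", gene = "GN2", strand = "-",
         exons = rbind(c(9400, 9800)), cds = NULL, stop = NULL),
    list(id = "TXP5", gene = "GP5", strand = "+",
         exons = rbind(c(10000, 11000)),
         cds = rbind(c(10100, 10500)), stop = c(10500, 10503)),
    list(id = "TXP5B", gene = "GP5", strand = "+",
         exons = rbind(c(10000, 10600), c(10800, 11000)),
         cds = rbind(c(10100, 10500)), stop = c(10500, 10503)),
    list(id = "TXM6", gene = "GM6", strand = "-",
         exons = rbind(c(11200, 11500), c(11600, 11900)), cds = NULL, stop = NULL),
    list(id = "TXP9", gene = "GP9", strand = "+",
         exons = rbind(c(12000, 12800)),
         cds = rbind(c(12100, 12400)), stop = c(12400, 12403)),
    list(id = "TXM7", gene = "GM7", strand = "-",
         exons = rbind(c(13000, 13800)),
         cds = rbind(c(13300, 13600)), stop = c(13297, 13300)),
    list(id = "TXN5", gene = "GN5", strand = "+",
         exons = rbind(c(14000, 14500)), cds = NULL, stop = NULL),
    list(id = "TXP10", gene = "GP10", strand = "+",
         exons = rbind(c(14700, 15500)),
         cds = rbind(c(14800, 15100)), stop = c(15100, 15103)),
    list(id = "TXM8", gene = "GM8", strand = "-",
         exons = rbind(c(15600, 15900)), cds = NULL, stop = NULL)
  )
  attr(tx, "chrom") <- "chrT"
  attr(tx, "chrom_len") <- 16000L
  tx
}

write_oracle_gtf <- function(tx, path, shuffle_seed = NULL) {
  chrom <- attr(tx, "chrom")
  lines <- character(0)
  for (t in tx) {
    a <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                 t$gene, t$id, t$gene)
    mk <- function(feature, m) {
      sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t.\t%s",
              chrom, feature, m[, 1] + 1L, m[, 2], t$strand, a)
    }
    lines <- c(lines, mk("exon", t$exons))
    if (!is.null(t$cds)) lines <- c(lines, mk("CDS", t$cds))
    if (!is.null(t$stop)) lines <- c(lines, mk("stop_codon", rbind(t$stop)))
  }
  if (!is.null(shuffle_seed)) {
    lines <- withr::with_seed(shuffle_seed, sample(lines))
  }
  writeLines(lines, path)
  invisible(path)
}

# per-base truth: for each transcript, UTR bases derived by walking exonic
# bases in transcript orientation relative to the CDS(+stop) bases
oracle_base_labels <- function(tx) {
  L <- attr(tx, "chrom_len")
  labels <- c("FIVE_UTR", "CDS", "THREE_UTR", "NONCODING_EXON")
  masks <- list(
    "+" = lapply(stats::setNames(labels, labels), function(l) rep(FALSE, L)),
    "-" = lapply(stats::setNames(labels, labels), function(l) rep(FALSE, L))
  )
  utr3_bases <- list()
  for (t in tx) {
    ex_bases <- sort(unlist(apply(t$exons, 1, function(r) (r[1] + 1):r[2],
                                  simplify = FALSE))) # 1-based base indices
    if (is.null(t$cds)) {
      masks[[t$strand]][["NONCODING_EXON"]][ex_bases] <- TRUE
      next
    }
    cds_bases <- sort(unique(c(
      unlist(apply(t$cds, 1, function(r) (r[1] + 1):r[2], simplify = FALSE)),
      if (!is.null(t$stop)) (t$stop[1] + 1):t$stop[2]
      else {
        # no stop feature: last 3 CDS bases in transcript orientation
        cb <- unlist(apply(t$cds, 1, function(r) (r[1] + 1):r[2],
                           simplify = FALSE))
        cb <- sort(cb)
        if (t$strand == "+") utils::tail(cb, 3) else utils::head(cb, 3)
      }
    )))
    walk <- if (t$strand == "+") ex_bases else rev(ex_bases)
    in_cds <- walk %in% cds_bases
    first <- min(which(in_cds)); last <- max(which(in_cds))
    u5 <- walk[seq_len(first - 1)]
    u3 <- if (last < length(walk)) walk[(last + 1):length(walk)] else integer(0)
    mid <- walk[first:last]
    masks[[t$strand]][["FIVE_UTR"]][u5] <- TRUE
    masks[[t$strand]][["CDS"]][mid] <- TRUE # internal non-CDS pieces fold in
    masks[[t$strand]][["THREE_UTR"]][u3] <- TRUE
    if (length(u3)) utr3_bases[[t$id]] <- list(strand = t$strand, bases = u3)
  }
  list(masks = masks, utr3_bases = utr3_bases, chrom_len = L)
}

# brute-force classification of one intron from per-base membership
oracle_classify_one <- function(s, e, strand, truth, stranded = FALSE) {
  bases <- (s + 1):e
  get <- function(lbl) {
    if (stranded) truth$masks[[strand]][[lbl]][bases]
    else truth$masks[["+"]][[lbl]][bases] | truth$masks[["-"]][[lbl]][bases]
  }
  has_cds <- any(get("CDS")); has_u5 <- any(get("FIVE_UTR"))
  has_u3 <- any(get("THREE_UTR")); has_nc <- any(get("NONCODING_EXON"))
  contained <- any(vapply(truth$utr3_bases, function(u) {
    u$strand == strand && all(bases %in% u$bases)
  }, logical(1)))
  if (contained && !has_cds && !has_u5) return("THREE_UTR_EXCLUSIVE")
  nl <- has_cds + has_u5 + has_u3 + has_nc
  if (nl >= 2) return("MIXED")
  if (nl == 0) return("NONCODING")
  if (has_cds) "CDS" else if (has_u5) "FIVE_UTR" else if (has_nc) "NONCODING" else "MIXED"
}

random_introns <- function(n, chrom_len, seed, chrom = "chrT") {
  withr::with_seed(seed, {
    start <- sample.int(chrom_len - 600L, n, replace = TRUE) - 1L
    len <- sample(20:500, n, replace = TRUE)
    data.frame(chrom = chrom, start = start, end = start + len,
               strand = sample(c("+", "-"), n, replace = TRUE),
               stringsAsFactors = FALSE)
  })
}

parsed_oracle_annotation <- function() {
  tx <- oracle_transcripts()
  gtf <- tempfile(fileext = ".gtf")
  write_oracle_gtf(tx, gtf)
  suppressWarnings(parse_gtf(gtf)) # TXP4 triggers the missing-stop warning
}

# exact two-sided Mann-Whitney p by enumeration of all group assignments
oracle_mw_exact_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  u_stat <- function(ix) {
    gx <- pooled[ix]; gy <- pooled[-ix]
    sum(outer(gx, gy, ">")) + 0.5 * sum(outer(gx, gy, "=="))
  }
  combos <- utils::combn(n, length(x))
  us <- apply(combos, 2, u_stat)
  u_obs <- u_stat(seq_along(x))
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# independent step-up BH
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- Inf
  for (k in rev(seq_len(m))) {
    prev <- min(prev, p[o[k]] * m / k)
    q[o[k]] <- min(1, prev)
  }
  q
}

# exhaustive hypergeometric upper tail by enumerating draws
oracle_hyper_upper <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K)) # first K items = set A
  mean(hits >= k)
}

# tiny simulated cohort for fast end-to-end tests
small_sim <- function(dir, seed = 11, ...) {
  cfg <- sim_config(n_events = 60L, n_tumour = 12L, n_normal = 12L,
                    n_reference = 12L, depth_mean = 60, seed = seed, ...)
  simulate_cohort(cfg, dir)
}

load_sim_matrix <- function(dir) {
  utr3splice:::load_spl_matrix(dir)
}
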