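# Synthetic cohort generator.
#
# Emulates the statistical structure the analysis assumes: per-event
# baseline splicing levels drawn from a Beta distribution, per-sample
# biological variation around the baseline, binomial read sampling at a
# Poisson depth, a median SPL shift in tumours for a designated dysregulated
# subset, SPL-dependent exponential survival with uniform censoring, and
# decoy events in CDS/5' UTR/non-coding regions to exercise the classifier.
# The splicing-in counts are generated as twice the unspliced draw
# (in = 2 * (depth - out)) so the plug-in SPL out/(out + in/2) = out/depth
# recovers the true splicing probability without bias: the simulator is the
# exact inverse of the SPL formula under its two-site convention.

#' Simulation configuration
#'
#' Defaults define the study conditions used throughout the package's
#' recovery tests: 400 events (80% in 3' UTRs), cohorts of 40 tumour / 40
#' matched normal / 40 reference normal samples, mean informative depth 80
#' reads per event per sample, Beta(2, 6) baseline SPLs, 5% of 3' UTR
#' events dysregulated with a +0.25 tumour median shift, and a log-hazard
#' of 1.5 per unit SPL for the prognostic (= dysregulated) events.
#'
#' @param n_events total designed events.
#' @param frac_3utr fraction placed in 3' UTRs (the rest split across CDS,
#'   5' UTR and non-coding decoys).
#' @param n_tumour,n_normal,n_reference cohort sizes.
#' @param depth_mean mean informative reads per event per sample (Poisson).
#' @param baseline_spl_alpha,baseline_spl_beta Beta parameters of per-event
#'   baseline SPLs.
#' @param frac_dysregulated fraction of 3' UTR events given a tumour shift.
#' @param delta tumour median SPL shift for dysregulated events.
#' @param surv_beta log hazard ratio per unit SPL for prognostic events.
#' @param frac_alu fraction of 3' UTR event introns overlapped by a
#'   designed Alu repeat.
#' @param frac_annotated fraction of 3' UTR events also present as an
#'   annotated spliced isoform in the reference GTF.
#' @param frac_pacbio fraction of 3' UTR events supported by a designed
#'   long-read isoform model.
#' @param spl_precision Beta concentration of per-sample variation around
#'   the event baseline.
#' @param seed integer seed for all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_events = 400L, frac_3utr = 0.8,
                       n_tumour = 40L, n_normal = 40L, n_reference = 40L,
                       depth_mean = 80, baseline_spl_alpha = 2,
                       baseline_spl_beta = 6, frac_dysregulated = 0.05,
                       delta = 0.25, surv_beta = 1.5, frac_alu = 0.4,
                       frac_annotated = 0.5, frac_pacbio = 0.5,
                       spl_precision = 100, seed = 1L) {
  cfg <- list(
    n_events = as.integer(n_events), frac_3utr = frac_3utr,
    n_tumour = as.integer(n_tumour), n_normal = as.integer(n_normal),
    n_reference = as.integer(n_reference), depth_mean = depth_mean,
    baseline_spl_alpha = baseline_spl_alpha,
    baseline_spl_beta = baseline_spl_beta,
    frac_dysregulated = frac_dysregulated, delta = delta,
    surv_beta = surv_beta, frac_alu = frac_alu,
    frac_annotated = frac_annotated, frac_pacbio = frac_pacbio,
    spl_precision = spl_precision, seed = as.integer(seed)
  )
  fr <- c(cfg$frac_3utr, cfg$frac_dysregulated, cfg$frac_alu,
          cfg$frac_annotated, cfg$frac_pacbio)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (abs(cfg$delta) >= 1) stop("delta must lie in (-1, 1)")
  if (cfg$depth_mean <= 0) stop("depth_mean must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

GENE_SPACING <- 10000L
GENE_LEN <- 4000L

# deterministic locus table: one gene per designed event
sim_loci <- function(cfg) {
  n <- cfg$n_events
  n3 <- max(1L, round(cfg$frac_3utr * n))
  rest <- n - n3
  placement <- c(rep("THREE_UTR_EXCLUSIVE", n3),
                 rep(c("CDS", "FIVE_UTR", "NONCODING"), length.out = rest))
  strand <- rep(c("+", "-"), length.out = n)
  strand[1] <- "+" # CTNNB1-like locus
  g0 <- (seq_len(n) - 1L) * GENE_SPACING
  ilen <- 300L
  # donor offsets downstream of the stop codon: concentrated near the stop
  # (most 3' UTR donors escape the 50-nt NMD window) with a long-distance
  # minority
  off <- rep_len(c(10L, 25L, 40L, 80L, 150L), n)
  off[1] <- 11L # splice site 11 nt downstream of the stop codon
  loci <- data.frame(
    idx = seq_len(n),
    gene_id = sprintf("G%04d", seq_len(n)),
    gene_name = c("CTNNB1L", sprintf("GENE%04d", seq_len(n)[-1])),
    chrom = "chrS",
    g0 = g0, strand = strand, placement = placement,
    coding = placement != "NONCODING",
    stringsAsFactors = FALSE
  )
  # intron coordinates (0-based half-open) per placement
  s <- integer(n); e <- integer(n)
  for (i in seq_len(n)) {
    gi <- g0[i]
    if (strand[i] == "+") {
      b0 <- gi + 1600L
      se <- switch(placement[i],
        THREE_UTR_EXCLUSIVE = c(b0 + off[i], b0 + off[i] + ilen),
        CDS = c(gi + 800L, gi + 1100L),
        FIVE_UTR = c(gi + 100L, gi + 400L),
        NONCODING = c(gi + 1000L, gi + 1300L))
    } else {
      b0 <- gi + 2400L
      se <- switch(placement[i],
        THREE_UTR_EXCLUSIVE = c(b0 - off[i] - ilen, b0 - off[i]),
        CDS = c(gi + 2600L, gi + 2900L),
        FIVE_UTR = c(gi + 3500L, gi + 3800L),
        NONCODING = c(gi + 1000L, gi + 1300L))
    }
    s[i] <- se[1]; e[i] <- se[2]
  }
  loci$start <- s
  loci$end <- e
  loci$junction_id <- junction_id(loci$chrom, loci$start, loci$end, loci$strand)
  loci$stop_offset <- off
  loci
}

gtf_attr <- function(gene_id, tx_id, gene_name) {
  sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
          gene_id, tx_id, gene_name)
}

gtf_line <- function(chrom, feature, start0, end0, strand, attr) {
  sprintf("%s\tsim\t%s\t%d\t%d\t.\t%s\t.\t%s",
          chrom, feature, start0 + 1L, end0, strand, attr)
}

# GTF lines for one locus; annotated_iso adds a second, spliced transcript
# whose exons flank the designed intron
locus_gtf <- function(l, annotated_iso = FALSE) {
  gs <- l$g0; ge <- l$g0 + GENE_LEN
  a1 <- gtf_attr(l$gene_id, paste0(l$gene_id, "T1"), l$gene_name)
  lines <- gtf_line(l$chrom, "exon", gs, ge, l$strand, a1)
  if (l$coding) {
    if (l$strand == "+") {
      cds <- c(gs + 600L, gs + 1597L); stp <- c(gs + 1597L, gs + 1600L)
    } else {
      cds <- c(gs + 2403L, gs + 3400L); stp <- c(gs + 2400L, gs + 2403L)
    }
    lines <- c(lines,
               gtf_line(l$chrom, "CDS", cds[1], cds[2], l$strand, a1),
               gtf_line(l$chrom, "stop_codon", stp[1], stp[2], l$strand, a1))
    if (annotated_iso) {
      a2 <- gtf_attr(l$gene_id, paste0(l$gene_id, "T2"), l$gene_name)
      lines <- c(lines,
                 gtf_line(l$chrom, "exon", gs, l$start, l$strand, a2),
                 gtf_line(l$chrom, "exon", l$end, ge, l$strand, a2),
                 gtf_line(l$chrom, "CDS", cds[1], cds[2], l$strand, a2),
                 gtf_line(l$chrom, "stop_codon", stp[1], stp[2], l$strand, a2))
    }
  }
  lines
}

#' Write the fixture annotation GTF for a simulation
#'
#' One gene per designed event: coding loci with 5' UTR / CDS / stop codon /
#' 3' UTR on alternating strands, non-coding decoys, and (for a designed
#' fraction of 3' UTR events) a second annotated isoform spliced exactly at
#' the event intron.  The first locus reproduces the CTNNB1 geometry: a 3'
#' UTR splice donor 11 nt downstream of the stop codon.
#'
#' @param cfg a `sim_config`.
#' @param path output GTF path.
#' @param annotated_idx indices of loci that get the spliced isoform
#'   (computed by [simulate_cohort()]; default none).
#' @return invisibly, the locus table.
#' @export
make_fixture_annotation <- function(cfg, path, annotated_idx = integer(0)) {
  loci <- sim_loci(cfg)
  lines <- unlist(lapply(seq_len(nrow(loci)), function(i) {
    locus_gtf(loci[i, ], annotated_iso = i %in% annotated_idx)
  }))
  writeLines(c("## fixture annotation (synthetic)", lines), path)
  invisible(loci)
}

write_isoform_gtf <- function(loci, idx, path) {
  lines <- unlist(lapply(idx, function(i) {
    l <- loci[i, ]
    a <- gtf_attr(paste0("PB", l$gene_id), paste0("PB", l$gene_id, "T1"),
                  l$gene_name)
    c(gtf_line(l$chrom, "exon", l$g0, l$start, l$strand, a),
      gtf_line(l$chrom, "exon", l$end, l$g0 + GENE_LEN, l$strand, a))
  }))
  writeLines(c("## long-read isoform models (synthetic)", lines %||% character(0)), path)
}

num <- function(x) sprintf("%.6g", x)

#' Simulate a full synthetic cohort
#'
#' Writes, under `out_dir`: `annotation.gtf`, per-sample STAR-dialect
#' junction tables under `sj/`, `in_reads.tsv`, `sample_sheet.tsv`,
#' `clinical.tsv` (tumour samples), `repeats.bed`, `isoforms.gtf`, and the
#' ground truth (`truth_events.tsv`, `true_spl.tsv`).  All outputs are
#' byte-stable for a fixed seed.
#'
#' @param cfg a `sim_config`.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the file `paths`, the locus table
#'   (`loci`), and the ground truth: `true_spl` (events x samples matrix),
#'   `dysregulated_ids`, `prognostic_ids`, `designed_over_spliced`
#'   (data.frame event_id/sample_id), `placement`.
#' @export
simulate_cohort <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  dir.create(file.path(out_dir, "sj"), recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  loci <- sim_loci(cfg)
  n_ev <- nrow(loci)
  idx3 <- which(loci$placement == "THREE_UTR_EXCLUSIVE")

  n_dys <- round(cfg$frac_dysregulated * n_ev)
  if (n_dys > length(idx3)) stop("frac_dysregulated exceeds available 3' UTR events")
  dys_idx <- sort(sample(idx3, n_dys))
  ann_idx <- sort(sample(idx3, round(cfg$frac_annotated * length(idx3))))
  pb_idx <- sort(sample(idx3, round(cfg$frac_pacbio * length(idx3))))
  alu_idx <- sort(sample(idx3, round(cfg$frac_alu * length(idx3))))

  samples <- data.frame(
    sample_id = c(sprintf("T%03d", seq_len(cfg$n_tumour)),
                  sprintf("N%03d", seq_len(cfg$n_normal)),
                  sprintf("R%03d", seq_len(cfg$n_reference))),
    cohort = c(rep("TUMOUR", cfg$n_tumour), rep("NORMAL", cfg$n_normal),
               rep("REFERENCE_NORMAL", cfg$n_reference)),
    stringsAsFactors = FALSE
  )
  n_smp <- nrow(samples)
  is_tum <- samples$cohort == "TUMOUR"

  baseline <- stats::rbeta(n_ev, cfg$baseline_spl_alpha, cfg$baseline_spl_beta)
  mshift <- matrix(0, n_ev, n_smp)
  mshift[dys_idx, is_tum] <- cfg$delta
  m <- baseline + mshift
  if (any(m <= 0 | m >= 1)) {
    warning("shifted mean SPL outside (0, 1); clipping")
    m <- pmin(pmax(m, 0.005), 0.995)
  }
  nu <- cfg$spl_precision
  p_true <- matrix(stats::rbeta(n_ev * n_smp, m * nu, (1 - m) * nu), n_ev, n_smp)
  depth <- matrix(stats::rpois(n_ev * n_smp, cfg$depth_mean), n_ev, n_smp)
  out <- matrix(stats::rbinom(n_ev * n_smp, depth, p_true), n_ev, n_smp)
  inn <- 2L * (depth - out)
  dimnames(p_true) <- dimnames(out) <- dimnames(inn) <-
    list(loci$junction_id, samples$sample_id)

  paths <- list(
    annotation = file.path(out_dir, "annotation.gtf"),
    isoforms = file.path(out_dir, "isoforms.gtf"),
    repeats = file.path(out_dir, "repeats.bed"),
    sample_sheet = file.path(out_dir, "sample_sheet.tsv"),
    in_reads = file.path(out_dir, "in_reads.tsv"),
    clinical = file.path(out_dir, "clinical.tsv"),
    truth_events = file.path(out_dir, "truth_events.tsv"),
    true_spl = file.path(out_dir, "true_spl.tsv"),
    sj_dir = file.path(out_dir, "sj")
  )

  make_fixture_annotation(cfg, paths$annotation, annotated_idx = ann_idx)
  write_isoform_gtf(loci, pb_idx, paths$isoforms)

  # repeats: an Alu over the left half of designed introns, plus an L1 decoy
  bed <- character(0)
  for (i in alu_idx) {
    bed <- c(bed, sprintf("%s\t%d\t%d\tAluYa5\t0\t+", loci$chrom[i],
                          loci$start[i] + 10L,
                          loci$start[i] + 10L + (loci$end[i] - loci$start[i]) %/% 2L))
  }
  bed <- c(bed, sprintf("%s\t%d\t%d\tL1PA2\t0\t-", loci$chrom[1],
                        loci$g0[1] + 4200L, loci$g0[1] + 4800L))
  writeLines(bed, paths$repeats)

  utils::write.table(samples, paths$sample_sheet, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  strand_code <- ifelse(loci$strand == "+", 1L, 2L)
  for (j in seq_len(n_smp)) {
    keep <- out[, j] > 0
    sj <- sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t20",
                  loci$chrom[keep], loci$start[keep] + 1L, loci$end[keep],
                  strand_code[keep], out[keep, j])
    writeLines(sj, file.path(paths$sj_dir,
                             paste0(samples$sample_id[j], ".SJ.out.tab")))
  }
  ii <- which(inn > 0, arr.ind = TRUE)
  in_df <- data.frame(
    junction_id = loci$junction_id[ii[, 1]],
    sample_id = samples$sample_id[ii[, 2]],
    in_reads_total = inn[ii]
  )
  in_df <- in_df[order(in_df$junction_id, in_df$sample_id), ]
  utils::write.table(in_df, paths$in_reads, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # survival: tumour hazard scales with the mean true SPL over prognostic
  # events; uniform censoring
  prog_idx <- dys_idx
  x_s <- if (length(prog_idx)) {
    colMeans(p_true[prog_idx, is_tum, drop = FALSE])
  } else {
    rep(0.5, sum(is_tum))
  }
  h0 <- 1 / 1500
  t_death <- stats::rexp(sum(is_tum), rate = h0 * exp(cfg$surv_beta * x_s))
  t_cens <- stats::runif(sum(is_tum), 1, 3000)
  clinical <- data.frame(
    sample_id = samples$sample_id[is_tum],
    time_days = num(pmax(pmin(t_death, t_cens), 0.1)),
    event = as.integer(t_death <= t_cens)
  )
  utils::write.table(clinical, paths$clinical, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # designed over-spliced (event, tumour sample) pairs: true SPL above the
  # nearest-rank q90 of the event's normal-group true SPLs
  designed <- list()
  nor_cols <- samples$cohort == "NORMAL"
  for (i in dys_idx) {
    q90 <- nearest_rank_quantile(p_true[i, nor_cols], 0.9)
    hits <- which(p_true[i, is_tum] > q90)
    if (length(hits)) {
      designed[[length(designed) + 1L]] <- data.frame(
        event_id = loci$junction_id[i],
        sample_id = samples$sample_id[is_tum][hits],
        stringsAsFactors = FALSE
      )
    }
  }
  designed <- if (length(designed)) do.call(rbind, designed) else
    data.frame(event_id = character(0), sample_id = character(0))

  truth <- data.frame(
    junction_id = loci$junction_id,
    placement = loci$placement,
    baseline_spl = num(baseline),
    dysregulated = seq_len(n_ev) %in% dys_idx,
    prognostic = seq_len(n_ev) %in% prog_idx,
    annotated_isoform = seq_len(n_ev) %in% ann_idx,
    pacbio_designed = seq_len(n_ev) %in% pb_idx,
    alu_designed = seq_len(n_ev) %in% alu_idx,
    stringsAsFactors = FALSE
  )
  utils::write.table(truth, paths$truth_events, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tsp <- data.frame(junction_id = loci$junction_id,
                    apply(p_true, 2, num), check.names = FALSE)
  utils::write.table(tsp, paths$true_spl, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    paths = paths, loci = loci, config = cfg,
    true_spl = p_true,
    dysregulated_ids = loci$junction_id[dys_idx],
    prognostic_ids = loci$junction_id[prog_idx],
    designed_over_spliced = designed,
    placement = stats::setNames(loci$placement, loci$junction_id)
  ))
}

#' Simulate proportional-hazards survival for a covariate
#'
#' Exponential event times with log-hazard `log_hr * x` over a baseline
#' hazard, censored uniformly: the parameter-recovery oracle for
#' [cox_per_event()].
#'
#' @param x named covariate vector (e.g. SPLs; names become sample ids).
#' @param log_hr log hazard ratio per unit covariate.
#' @param baseline_hazard events per day at `x = 0` (default 1/1500).
#' @param censor_max upper bound of uniform censoring in days.
#' @return clinical data.frame (`sample_id`, `time_days`, `event`).
#' @export
simulate_survival <- function(x, log_hr, baseline_hazard = 1 / 1500,
                              censor_max = 3000) {
  n <- length(x)
  t_death <- stats::rexp(n, rate = baseline_hazard * exp(log_hr * x))
  t_cens <- stats::runif(n, 1, censor_max)
  data.frame(
    sample_id = names(x) %||% sprintf("S%03d", seq_len(n)),
    time_days = pmax(pmin(t_death, t_cens), 0.1),
    event = as.integer(t_death <= t_cens),
    stringsAsFactors = FALSE
  )
}
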