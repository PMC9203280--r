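# helper: spl_matrix with designed counts on the oracle fixture's 3' UTR
# introns plus decoys, for exercising the discovery filters
make_discovery_matrix <- function() {
  ids <- c(
    u1 = "chrT:950-1100:+",   # TXP1 3' UTR
    u2 = "chrT:1650-1800:-",  # TXM1 3' UTR
    u3 = "chrT:3650-3750:+",  # TXP2 3' UTR
    mx = "chrT:4000-4100:+",  # 3' UTR but antisense CDS overlap
    cd = "chrT:250-350:+",    # CDS
    nc = "chrT:4900-5100:+"   # non-coding exon
  )
  sheet <- data.frame(sample_id = c("s1", "s2", "s3"),
                      cohort = c("TUMOUR", "TUMOUR", "NORMAL"))
  sj <- expand.grid(junction_id = unname(ids), sample_id = sheet$sample_id,
                    stringsAsFactors = FALSE)
  # designed counts: u1 well supported; u2 only 1 read; u3 SPL exactly 0.10;
  # mx/cd/nc well supported but wrong region
  out_by <- c(10L, 1L, 1L, 10L, 10L, 10L)
  names(out_by) <- unname(ids)
  sj$out_reads <- out_by[sj$junction_id]
  inr <- sj
  names(inr)[3] <- "in_reads_total"
  inr$in_reads_total <- 20L
  inr$in_reads_total[inr$junction_id == ids[["u3"]]] <- 18L # 1/(1+9) = 0.10
  list(sm = build_spl_matrix(sj, inr, sheet), ids = ids)
}

test_that("discovery applies region, read-support and SPL filters jointly", {
  ann <- parsed_oracle_annotation()
  d <- make_discovery_matrix()
  ev <- discover_3usps(d$sm, ann)
  # u1 passes; u2 fails min_reads; u3 fails strict SPL > 0.10; mx/cd/nc fail
  # the region filter
  expect_equal(ev$junction_id, unname(d$ids[["u1"]]))
  expect_equal(ev$region, "THREE_UTR_EXCLUSIVE")
  expect_equal(ev$gene_ids, "GP1")
  # all survivors re-classify as exclusive
  expect_true(all(classify_introns(ev, ann) == "THREE_UTR_EXCLUSIVE"))
  # loosening thresholds admits the boundary cases
  ev2 <- discover_3usps(d$sm, ann, min_reads = 1, min_spl = 0.09)
  expect_setequal(ev2$junction_id, unname(d$ids[c("u1", "u2", "u3")]))
})

test_that("support conditions are evaluated within the same sample", {
  ann <- parsed_oracle_annotation()
  sheet <- data.frame(sample_id = c("s1", "s2"), cohort = c("TUMOUR", "NORMAL"))
  # s1 has reads but low SPL; s2 has high SPL but 1 read
  sj <- data.frame(junction_id = rep("chrT:950-1100:+", 2),
                   sample_id = c("s1", "s2"), out_reads = c(5L, 1L))
  inr <- data.frame(junction_id = rep("chrT:950-1100:+", 2),
                    sample_id = c("s1", "s2"), in_reads_total = c(200L, 0L))
  sm <- build_spl_matrix(sj, inr, sheet)
  expect_equal(nrow(discover_3usps(sm, ann)), 0)
})

test_that("c3USP requires SPL above threshold in a strict majority", {
  expect_true(call_c3usp(c(rep(0.2, 6), rep(0.05, 4))))   # 6 of 10
  expect_false(call_c3usp(c(rep(0.2, 5), rep(0.05, 5))))  # 5 of 10
  expect_false(call_c3usp(rep(NA_real_, 8)))
  expect_false(call_c3usp(rep(0.10, 9)))                  # strict >
  expect_error(call_c3usp(numeric(0)), "empty")
  # missing counts in the denominator by default, not under "observed"
  x <- c(0.3, 0.3, NA, NA)
  expect_false(call_c3usp(x))
  expect_true(call_c3usp(x, denominator = "observed"))
})

test_that("c3USP agrees with a counting oracle on all small configurations", {
  # every assignment of {below, above, missing} to up to 8 samples
  for (n in 1:8) {
    grid <- expand.grid(rep(list(0:2), n))
    for (r in seq_len(nrow(grid))) {
      v <- c(0.02, 0.5, NA_real_)[unlist(grid[r, ]) + 1L]
      n_above <- sum(!is.na(v) & v > 0.10)
      expect_equal(call_c3usp(v), n_above > n / 2)
      n_obs <- sum(!is.na(v))
      expect_equal(call_c3usp(v, denominator = "observed"),
                   n_obs > 0 && n_above > n_obs / 2)
    }
  }
})

test_that("c3USP is monotone in adding above-threshold samples", {
  set.seed(9)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    v <- runif(n)
    if (call_c3usp(v)) {
      expect_true(call_c3usp(c(v[-1], 0.9))) # replace one sample with high SPL
    }
  }
})

test_that("burden normalization divides and rejects bad inputs", {
  expect_equal(normalize_burden(0, 5000), 0)
  expect_equal(normalize_burden(250, 5000), 0.05)
  expect_error(normalize_burden(10, 0), "> 0")
  expect_error(normalize_burden(10, 5), "<=")
})

test_that("per-sample burden flags low-depth samples for exclusion", {
  d <- make_discovery_matrix()
  ann <- parsed_oracle_annotation()
  ev <- discover_3usps(d$sm, ann)
  b <- splice_burden(d$sm, ev, min_depth_junctions = 1000L)
  expect_true(all(b$low_depth)) # tiny fixture is far below 1,000 junctions
  expect_true(all(b$burden >= 0 & b$burden <= 1, na.rm = TRUE))
  # s1: supported junctions = u1, mx, cd, nc (out=10, spl=0.5); 3USP = u1
  s1 <- b[b$sample_id == "s1", ]
  expect_equal(s1$n_all_splicing, 4)
  expect_equal(s1$n_3usp, 1)
  expect_equal(s1$burden, 0.25)
})

test_that("long-read and annotation support require exact boundary identity", {
  iso <- tempfile(fileext = ".gtf")
  writeLines(c(
    'c1\tpb\texon\t1\t100\t.\t+\t.\tgene_id "pb1"; transcript_id "pbt1";',
    'c1\tpb\texon\t201\t300\t.\t+\t.\tgene_id "pb1"; transcript_id "pbt1";',
    'c1\tpb\texon\t401\t500\t.\t+\t.\tgene_id "pb2"; transcript_id "pbt2";',
    'c1\tpb\texon\t601\t700\t.\t+\t.\tgene_id "pb2"; transcript_id "pbt2";'
  ), iso)
  ev <- data.frame(
    chrom = c("c1", "c1", "c1", "c2"),
    start = c(100, 101, 500, 100),
    end = c(200, 200, 600, 200),
    strand = "+", stringsAsFactors = FALSE
  )
  expect_equal(match_longread_support(ev, iso), c(TRUE, FALSE, TRUE, FALSE))
})

test_that("long-read support matches a brute-force all-pairs comparison", {
  set.seed(31)
  # random isoforms: 10 two-exon models
  iso_introns <- data.frame(chrom = sample(c("c1", "c2"), 10, replace = TRUE),
                            start = sample(1000:2000, 10),
                            strand = sample(c("+", "-"), 10, replace = TRUE))
  iso_introns$end <- iso_introns$start + sample(50:200, 10)
  iso <- tempfile(fileext = ".gtf")
  writeLines(unlist(lapply(seq_len(10), function(i) {
    a <- sprintf('gene_id "g%d"; transcript_id "t%d";', i, i)
    with(iso_introns[i, ], c(
      sprintf("%s\tpb\texon\t%d\t%d\t.\t%s\t.\t%s", chrom, start - 99L, start, strand, a),
      sprintf("%s\tpb\texon\t%d\t%d\t.\t%s\t.\t%s", chrom, end + 1L, end + 100L, strand, a)
    ))
  })), iso)
  # 20 query events: half copied from isoforms (strand scrambled), half shifted
  ev <- iso_introns[sample(10, 20, replace = TRUE), ]
  ev$strand <- sample(c("+", "-"), 20, replace = TRUE)
  shift <- sample(c(rep(0, 10), rep(1, 10)))
  ev$start <- ev$start + shift
  got <- match_longread_support(ev, iso)
  want <- vapply(seq_len(20), function(i) {
    any(vapply(seq_len(10), function(j) {
      ev$chrom[i] == iso_introns$chrom[j] &&
        ev$start[i] == iso_introns$start[j] &&
        ev$end[i] == iso_introns$end[j]
    }, logical(1)))
  }, logical(1))
  expect_equal(got, want)
})

test_that("annotated-intron check uses the reference annotation's exon gaps", {
  ann <- parsed_oracle_annotation()
  ev <- data.frame(
    chrom = "chrT",
    start = c(3700, 500, 3701, 10600),
    end = c(3900, 700, 3900, 10800),
    strand = "+", stringsAsFactors = FALSE
  )
  # TXP2B's 3'UTR intron and TXP1's CDS intron are annotated; offsets are not
  expect_equal(check_annotated(ev, ann), c(TRUE, TRUE, FALSE, TRUE))
})
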