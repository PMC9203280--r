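test_that("SPL follows the closed form and returns missing on no evidence", {
  expect_equal(compute_spl(10, 0), 1.0)
  expect_equal(compute_spl(0, 8), 0.0)
  expect_equal(compute_spl(5, 10), 0.5) # 5 / (5 + 10/2)
  expect_true(is.na(compute_spl(0, 0)))
  expect_error(compute_spl(-1, 5), "non-negative")

  # full grid against the closed form, including monotonicity
  g <- expand.grid(out = 0:100, inn = 0:100)
  spl <- compute_spl(g$out, g$inn)
  want <- g$out / (g$out + g$inn / 2)
  want[g$out == 0 & g$inn == 0] <- NA_real_
  expect_equal(spl, want)
  m <- matrix(spl, 101, 101) # rows: out 0..100, cols: in 0..100
  expect_true(all(diff(m[, 1]) >= 0 | is.na(diff(m[, 1]))))
  for (j in 2:101) expect_true(all(diff(m[, j]) > 0, na.rm = TRUE))
  for (i in 2:101) expect_true(all(diff(m[i, ]) < 0, na.rm = TRUE))
})

test_that("SJ tables parse with 1-based to 0-based conversion", {
  f <- tempfile()
  writeLines(c("chr1\t101\t200\t1\t1\t0\t7\t3\t30",
               "chr1\t501\t700\t2\t2\t1\t4\t0\t25",
               "chr2\t11\t90\t0\t0\t0\t2\t5\t12"), f)
  sj <- read_sj_table(f, "s1")
  expect_equal(sj$junction_id,
               c("chr1:100-200:+", "chr1:500-700:-", "chr2:10-90:+"))
  expect_equal(sj$out_reads, c(7, 4, 2))
  expect_equal(sj$strand_undefined, c(FALSE, FALSE, TRUE))
  sj_mm <- read_sj_table(f, "s1", include_multimappers = TRUE)
  expect_equal(sj_mm$out_reads, c(10, 4, 7))

  writeLines(character(0), f)
  expect_equal(nrow(read_sj_table(f, "s1")), 0)

  writeLines("chr1\t101\tx\t1\t1\t0\t7\t3\t30", f)
  expect_error(read_sj_table(f, "s1"), "non-integer")
})

test_that("a 50-line SJ fixture equals an independent line-by-line parse", {
  f <- tempfile()
  set.seed(41)
  n <- 50
  ch <- sample(paste0("chr", 1:3), n, replace = TRUE)
  st <- sample.int(100000, n)
  en <- st + sample(50:5000, n)
  sc <- sample(0:2, n, replace = TRUE)
  uq <- sample(0:500, n)
  writeLines(sprintf("%s\t%d\t%d\t%d\t0\t0\t%d\t0\t20", ch, st, en, sc, uq), f)
  got <- read_sj_table(f, "sx")
  # independent parse: raw string splitting, no shared code
  want <- do.call(rbind, lapply(readLines(f), function(ln) {
    p <- strsplit(ln, "\t")[[1]]
    data.frame(chrom = p[1], start = as.integer(p[2]) - 1L,
               end = as.integer(p[3]),
               strand = if (p[4] == "2") "-" else "+",
               out = as.integer(p[7]), stringsAsFactors = FALSE)
  }))
  expect_equal(got$chrom, want$chrom)
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$strand, want$strand)
  expect_equal(got$out_reads, want$out)
})

test_that("splicing-in counting honours the 6-nt overhang rule", {
  jx <- list(chrom = "chr1", start = 1000, end = 1200)
  blocks <- data.frame(
    read_id = c("r1", "r2", "r3", "r4", "r4", "r5", "r6"),
    chrom = "chr1",
    start = c(994, 996, 900, 800, 1100, 1194, 990),
    end = c(1006, 1005, 1000, 1000, 1300, 1206, 1500),
    stringsAsFactors = FALSE
  )
  # r1: donor with exactly 6/6 -> counts; r2: 4 nt left of donor -> no
  # r3/r4: blocks stop at the boundary (spliced there) -> no at donor;
  # r4 second block covers acceptor 1200 with 100/100 -> counts
  # r5: acceptor with exactly 6/6 -> counts; r6: spans both -> contributes 2
  expect_equal(count_in_reads(blocks, jx), 1 + 1 + 1 + 2)
  expect_equal(count_in_reads(blocks, jx, dedupe_spanning_reads = TRUE), 4)
  # stricter overhang drops the exact-6 reads
  expect_equal(count_in_reads(blocks, jx, min_overhang = 7), 1 + 2)
})

test_that("splicing-in counting equals a per-base brute-force oracle", {
  set.seed(77)
  for (rep in 1:20) {
    jx <- list(chrom = "c", start = sample(50:200, 1), end = 0)
    jx$end <- jx$start + sample(30:100, 1)
    n_reads <- 30
    blocks <- do.call(rbind, lapply(seq_len(n_reads), function(r) {
      nb <- sample(1:2, 1)
      s <- sample(0:300, nb)
      data.frame(read_id = paste0("r", r), chrom = "c",
                 start = s, end = s + sample(10:60, nb, replace = TRUE))
    }))
    got <- count_in_reads(blocks, jx)
    # oracle: per read, per boundary, is there a block whose covered base
    # set includes every base in [b-6, b+6)?
    covers <- function(b) {
      byread <- split(blocks, blocks$read_id)
      sum(vapply(byread, function(bl) {
        any(vapply(seq_len(nrow(bl)), function(i) {
          basis <- seq(bl$start[i], bl$end[i] - 1)
          all((b - 6):(b + 5) %in% basis)
        }, logical(1)))
      }, logical(1)))
    }
    expect_equal(got, covers(jx$start) + covers(jx$end))
  }
})

test_that("SPL matrices assemble with union junctions and cohort labels", {
  sheet <- data.frame(sample_id = c("a", "b", "c"),
                      cohort = c("TUMOUR", "NORMAL", "REFERENCE_NORMAL"))
  sj <- data.frame(
    junction_id = c("c1:10-20:+", "c1:10-20:+", "c1:30-40:+"),
    sample_id = c("a", "b", "a"),
    out_reads = c(6L, 2L, 10L), stringsAsFactors = FALSE
  )
  inr <- data.frame(
    junction_id = c("c1:10-20:+", "c1:10-20:+", "c1:30-40:+"),
    sample_id = c("a", "b", "c"),
    in_reads_total = c(12L, 0L, 8L), stringsAsFactors = FALSE
  )
  sm <- build_spl_matrix(sj, inr, sheet)
  expect_equal(dim(sm$spl), c(2, 3))
  expect_equal(sm$spl["c1:10-20:+", "a"], 6 / (6 + 6)) # hand: 0.5
  expect_equal(sm$spl["c1:10-20:+", "b"], 1.0)
  expect_equal(sm$spl["c1:30-40:+", "a"], 1.0)
  expect_equal(sm$spl["c1:30-40:+", "c"], 0.0)
  expect_true(is.na(sm$spl["c1:10-20:+", "c"])) # absent = missing
  expect_true(is.na(sm$spl["c1:30-40:+", "b"]))

  # permuting sample-sheet order permutes columns, not values
  sm2 <- build_spl_matrix(sj, inr, sheet[c(3, 1, 2), ])
  expect_equal(sm2$spl[, c("a", "b", "c")], sm$spl)

  expect_error(build_spl_matrix(sj, inr, sheet[1:2, ]), "absent from sample sheet")
  expect_error(build_spl_matrix(sj, inr,
                                data.frame(sample_id = c("a", "b", "c"),
                                           cohort = c("TUMOUR", "X", "NORMAL"))),
               "cohort")
})

test_that("plug-in SPL concentrates on the true splicing probability", {
  set.seed(3)
  p <- 0.3; d <- 1000L; n <- 500
  out <- rbinom(n, d, p)
  spl <- compute_spl(out, 2L * (d - out))
  expect_lt(abs(mean(spl) - p), 0.02)
})

test_that("SPL matrices round-trip through TSV", {
  sheet <- data.frame(sample_id = c("a", "b"), cohort = c("TUMOUR", "NORMAL"))
  sj <- data.frame(junction_id = "c1:10-20:+", sample_id = "a",
                   out_reads = 4L, stringsAsFactors = FALSE)
  inr <- data.frame(junction_id = "c1:10-20:+", sample_id = "a",
                    in_reads_total = 4L, stringsAsFactors = FALSE)
  sm <- build_spl_matrix(sj, inr, sheet)
  f <- tempfile()
  write_spl_matrix(sm, f)
  back <- read.delim(f, check.names = FALSE)
  expect_equal(back$a, 4 / (4 + 2))
  expect_true(is.na(back$b))
})
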