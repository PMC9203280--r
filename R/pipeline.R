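# Stage orchestration: each stage reads its inputs from a run directory,
# writes TSV outputs with a '#'-prefixed provenance header, and is a pure
# function of inputs + configuration.

#' Default run configuration
#'
#' @param seed integer seed.
#' @return named list of thresholds and simulation settings understood by
#'   [run_stage()].
#' @export
default_run_config <- function(seed = 1L) {
  list(
    min_reads = 2, min_spl = 0.10, fdr_cut = 0.1, min_delta = 0.05,
    q_high = 0.90, q_low = 0.10, nmd_threshold = 50,
    min_depth_junctions = 1000,
    n_events = 400, frac_3utr = 0.8, n_tumour = 40, n_normal = 40,
    n_reference = 40, depth_mean = 80, baseline_spl_alpha = 2,
    baseline_spl_beta = 6, frac_dysregulated = 0.05, delta = 0.25,
    surv_beta = 1.5, frac_alu = 0.4,
    seed = as.integer(seed)
  )
}

#' Read a flat key:value run-configuration file
#'
#' One `key: value` pair per line; `#` comments allowed.  Unknown keys are
#' rejected; missing keys take the defaults of [default_run_config()].
#'
#' @param path configuration file.
#' @return validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cfg[[key]] <- as.numeric(val)
  }
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  chk01 <- c("min_spl", "fdr_cut", "min_delta", "q_high", "q_low",
             "frac_3utr", "frac_dysregulated", "frac_alu")
  for (k in chk01) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1) {
      stop("config value out of range [0, 1]: ", k, " = ", cfg[[k]])
    }
  }
  if (cfg$q_low >= cfg$q_high) stop("q_low must be < q_high")
  if (cfg$min_reads < 0 || cfg$nmd_threshold < 0 || cfg$depth_mean <= 0) {
    stop("invalid threshold in config")
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

provenance_header <- function(stage, cfg) {
  c(sprintf("# utr3splice %s", as.character(utils::packageVersion("utr3splice"))),
    sprintf("# stage: %s", stage),
    sprintf("# seed: %d", cfg$seed),
    sprintf("# config: %s", paste(names(cfg), unlist(cfg), sep = "=",
                                  collapse = " ")))
}

write_stage_tsv <- function(df, path, stage, cfg) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(stage, cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

read_stage_tsv <- function(path, stage) {
  if (!file.exists(path)) {
    stop("missing output '", basename(path), "': run prerequisite stage '",
         stage, "' first")
  }
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

# shared loader: SPL matrix from the simulate stage outputs
load_spl_matrix <- function(dir) {
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  if (!file.exists(sheet_path)) {
    stop("missing output 'sample_sheet.tsv': run prerequisite stage 'simulate' first")
  }
  sheet <- utils::read.delim(sheet_path, stringsAsFactors = FALSE)
  sj <- do.call(rbind, lapply(sheet$sample_id, function(s) {
    read_sj_table(file.path(dir, "sj", paste0(s, ".SJ.out.tab")), s)
  }))
  inr <- read_in_reads(file.path(dir, "in_reads.tsv"))
  build_spl_matrix(sj, inr, sheet)
}

#' Run one pipeline stage
#'
#' Stages (each writes TSVs with a provenance header into `out_dir`):
#' \describe{
#'   \item{simulate}{generate the synthetic cohort from the config.}
#'   \item{discover}{build the SPL matrix and discover 3USPs
#'     (`events.tsv`, `spl_matrix.tsv`).}
#'   \item{c3usp}{common-event flags per cohort (`c3usp.tsv`).}
#'   \item{diff}{differential splicing table (`differential.tsv`).}
#'   \item{classify}{over-/under-splicing calls for significant events
#'     (`status_calls.tsv`, `over_under.tsv`).}
#'   \item{burden}{per-sample burden table (`burden.tsv`).}
#'   \item{survive}{per-event prognosis and burden survival
#'     (`prognosis.tsv`, `burden_survival.tsv`).}
#'   \item{annotate}{event features: stop distance, NMD, repeats, long-read
#'     and annotation support (`features.tsv`).}
#'   \item{report}{one-line run summary (`summary.tsv`).}
#' }
#'
#' @param stage stage name.
#' @param cfg configuration list from [default_run_config()] /
#'   [read_run_config()].
#' @param out_dir run directory shared by all stages.
#' @return invisibly, the stage's main data.frame (or output paths for
#'   `simulate`).
#' @export
run_stage <- function(stage, cfg, out_dir) {
  cfg <- validate_run_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  res <- switch(
    stage,
    simulate = {
      sc <- sim_config(
        n_events = cfg$n_events, frac_3utr = cfg$frac_3utr,
        n_tumour = cfg$n_tumour, n_normal = cfg$n_normal,
        n_reference = cfg$n_reference, depth_mean = cfg$depth_mean,
        baseline_spl_alpha = cfg$baseline_spl_alpha,
        baseline_spl_beta = cfg$baseline_spl_beta,
        frac_dysregulated = cfg$frac_dysregulated, delta = cfg$delta,
        surv_beta = cfg$surv_beta, frac_alu = cfg$frac_alu, seed = cfg$seed
      )
      sim <- simulate_cohort(sc, out_dir)
      sim$paths
    },
    discover = {
      if (!file.exists(file.path(out_dir, "annotation.gtf"))) {
        stop("missing output 'annotation.gtf': run prerequisite stage ",
             "'simulate' first")
      }
      ann <- parse_gtf(file.path(out_dir, "annotation.gtf"))
      sm <- load_spl_matrix(out_dir)
      ev <- discover_3usps(sm, ann, min_reads = cfg$min_reads,
                           min_spl = cfg$min_spl)
      write_stage_tsv(ev, file.path(out_dir, "events.tsv"), "discover", cfg)
      spl_df <- data.frame(junction_id = rownames(sm$spl),
                           round(sm$spl, 6), check.names = FALSE)
      write_stage_tsv(spl_df, file.path(out_dir, "spl_matrix.tsv"),
                      "discover", cfg)
      ev
    },
    c3usp = {
      ev <- read_stage_tsv(file.path(out_dir, "events.tsv"), "discover")
      sm <- load_spl_matrix(out_dir)
      cohorts <- unique(sm$samples$cohort)
      flags <- sapply(cohorts, function(co) {
        f <- c3usp_flags(sm, cohort = co, min_spl = cfg$min_spl)
        f[ev$junction_id]
      })
      out <- data.frame(junction_id = ev$junction_id, flags,
                        check.names = FALSE)
      names(out)[-1] <- paste0("c3usp_", tolower(cohorts))
      write_stage_tsv(out, file.path(out_dir, "c3usp.tsv"), "c3usp", cfg)
      out
    },
    diff = {
      ev <- read_stage_tsv(file.path(out_dir, "events.tsv"), "discover")
      sm <- load_spl_matrix(out_dir)
      sm3 <- sm
      keep <- rownames(sm$spl) %in% ev$junction_id
      sm3$spl <- sm$spl[keep, , drop = FALSE]
      sm3$out_reads <- sm$out_reads[keep, , drop = FALSE]
      sm3$in_reads <- sm$in_reads[keep, , drop = FALSE]
      sm3$events <- sm$events[keep, , drop = FALSE]
      dr <- differential_cohort(sm3, fdr_cut = cfg$fdr_cut,
                                min_delta = cfg$min_delta)
      dr_out <- dr
      num_cols <- vapply(dr_out, is.numeric, logical(1))
      dr_out[num_cols] <- lapply(dr_out[num_cols], function(x) round(x, 6))
      write_stage_tsv(dr_out, file.path(out_dir, "differential.tsv"),
                      "diff", cfg)
      dr
    },
    classify = {
      dr <- read_stage_tsv(file.path(out_dir, "differential.tsv"), "diff")
      sm <- load_spl_matrix(out_dir)
      sig <- dr$event_id[dr$significant]
      calls <- call_splice_status(sm, event_ids = sig, q_low = cfg$q_low,
                                  q_high = cfg$q_high)
      calls_out <- calls
      for (cc in c("spl", "cutoff_low", "cutoff_high")) {
        calls_out[[cc]] <- round(calls_out[[cc]], 6)
      }
      write_stage_tsv(calls_out, file.path(out_dir, "status_calls.tsv"),
                      "classify", cfg)
      write_stage_tsv(tabulate_over_under(calls),
                      file.path(out_dir, "over_under.tsv"), "classify", cfg)
      calls
    },
    burden = {
      ev <- read_stage_tsv(file.path(out_dir, "events.tsv"), "discover")
      sm <- load_spl_matrix(out_dir)
      b <- splice_burden(sm, ev, min_reads = cfg$min_reads,
                         min_spl = cfg$min_spl,
                         min_depth_junctions = cfg$min_depth_junctions)
      b$burden <- round(b$burden, 6)
      write_stage_tsv(b, file.path(out_dir, "burden.tsv"), "burden", cfg)
      b
    },
    survive = {
      dr <- read_stage_tsv(file.path(out_dir, "differential.tsv"), "diff")
      sm <- load_spl_matrix(out_dir)
      clin <- read_clinical(file.path(out_dir, "clinical.tsv"))
      sig <- dr$event_id[dr$significant]
      pr <- prognosis_table(sm, clin, event_ids = sig)
      num_cols <- vapply(pr, is.numeric, logical(1))
      pr[num_cols] <- lapply(pr[num_cols], function(x) round(x, 6))
      write_stage_tsv(pr, file.path(out_dir, "prognosis.tsv"), "survive", cfg)
      b <- read_stage_tsv(file.path(out_dir, "burden.tsv"), "burden")
      bt <- b[b$cohort == "TUMOUR" & !b$low_depth, ]
      bs <- burden_survival(stats::setNames(bt$n_3usp, bt$sample_id), clin)
      bs_df <- data.frame(covariate = "n_3usp",
                          hazard_ratio = round(bs$hazard_ratio, 6),
                          p_value = round(bs$p_value, 6),
                          km_p = round(bs$km_p, 6),
                          label = bs$label, n = bs$n, flag = bs$flag)
      write_stage_tsv(bs_df, file.path(out_dir, "burden_survival.tsv"),
                      "survive", cfg)
      pr
    },
    annotate = {
      ev <- read_stage_tsv(file.path(out_dir, "events.tsv"), "discover")
      ann <- parse_gtf(file.path(out_dir, "annotation.gtf"))
      reps <- read_repeats_bed(file.path(out_dir, "repeats.bed"))
      fe <- annotate_events(ev, ann, repeats = reps,
                            nmd_threshold = cfg$nmd_threshold)
      fe$annotated <- check_annotated(ev, ann)
      iso <- file.path(out_dir, "isoforms.gtf")
      fe$pacbio_supported <- if (file.exists(iso)) {
        match_longread_support(ev, iso)
      } else NA
      fe$repeat_overlap_fraction <- round(fe$repeat_overlap_fraction, 6)
      write_stage_tsv(fe, file.path(out_dir, "features.tsv"), "annotate", cfg)
      fe
    },
    report = {
      ev <- read_stage_tsv(file.path(out_dir, "events.tsv"), "discover")
      dr <- read_stage_tsv(file.path(out_dir, "differential.tsv"), "diff")
      pr <- read_stage_tsv(file.path(out_dir, "prognosis.tsv"), "survive")
      smry <- data.frame(
        n_3usp = nrow(ev),
        n_tested = sum(dr$testable),
        n_significant = sum(dr$significant),
        n_up = sum(dr$significant & dr$direction == "UP"),
        n_down = sum(dr$significant & dr$direction == "DOWN"),
        n_unfavourable = sum(pr$label == "UNFAVOURABLE"),
        n_favourable = sum(pr$label == "FAVOURABLE")
      )
      write_stage_tsv(smry, file.path(out_dir, "summary.tsv"), "report", cfg)
      smry
    },
    stop("unknown stage: ", stage)
  )
  message(sprintf("[utr3splice] stage %-9s %6.2fs", stage,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  invisible(res)
}

#' Run the full pipeline
#'
#' Executes all stages in order on one run directory.
#'
#' @inheritParams run_stage
#' @return invisibly, the report-stage summary data.frame.
#' @export
run_pipeline <- function(cfg = default_run_config(), out_dir) {
  stages <- c("simulate", "discover", "c3usp", "diff", "classify", "burden",
              "survive", "annotate", "report")
  res <- NULL
  for (s in stages) res <- run_stage(s, cfg, out_dir)
  invisible(res)
}
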