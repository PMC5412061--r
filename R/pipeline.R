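#' Pipeline configuration
#'
#' Bundles per-stage settings and a single global seed from which every
#' stage derives its own reproducible sub-seed.  With `emit_fastq = TRUE`
#' the simulate stage writes paired FASTQ and the demux stage recounts
#' reads from them; otherwise counts come directly from the molecule tally
#' (equivalent on error-free data, and far faster at full depth).
#'
#' @param sim a [sim_config()]
#' @param emit_fastq write and re-demultiplex FASTQ (slow at full depth)
#' @param cv_threshold,min_is_reads quantification QC thresholds
#' @param max_missing_frac,min_assays missingness filters
#' @param m_copies,n_iterations,k_donors imputation settings
#' @param k_grid,vote_threshold,folds,cv_mode model-search settings
#' @param seed global seed
#' @return object of class `pipeline_config`
#' @export
pipeline_config <- function(sim = sim_config(),
                            emit_fastq = FALSE,
                            cv_threshold = 1.0, min_is_reads = 10,
                            max_missing_frac = 0.30, min_assays = 6,
                            m_copies = 50, n_iterations = 10,
                            k_donors = 5,
                            k_grid = 1:25, vote_threshold = 0.60,
                            folds = 10, cv_mode = "honest",
                            seed = 1) {
  sim$seed <- derive_seed(seed, 101)
  structure(list(sim = sim, emit_fastq = emit_fastq,
                 cv_threshold = cv_threshold, min_is_reads = min_is_reads,
                 max_missing_frac = max_missing_frac,
                 min_assays = min_assays,
                 m_copies = m_copies, n_iterations = n_iterations,
                 k_donors = k_donors,
                 k_grid = k_grid, vote_threshold = vote_threshold,
                 folds = folds, cv_mode = cv_mode, seed = seed),
            class = "pipeline_config")
}

#' Run the full simulate - demux - quantify - impute - train - evaluate
#' pipeline
#'
#' Every stage writes its artifacts under `out_dir` together with a JSON
#' provenance record (package version, seeds, input file hashes).  Rerun
#' with an identical config and output directory reproduces identical
#' artifacts.
#'
#' @param config a [pipeline_config()]
#' @param out_dir output directory (created)
#' @param quiet suppress progress messages
#' @return invisible list with the main in-memory objects (cohort, counts,
#'   abundance matrix, imputed stack, model search result, performance
#'   report, cohort summary)
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[lcrt] ", ...)
  hashes <- list()
  track <- function(path) {
    hashes[[basename(path)]] <<- unname(tools::md5sum(path))
    path
  }

  # --- simulate ------------------------------------------------------
  say("simulate: cohort, truth, counts")
  design <- synthetic_assay_design(n_assays = config$sim$n_assays,
                                   n_genes = config$sim$n_genes,
                                   seed = derive_seed(config$seed, 11))
  cohort <- generate_cohort(config$sim)
  tally <- simulate_counts(cohort$truth, cohort$subjects, design,
                           config$sim,
                           seed = derive_seed(config$seed, 12))
  track(write_assay_design(design, file.path(out_dir, "assay_design.tsv")))
  track(write_sample_sheet(cohort$subjects,
                           file.path(out_dir, "sample_sheet.tsv")))
  truth_df <- data.frame(subject_id = rownames(cohort$truth$abundance),
                         actb_per_ul = cohort$truth$actb_per_ul,
                         cohort$truth$abundance, check.names = FALSE)
  utils::write.table(truth_df, file.path(out_dir, "truth_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  track(file.path(out_dir, "truth_abundance.tsv"))

  # --- demux (optional FASTQ round trip) -----------------------------
  if (isTRUE(config$emit_fastq)) {
    say("demux: FASTQ round trip")
    r1 <- file.path(out_dir, "reads_R1.fastq.gz")
    r2 <- file.path(out_dir, "reads_R2.fastq.gz")
    emit_fastq(tally, cohort$subjects, design, config$sim, r1, r2,
               seed = derive_seed(config$seed, 13))
    track(r1); track(r2)
    rc <- count_reads(r1, r2, cohort$subjects, design,
                      barcode_len = config$sim$barcode_len)
    counts <- rc$counts
    write_read_counts(rc, file.path(out_dir, "counts.tsv"),
                      file.path(out_dir, "demux_summary.json"))
  } else {
    counts <- tally_to_counts(tally)
    write_counts(counts, file.path(out_dir, "counts.tsv"))
  }
  track(file.path(out_dir, "counts.tsv"))

  # --- quantify ------------------------------------------------------
  say("quantify: NT/IS ratios, CV filter, missingness filters")
  ab <- quantify_abundance(counts, design,
                           cv_threshold = config$cv_threshold,
                           min_is_reads = config$min_is_reads)
  utils::write.table(ab$qc, file.path(out_dir, "qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ab <- add_demographics(ab, cohort$subjects)
  ab <- filter_assays(ab, config$max_missing_frac)
  ab <- filter_subjects(ab, config$min_assays)
  ab <- log10_transform(ab)
  track(write_abundance(ab, file.path(out_dir, "abundance.tsv")))
  jsonlite::write_json(
    list(removed_assays = ab$log$removed_assays %||% character(0),
         removed_subjects = ab$log$removed_subjects %||% character(0),
         actb_failed_subjects =
           ab$log$actb_failed_subjects %||% character(0)),
    file.path(out_dir, "filter_log.json"), auto_unbox = FALSE,
    pretty = TRUE)

  # --- impute --------------------------------------------------------
  say("impute: MICE-PMM, M = ", config$m_copies)
  stack <- mice_pmm(ab, m_copies = config$m_copies,
                    n_iterations = config$n_iterations,
                    k_donors = config$k_donors,
                    seed = derive_seed(config$seed, 14))
  write_imputed_stack(stack, file.path(out_dir, "imputed"))

  # --- train + evaluate ----------------------------------------------
  say("train: CAT-vote LDA model search (", config$cv_mode, " CV)")
  y <- cohort$subjects$class_label[
    match(rownames(ab$values), cohort$subjects$subject_id)]
  result <- select_and_train(stack, y, k_grid = config$k_grid,
                             vote_threshold = config$vote_threshold,
                             folds = config$folds,
                             seed = derive_seed(config$seed, 15),
                             mode = config$cv_mode)
  report <- evaluate_performance(result, stack)
  write_report(report, result, out_dir)

  # --- summarize -----------------------------------------------------
  say("summarize: cohort table")
  kept <- cohort$subjects[cohort$subjects$subject_id %in%
                            rownames(ab$values), ]
  summary_tab <- summarize_cohort(kept)
  utils::write.table(summary_tab, file.path(out_dir, "cohort_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prov <- list(package = "lcrt",
               version = as.character(utils::packageVersion("lcrt")),
               seed = config$seed,
               stage_seeds = list(design = derive_seed(config$seed, 11),
                                  counts = derive_seed(config$seed, 12),
                                  fastq = derive_seed(config$seed, 13),
                                  impute = derive_seed(config$seed, 14),
                                  train = derive_seed(config$seed, 15)),
               input_md5 = hashes)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  say("done: ", out_dir)
  invisible(list(design = design, cohort = cohort, tally = tally,
                 counts = counts, abundance = ab, stack = stack,
                 result = result, report = report,
                 cohort_summary = summary_tab))
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (the full pipeline), `simulate`, `summarize`.
#' `run-all` accepts `--config <json>` (keys override
#' [pipeline_config()] / [sim_config()] defaults), `--out <dir>` and
#' `--seed <int>`.  Invoked by the `inst/cli/lcrt` wrapper script.
#'
#' @param args character vector of command-line arguments
#' @return exit status (0 on success), invisibly
#' @export
lcrt_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: lcrt <run-all|simulate|summarize> [--config cfg.json]",
    "[--out dir] [--seed int]")
  if (!length(args)) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- list(out = "lcrt_out", seed = 1L, config = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt)) stop("unknown option: ", args[i])
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  opt$seed <- as.integer(opt$seed)

  overrides <- if (!is.null(opt$config)) {
    jsonlite::read_json(opt$config, simplifyVector = TRUE)
  } else list()
  sim_args <- overrides$sim %||% list()
  sim <- do.call(sim_config, sim_args)
  pipe_args <- overrides[setdiff(names(overrides), "sim")]
  pipe_args$sim <- sim
  pipe_args$seed <- opt$seed
  config <- do.call(pipeline_config, pipe_args)

  if (cmd == "run-all") {
    run_pipeline(config, opt$out)
  } else if (cmd == "simulate") {
    dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)
    design <- synthetic_assay_design(n_assays = config$sim$n_assays,
                                     n_genes = config$sim$n_genes,
                                     seed = derive_seed(opt$seed, 11))
    cohort <- generate_cohort(config$sim)
    tally <- simulate_counts(cohort$truth, cohort$subjects, design,
                             config$sim,
                             seed = derive_seed(opt$seed, 12))
    write_assay_design(design, file.path(opt$out, "assay_design.tsv"))
    write_sample_sheet(cohort$subjects,
                       file.path(opt$out, "sample_sheet.tsv"))
    write_counts(tally_to_counts(tally), file.path(opt$out, "counts.tsv"))
  } else if (cmd == "summarize") {
    sheet <- read_sample_sheet(file.path(opt$out, "sample_sheet.tsv"))
    print(summarize_cohort(sheet))
  } else {
    message(usage)
    return(invisible(1L))
  }
  invisible(0L)
}
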