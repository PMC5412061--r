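#' Simulate competitive NT/IS molecule loading and read counts
#'
#' Implements the equal-efficiency competitive amplification model.  For a
#' 1-uL aliquot, the number of native-template (NT) molecules entering the
#' reaction is Poisson with mean `true_abundance x actb_per_ul / 1e6` for
#' target assays (and `actb_per_ul` for the ACTB reference).  Internal
#' standard (IS) input is the manifest's fixed spike (600 copies per target,
#' 6000 for ACTB), optionally Poisson-jittered.  Total reads per
#' assay-sample cell are lognormal; NT reads are binomial with probability
#' `nt / (nt + is)`, and IS reads the remainder — amplification does not
#' change the NT:IS ratio, only sequencing sampling does.
#'
#' @param truth truth table from [generate_cohort()]
#' @param subjects subject table from [generate_cohort()]
#' @param design assay manifest from [synthetic_assay_design()]
#' @param config the [sim_config()] used to generate the cohort
#' @param seed RNG seed; defaults to a sub-seed derived from `config$seed`
#' @return object of class `molecule_tally`: list of subjects x assays
#'   integer matrices `nt_molecules`, `is_molecules`, `total_reads`,
#'   `nt_reads`, `is_reads` (columns ordered as the design, ACTB last)
#' @export
simulate_counts <- function(truth, subjects, design, config,
                            seed = derive_seed(config$seed, 1)) {
  targets <- which(!design$is_reference_assay)
  ref <- which(design$is_reference_assay)
  if (length(targets) != ncol(truth$abundance)) {
    stop("design target assays (", length(targets),
         ") do not match truth table columns (", ncol(truth$abundance), ")")
  }
  if (!identical(rownames(truth$abundance), subjects$subject_id)) {
    stop("truth table subjects do not match subject table")
  }
  set.seed(seed)
  n <- nrow(subjects)
  k <- nrow(design)
  assay_ids <- design$assay_id

  # expected NT molecules per cell, design order (targets then ACTB)
  lambda <- matrix(0, n, k, dimnames = list(subjects$subject_id, assay_ids))
  lambda[, targets] <- truth$abundance * truth$actb_per_ul / 1e6
  lambda[, ref] <- truth$actb_per_ul

  nt_mol <- matrix(stats::rpois(n * k, lambda), n, k,
                   dimnames = dimnames(lambda))
  is_nominal <- matrix(rep(design$is_input_copies, each = n), n, k,
                       dimnames = dimnames(lambda))
  if (isTRUE(config$is_poisson_jitter)) {
    is_mol <- matrix(stats::rpois(n * k, is_nominal), n, k,
                     dimnames = dimnames(lambda))
  } else {
    is_mol <- is_nominal
  }

  depth <- matrix(round(rlnorm_mean_cv(n * k, config$depth_mean,
                                       config$depth_cv)), n, k,
                  dimnames = dimnames(lambda))
  tot_mol <- nt_mol + is_mol
  pr_nt <- ifelse(tot_mol > 0, nt_mol / tot_mol, 0)
  depth[tot_mol == 0] <- 0
  nt_reads <- matrix(stats::rbinom(n * k, depth, pr_nt), n, k,
                     dimnames = dimnames(lambda))
  is_reads <- depth - nt_reads

  structure(list(nt_molecules = nt_mol, is_molecules = is_mol,
                 total_reads = depth, nt_reads = nt_reads,
                 is_reads = is_reads),
            class = "molecule_tally")
}

#' Convert a molecule tally to a read-count table
#'
#' Produces the long-format count table that the demultiplexer would emit
#' on error-free data: one row per subject x assay with NT, IS, ambiguous
#' and unassigned read counts (the latter two zero for a direct tally).
#'
#' @param tally a `molecule_tally`
#' @return data.frame with columns subject_id, assay_id, nt_reads,
#'   is_reads, ambiguous_reads, unassigned_reads
#' @export
tally_to_counts <- function(tally) {
  stopifnot(inherits(tally, "molecule_tally"))
  subj <- rownames(tally$nt_reads)
  assays <- colnames(tally$nt_reads)
  data.frame(
    subject_id = rep(subj, times = length(assays)),
    assay_id = rep(assays, each = length(subj)),
    nt_reads = as.integer(tally$nt_reads),
    is_reads = as.integer(tally$is_reads),
    ambiguous_reads = 0L,
    unassigned_reads = 0L,
    stringsAsFactors = FALSE
  )
}

#' Write / read a count table as tab-delimited text
#'
#' @param counts count table data.frame
#' @param path file path
#' @export
write_counts <- function(counts, path) {
  utils::write.table(counts, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Emit simulated paired FASTQ files for a molecule tally
#'
#' Each read pair, once joined, has the layout
#' `[barcode_f][primer_f][captured][revcomp(primer_r)][revcomp(barcode_r)]`
#' where `captured` is the assay's NT or IS sequence according to the
#' tally.  Read 1 covers the first half of the joined amplicon; read 2 is
#' the reverse complement of the remainder (non-overlapping layout).
#' Substitution errors are injected at `config$base_error_rate`, and the
#' constant Phred quality written is consistent with that rate.
#'
#' @param tally a `molecule_tally`
#' @param subjects subject table (barcodes used)
#' @param design assay manifest
#' @param config the [sim_config()] (error rate used)
#' @param r1_path,r2_path output FASTQ paths (gzip-compressed when ending
#'   in `.gz`)
#' @param seed RNG seed for error injection and read shuffling
#' @return invisible list with `n_reads` and the two paths
#' @export
emit_fastq <- function(tally, subjects, design, config, r1_path, r2_path,
                       seed = derive_seed(config$seed, 2)) {
  stopifnot(inherits(tally, "molecule_tally"))
  if (!all(rownames(tally$nt_reads) %in% subjects$subject_id)) {
    stop("tally contains subjects missing from the sample sheet")
  }
  if (!all(colnames(tally$nt_reads) %in% design$assay_id)) {
    stop("tally contains assays missing from the design")
  }
  set.seed(seed)
  si <- match(rownames(tally$nt_reads), subjects$subject_id)
  ai <- match(colnames(tally$nt_reads), design$assay_id)

  n_cells <- length(tally$nt_reads)
  nt_n <- as.integer(tally$nt_reads)
  is_n <- as.integer(tally$is_reads)
  cell_subj <- rep(si, times = ncol(tally$nt_reads))
  cell_assay <- rep(ai, each = nrow(tally$nt_reads))

  # one joined amplicon per (cell, allele), replicated read-count times
  amplicon <- function(a_idx, allele) {
    capt <- if (allele == "NT") design$nt_captured[a_idx]
            else design$is_captured[a_idx]
    paste0(design$primer_f[a_idx], capt, revcomp(design$primer_r[a_idx]))
  }
  core_nt <- vapply(seq_len(nrow(design)), amplicon, character(1),
                    allele = "NT")
  core_is <- vapply(seq_len(nrow(design)), amplicon, character(1),
                    allele = "IS")

  subj_of <- c(rep(cell_subj, nt_n), rep(cell_subj, is_n))
  core <- c(core_nt[rep(cell_assay, nt_n)], core_is[rep(cell_assay, is_n)])
  n_reads <- length(core)
  if (n_reads == 0) {
    joined <- character(0)
  } else {
    joined <- paste0(subjects$barcode_f[subj_of], core,
                     revcomp(subjects$barcode_r[subj_of]))
    joined <- inject_substitutions(joined, config$base_error_rate)
    joined <- joined[sample.int(n_reads)]
  }

  L <- nchar(design$primer_f[1]) * 2 +
    nchar(design$nt_captured[1]) + 2 * config$barcode_len
  r1_len <- ceiling(L / 2)
  r1 <- substr(joined, 1, r1_len)
  r2 <- revcomp(substring(joined, r1_len + 1, L))
  ids <- sprintf("sim:%07d", seq_len(max(n_reads, 0)))

  q <- if (config$base_error_rate <= 0) 40L else {
    max(2L, min(40L, as.integer(round(-10 * log10(config$base_error_rate)))))
  }
  write_fastq(ids, r1, q, r1_path)
  write_fastq(ids, r2, q, r2_path)
  invisible(list(n_reads = n_reads, r1 = r1_path, r2 = r2_path))
}

# write one FASTQ file with a constant quality value
write_fastq <- function(ids, seqs, qual_int, path) {
  compress <- grepl("\\.gz$", path)
  if (length(seqs) == 0) {
    con <- if (compress) gzfile(path, "wt") else file(path, "wt")
    close(con)
    return(invisible(path))
  }
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  qchar <- rawToChar(as.raw(qual_int + 33L))
  quals <- Biostrings::PhredQuality(strrep(qchar, nchar(seqs)))
  Biostrings::writeXStringSet(x, path, compress = compress,
                              format = "fastq", qualities = quals)
  invisible(path)
}

# read one FASTQ file (sequences only; qualities are not used downstream)
read_fastq_seqs <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = FALSE)
  out <- as.character(x)
  names(out) <- sub(" .*$", "", names(out))
  out
}
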