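#' Absolute molecule estimate from competitive NT/IS read counts
#'
#' Because native template and internal standard share primers and amplify
#' with equal efficiency, the starting NT copy number is the known IS input
#' multiplied by the NT:IS read ratio.
#'
#' @param nt_reads,is_reads read counts (vectorised)
#' @param is_input_copies IS copies spiked into the reaction
#' @return estimated NT molecules; NA where `is_reads` is zero (the ratio
#'   is undefined and the measurement is treated as missing)
#' @export
molecules_from_counts <- function(nt_reads, is_reads, is_input_copies) {
  ifelse(is_reads > 0, is_input_copies * nt_reads / is_reads, NA_real_)
}

#' Normalise molecules to the ACTB reference
#'
#' @param target_molecules estimated molecules for a target assay
#' @param actb_molecules estimated ACTB molecules in the same library
#' @return target molecules per million ACTB molecules; NA where the ACTB
#'   denominator is non-positive or missing
#' @export
abundance_per_million_actb <- function(target_molecules, actb_molecules) {
  ifelse(!is.na(actb_molecules) & actb_molecules > 0,
         target_molecules / actb_molecules * 1e6, NA_real_)
}

#' Predicted coefficient of variation from stochastic sampling
#'
#' Closed-form CV of a competitive measurement given the number of analyte
#' molecules loaded into library preparation (M) and the number of
#' sequencing reads obtained (R):
#' \deqn{CV = -1 + 10^{\,M^{-0.54} + R^{-0.54} - (M R)^{-0.54}}}
#' The function is strictly decreasing in each argument and tends to zero
#' as both grow.  Non-positive or missing arguments give NA (an undefined
#' measurement, treated as a QC failure).
#'
#' @param molecules_input molecules loaded (M)
#' @param sequence_reads reads obtained (R)
#' @return predicted CV (vectorised)
#' @export
stochastic_cv <- function(molecules_input, sequence_reads) {
  m <- as.numeric(molecules_input)
  r <- as.numeric(sequence_reads)
  out <- rep(NA_real_, length(m))
  ok <- !is.na(m) & !is.na(r) & m > 0 & r > 0
  out[ok] <- -1 + 10^(m[ok]^-0.54 + r[ok]^-0.54 - (m[ok] * r[ok])^-0.54)
  out
}

#' Convert a molar concentration to copies per microlitre
#'
#' Used for checking internal-standard mixture specifications: a 1e-15 M
#' solution carries about 600 copies/uL and 1e-14 M about 6000.
#'
#' @param molarity concentration in mol/L
#' @return copies per microlitre
#' @export
copies_per_microliter <- function(molarity) {
  avogadro <- 6.02214076e23
  molarity * avogadro / 1e6
}

#' Per-cell QC and molecule estimation for a count table
#'
#' For every subject x assay cell, estimates loaded NT molecules from the
#' NT:IS read ratio, evaluates the stochastic-sampling CV with
#' M = estimated molecules and R = total (NT+IS) reads (configurable to
#' NT reads only), and flags the cell as passing when CV < `cv_threshold`
#' and IS reads are at least `min_is_reads`.
#'
#' @param counts long count table (subject_id, assay_id, nt_reads,
#'   is_reads, ...)
#' @param design assay manifest (IS input copies per assay)
#' @param cv_threshold retain cells with CV strictly below this (default 1)
#' @param min_is_reads minimum IS reads for a defined ratio (default 10)
#' @param cv_reads which read count feeds the CV formula's R term
#' @return data.frame: subject_id, assay_id, molecules, reads, cv, pass
#' @export
apply_measurement_filter <- function(counts, design, cv_threshold = 1.0,
                                     min_is_reads = 10,
                                     cv_reads = c("total", "nt")) {
  cv_reads <- match.arg(cv_reads)
  counts <- counts[counts$assay_id %in% design$assay_id, , drop = FALSE]
  is_input <- design$is_input_copies[match(counts$assay_id,
                                           design$assay_id)]
  molecules <- molecules_from_counts(counts$nt_reads, counts$is_reads,
                                     is_input)
  reads <- if (cv_reads == "total") counts$nt_reads + counts$is_reads
           else counts$nt_reads
  cv <- stochastic_cv(molecules, reads)
  pass <- !is.na(cv) & cv < cv_threshold & counts$is_reads >= min_is_reads
  data.frame(subject_id = counts$subject_id, assay_id = counts$assay_id,
             molecules = molecules, reads = reads, cv = cv, pass = pass,
             stringsAsFactors = FALSE)
}

#' Quantify transcript abundance with QC masking
#'
#' Runs [apply_measurement_filter()], converts passing target measurements
#' to molecules per million ACTB molecules, and masks everything else as
#' missing.  A subject whose ACTB reference measurement fails QC loses the
#' whole library (all assays missing), since every abundance is a ratio to
#' ACTB.
#'
#' @inheritParams apply_measurement_filter
#' @return object of class `abundance_matrix`: list with
#'   `values` (subjects x target-assay matrix of raw abundances, NA =
#'   missing), `feature_type` (all "gene" here), `provenance` (character
#'   matrix: measured / filtered_low_confidence / absent), `qc` (the QC
#'   table) and `log` (filter bookkeeping)
#' @export
quantify_abundance <- function(counts, design, cv_threshold = 1.0,
                               min_is_reads = 10,
                               cv_reads = c("total", "nt")) {
  cv_reads <- match.arg(cv_reads)
  qc <- apply_measurement_filter(counts, design, cv_threshold,
                                 min_is_reads, cv_reads)
  ref_assay <- design$assay_id[design$is_reference_assay]
  targets <- design$assay_id[!design$is_reference_assay]
  subjects <- unique(counts$subject_id)

  qc_ref <- qc[qc$assay_id == ref_assay, ]
  actb <- stats::setNames(ifelse(qc_ref$pass, qc_ref$molecules, NA_real_),
                          qc_ref$subject_id)

  qc_t <- qc[qc$assay_id %in% targets, ]
  mol <- matrix(NA_real_, length(subjects), length(targets),
                dimnames = list(subjects, targets))
  passed <- matrix(FALSE, length(subjects), length(targets),
                   dimnames = list(subjects, targets))
  ij <- cbind(match(qc_t$subject_id, subjects),
              match(qc_t$assay_id, targets))
  mol[ij] <- ifelse(qc_t$pass, qc_t$molecules, NA_real_)
  passed[ij] <- qc_t$pass

  values <- sweep(mol, 1, actb[subjects], "/") * 1e6
  values[is.na(mol) | is.na(actb[subjects]) | actb[subjects] <= 0] <- NA_real_

  provenance <- matrix("filtered_low_confidence", length(subjects),
                       length(targets), dimnames = dimnames(values))
  provenance[!is.na(values)] <- "measured"

  structure(list(
    values = values,
    feature_type = stats::setNames(rep("gene", length(targets)), targets),
    provenance = provenance,
    qc = qc,
    log = list(actb_failed_subjects =
                 subjects[is.na(actb[subjects]) | actb[subjects] <= 0])
  ), class = "abundance_matrix")
}

#' Attach demographic features to an abundance matrix
#'
#' Adds age, gender (encoded 0 = F, 1 = M) and pack-years as demographic
#' features alongside the gene features.
#'
#' @param x an `abundance_matrix`
#' @param subjects subject table with age, gender, pack_years
#' @return the augmented `abundance_matrix`
#' @export
add_demographics <- function(x, subjects) {
  stopifnot(inherits(x, "abundance_matrix"))
  i <- match(rownames(x$values), subjects$subject_id)
  if (anyNA(i)) stop("abundance matrix contains unknown subjects")
  demo <- cbind(age = subjects$age[i],
                gender = ifelse(is.na(subjects$gender[i]), NA_real_,
                                as.numeric(subjects$gender[i] == "M")),
                pack_years = subjects$pack_years[i])
  rownames(demo) <- rownames(x$values)
  x$values <- cbind(x$values, demo)
  x$feature_type <- c(x$feature_type,
                      stats::setNames(rep("demographic", 3),
                                      colnames(demo)))
  x
}

#' Drop gene features with excessive missingness
#'
#' Gene features whose missing fraction strictly exceeds
#' `max_missing_frac` are removed; demographic features are never removed
#' here.  Idempotent.
#'
#' @param x an `abundance_matrix`
#' @param max_missing_frac threshold on the per-feature missing fraction
#' @return filtered `abundance_matrix`; removed features recorded in
#'   `x$log$removed_assays`
#' @export
filter_assays <- function(x, max_missing_frac = 0.30) {
  stopifnot(inherits(x, "abundance_matrix"), nrow(x$values) >= 1)
  gene_cols <- names(x$feature_type)[x$feature_type == "gene"]
  frac <- colMeans(is.na(x$values[, gene_cols, drop = FALSE]))
  drop <- gene_cols[frac > max_missing_frac]
  keep <- setdiff(colnames(x$values), drop)
  x$values <- x$values[, keep, drop = FALSE]
  x$feature_type <- x$feature_type[keep]
  if (!is.null(x$provenance)) {
    x$provenance <- x$provenance[, intersect(colnames(x$provenance), keep),
                                 drop = FALSE]
  }
  x$log$removed_assays <- unique(c(x$log$removed_assays, drop))
  x
}

#' Drop subjects with too few measured assays
#'
#' Subjects with fewer than `min_assays` non-missing gene features are
#' removed.  Idempotent.
#'
#' @param x an `abundance_matrix`
#' @param min_assays minimum number of measured gene features per subject
#' @return filtered `abundance_matrix`; removed subjects recorded in
#'   `x$log$removed_subjects`
#' @export
filter_subjects <- function(x, min_assays = 6) {
  stopifnot(inherits(x, "abundance_matrix"))
  gene_cols <- names(x$feature_type)[x$feature_type == "gene"]
  n_measured <- rowSums(!is.na(x$values[, gene_cols, drop = FALSE]))
  drop <- rownames(x$values)[n_measured < min_assays]
  keep <- setdiff(rownames(x$values), drop)
  if (!length(keep)) stop("all subjects removed by the min-assay filter")
  x$values <- x$values[keep, , drop = FALSE]
  if (!is.null(x$provenance)) {
    x$provenance <- x$provenance[keep, , drop = FALSE]
  }
  x$log$removed_subjects <- unique(c(x$log$removed_subjects, drop))
  x
}

#' Log10-transform gene features
#'
#' Gene abundances are replaced by their base-10 logarithm.  Zeros become
#' missing (a zero NT count carries no usable abundance information and is
#' handed to imputation), negatives are a data-integrity error, and
#' demographic features are untouched.
#'
#' @param x an `abundance_matrix`
#' @return transformed `abundance_matrix` with `x$log$log10 = TRUE`
#' @export
log10_transform <- function(x) {
  stopifnot(inherits(x, "abundance_matrix"))
  gene_cols <- names(x$feature_type)[x$feature_type == "gene"]
  v <- x$values[, gene_cols, drop = FALSE]
  if (any(v < 0, na.rm = TRUE)) {
    stop("negative abundance encountered before log10 transform")
  }
  v[!is.na(v) & v == 0] <- NA_real_
  x$values[, gene_cols] <- log10(v)
  x$log$log10 <- TRUE
  x
}

#' @export
print.abundance_matrix <- function(x, ...) {
  ft <- table(x$feature_type)
  cat("abundance_matrix: ", nrow(x$values), " subjects x ",
      ncol(x$values), " features (",
      paste(names(ft), ft, sep = "=", collapse = ", "), ")\n", sep = "")
  cat(sprintf("missing: %.1f%%\n", 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Write / read an abundance matrix as tab-delimited text
#'
#' @param x an `abundance_matrix`
#' @param path file path ("NA" marks missing cells); feature types are
#'   stored in a companion header line prefixed `#feature_type`
#' @export
write_abundance <- function(x, path) {
  stopifnot(inherits(x, "abundance_matrix"))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(paste0("#feature_type\t",
                    paste(x$feature_type, collapse = "\t")), con)
  df <- data.frame(subject_id = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abundance
#' @export
read_abundance <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#feature_type")) {
    stop("not an abundance matrix file: ", path)
  }
  types <- strsplit(first, "\t")[[1]][-1]
  df <- utils::read.delim(path, skip = 1, check.names = FALSE,
                          stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$subject_id
  structure(list(values = values,
                 feature_type = stats::setNames(types, colnames(values)),
                 provenance = NULL, qc = NULL, log = list()),
            class = "abundance_matrix")
}
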