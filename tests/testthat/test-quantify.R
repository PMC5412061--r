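# quantification: ratio estimator, CV formula, QC masking, filters

test_that("molecules_from_counts implements the IS ratio estimator", {
  expect_equal(molecules_from_counts(600, 600, 600), 600)
  expect_equal(molecules_from_counts(1200, 600, 600), 1200)
  expect_equal(molecules_from_counts(0, 600, 600), 0)
  expect_true(is.na(molecules_from_counts(10, 0, 600)))
})

test_that("abundance_per_million_actb arithmetic", {
  expect_equal(abundance_per_million_actb(600, 6000), 1e5)
  expect_equal(abundance_per_million_actb(0, 6000), 0)
  expect_equal(abundance_per_million_actb(6, 60000), 100)
  expect_true(is.na(abundance_per_million_actb(5, 0)))
})

test_that("stochastic_cv matches direct evaluation of the formula", {
  # frozen values computed by arbitrary-precision evaluation of
  # CV = -1 + 10^(M^-0.54 + R^-0.54 - (M R)^-0.54)
  expect_equal(stochastic_cv(600, 600), 0.1540301, tolerance = 1e-6)
  expect_equal(stochastic_cv(6, 60), 1.805185, tolerance = 1e-6)
  expect_lt(stochastic_cv(1e9, 1e9), 1e-3)
  expect_true(is.na(stochastic_cv(0, 100)))
  expect_true(is.na(stochastic_cv(100, -1)))
})

test_that("stochastic_cv is strictly decreasing in each argument", {
  grid <- 10^seq(0.3, 6, length.out = 32)
  cv <- outer(grid, grid, stochastic_cv)
  # decreasing along rows (M) and columns (R) over the full 32x32 grid
  expect_true(all(diff(cv) < 0))
  expect_true(all(t(diff(t(cv))) < 0))
})

test_that("copies_per_microliter reproduces the ISM specification", {
  expect_equal(copies_per_microliter(1e-15), 600, tolerance = 0.01)
  expect_equal(copies_per_microliter(1e-14), 6000, tolerance = 0.01)
})

test_that("apply_measurement_filter passes/fails the documented cells", {
  design <- data.frame(assay_id = "A1", gene = "G", primer_f = "ACGT",
                       primer_r = "ACGT", nt_captured = "AAATTT",
                       is_captured = "CCCGGG", is_input_copies = 600,
                       is_reference_assay = FALSE)
  counts <- data.frame(subject_id = c("s1", "s2", "s3"),
                       assay_id = "A1",
                       nt_reads = c(600L, 2L, 0L),
                       is_reads = c(600L, 600L, 0L))
  qc <- apply_measurement_filter(counts, design)
  # nt=600/is=600: M = 600 molecules, R = 1200 reads -> cv ~ 0.13, pass
  expect_true(qc$pass[1])
  expect_lt(qc$cv[1], 1.0)
  # nt=2: M = 2 molecules -> cv >> 1, fail
  expect_false(qc$pass[2])
  expect_gt(qc$cv[2], 1.0)
  # all-zero cell: undefined, fail
  expect_false(qc$pass[3])
  expect_true(is.na(qc$cv[3]))
})

test_that("every cell failing QC is missing downstream; retained cells have cv < 1", {
  ts <- tiny_sim(seed = 61, n_ca = 10, n_nc = 10, n_assays = 12,
                 n_genes = 8, n_informative = 3)
  counts <- tally_to_counts(ts$tally)
  qc <- apply_measurement_filter(counts, ts$design)
  ab <- quantify_abundance(counts, ts$design)
  targets <- ts$design$assay_id[!ts$design$is_reference_assay]
  qc_t <- qc[qc$assay_id %in% targets, ]
  for (i in seq_len(nrow(qc_t))) {
    v <- ab$values[qc_t$subject_id[i], qc_t$assay_id[i]]
    if (!qc_t$pass[i]) expect_true(is.na(v))
  }
  expect_true(all(qc$cv[qc$pass] < 1.0))
  # measured cells: provenance is consistent with the mask
  expect_identical(ab$provenance == "measured", !is.na(ab$values))
})

test_that("ACTB QC failure invalidates the whole library", {
  ts <- tiny_sim(seed = 63, n_ca = 3, n_nc = 3, n_assays = 5, n_genes = 3,
                 n_informative = 1)
  counts <- tally_to_counts(ts$tally)
  # break subject S001's ACTB cell
  idx <- counts$subject_id == "S001" & counts$assay_id == "ACTB"
  counts$is_reads[idx] <- 0L
  ab <- quantify_abundance(counts, ts$design)
  expect_true(all(is.na(ab$values["S001", ])))
  expect_true("S001" %in% ab$log$actb_failed_subjects)
})

test_that("assay and subject filters apply strict boundaries and idempotence", {
  set.seed(71)
  vals <- matrix(rnorm(100 * 5, 3), 100, 5,
                 dimnames = list(sprintf("P%03d", 1:100),
                                 paste0("A", 1:5)))
  vals[1:31, 1] <- NA   # 31% missing -> removed
  vals[1:30, 2] <- NA   # 30% missing -> retained (strict inequality)
  x <- structure(list(values = vals,
                      feature_type = setNames(rep("gene", 5),
                                              colnames(vals)),
                      provenance = NULL, qc = NULL, log = list()),
                 class = "abundance_matrix")
  f1 <- filter_assays(x, 0.30)
  expect_false("A1" %in% colnames(f1$values))
  expect_true("A2" %in% colnames(f1$values))
  expect_identical(filter_assays(f1, 0.30)$values, f1$values)

  # subject filter at min_assays = 3 on the 4 remaining features
  vals2 <- f1$values
  vals2["P050", ] <- NA
  vals2["P051", c("A2", "A3")] <- NA  # 2 measured < 3 -> removed
  x2 <- f1; x2$values <- vals2
  f2 <- filter_subjects(x2, min_assays = 3)
  expect_false("P050" %in% rownames(f2$values))
  expect_false("P051" %in% rownames(f2$values))
  expect_identical(filter_subjects(f2, 3)$values, f2$values)
})

test_that("a run with 23 of 68 high-missingness assays keeps 45 features", {
  # configure baselines so that exactly 23 assays sit below the detection
  # limit (mostly-missing) and the rest are comfortably measurable
  cfg <- sim_config(seed = 101)
  design <- synthetic_assay_design(seed = 102)
  cohort <- generate_cohort(cfg)
  la <- log10(cohort$truth$abundance)
  # recentre 23 assays far below, the other 45 far above, the CV cutoff
  lo <- 1:23; hi <- 24:68
  la[, lo] <- la[, lo] - (colMeans(la[, lo])[col(la[, lo])]) + 0.5
  la[, hi] <- la[, hi] - (colMeans(la[, hi])[col(la[, hi])]) + 4.0
  cohort$truth$abundance <- 10^la
  tally <- simulate_counts(cohort$truth, cohort$subjects, design, cfg)
  ab <- quantify_abundance(tally_to_counts(tally), design)
  ab <- filter_assays(ab, 0.30)
  expect_equal(sum(ab$feature_type == "gene"), 45)
  expect_equal(length(ab$log$removed_assays), 23)
})

test_that("subject filter: 5 of 120 sparse subjects leave 115", {
  set.seed(81)
  vals <- matrix(rnorm(120 * 20, 3), 120, 20,
                 dimnames = list(sprintf("P%03d", 1:120),
                                 paste0("A", 1:20)))
  vals[1:5, 6:20] <- NA   # subjects 1..5 keep only 5 measured assays
  x <- structure(list(values = vals,
                      feature_type = setNames(rep("gene", 20),
                                              colnames(vals)),
                      provenance = NULL, qc = NULL, log = list()),
                 class = "abundance_matrix")
  f <- filter_subjects(x, min_assays = 6)
  expect_equal(nrow(f$values), 115)
  expect_equal(length(f$log$removed_subjects), 5)
})

test_that("log10_transform maps zeros to missing and rejects negatives", {
  vals <- matrix(c(1e5, 1, 0, 10), 2, 2,
                 dimnames = list(c("a", "b"), c("g1", "g2")))
  x <- structure(list(values = vals,
                      feature_type = setNames(rep("gene", 2),
                                              colnames(vals)),
                      provenance = NULL, qc = NULL, log = list()),
                 class = "abundance_matrix")
  lx <- log10_transform(x)
  expect_equal(lx$values["a", "g1"], 5)
  expect_equal(lx$values["b", "g1"], 0)
  expect_true(is.na(lx$values["a", "g2"]))
  expect_equal(lx$values["b", "g2"], 1)
  x$values[1, 1] <- -1
  expect_error(log10_transform(x), "negative")
})

test_that("abundance estimation recovers loaded molecules at depth 1e4", {
  # the sequencing measurement estimates the molecules actually loaded;
  # median relative error < 5% at depth >= 1e4, shrinking with depth
  err_at_depth <- function(depth_mean, seed) {
    ts <- tiny_sim(seed = seed, n_ca = 15, n_nc = 15, n_assays = 15,
                   n_genes = 8, n_informative = 0,
                   depth_mean = depth_mean, depth_cv = 0.2,
                   abundance_log10_range = c(2.5, 4.2))
    tl <- ts$tally
    targets <- !ts$design$is_reference_assay
    est <- 600 * tl$nt_reads[, targets] / tl$is_reads[, targets]
    truth <- tl$nt_molecules[, targets]
    ok <- truth > 0 & tl$is_reads[, targets] > 0
    stats::median(abs(est[ok] - truth[ok]) / truth[ok])
  }
  e4 <- err_at_depth(1e4, 91)
  expect_lt(e4, 0.05)
  e3 <- err_at_depth(1e3, 91)
  e5 <- err_at_depth(1e5, 91)
  expect_true(e5 < e4 && e4 < e3)
})

test_that("abundance matrix round-trips through its TSV format", {
  ts <- tiny_sim(seed = 93, n_ca = 4, n_nc = 4, n_assays = 5, n_genes = 3,
                 n_informative = 1)
  ab <- quantify_abundance(tally_to_counts(ts$tally), ts$design)
  ab <- add_demographics(ab, ts$cohort$subjects)
  path <- tempfile(fileext = ".tsv")
  write_abundance(ab, path)
  back <- read_abundance(path)
  expect_equal(back$values, ab$values, tolerance = 1e-8)
  expect_identical(back$feature_type, ab$feature_type)
})
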