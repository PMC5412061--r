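#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator.  Defaults describe
#' a retrospective case-control cohort of 115 subjects (58 cancer, 57
#' non-cancer) measured on a 68-assay / 33-gene panel, with demographic
#' distributions matching the study population: non-cancer age 59.3 (SD
#' 14.2) years vs cancer 64.4 (SD 9.5); pack-years 43 (SD 28.7) vs 53 (SD
#' 31.3); male fraction 28/57 vs 40/56.
#'
#' True log10 abundances follow a latent-factor Gaussian model: per-assay
#' baseline + loadings x subject factors + residual noise, with a class
#' shift of `effect_size_log10` applied to informative assays in the cancer
#' class.  Baselines are uniform on `abundance_log10_range` (molecules per
#' million ACTB molecules); the low end deliberately sits below the
#' stochastic-sampling detection limit so that a realistic subset of assays
#' acquires >30% missing values after QC filtering.
#'
#' @param n_subjects_cancer,n_subjects_control class sizes
#' @param n_assays,n_genes panel dimensions (ACTB reference excluded)
#' @param n_informative_assays number of assays carrying a class effect
#' @param effect_size_log10 class-mean difference on the log10 scale for
#'   informative assays
#' @param latent_factors number of latent factors driving inter-gene
#'   correlation
#' @param latent_sd standard deviation of factor loadings
#' @param residual_sd per-cell residual SD of log10 abundance
#' @param abundance_log10_range range of per-assay baseline log10 abundance
#' @param actb_molecules_mean,actb_molecules_cv lognormal mean / CV of
#'   per-microlitre ACTB copies in the cDNA aliquot
#' @param depth_mean,depth_cv lognormal mean / CV of total reads per
#'   assay-sample cell
#' @param base_error_rate per-base substitution error rate for FASTQ output
#' @param is_poisson_jitter if TRUE, IS molecule input is Poisson around the
#'   nominal spike instead of the fixed count
#' @param age_mean,age_sd,pack_years_mean,pack_years_sd,male_prop per-class
#'   demographic parameters, each `c(NC, CA)`
#' @param demographic_missing_rate probability each demographic value is
#'   masked missing
#' @param barcode_len sample barcode length in bases
#' @param seed RNG seed; identical seeds give byte-identical output
#' @return object of class `sim_config`
#' @export
sim_config <- function(n_subjects_cancer = 58,
                       n_subjects_control = 57,
                       n_assays = 68,
                       n_genes = 33,
                       n_informative_assays = 13,
                       effect_size_log10 = 0.5,
                       latent_factors = 4,
                       latent_sd = 0.25,
                       residual_sd = 0.3,
                       abundance_log10_range = c(1.5, 4.5),
                       actb_molecules_mean = 60000,
                       actb_molecules_cv = 0.5,
                       depth_mean = 3000,
                       depth_cv = 0.5,
                       base_error_rate = 0.001,
                       is_poisson_jitter = FALSE,
                       age_mean = c(NC = 59.3, CA = 64.4),
                       age_sd = c(NC = 14.2, CA = 9.5),
                       pack_years_mean = c(NC = 43, CA = 53),
                       pack_years_sd = c(NC = 28.7, CA = 31.3),
                       male_prop = c(NC = 28 / 57, CA = 40 / 56),
                       demographic_missing_rate = 0.03,
                       barcode_len = 8,
                       seed = 1) {
  cfg <- list(
    n_subjects_cancer = n_subjects_cancer,
    n_subjects_control = n_subjects_control,
    n_assays = n_assays, n_genes = n_genes,
    n_informative_assays = n_informative_assays,
    effect_size_log10 = effect_size_log10,
    latent_factors = latent_factors,
    latent_sd = latent_sd, residual_sd = residual_sd,
    abundance_log10_range = abundance_log10_range,
    actb_molecules_mean = actb_molecules_mean,
    actb_molecules_cv = actb_molecules_cv,
    depth_mean = depth_mean, depth_cv = depth_cv,
    base_error_rate = base_error_rate,
    is_poisson_jitter = is_poisson_jitter,
    age_mean = age_mean, age_sd = age_sd,
    pack_years_mean = pack_years_mean, pack_years_sd = pack_years_sd,
    male_prop = male_prop,
    demographic_missing_rate = demographic_missing_rate,
    barcode_len = barcode_len,
    seed = seed
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  counts <- c("n_subjects_cancer", "n_subjects_control", "n_assays",
              "n_genes", "latent_factors")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      stop("sim_config: '", f, "' must be a positive count")
    }
  }
  if (cfg$n_informative_assays < 0 ||
      cfg$n_informative_assays > cfg$n_assays) {
    stop("sim_config: n_informative_assays must be in [0, n_assays]")
  }
  probs <- c(cfg$base_error_rate, cfg$demographic_missing_rate,
             cfg$male_prop)
  if (any(probs < 0 | probs > 1)) {
    stop("sim_config: probabilities must lie in [0, 1]")
  }
  if (cfg$actb_molecules_mean <= 0 || cfg$depth_mean <= 0) {
    stop("sim_config: means must be positive")
  }
  invisible(cfg)
}

# lognormal parameterised by mean and coefficient of variation
rlnorm_mean_cv <- function(n, mean, cv) {
  sigma2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Generate a synthetic case-control cohort with ground-truth abundances
#'
#' Draws subjects (demographics, class labels, unique dual barcodes) and a
#' truth table of per-subject true transcript abundances (molecules per
#' million ACTB molecules) plus per-subject ACTB copies per microlitre.
#' Informative assays have their cancer-class mean shifted by exactly
#' `effect_size_log10` (sign per assay) on the log10 scale.
#'
#' @param config a [sim_config()]
#' @return list with elements
#'   `subjects` (data.frame: subject_id, class_label, age, gender,
#'   pack_years, barcode_f, barcode_r) and
#'   `truth` (list: `abundance` subjects x assays matrix,
#'   `actb_per_ul` vector, `baseline_log10`, `informative`,
#'   `effect_direction`, `loadings`)
#' @export
generate_cohort <- function(config = sim_config()) {
  validate_sim_config(config)
  set.seed(config$seed)
  n_ca <- config$n_subjects_cancer
  n_nc <- config$n_subjects_control
  n <- n_ca + n_nc
  p <- config$n_assays

  class_label <- c(rep("NC", n_nc), rep("CA", n_ca))
  subject_id <- sprintf("S%03d", seq_len(n))

  # demographics per class, then masked missing completely at random
  idx <- ifelse(class_label == "NC", 1L, 2L)
  age <- round(stats::rnorm(n, config$age_mean[idx], config$age_sd[idx]), 1)
  age <- pmax(age, 30)
  pack_years <- round(stats::rnorm(n, config$pack_years_mean[idx],
                                   config$pack_years_sd[idx]), 1)
  pack_years <- pmax(pack_years, 0)
  gender <- ifelse(stats::runif(n) < config$male_prop[idx], "M", "F")
  mask <- function(x) {
    x[stats::runif(n) < config$demographic_missing_rate] <- NA
    x
  }
  age <- mask(age); gender <- mask(gender); pack_years <- mask(pack_years)

  bc_f <- generate_barcodes(n, config$barcode_len, min_dist = 3,
                            max_tries = 200 * n)
  bc_r <- generate_barcodes(n, config$barcode_len, min_dist = 3,
                            max_tries = 200 * n)

  subjects <- data.frame(
    subject_id = subject_id, class_label = class_label,
    age = age, gender = gender, pack_years = pack_years,
    barcode_f = bc_f, barcode_r = bc_r,
    stringsAsFactors = FALSE
  )

  # latent-factor model for log10 abundance
  baseline <- stats::runif(p, config$abundance_log10_range[1],
                           config$abundance_log10_range[2])
  informative <- rep(FALSE, p)
  informative[sample.int(p, config$n_informative_assays)] <- TRUE
  direction <- ifelse(informative,
                      sample(c(-1, 1), p, replace = TRUE), 0)
  loadings <- matrix(stats::rnorm(p * config$latent_factors,
                                  sd = config$latent_sd),
                     nrow = p)
  factors <- matrix(stats::rnorm(n * config$latent_factors), nrow = n)
  eps <- matrix(stats::rnorm(n * p, sd = config$residual_sd), nrow = n)
  shift <- outer(class_label == "CA",
                 direction * config$effect_size_log10)
  log10_ab <- sweep(factors %*% t(loadings) + eps, 2, baseline, "+") + shift
  abundance <- 10^log10_ab
  dimnames(abundance) <- list(subject_id, NULL)

  actb_per_ul <- rlnorm_mean_cv(n, config$actb_molecules_mean,
                                config$actb_molecules_cv)

  truth <- list(abundance = abundance,
                actb_per_ul = stats::setNames(actb_per_ul, subject_id),
                baseline_log10 = baseline,
                informative = informative,
                effect_direction = direction,
                loadings = loadings)
  list(subjects = subjects, truth = truth)
}

#' Write / read a sample sheet as tab-delimited text
#'
#' @param subjects subject table as produced by [generate_cohort()]
#' @param path file path
#' @export
write_sample_sheet <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE,
                             na.strings = c("NA", ""))
  req <- c("subject_id", "barcode_f", "barcode_r")
  if (!all(req %in% names(sheet))) {
    stop("sample sheet must contain columns: ", paste(req, collapse = ", "))
  }
  sheet
}
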