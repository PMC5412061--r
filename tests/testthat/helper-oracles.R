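# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths.

# full dynamic-programming Levenshtein distance
edit_distance_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1, m + 1)
  d[, 1] <- 0:n
  d[1, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L,
                             d[i + 1, j] + 1L,
                             d[i, j] + (x[i] != y[j]))
    }
  }
  d[n + 1, m + 1]
}

# AUC by exhaustive enumeration of all case-control pairs
auc_enumeration <- function(scores, y, positive = "CA") {
  s1 <- scores[y == positive]
  s0 <- scores[y != positive]
  total <- 0
  for (a in s1) for (b in s0) {
    total <- total + (a > b) + 0.5 * (a == b)
  }
  total / (length(s1) * length(s0))
}

# two-sided Fisher exact p for a 2x2 table by direct enumeration of the
# free cell with binomial-coefficient arithmetic (no dhyper)
fisher_2x2_enumeration <- function(tab) {
  m <- sum(tab[1, ]); n_ <- sum(tab[2, ]); k <- sum(tab[, 1])
  prob <- function(a) {
    choose(m, a) * choose(n_, k - a) / choose(m + n_, k)
  }
  support <- max(0, k - n_):min(k, m)
  probs <- vapply(support, prob, numeric(1))
  p_obs <- prob(tab[1, 1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# matrix inverse square root via SVD (package code uses eigen)
inv_sqrt_svd <- function(R) {
  sv <- svd(R)
  sv$u %*% diag(1 / sqrt(pmax(sv$d, 1e-8)), nrow = length(sv$d)) %*% t(sv$u)
}

# small standard fixture: cohort + design + tally, shared by several files
tiny_sim <- function(seed = 42, n_ca = 12, n_nc = 12, n_assays = 10,
                     n_genes = 6, n_informative = 3, depth_mean = 2000,
                     error_rate = 0, ...) {
  cfg <- sim_config(n_subjects_cancer = n_ca, n_subjects_control = n_nc,
                    n_assays = n_assays, n_genes = n_genes,
                    n_informative_assays = n_informative,
                    depth_mean = depth_mean,
                    base_error_rate = error_rate, seed = seed, ...)
  design <- synthetic_assay_design(n_assays = n_assays, n_genes = n_genes,
                                   seed = seed + 1)
  cohort <- generate_cohort(cfg)
  tally <- simulate_counts(cohort$truth, cohort$subjects, design, cfg)
  list(cfg = cfg, design = design, cohort = cohort, tally = tally)
}
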