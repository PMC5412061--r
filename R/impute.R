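#' Multiple imputation by chained equations with predictive mean matching
#'
#' Creates `m_copies` completed copies of a numeric matrix with missing
#' cells.  Each copy starts from random draws from the observed marginal of
#' each incomplete feature, then cycles over the incomplete features
#' (ascending missingness, ties by column order) for `n_iterations`
#' rounds.  Each visit regresses the feature on all other features over
#' its observed rows, draws regression parameters from their approximate
#' posterior (proper imputation: a scaled inverse-chi-square draw for the
#' residual variance and a normal draw for the coefficients), predicts the
#' missing cells with the drawn parameters, and fills each from a donor
#' sampled uniformly among the `k_donors` observed rows with the nearest
#' predicted mean (type-1 matching: donor means use the posterior-mode
#' coefficients).  Because donors are observed values, every imputed value
#' lies in the feature's observed support; binary 0/1 features therefore
#' stay binary without special casing.
#'
#' @param x numeric matrix (subjects x features) with NAs, or an
#'   `abundance_matrix`
#' @param m_copies number of completed copies M (default 50)
#' @param n_iterations chained-equation cycles per copy (default 10)
#' @param k_donors donor-pool size for matching (default 5)
#' @param ridge ridge added to the normal equations for stability
#' @param seed RNG seed
#' @return object of class `imputed_stack`: list with `copies` (list of M
#'   complete matrices), `mask` (logical missingness matrix) and `config`
#' @export
mice_pmm <- function(x, m_copies = 50, n_iterations = 10, k_donors = 5,
                     ridge = 1e-5, seed = NULL) {
  if (inherits(x, "abundance_matrix")) x <- x$values
  stopifnot(is.matrix(x), is.numeric(x), m_copies >= 2, k_donors >= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(x); p <- ncol(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(p))
  mask <- is.na(x)

  n_obs <- colSums(!mask)
  if (any(n_obs == 0)) {
    stop("feature(s) 100% missing: ",
         paste(colnames(x)[n_obs == 0], collapse = ", "))
  }
  bad <- n_obs < k_donors
  if (any(bad)) {
    stop("feature(s) with fewer than k_donors = ", k_donors,
         " observed values: ", paste(colnames(x)[bad], collapse = ", "))
  }

  incomplete <- which(colSums(mask) > 0)
  # visit order: ascending missingness, ties by column order
  visit <- incomplete[order(colSums(mask)[incomplete], incomplete)]

  copies <- vector("list", m_copies)
  for (m in seq_len(m_copies)) {
    data <- x
    # initialise missing cells from observed marginals
    for (j in incomplete) {
      obs_vals <- x[!mask[, j], j]
      data[mask[, j], j] <- sample(obs_vals, sum(mask[, j]),
                                   replace = TRUE)
    }
    for (it in seq_len(n_iterations)) {
      for (j in visit) {
        data[, j] <- pmm_draw(data, x, mask, j, k_donors, ridge)
      }
    }
    copies[[m]] <- data
  }
  structure(list(copies = copies, mask = mask,
                 config = list(m_copies = m_copies,
                               n_iterations = n_iterations,
                               k_donors = k_donors, ridge = ridge,
                               seed = seed)),
            class = "imputed_stack")
}

# one PMM update of feature j given current completed data
pmm_draw <- function(data, x, mask, j, k_donors, ridge) {
  obs <- !mask[, j]
  mis <- mask[, j]
  y <- x[obs, j]
  col <- data[, j]
  if (!any(mis)) return(col)
  X <- cbind(1, data[, -j, drop = FALSE])
  Xo <- X[obs, , drop = FALSE]
  Xm <- X[mis, , drop = FALSE]
  q <- ncol(Xo)

  # scale-aware ridge keeps the draw stable when p approaches n
  XtX <- crossprod(Xo)
  diag(XtX) <- diag(XtX) * (1 + ridge) + ridge
  R <- chol(XtX)
  betahat <- backsolve(R, forwardsolve(t(R), crossprod(Xo, y)))
  resid <- y - Xo %*% betahat
  df <- max(length(y) - q, 1)
  sigma2_star <- sum(resid^2) / stats::rchisq(1, df)
  beta_star <- betahat +
    backsolve(R, stats::rnorm(q)) * sqrt(sigma2_star)

  yhat_obs <- drop(Xo %*% betahat)
  yhat_mis <- drop(Xm %*% beta_star)

  imp <- vapply(yhat_mis, function(target) {
    d <- abs(yhat_obs - target)
    k <- min(k_donors, length(d))
    donors <- order(d)[seq_len(k)]
    y[donors[sample.int(k, 1)]]
  }, numeric(1))
  col[mis] <- imp
  col
}

#' Pool estimates across multiply imputed datasets by Rubin's rules
#'
#' The pooled point estimate is the mean over copies; total variance is
#' within-imputation variance plus `(1 + 1/M)` times the between-imputation
#' variance; the standard error is its square root.  Confidence intervals
#' use the normal approximation by default, or the Barnard-Rubin
#' small-sample t correction.
#'
#' @param estimates per-copy point estimates (length M >= 2)
#' @param variances per-copy squared standard errors (same length)
#' @param conf_level confidence level (default 0.95)
#' @param df_method "normal" or "barnard_rubin"
#' @return object of class `pooled_estimate`: list with point, within_var,
#'   between_var, total_var, se, ci_low, ci_high, m
#' @export
rubin_pool <- function(estimates, variances, conf_level = 0.95,
                       df_method = c("normal", "barnard_rubin")) {
  df_method <- match.arg(df_method)
  if (length(estimates) != length(variances)) {
    stop("estimates and variances must have equal length")
  }
  m <- length(estimates)
  if (m < 2) stop("Rubin pooling needs at least 2 copies")
  point <- mean(estimates)
  within <- mean(variances)
  between <- stats::var(estimates)
  total <- within + (1 + 1 / m) * between
  se <- sqrt(total)
  alpha <- 1 - conf_level
  if (df_method == "normal" || between == 0 || total == 0) {
    crit <- stats::qnorm(1 - alpha / 2)
  } else {
    nu <- (m - 1) * (1 + within / ((1 + 1 / m) * between))^2
    crit <- stats::qt(1 - alpha / 2, df = nu)
  }
  structure(list(point = point, within_var = within,
                 between_var = between, total_var = total, se = se,
                 ci_low = point - crit * se, ci_high = point + crit * se,
                 m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("pooled estimate: %.4g (SE %.4g, 95%% CI %.4g..%.4g, M=%d)\n",
              x$point, x$se, x$ci_low, x$ci_high, x$m))
  invisible(x)
}

#' Write an imputed stack to disk
#'
#' M tab-delimited complete matrices plus a JSON manifest recording the
#' configuration and per-feature missing fractions.
#'
#' @param stack an `imputed_stack`
#' @param dir output directory (created if needed)
#' @return invisible vector of copy file paths
#' @export
write_imputed_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputed_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(stack$copies))
  for (m in seq_along(stack$copies)) {
    paths[m] <- file.path(dir, sprintf("imputed_copy_%03d.tsv", m))
    df <- data.frame(subject_id = rownames(stack$copies[[m]]),
                     stack$copies[[m]], check.names = FALSE)
    utils::write.table(df, paths[m], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  manifest <- list(
    m_copies = length(stack$copies),
    config = stack$config,
    missing_fraction = as.list(round(colMeans(stack$mask), 6))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

#' Read an imputed stack written by [write_imputed_stack()]
#'
#' @param dir directory containing the copies and manifest
#' @return an `imputed_stack` (mask reconstructed from the manifest is not
#'   cell-level; cell-level mask requires the original matrix, so `mask`
#'   is NULL here)
#' @export
read_imputed_stack <- function(dir) {
  files <- sort(list.files(dir, pattern = "^imputed_copy_.*\\.tsv$",
                           full.names = TRUE))
  if (!length(files)) stop("no imputed copies found in ", dir)
  copies <- lapply(files, function(f) {
    df <- utils::read.delim(f, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df$subject_id
    m
  })
  config <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                simplifyVector = TRUE)$config
  structure(list(copies = copies, mask = NULL, config = config),
            class = "imputed_stack")
}
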