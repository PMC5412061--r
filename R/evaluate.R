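#' Pooled performance report for a trained model search
#'
#' Pools cross-validated performance across the M imputed copies.  AUC is
#' pooled by Rubin's rules on the logit scale (per-copy variance by the
#' Hanley-McNeil formula); accuracy, sensitivity, specificity, PPV and NPV
#' are pooled on the proportion scale with binomial within-copy variance.
#' The report also contains ROC points for the copy-averaged scores, the
#' specificity at the smallest threshold reaching 95% cross-validated
#' sensitivity, a feature table (CAT rank, selection frequency, missing
#' fraction) and the consensus confusion matrix (majority vote across
#' copies at the default LDA threshold).
#'
#' @param result a `model_search` from [select_and_train()]
#' @param stack the `imputed_stack` used for training (missing fractions)
#' @param conf_level confidence level for the pooled intervals
#' @param target_sensitivity sensitivity floor for the screening threshold
#' @return object of class `performance_report`
#' @export
evaluate_performance <- function(result, stack = NULL, conf_level = 0.95,
                                 target_sensitivity = 0.95) {
  stopifnot(inherits(result, "model_search"))
  y <- result$y
  M <- ncol(result$scores)
  n_pos <- sum(y == "CA"); n_neg <- sum(y == "NC")

  # AUC pooled on the logit scale; degenerate per-copy AUCs of 0 or 1 are
  # clamped at the estimator's resolution (half a concordant pair)
  auc_m <- result$auc_by_copy
  res_lim <- 1 / (2 * n_pos * n_neg)
  auc_clamped <- pmin(pmax(auc_m, res_lim), 1 - res_lim)
  logit <- function(p) log(p / (1 - p))
  var_logit <- vapply(auc_clamped, function(a) {
    auc_variance(a, n_pos, n_neg) / (a * (1 - a))^2
  }, numeric(1))
  pooled_logit <- rubin_pool(logit(auc_clamped), var_logit,
                             conf_level = conf_level)
  expit <- function(x) 1 / (1 + exp(-x))
  auc_pooled <- list(point = mean(auc_m),
                     ci_low = expit(pooled_logit$ci_low),
                     ci_high = expit(pooled_logit$ci_high),
                     se = pooled_logit$se)

  # proportion metrics per copy from CV predictions
  prop_metrics <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")
  per_copy <- lapply(seq_len(M), function(m) {
    pred <- result$predictions[, m]
    tp <- sum(pred == "CA" & y == "CA")
    fn <- sum(pred == "NC" & y == "CA")
    fp <- sum(pred == "CA" & y == "NC")
    tn <- sum(pred == "NC" & y == "NC")
    met <- confusion_metrics(tp, fn, fp, tn)
    denom <- list(accuracy = length(y), sensitivity = tp + fn,
                  specificity = tn + fp, ppv = tp + fp, npv = tn + fn)
    list(metrics = met, denom = denom)
  })
  pooled <- lapply(prop_metrics, function(metric) {
    est <- vapply(per_copy, function(pc) pc$metrics[[metric]], numeric(1))
    dn <- vapply(per_copy, function(pc) pc$denom[[metric]], numeric(1))
    est[is.nan(est)] <- 0.5
    v <- est * (1 - est) / pmax(dn, 1)
    rubin_pool(est, v, conf_level = conf_level)
  })
  names(pooled) <- prop_metrics

  # consensus predictions and confusion matrix (majority over copies)
  consensus <- apply(result$predictions, 1, function(row) {
    if (mean(row == "CA") >= 0.5) "CA" else "NC"
  })
  confusion <- c(tp = sum(consensus == "CA" & y == "CA"),
                 fn = sum(consensus == "NC" & y == "CA"),
                 fp = sum(consensus == "CA" & y == "NC"),
                 tn = sum(consensus == "NC" & y == "NC"))

  mean_scores <- rowMeans(result$scores)
  roc <- roc_points(mean_scores, y)
  screen <- specificity_at_sensitivity(mean_scores, y,
                                       target_sensitivity)

  feature_table <- result$cat_table
  feature_table <- feature_table[order(-feature_table$mean_abs_cat), ]
  feature_table$rank <- seq_len(nrow(feature_table))
  if (!is.null(stack) && !is.null(stack$mask)) {
    feature_table$missing_fraction <-
      colMeans(stack$mask)[feature_table$feature]
  }
  rownames(feature_table) <- NULL

  structure(list(
    auc = auc_pooled,
    metrics = pooled,
    confusion = confusion,
    roc = roc,
    mean_scores = mean_scores,
    screening = screen,
    feature_table = feature_table,
    selected_features = result$selected_features,
    best_k = result$best_k,
    y = y,
    m_copies = M,
    conf_level = conf_level
  ), class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat("performance_report (M =", x$m_copies, "imputations, best k =",
      x$best_k, ")\n")
  cat(sprintf("  AUC        %s (95%% CI %s..%s)\n", pct(x$auc$point),
              pct(x$auc$ci_low), pct(x$auc$ci_high)))
  for (m in names(x$metrics)) {
    pe <- x$metrics[[m]]
    cat(sprintf("  %-10s %s (95%% CI %s..%s)\n", m, pct(pe$point),
                pct(max(pe$ci_low, 0)), pct(min(pe$ci_high, 1))))
  }
  cat(sprintf("  specificity at >=%.0f%% sensitivity: %s\n",
              100 * 0.95, pct(x$screening$specificity)))
  cat("  features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Compare two classifiers by paired bootstrap of the AUC difference
#'
#' Both reports must score the same subjects.  Subjects are resampled with
#' replacement (stratified by class); the two AUCs and their difference
#' are recomputed per resample; the two-sided p-value is the bootstrap
#' probability that the difference crosses zero.
#'
#' @param report_full,report_reduced `performance_report`s on identical
#'   subjects (e.g. genes+demographics vs demographics only)
#' @param n_boot bootstrap resamples (default 2000)
#' @param seed RNG seed
#' @return list with observed AUCs, difference, bootstrap CI and p-value
#' @export
compare_models <- function(report_full, report_reduced, n_boot = 2000,
                           seed = 1) {
  stopifnot(inherits(report_full, "performance_report"),
            inherits(report_reduced, "performance_report"))
  if (!identical(report_full$y, report_reduced$y)) {
    stop("the two reports must cover the same subjects")
  }
  y <- report_full$y
  s1 <- report_full$mean_scores
  s2 <- report_reduced$mean_scores
  auc1 <- auc_mannwhitney(s1, y)
  auc2 <- auc_mannwhitney(s2, y)
  obs_diff <- auc1 - auc2

  set.seed(seed)
  pos <- which(y == "CA"); neg <- which(y == "NC")
  diffs <- vapply(seq_len(n_boot), function(b) {
    idx <- c(sample(pos, length(pos), replace = TRUE),
             sample(neg, length(neg), replace = TRUE))
    auc_mannwhitney(s1[idx], y[idx]) - auc_mannwhitney(s2[idx], y[idx])
  }, numeric(1))
  # two-sided bootstrap p: twice the smaller tail around zero
  p <- 2 * min(mean(diffs <= 0), mean(diffs >= 0))
  p <- min(max(p, 1 / n_boot), 1)
  list(auc_full = auc1, auc_reduced = auc2, auc_difference = obs_diff,
       ci = stats::quantile(diffs, c(0.025, 0.975), names = FALSE),
       p_value = p, n_boot = n_boot)
}

#' Serialise a performance report and model to JSON / TSV
#'
#' @param report a `performance_report`
#' @param result the `model_search` (per-copy models)
#' @param dir output directory
#' @export
write_report <- function(report, result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pe_list <- function(pe) list(point = pe$point, ci_low = pe$ci_low,
                               ci_high = pe$ci_high)
  out <- list(
    best_k = report$best_k,
    selected_features = report$selected_features,
    auc = pe_list(report$auc),
    metrics = lapply(report$metrics, pe_list),
    confusion = as.list(report$confusion),
    screening = report$screening,
    m_copies = report$m_copies
  )
  jsonlite::write_json(out, file.path(dir, "report.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.table(report$roc, file.path(dir, "roc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(report$feature_table,
                     file.path(dir, "feature_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  model_json <- list(
    features = result$selected_features,
    mean_weights = {
      W <- sapply(result$models, function(m) m$weights)
      if (is.null(dim(W))) W <- matrix(W, nrow = 1)
      as.list(stats::setNames(rowMeans(W), result$selected_features))
    },
    mean_threshold = mean(vapply(result$models, function(m) m$threshold,
                                 numeric(1)))
  )
  jsonlite::write_json(model_json, file.path(dir, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
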