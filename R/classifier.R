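#' Two-sample pooled-variance t scores per feature
#'
#' Sign convention: cancer mean minus non-cancer mean.  Features with zero
#' pooled variance get t = 0 with a warning.
#'
#' @param X complete numeric matrix (subjects x features)
#' @param y class labels with positives `positive`
#' @param positive positive-class label (default "CA")
#' @return named vector of t statistics
#' @export
t_scores <- function(X, y, positive = "CA") {
  pos <- y == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 < 2 || n0 < 2) stop("both classes need at least 2 subjects")
  m1 <- colMeans(X[pos, , drop = FALSE])
  m0 <- colMeans(X[!pos, , drop = FALSE])
  v1 <- apply(X[pos, , drop = FALSE], 2, stats::var)
  v0 <- apply(X[!pos, , drop = FALSE], 2, stats::var)
  sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n0))
  t <- (m1 - m0) / se
  if (any(se == 0)) {
    warning("zero-variance feature(s); t set to 0")
    t[se == 0] <- 0
  }
  t
}

#' Shrinkage estimate of the feature-feature correlation matrix
#'
#' Shrinks the sample correlation matrix toward the identity with an
#' analytically estimated intensity: lambda is the sum of estimated
#' variances of the off-diagonal correlations divided by the sum of their
#' squares, clipped to `[0, 1]` (the Schafer-Strimmer estimator).
#' Constant features contribute zero correlation.
#'
#' @param X numeric matrix (subjects x features), n >= 3
#' @return list with `R` (shrunk correlation matrix) and `lambda`
#' @export
shrinkage_correlation <- function(X) {
  n <- nrow(X); p <- ncol(X)
  if (n < 3) stop("shrinkage correlation needs n >= 3")
  sds <- apply(X, 2, stats::sd)
  const <- sds == 0
  Xs <- scale(X)
  Xs[, const] <- 0
  r <- crossprod(Xs) / (n - 1)
  diag(r) <- 1

  # var-hat of each off-diagonal r_ij from the products w_kij = x_ki x_kj,
  # computed one column block at a time to avoid an n x p x p array
  var_r <- matrix(0, p, p)
  for (j in seq_len(p)) {
    wj <- Xs * Xs[, j]                       # n x p matrix of products
    wbar <- colMeans(wj)
    var_r[, j] <- n / ((n - 1)^3) *
      colSums(sweep(wj, 2, wbar, "-")^2)
  }
  off <- upper.tri(r)
  denom <- sum(r[off]^2)
  lambda <- if (denom > 0) min(1, max(0, sum(var_r[off]) / denom)) else 1
  R <- (1 - lambda) * r
  diag(R) <- 1
  list(R = R, lambda = lambda)
}

#' Correlation-adjusted t (CAT) scores
#'
#' Decorrelates a vector of t scores with the inverse matrix square root
#' of the (shrunk) correlation matrix: tau = R^(-1/2) t.  The square root
#' is taken by eigendecomposition with eigenvalues floored at `eps`.
#'
#' @param t named vector of t scores
#' @param R symmetric positive-definite correlation matrix
#' @param eps eigenvalue floor
#' @return named vector of CAT scores
#' @export
cat_scores <- function(t, R, eps = 1e-8) {
  stopifnot(length(t) == nrow(R), nrow(R) == ncol(R))
  eg <- eigen(R, symmetric = TRUE)
  vals <- pmax(eg$values, eps)
  Rinv_sqrt <- eg$vectors %*% (t(eg$vectors) / sqrt(vals))
  tau <- drop(Rinv_sqrt %*% t)
  names(tau) <- names(t)
  tau
}

# CAT ranking of all features of a complete matrix (helper used by CV)
cat_ranking <- function(X, y, positive = "CA") {
  t <- t_scores(X, y, positive)
  sc <- shrinkage_correlation(X)
  tau <- cat_scores(t, sc$R)
  # rank by |tau| descending; ties broken by feature name for determinism
  ord <- order(-abs(tau), colnames(X))
  list(t = t, tau = tau, lambda = sc$lambda,
       ranked_features = colnames(X)[ord])
}

#' Fit a pooled-covariance linear discriminant model
#'
#' Classical two-class LDA: discriminant weights
#' `w = (S + ridge I)^{-1} (mu_CA - mu_NC)` with S the pooled
#' within-class covariance; score `s(x) = w . x`; decision threshold
#' `w . (mu_CA + mu_NC)/2 + log(prior_NC / prior_CA)` (equal priors by
#' default).
#'
#' @param X complete numeric matrix (subjects x features)
#' @param y class labels
#' @param ridge ridge added to the pooled covariance diagonal
#' @param positive positive-class label
#' @param equal_priors use equal class priors for the threshold
#' @return object of class `lda_model`
#' @export
fit_lda <- function(X, y, ridge = 1e-6, positive = "CA",
                    equal_priors = TRUE) {
  X <- as.matrix(X)
  pos <- y == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  n1 <- sum(pos); n0 <- sum(!pos); p <- ncol(X)
  mu1 <- colMeans(X[pos, , drop = FALSE])
  mu0 <- colMeans(X[!pos, , drop = FALSE])
  c1 <- X[pos, , drop = FALSE] - rep(mu1, each = n1)
  c0 <- X[!pos, , drop = FALSE] - rep(mu0, each = n0)
  S <- (crossprod(c1) + crossprod(c0)) / (n1 + n0 - 2)
  Sr <- S + diag(ridge, p)
  w <- tryCatch(solve(Sr, mu1 - mu0), error = function(e) {
    stop("singular pooled covariance; increase ridge (", ridge, ")")
  })
  prior_term <- if (equal_priors) 0 else log(n0 / n1)
  threshold <- sum(w * (mu1 + mu0) / 2) + prior_term
  structure(list(features = colnames(X), weights = w,
                 mu_pos = mu1, mu_neg = mu0, covariance = Sr,
                 threshold = threshold, positive = positive,
                 ridge = ridge),
            class = "lda_model")
}

#' Discriminant scores and class predictions
#'
#' @param object an `lda_model`
#' @param newdata matrix with the model's features as columns
#' @param type "score" for the linear discriminant value, "class" for the
#'   thresholded label
#' @param ... unused
#' @return numeric scores or character labels
#' @export
predict.lda_model <- function(object, newdata,
                              type = c("score", "class"), ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)[, object$features, drop = FALSE]
  s <- drop(newdata %*% object$weights)
  if (type == "score") return(s)
  ifelse(s > object$threshold, object$positive,
         if (object$positive == "CA") "NC" else "CA")
}

# stratified fold assignment; every fold's training set keeps both classes
stratified_folds <- function(y, folds, seed = NULL, positive = "CA") {
  if (!is.null(seed)) set.seed(seed)
  f <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    f[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }
  f
}

#' Cross-validated LDA AUC for a fixed feature set
#'
#' Stratified k-fold cross-validation; the LDA is refit on each training
#' split; held-out discriminant scores are pooled and the AUC computed by
#' the rank formulation with tie correction.
#'
#' @param X complete matrix
#' @param y labels
#' @param features feature names to use
#' @param folds number of folds (default 10)
#' @param seed fold-assignment seed
#' @param ridge LDA ridge
#' @return list with `auc`, `scores` (held-out, in subject order),
#'   `predictions`, `fold`
#' @export
cv_auc <- function(X, y, features, folds = 10, seed = NULL, ridge = 1e-6) {
  fold <- stratified_folds(y, folds, seed)
  scores <- numeric(length(y))
  preds <- character(length(y))
  for (f in sort(unique(fold))) {
    test <- fold == f
    fit <- fit_lda(X[!test, features, drop = FALSE], y[!test],
                   ridge = ridge)
    scores[test] <- predict(fit, X[test, features, drop = FALSE])
    preds[test] <- predict(fit, X[test, features, drop = FALSE],
                           type = "class")
  }
  list(auc = auc_mannwhitney(scores, y), scores = scores,
       predictions = preds, fold = fold)
}

#' Vote-based feature selection and model-size search over imputed copies
#'
#' For each candidate model size k, every imputed copy casts one vote for
#' each of its top-k features by absolute CAT score; features with a vote
#' fraction of at least `vote_threshold` form the candidate set, which is
#' evaluated by 10-fold cross-validated LDA on every copy.  The AUC and
#' accuracy are averaged across copies, and the best k maximises average
#' AUC (ties to the smaller k).
#'
#' In the default honest mode, CAT ranking and voting are recomputed
#' inside each training fold, so no information from held-out subjects
#' leaks into feature selection.  Mode "full" ranks once on each complete
#' copy (optimistically biased; provided for comparison).
#'
#' @param stack an `imputed_stack`
#' @param y class labels in stack row order
#' @param k_grid candidate model sizes (default 1..25, capped at p)
#' @param vote_threshold minimum vote fraction (default 0.60)
#' @param folds CV folds (default 10)
#' @param seed fold/selection seed
#' @param mode "honest" or "full"
#' @param ridge LDA ridge
#' @return object of class `model_search`: per-k summary, best_k, final
#'   selected features with vote fractions, per-copy CV AUC/accuracy at
#'   best_k, held-out score matrix (subjects x M), per-copy full-data
#'   models, CAT ranking table
#' @export
select_and_train <- function(stack, y, k_grid = 1:25,
                             vote_threshold = 0.60, folds = 10,
                             seed = 1, mode = c("honest", "full"),
                             ridge = 1e-6) {
  mode <- match.arg(mode)
  stopifnot(inherits(stack, "imputed_stack"))
  copies <- stack$copies
  M <- length(copies)
  p <- ncol(copies[[1]])
  feat_names <- colnames(copies[[1]])
  k_grid <- sort(unique(pmin(k_grid, p)))
  y <- as.character(y)
  n <- length(y)
  stopifnot(nrow(copies[[1]]) == n)

  fold <- stratified_folds(y, folds, seed)

  # rankings are k-independent: compute once per (fold, copy) in honest
  # mode, once per copy in full mode, then read top-k prefixes
  if (mode == "honest") {
    fold_rankings <- lapply(sort(unique(fold)), function(f) {
      lapply(copies, function(Xc) {
        cat_ranking(Xc[fold != f, , drop = FALSE], y[fold != f])
      })
    })
  }
  full_rankings <- lapply(copies, function(Xc) cat_ranking(Xc, y))

  vote_fraction <- function(rankings, k) {
    votes <- table(factor(unlist(lapply(rankings, function(r) {
      r$ranked_features[seq_len(k)]
    })), levels = feat_names))
    as.numeric(votes) / length(rankings)
  }

  per_k <- data.frame(k = k_grid, n_selected = NA_integer_,
                      mean_auc = NA_real_, mean_accuracy = NA_real_)
  details <- vector("list", length(k_grid))

  for (ki in seq_along(k_grid)) {
    k <- k_grid[ki]
    scores <- matrix(NA_real_, n, M)
    preds <- matrix(NA_character_, n, M)
    if (mode == "honest") {
      empty_fold <- FALSE
      for (fi in seq_along(sort(unique(fold)))) {
        f <- sort(unique(fold))[fi]
        vf <- vote_fraction(fold_rankings[[fi]], k)
        sel <- feat_names[vf >= vote_threshold]
        if (!length(sel)) {
          # degenerate fold: fall back to the highest-vote features
          sel <- feat_names[vf == max(vf)]
          empty_fold <- TRUE
        }
        test <- fold == f
        for (m in seq_len(M)) {
          Xc <- copies[[m]]
          fit <- fit_lda(Xc[!test, sel, drop = FALSE], y[!test],
                         ridge = ridge)
          scores[test, m] <- predict(fit, Xc[test, sel, drop = FALSE])
          preds[test, m] <- predict(fit, Xc[test, sel, drop = FALSE],
                                    type = "class")
        }
      }
      vf_full <- vote_fraction(full_rankings, k)
      sel_full <- feat_names[vf_full >= vote_threshold]
    } else {
      vf_full <- vote_fraction(full_rankings, k)
      sel_full <- feat_names[vf_full >= vote_threshold]
      if (!length(sel_full)) {
        warning("no feature reaches the vote threshold at k = ", k,
                "; k skipped")
        details[[ki]] <- list(skipped = TRUE)
        next
      }
      for (m in seq_len(M)) {
        cv <- cv_auc(copies[[m]], y, sel_full, folds = folds,
                     seed = seed, ridge = ridge)
        scores[, m] <- cv$scores
        preds[, m] <- cv$predictions
      }
    }
    auc_m <- vapply(seq_len(M), function(m) {
      auc_mannwhitney(scores[, m], y)
    }, numeric(1))
    acc_m <- vapply(seq_len(M), function(m) mean(preds[, m] == y),
                    numeric(1))
    per_k$n_selected[ki] <- length(sel_full)
    per_k$mean_auc[ki] <- mean(auc_m)
    per_k$mean_accuracy[ki] <- mean(acc_m)
    details[[ki]] <- list(vote_fraction = stats::setNames(vf_full,
                                                          feat_names),
                          selected = sel_full, scores = scores,
                          preds = preds, auc_by_copy = auc_m,
                          acc_by_copy = acc_m)
  }

  valid <- which(!is.na(per_k$mean_auc))
  if (!length(valid)) stop("no candidate model size produced a model")
  best_i <- valid[which.max(per_k$mean_auc[valid])]  # ties -> smaller k
  best <- details[[best_i]]

  # final per-copy models refit on complete copies with the selected set
  models <- lapply(copies, function(Xc) {
    fit_lda(Xc[, best$selected, drop = FALSE], y, ridge = ridge)
  })

  structure(list(
    per_k = per_k, best_k = per_k$k[best_i],
    selected_features = best$selected,
    vote_fraction = best$vote_fraction,
    auc_by_copy = best$auc_by_copy,
    accuracy_by_copy = best$acc_by_copy,
    scores = best$scores, predictions = best$preds,
    y = y, fold = fold, models = models, mode = mode,
    vote_threshold = vote_threshold,
    cat_table = data.frame(
      feature = feat_names,
      mean_abs_cat = rowMeans(vapply(full_rankings, function(r) {
        abs(r$tau)[feat_names]
      }, numeric(p))),
      vote_fraction = as.numeric(best$vote_fraction)
    )
  ), class = "model_search")
}

#' @export
print.model_search <- function(x, ...) {
  cat("model_search (", x$mode, " CV): best k =", x$best_k,
      "-> ", length(x$selected_features), "features, mean AUC",
      sprintf("%.3f", max(x$per_k$mean_auc, na.rm = TRUE)), "\n")
  cat("selected:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}
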