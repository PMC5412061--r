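# CAT scores, LDA, cross-validated AUC, vote selection, pooling

test_that("t_scores: hand-computed case and conventions", {
  X <- matrix(c(1, 2, 3, 4, 5, 6), ncol = 1)
  y <- c(rep("CA", 3), rep("NC", 3))
  # CA {1,2,3} vs NC {4,5,6}: pooled sd 1, t = -3.674
  expect_equal(unname(t_scores(X, y)), -3.674235, tolerance = 1e-5)
  # identical class means -> t ~ 0
  set.seed(3)
  X2 <- matrix(rnorm(400), 200, 2)
  y2 <- rep(c("CA", "NC"), each = 100)
  expect_lt(max(abs(t_scores(X2, y2))), 3)
  # zero-variance feature -> 0 with warning
  X3 <- cbind(a = rep(1, 6), b = c(1, 2, 3, 4, 5, 6))
  expect_warning(t3 <- t_scores(X3, y), "zero-variance")
  expect_equal(unname(t3["a"]), 0)
  # strong separation: large |t| with CA-minus-NC sign
  X4 <- matrix(c(0, 0, 0, 1, 1, 1) + rnorm(6, sd = 1e-3), ncol = 1)
  expect_lt(unname(t_scores(X4, y)), -50)
})

test_that("shrinkage_correlation: direction, nulls, and brute-force check", {
  set.seed(13)
  # independent features, large n: off-diagonals near 0
  X <- matrix(rnorm(5000), 1000, 5)
  sc <- shrinkage_correlation(X)
  expect_lt(max(abs(sc$R[upper.tri(sc$R)])), 0.1)
  # duplicated feature: shrunk correlation strictly between sample and 0
  X2 <- cbind(rnorm(30), 0)
  X2[, 2] <- X2[, 1] + rnorm(30, sd = 0.1)
  r_sample <- cor(X2)[1, 2]
  sc2 <- shrinkage_correlation(X2)
  expect_gt(sc2$R[1, 2], 0)
  expect_lt(sc2$R[1, 2], r_sample)
  expect_gte(sc2$lambda, 0); expect_lte(sc2$lambda, 1)

  # brute-force recomputation on a 5 x 30 matrix
  set.seed(17)
  X3 <- matrix(rnorm(150), 30, 5)
  sc3 <- shrinkage_correlation(X3)
  n <- 30
  Xs <- scale(X3)
  r <- cor(X3)
  var_r <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    w <- Xs[, i] * Xs[, j]
    var_r[i, j] <- n / ((n - 1)^3) * sum((w - mean(w))^2)
  }
  off <- upper.tri(r)
  lambda <- min(1, max(0, sum(var_r[off]) / sum(r[off]^2)))
  expect_equal(sc3$lambda, lambda, tolerance = 1e-10)
  expect_equal(sc3$R[off], ((1 - lambda) * r)[off], tolerance = 1e-10)
})

test_that("cat_scores: identity, symmetry, and matrix-root oracle", {
  t <- c(a = 1.2, b = -0.5, c = 2)
  expect_equal(cat_scores(t, diag(3)), t)
  # 2-feature symmetric case: equal t stays equal
  R2 <- matrix(c(1, 0.6, 0.6, 1), 2)
  tau2 <- cat_scores(c(x = 1, y = 1), R2)
  expect_equal(tau2[["x"]], tau2[["y"]])
  # 3x3 oracle: independent inverse square root via SVD
  set.seed(19)
  A <- matrix(rnorm(9), 3)
  R3 <- cov2cor(crossprod(A) + diag(3))
  tau <- cat_scores(t, R3)
  expect_equal(unname(tau), drop(inv_sqrt_svd(R3) %*% t),
               tolerance = 1e-8)
})

test_that("fit_lda: separation, null, and 1-D closed form", {
  set.seed(23)
  X <- rbind(matrix(rnorm(100, 0), 50, 2), matrix(rnorm(100, 5), 50, 2))
  colnames(X) <- c("u", "v")
  y <- rep(c("NC", "CA"), each = 50)
  fit <- fit_lda(X, y)
  expect_equal(mean(predict(fit, X, type = "class") == y), 1)

  # 1-feature closed form: w = (mu1 - mu0) / sigma2
  x1 <- matrix(c(rnorm(40, 0, 1), rnorm(40, 2, 1)), ncol = 1,
               dimnames = list(NULL, "f"))
  y1 <- rep(c("NC", "CA"), each = 40)
  fit1 <- fit_lda(x1, y1, ridge = 0)
  mu1 <- mean(x1[41:80, ]); mu0 <- mean(x1[1:40, ])
  s2 <- (39 * var(x1[1:40, ]) + 39 * var(x1[41:80, ])) / 78
  expect_equal(unname(fit1$weights), (mu1 - mu0) / s2, tolerance = 1e-10)

  expect_error(fit_lda(X[1:50, ], y[1:50]), "both classes")
})

test_that("auc: worked example, enumeration oracle, invariances", {
  # CA {0.9, 0.4}, NC {0.7, 0.1}: 3 of 4 pairs concordant
  s <- c(0.9, 0.4, 0.7, 0.1)
  y <- c("CA", "CA", "NC", "NC")
  expect_equal(auc_mannwhitney(s, y), 0.75)
  # enumeration oracle on random score sets with ties
  set.seed(29)
  for (i in 1:25) {
    n <- sample(6:20, 1)
    yy <- sample(c("CA", "NC"), n, replace = TRUE,
                 prob = c(0.5, 0.5))
    if (length(unique(yy)) < 2) yy[1:2] <- c("CA", "NC")
    ss <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # ties likely
    expect_equal(auc_mannwhitney(ss, yy), auc_enumeration(ss, yy))
    # invariance under strictly monotone transforms
    expect_equal(auc_mannwhitney(exp(3 * ss) - 1, yy),
                 auc_mannwhitney(ss, yy))
  }
})

test_that("cv_auc: perfect separation, permutation null", {
  set.seed(31)
  n <- 60
  y <- rep(c("CA", "NC"), each = n / 2)
  X <- cbind(sep = ifelse(y == "CA", 10, -10) + rnorm(n, sd = 0.1),
             noise = rnorm(n))
  expect_equal(cv_auc(X, y, "sep", folds = 5, seed = 1)$auc, 1.0)
  # label-permuted data: mean AUC over 50 permutations near 0.5
  aucs <- vapply(1:50, function(i) {
    set.seed(100 + i)
    cv_auc(X, sample(y), c("sep", "noise"), folds = 5, seed = i)$auc
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("select_and_train finds a deterministic marker and reports votes", {
  set.seed(37)
  n <- 60
  y <- rep(c("CA", "NC"), each = n / 2)
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X[, "f3"] <- ifelse(y == "CA", 3, 0) + rnorm(n, sd = 0.5)
  stack <- structure(list(copies = lapply(1:4, function(m) X),
                          mask = matrix(FALSE, n, 6),
                          config = list()),
                     class = "imputed_stack")
  res <- select_and_train(stack, y, k_grid = c(1, 3), folds = 5, seed = 7)
  expect_true("f3" %in% res$selected_features)
  expect_equal(unname(res$vote_fraction["f3"]), 1.0)
  expect_gt(max(res$per_k$mean_auc), 0.95)
  expect_equal(res$per_k$k[which.max(res$per_k$mean_auc)], res$best_k)
})

test_that("evaluate_performance reproduces confusion-matrix metrics", {
  # construct a search result whose CV predictions give the fixed matrix
  # TP=54 FN=4 FP=4 TN=53 in every copy
  y <- c(rep("CA", 58), rep("NC", 57))
  pred <- c(rep("CA", 54), rep("NC", 4), rep("CA", 4), rep("NC", 53))
  scores <- ifelse(pred == "CA", 1, -1) + seq_along(y) * 1e-4
  M <- 3
  res <- structure(list(
    per_k = data.frame(k = 1, n_selected = 1, mean_auc = NA,
                       mean_accuracy = NA),
    best_k = 1, selected_features = "f",
    vote_fraction = c(f = 1),
    auc_by_copy = rep(auc_mannwhitney(scores, y), M),
    accuracy_by_copy = rep(mean(pred == y), M),
    scores = matrix(rep(scores, M), ncol = M),
    predictions = matrix(rep(pred, M), ncol = M),
    y = y, fold = rep(1, length(y)), models = list(), mode = "honest",
    vote_threshold = 0.6,
    cat_table = data.frame(feature = "f", mean_abs_cat = 1,
                           vote_fraction = 1)
  ), class = "model_search")
  rep_ <- evaluate_performance(res)
  expect_equal(rep_$metrics$sensitivity$point, 54 / 58, tolerance = 1e-12)
  expect_equal(rep_$metrics$specificity$point, 53 / 57, tolerance = 1e-12)
  expect_equal(rep_$metrics$ppv$point, 54 / 58, tolerance = 1e-12)
  expect_equal(rep_$metrics$npv$point, 53 / 57, tolerance = 1e-12)
  expect_equal(rep_$metrics$accuracy$point, 107 / 115, tolerance = 1e-12)
  expect_equal(unname(rep_$confusion),
               c(54, 4, 4, 53), tolerance = 0)
})

test_that("perfect classifier: all metrics 100%, specificity 100% at
           95% sensitivity", {
  y <- rep(c("CA", "NC"), each = 20)
  s <- ifelse(y == "CA", 2, -2) + rnorm(40, sd = 0.1)
  expect_equal(auc_mannwhitney(s, y), 1)
  sc <- specificity_at_sensitivity(s, y, 0.95)
  expect_equal(sc$specificity, 1)
  roc <- roc_points(s, y)
  expect_true(all(diff(roc$tpr) >= 0))
  expect_true(all(diff(roc$fpr) >= 0))
})

test_that("compare_models: identity gives p ~ 1, extremes give small p", {
  y <- rep(c("CA", "NC"), times = c(58, 57))
  set.seed(41)
  s_good <- ifelse(y == "CA", 1, 0) + rnorm(115, sd = 0.05)
  s_null <- rnorm(115)
  mk_report <- function(scores) {
    structure(list(y = y, mean_scores = scores),
              class = "performance_report")
  }
  same <- compare_models(mk_report(s_null), mk_report(s_null),
                         n_boot = 300, seed = 5)
  expect_equal(same$auc_difference, 0)
  expect_gt(same$p_value, 0.5)
  extreme <- compare_models(mk_report(s_good), mk_report(s_null),
                            n_boot = 1000, seed = 6)
  expect_lt(extreme$p_value, 0.005)
  bad <- mk_report(s_null); bad$y <- rev(y)
  expect_error(compare_models(mk_report(s_good), bad), "same subjects")
})

test_that("honest CV calibration holds on a null imputed stack", {
  # selection inside folds keeps the null AUC near 0.5 even though
  # selection picks the apparently best features
  set.seed(43)
  n <- 60; p <- 20
  y <- rep(c("CA", "NC"), each = n / 2)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  stack <- structure(list(copies = list(X, X, X),
                          mask = matrix(FALSE, n, p), config = list()),
                     class = "imputed_stack")
  res_honest <- select_and_train(stack, y, k_grid = 5, folds = 5,
                                 seed = 9, mode = "honest")
  res_full <- select_and_train(stack, y, k_grid = 5, folds = 5,
                               seed = 9, mode = "full")
  # full-data selection is optimistically biased relative to honest CV
  expect_gt(mean(res_full$auc_by_copy), mean(res_honest$auc_by_copy))
})
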