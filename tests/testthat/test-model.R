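test_that("the classifier trainer is seed-reproducible and separates by design", {
  set.seed(111)
  x <- matrix(rnorm(150 * 4), 150, dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)  # perfectly determined by one feature
  fit <- fit_site_classifier(x, y, trainer = fast_trainer(), seed = 5)
  expect_equal(roc_auc(y, predict_prob(fit, x))$auc, 1)
  fit2 <- fit_site_classifier(x, y, trainer = fast_trainer(), seed = 5)
  expect_identical(predict_prob(fit, x), predict_prob(fit2, x))
  expect_error(fit_site_classifier(x, rep(1, 150), trainer = fast_trainer()),
               "single class")
})

test_that("stratified folds partition both classes evenly", {
  y <- rep(c(0, 1), c(53, 47))
  fold <- stratified_folds(y, k = 10, seed = 3)
  expect_true(all(fold %in% 1:10))
  expect_lte(diff(range(table(fold))), 1)
  for (cls in 0:1) {
    expect_lte(diff(range(table(fold[y == cls]))), 1)
  }
  expect_identical(fold, stratified_folds(y, k = 10, seed = 3))
})

test_that("k-fold CV predicts every row once and pools metrics consistently", {
  set.seed(112)
  n <- 60
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("f", 1:3)))
  y <- as.integer(runif(n) < 0.5)
  cv <- kfold_cv(x, y, k = n, seed = 2, trainer = fast_trainer())  # leave-one-out
  expect_length(cv$prob, n)
  expect_true(all(cv$prob >= 0 & cv$prob <= 1))
  expect_equal(sort(unique(cv$fold)), 1:n)
  # pooled out-of-fold AUC equals the metrics module applied to the pooled vector
  cv10 <- kfold_cv(x, y, k = 10, seed = 2, trainer = fast_trainer())
  expect_equal(cv10$auc, roc_auc(y, cv10$prob)$auc)
})

test_that("label-permuted data yields a chance-level CV AUC", {
  set.seed(113)
  n <- 500
  x <- matrix(rnorm(n * 10), n, dimnames = list(NULL, paste0("f", 1:10)))
  y <- sample(rep(0:1, each = n / 2))  # labels independent of features
  cv <- kfold_cv(x, y, k = 10, seed = 7, trainer = fast_trainer())
  expect_gt(cv$auc, 0.4)
  expect_lt(cv$auc, 0.6)
})

test_that("ensemble probability is the exact affine blend, monotone and bounded", {
  p_m <- c(0, 0.25, 0.5, 1)
  p_lnc <- c(1, 0.5, 0.25, 0)
  expect_identical(ensemble_probability(p_m, p_lnc, 0), p_lnc)
  expect_identical(ensemble_probability(p_m, p_lnc, 1), p_m)
  expect_equal(ensemble_probability(0.5, 1.0, 0.3), 0.85)
  expect_error(ensemble_probability(0.5, 0.5, 1.5), "alpha")
  expect_error(ensemble_probability(1.5, 0.5, 0.5), "probabilities")
  set.seed(114)
  for (r in 1:50) {
    a <- runif(1); pm <- runif(5); pl <- runif(5)
    p <- ensemble_probability(pm, pl, a)
    expect_true(all(p >= 0 & p <= 1))
    eps <- 0.01
    expect_true(all(ensemble_probability(pmin(1, pm + eps), pl, a) >= p))
    expect_true(all(ensemble_probability(pm, pmin(1, pl + eps), a) >= p))
  }
})

test_that("alpha grid search maximises validation AUC with tie to smaller alpha", {
  y <- rep(0:1, each = 20)
  p_perfect <- y * 0.8 + 0.1
  set.seed(115)
  p_rand <- runif(40)
  sel <- select_alpha(p_perfect, p_rand, y)
  # the perfectly separating member keeps AUC = 1 for every alpha >= 0.5
  # (its margin dominates the random member), so the tie rule settles on
  # the smallest such alpha
  expect_equal(sel$auc, 1)
  expect_equal(sel$alpha, 0.5)
  expect_equal(roc_auc(y, ensemble_probability(p_perfect, p_rand, sel$alpha))$auc, 1)
  sel2 <- select_alpha(p_perfect, p_perfect, y)
  expect_equal(sel2$alpha, 0)  # AUC constant in alpha -> smallest grid member
  expect_true(sel$alpha %in% seq(0, 1, by = 0.1))
  expect_equal(nrow(sel$curve), 11L)
  expect_error(select_alpha(p_perfect, p_rand, y, grid = numeric(0)),
               "empty")
  # selected blend never loses to either endpoint on its own selection set
  p_half <- ifelse(y == 1, runif(40, 0.3, 1), runif(40, 0, 0.7))
  sel3 <- select_alpha(p_half, p_rand, y)
  ends <- sel3$curve$auc[sel3$curve$alpha %in% c(0, 1)]
  expect_gte(sel3$auc, max(ends) - 0.001)
})

test_that("feature ranking puts planted signal first and permutes all names", {
  set.seed(116)
  n <- 120
  x <- matrix(rnorm(n * 8), n, dimnames = list(NULL, paste0("f", 1:8)))
  y <- as.integer(x[, 5] + rnorm(n, sd = 0.3) > 0)
  rk <- rank_features(x, y, k = 5, seed = 1, trainer = fast_trainer())
  expect_equal(rk$ranked[1], "f5")
  expect_setequal(rk$ranked, colnames(x))
  # all-noise: scores hover near 1/2
  y0 <- sample(rep(0:1, each = n / 2))
  rk0 <- rank_features(x, y0, k = 5, seed = 1, trainer = fast_trainer())
  expect_true(all(abs(rk0$score - 0.5) < 0.2))
  rki <- rank_features(x, y, method = "impurity", seed = 1)
  expect_equal(rki$ranked[1], "f5")
})

test_that("greedy forward selection recovers a compact informative prefix", {
  set.seed(117)
  n <- 200
  p_noise <- 12
  signal <- matrix(rnorm(n * 3), n)
  y <- as.integer(rowSums(signal) + rnorm(n, sd = 0.5) > 0)
  x <- cbind(signal, matrix(rnorm(n * p_noise), n))
  colnames(x) <- c(paste0("sig", 1:3), paste0("noise", seq_len(p_noise)))
  rk <- rank_features(x, y, k = 5, seed = 1, trainer = fast_trainer())
  fs <- greedy_forward_selection(rk$ranked, x, y, k = 5, seed = 1,
                                 trainer = fast_trainer())
  expect_length(fs$auc_curve, ncol(x))
  expect_lte(fs$n_selected, 10L)
  expect_true(all(paste0("sig", 1:3) %in% fs$selected))
  expect_equal(fs$auc_curve[fs$n_selected], max(fs$auc_curve))
  single <- greedy_forward_selection("sig1", x, y, k = 5, seed = 1,
                                     trainer = fast_trainer())
  expect_equal(single$n_selected, 1L)
})
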