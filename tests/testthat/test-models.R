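test_that("auc_score matches the brute-force pair-counting oracle", {
  oracle_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  set.seed(50)
  for (i in 1:5) {
    y <- rbinom(30, 1, 0.5)
    if (length(unique(y)) < 2) next
    s <- sample(seq(0, 1, by = 0.1), 30, replace = TRUE)  # with ties
    expect_equal(auc_score(s, y), oracle_auc(s, y))
  }
  expect_error(auc_score(1:5, rep(1, 5)), "both classes")
})

test_that("marker selection ranks by single-marker AUC, deterministically", {
  set.seed(51)
  y <- rep(c("malignant", "benign"), each = 30)
  x <- matrix(runif(60 * 15), nrow = 60,
              dimnames = list(NULL, sprintf("m%02d", 1:15)))
  x[, "m07"] <- ifelse(y == "malignant", 1, 0)  # perfect marker
  sel <- select_markers(x, y, k = 10)
  expect_length(sel, 10)
  expect_equal(sel[1], "m07")
  expect_error(select_markers(x, y, k = 99), "invalid argument")
})

test_that("marker selection is unstable on label-permuted null data", {
  set.seed(52)
  x <- matrix(runif(60 * 40), nrow = 60,
              dimnames = list(NULL, sprintf("m%02d", 1:40)))
  y <- rep(c("malignant", "benign"), each = 30)
  hits <- table(unlist(lapply(1:20, function(i)
    select_markers(x, sample(y), k = 10))))
  expect_lt(max(hits) / 20, 0.6)
})

test_that("cfMeth CV scores every sample once, out of fold", {
  set.seed(53)
  y <- rep(c("malignant", "benign"), each = 30)
  x <- matrix(rnorm(60 * 5), nrow = 60,
              dimnames = list(sprintf("s%02d", 1:60), paste0("m", 1:5)))
  fit <- train_cfmeth(x, y, n_folds = 5, seed = 1, num_trees = 50)
  expect_false(any(is.na(fit$oof_scores)))
  expect_length(fit$oof_scores, 60)
  # each fold's samples were excluded from that fold's training set
  expect_equal(sort(unique(fit$folds)), 1:5)

  # determinism
  fit2 <- train_cfmeth(x, y, n_folds = 5, seed = 1, num_trees = 50)
  expect_identical(fit$oof_scores, fit2$oof_scores)

  # separable features give near-perfect out-of-fold discrimination
  xs <- x
  xs[, 1] <- ifelse(y == "malignant", 1, 0) + rnorm(60, 0, 0.01)
  fs <- train_cfmeth(xs, y, n_folds = 5, seed = 2, num_trees = 100)
  expect_gte(auc_score(fs$oof_scores, y), 0.99)

  # a fold that cannot hold both classes is an error
  y_rare <- c(rep("malignant", 3), rep("benign", 57))
  expect_error(train_cfmeth(x, y_rare, n_folds = 10, seed = 1),
               "stratification")
})

test_that("combined model behaves with noise or informative imaging", {
  set.seed(54)
  n <- 120
  y <- rep(c("malignant", "benign"), each = n / 2)
  cf <- plogis(ifelse(y == "malignant", 1.2, -1.2) + rnorm(n))
  noise <- data.frame(mammography_score = sample(1:5, n, TRUE),
                      ultrasound_score = sample(1:5, n, TRUE))
  cmb_noise <- train_combined(cf, noise, y, seed = 3)
  expect_true(all(cmb_noise$scores >= 0 & cmb_noise$scores <= 1))
  expect_lte(abs(auc_score(cmb_noise$scores, y) - auc_score(cf, y)), 0.03)

  info <- data.frame(
    mammography_score = pmin(5, pmax(1, round(3 + ifelse(y == "malignant",
                                                         1, -1) +
                                                rnorm(n, 0, 0.8)))),
    ultrasound_score = pmin(5, pmax(1, round(3 + ifelse(y == "malignant",
                                                        1, -1) +
                                               rnorm(n, 0, 0.8)))))
  cmb <- train_combined(cf, info, y, seed = 3)
  best_single <- max(auc_score(cf, y),
                     auc_score(info$mammography_score, y),
                     auc_score(info$ultrasound_score, y))
  expect_gte(auc_score(cmb$scores, y), best_single - 0.01)

  const <- data.frame(mammography_score = rep(3, n),
                      ultrasound_score = sample(1:5, n, TRUE))
  expect_warning(train_combined(cf, const, y, seed = 3), "constant")
})

test_that("cutoff selection bounds the false-negative rate", {
  fnr_at <- function(scores, y, t) mean(scores[y == 1] < t)
  # perfectly separated scores: FNR 0 at the returned threshold
  y <- rep(c(1, 0), each = 10)
  s <- c(seq(0.8, 0.99, length.out = 10), seq(0.01, 0.2, length.out = 10))
  t <- select_cutoff(s, y, max_fnr = 0.02)
  expect_equal(fnr_at(s, y, t), 0)
  expect_gt(t, max(s[y == 0]))

  # max_fnr = 0 cannot be satisfied strictly: threshold <= min positive
  expect_warning(t0 <- select_cutoff(s, y, max_fnr = 0), "no threshold")
  expect_lte(t0, min(s[y == 1]))

  # random scores: definitional postcondition + maximality
  set.seed(55)
  for (i in 1:10) {
    y2 <- rbinom(80, 1, 0.5)
    if (sum(y2) < 2) next
    s2 <- runif(80)
    t2 <- select_cutoff(s2, y2, max_fnr = 0.1)
    expect_lt(fnr_at(s2, y2, t2), 0.1)
    higher <- sort(unique(s2[s2 > t2]))
    if (length(higher) > 0)
      expect_gte(fnr_at(s2, y2, higher[1]), 0.1)
  }
})

test_that("evaluation metrics, conservation and permutation invariance", {
  y <- rep(c("malignant", "benign"), each = 25)
  s <- ifelse(y == "malignant", 0.9, 0.1)
  ev <- evaluate_model(s, y, threshold = 0.5, n_boot = 100)
  expect_equal(ev$auc, 1.0)
  expect_equal(ev$sensitivity, 1.0)
  expect_equal(ev$specificity, 1.0)
  expect_equal(ev$accuracy, 1.0)
  expect_equal(sum(ev$confusion), 50)
  expect_true(ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2])

  set.seed(56)
  s2 <- runif(50)
  ev2 <- evaluate_model(s2, y, threshold = 0.5, n_boot = 200, seed = 9)
  perm <- sample(50)
  ev3 <- evaluate_model(s2[perm], y[perm], threshold = 0.5, n_boot = 200,
                        seed = 9)
  expect_equal(ev2$auc, ev3$auc)
  expect_equal(ev2$confusion, ev3$confusion)

  expect_error(evaluate_model(s2, rep("benign", 50), 0.5), "single-class")
})

test_that("label-independent scores give chance AUC at n = 200", {
  set.seed(570)
  y <- rep(c("malignant", "benign"), each = 100)
  inside <- vapply(1:20, function(i) {
    a <- auc_score(runif(200), y)
    a >= 0.40 && a <= 0.60
  }, logical(1))
  expect_gte(mean(inside), 0.95)
})

test_that("bootstrap CI contains the point AUC across runs", {
  set.seed(58)
  y <- rep(c("malignant", "benign"), each = 40)
  ok <- vapply(1:10, function(i) {
    s <- runif(80) + 0.3 * (y == "malignant")
    ev <- evaluate_model(s, y, threshold = 0.5, n_boot = 500, seed = i)
    ev$auc_ci[1] <= ev$auc && ev$auc <= ev$auc_ci[2]
  }, logical(1))
  expect_true(all(ok))
})

test_that("stage association trend statistic behaves", {
  set.seed(59)
  stages <- rep(c("I", "II", "III"), each = 10)
  scores <- as.integer(factor(stages)) + rnorm(30, 0, 0.3)
  a <- association_with_stage(scores, stages)
  expect_gt(a$tau, 0)
  expect_lt(a$p_value, 0.05)

  # antisymmetry
  b <- association_with_stage(-scores, stages)
  expect_equal(b$tau, -a$tau)

  # constant scores -> zero trend
  expect_equal(association_with_stage(rep(1, 30), stages)$tau, 0)

  expect_error(association_with_stage(scores[1:10], stages[1:10]),
               "invalid input")
})

test_that("validation scoring never touches validation labels", {
  pipe <- study_pipeline(1)
  res <- pipe$res
  study <- pipe$study
  prof_v <- build_marker_profiles(
    study$validation$samples, res$panel,
    impute_values = res$profiles$benign_medians, drop_frac = 1)
  s1 <- predict(res$cfmeth, prof_v$ratios)
  # shuffling validation labels cannot change the scores: they are not
  # an input to profiling or prediction
  expect_identical(s1, res$validation$cfmeth_scores)
  expect_identical(unname(s1), unname(predict(res$cfmeth, prof_v$ratios)))
})
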