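#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a score against binary labels,
#' identical to the trapezoid area under the empirical ROC with ties
#' handled as diagonal segments.
#'
#' @param scores numeric scores, higher = more malignant.
#' @param labels `"malignant"`/`"benign"`, factor, or 0/1.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_label(labels)
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0)
    stop("undefined AUC: need both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Select the top discriminating marker DMRs
#'
#' Ranks candidate hypo-DMR markers by the single-marker AUC of their
#' malignant ratio against the (discovery) labels; ties are broken by the
#' Wilcoxon rank-sum p-value, then by marker id, so the selection is
#' deterministic. Returns the top `k` marker ids.
#'
#' @param profiles a `marker_profiles` object or a samples x markers
#'   ratio matrix.
#' @param labels discovery labels.
#' @param k number of markers to keep (default 10).
#' @return character vector of `k` marker ids, best first.
#' @export
select_markers <- function(profiles, labels, k = 10L) {
  x <- if (inherits(profiles, "marker_profiles")) profiles$ratios else profiles
  if (k > ncol(x))
    stop("invalid argument: k exceeds the number of candidate markers",
         call. = FALSE)
  y <- as_binary_label(labels)
  auc <- apply(x, 2, auc_score, labels = y)
  pv <- apply(x, 2, function(col) {
    if (stats::sd(col) == 0) return(1)
    suppressWarnings(stats::wilcox.test(col[y == 1], col[y == 0])$p.value)
  })
  ord <- order(-auc, pv, colnames(x))
  colnames(x)[ord][seq_len(k)]
}

#' Train the cfMeth score with out-of-fold cross-validation
#'
#' Fits the random-forest classifier on the selected marker ratios with
#' stratified k-fold cross-validation: every discovery sample is scored
#' exactly once, by a forest that was not trained on it (the out-of-fold
#' cfMeth score), which is what all discovery-cohort performance figures
#' use. A final forest refit on all discovery data is kept for scoring
#' external (validation) samples.
#'
#' @param x samples x markers ratio matrix (selected markers only), or a
#'   `marker_profiles` object.
#' @param labels discovery labels.
#' @param n_folds folds (default 10).
#' @param seed integer seed for fold assignment and forest growth.
#' @param num_trees,mtry,min_node forwarded to [rf_fit()].
#' @return object of class `cfmeth_model`: list with `oof_scores`
#'   (out-of-fold cfMeth score per discovery sample), `model` (the refit
#'   forest), `folds`, `markers`.
#' @export
train_cfmeth <- function(x, labels, n_folds = 10L, seed = 1L,
                         num_trees = 500L, mtry = NULL, min_node = 5L) {
  if (inherits(x, "marker_profiles")) x <- x$ratios
  x <- as.matrix(x)
  y <- as_binary_label(labels)
  if (length(y) != nrow(x)) stop("labels do not match rows of x", call. = FALSE)
  set.seed(seed)
  fold <- stratified_folds(y, n_folds)
  oof <- rep(NA_real_, nrow(x))
  for (f in seq_len(n_folds)) {
    tr <- fold != f
    fit <- rf_fit(x[tr, , drop = FALSE], y[tr], num_trees = num_trees,
                  mtry = mtry, min_node = min_node)
    oof[!tr] <- predict(fit, x[!tr, , drop = FALSE])
  }
  final <- rf_fit(x, y, num_trees = num_trees, mtry = mtry,
                  min_node = min_node)
  structure(list(oof_scores = stats::setNames(oof, rownames(x)),
                 model = final, folds = fold, markers = colnames(x)),
            class = "cfmeth_model")
}

#' @rdname train_cfmeth
#' @param object a fitted `cfmeth_model`.
#' @param newdata marker-ratio matrix of new samples (validation cohort).
#' @param ... unused.
#' @export
predict.cfmeth_model <- function(object, newdata, ...) {
  if (inherits(newdata, "marker_profiles")) newdata <- newdata$ratios
  predict(object$model, newdata[, object$markers, drop = FALSE])
}

#' Train the combined cfMeth + imaging model
#'
#' Ridge (L2-penalized) logistic regression on the cfMeth score and the
#' two standardized ordinal imaging scores (mammography, ultrasound),
#' fitted on discovery data only. The penalty is chosen by internal
#' stratified cross-validation over a log-spaced grid. Constant features
#' are dropped with a warning.
#'
#' @param cfmeth_scores per-sample cfMeth scores (out-of-fold in
#'   discovery).
#' @param imaging data.frame/matrix with columns `mammography_score` and
#'   `ultrasound_score`.
#' @param labels discovery labels.
#' @param n_folds internal CV folds for the penalty (default 5).
#' @param seed integer seed.
#' @return object of class `combined_model`: list with `scores` (combined
#'   probability per discovery sample), `coefficients`, `lambda`, `fit`,
#'   `center`, `scale`, `features`.
#' @export
train_combined <- function(cfmeth_scores, imaging, labels, n_folds = 5L,
                           seed = 1L) {
  x <- cbind(cfmeth = cfmeth_scores,
             mammography = imaging[["mammography_score"]],
             ultrasound = imaging[["ultrasound_score"]])
  y <- as_binary_label(labels)
  keep <- apply(x, 2, function(col) stats::sd(col) > 0)
  if (!all(keep)) {
    warning("constant feature(s) dropped: ",
            paste(colnames(x)[!keep], collapse = ", "))
    x <- x[, keep, drop = FALSE]
  }
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  xs <- scale(x, center = ctr, scale = scl)
  set.seed(seed)
  lambda <- exp(seq(log(50), log(1e-4), length.out = 60))
  if (ncol(xs) >= 2) {
    foldid <- stratified_folds(y, n_folds)
    cv <- glmnet::cv.glmnet(xs, y, family = "binomial", alpha = 0,
                            lambda = lambda, foldid = foldid,
                            standardize = FALSE)
    fit <- cv$glmnet.fit
    lam <- cv$lambda.min
    scores <- as.vector(stats::predict(fit, newx = xs, s = lam,
                                       type = "response"))
    coefs <- stats::setNames(as.vector(stats::coef(fit, s = lam)),
                             rownames(stats::coef(fit, s = lam)))
  } else {
    # glmnet needs >= 2 columns; with a single surviving feature plain
    # logistic regression is the ridge limit we want
    df <- data.frame(y = y, x1 = xs[, 1])
    g <- stats::glm(y ~ x1, family = stats::binomial(), data = df)
    fit <- g
    lam <- 0
    scores <- as.vector(stats::fitted(g))
    coefs <- stats::coef(g)
  }
  structure(list(scores = scores, coefficients = coefs, lambda = lam,
                 fit = fit, center = ctr, scale = scl,
                 features = colnames(x)),
            class = "combined_model")
}

#' @rdname train_combined
#' @param object a fitted `combined_model`.
#' @param newdata list/data.frame providing `cfmeth`, `mammography` and
#'   `ultrasound` columns for new samples (or the subset that survived
#'   training).
#' @param ... unused.
#' @export
predict.combined_model <- function(object, newdata, ...) {
  x <- as.matrix(as.data.frame(newdata)[, object$features, drop = FALSE])
  xs <- scale(x, center = object$center, scale = object$scale)
  if (inherits(object$fit, "glm")) {
    as.vector(stats::plogis(stats::coef(object$fit)[1] +
                              xs[, 1] * stats::coef(object$fit)[2]))
  } else {
    as.vector(stats::predict(object$fit, newx = xs, s = object$lambda,
                             type = "response"))
  }
}

#' Select the operating cutoff at a bounded false-negative rate
#'
#' Returns the largest threshold such that the false-negative rate
#' (`FN / (FN + TP)`, with `score >= threshold` called malignant) is
#' strictly below `max_fnr` on the given (discovery) scores. If no
#' threshold can satisfy the bound (e.g. `max_fnr = 0`), the minimal score
#' minus a machine tolerance is returned with a warning, so that every
#' sample is called malignant.
#'
#' @param scores discovery scores.
#' @param labels discovery labels (>= 1 positive).
#' @param max_fnr FNR bound in [0, 1); default 0.02, i.e. "less than 2%".
#' @return the threshold.
#' @export
select_cutoff <- function(scores, labels, max_fnr = 0.02) {
  y <- as_binary_label(labels)
  if (sum(y) == 0) stop("need at least one positive sample", call. = FALSE)
  if (max_fnr < 0 || max_fnr >= 1)
    stop("max_fnr must be in [0, 1)", call. = FALSE)
  pos <- sort(scores[y == 1])
  P <- length(pos)
  lim <- max_fnr * P
  # largest number of positives we may leave below the threshold
  fn_max <- if (lim == floor(lim)) lim - 1 else floor(lim)
  if (fn_max < 0) {
    warning("no threshold satisfies FNR < ", max_fnr,
            "; returning minimal score minus tolerance")
    return(min(scores) - 1e-9)
  }
  pos[fn_max + 1]
}

#' Evaluate scores against labels
#'
#' Computes the empirical ROC (threshold sweep), the trapezoid AUC with a
#' stratified-bootstrap percentile 95% CI, the confusion matrix and
#' sensitivity/specificity/accuracy at the operating threshold
#' (`score >= threshold` called malignant), and per-stage detection
#' fractions when stages are supplied (DCIS, stage 0, reported
#' separately).
#'
#' @param scores numeric scores.
#' @param labels `"malignant"`/`"benign"`, factor, or 0/1.
#' @param threshold operating threshold (from [select_cutoff()]).
#' @param stages optional per-sample stage (`"0"`, `"I"`, `"II"`, `"III"`;
#'   NA for benign).
#' @param n_boot bootstrap replicates for the AUC CI.
#' @param seed integer seed for the bootstrap.
#' @return object of class `model_result`: list with `roc` (data.frame
#'   `fpr`, `tpr`), `auc`, `auc_ci`, `threshold`, `confusion` (named TP,
#'   FP, TN, FN), `sensitivity`, `specificity`, `accuracy`,
#'   `stage_detection`, `n`.
#' @export
evaluate_model <- function(scores, labels, threshold, stages = NULL,
                           n_boot = 2000L, seed = 1L) {
  y <- as_binary_label(labels)
  if (length(unique(y)) < 2)
    stop("undefined AUC: single-class labels", call. = FALSE)
  auc <- auc_score(scores, y)

  ths <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(ths, function(t) mean(scores[y == 1] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(scores[y == 0] >= t), numeric(1))
  roc <- data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))

  set.seed(seed)
  i_pos <- which(y == 1); i_neg <- which(y == 0)
  boot <- vapply(seq_len(n_boot), function(b) {
    ip <- sample(i_pos, length(i_pos), replace = TRUE)
    ine <- sample(i_neg, length(i_neg), replace = TRUE)
    auc_score(scores[c(ip, ine)], y[c(ip, ine)])
  }, numeric(1))
  ci <- stats::quantile(boot, c(0.025, 0.975), names = FALSE)

  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & y == 1); fp <- sum(pred == 1 & y == 0)
  tn <- sum(pred == 0 & y == 0); fn <- sum(pred == 0 & y == 1)

  stage_det <- NULL
  if (!is.null(stages)) {
    st <- stages[y == 1]
    pr <- pred[y == 1]
    stage_det <- vapply(split(pr, st), mean, numeric(1))
  }
  structure(list(roc = roc, auc = auc, auc_ci = ci, threshold = threshold,
                 confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
                 sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
                 accuracy = (tp + tn) / length(y),
                 stage_detection = stage_det, n = length(y)),
            class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> n = %d | AUC %.3f (95%% CI %.3f-%.3f)\n",
              x$n, x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  threshold %.4f: sensitivity %.1f%%, specificity %.1f%%, accuracy %.1f%%\n",
              x$threshold, 100 * x$sensitivity, 100 * x$specificity,
              100 * x$accuracy))
  if (!is.null(x$stage_detection))
    cat("  stage detection:",
        paste(sprintf("%s %.1f%%", names(x$stage_detection),
                      100 * x$stage_detection), collapse = ", "), "\n")
  invisible(x)
}

#' Association of cfMeth scores with tumor stage
#'
#' Ordinal trend of the score across stages (0/DCIS < I < II < III),
#' measured by Kendall's tau-b with its asymptotic test. Requires at
#' least two stages with three or more samples each.
#'
#' @param scores cfMeth scores of malignant samples.
#' @param stages matching stage labels.
#' @return list with `tau`, `p_value`, `n`.
#' @export
association_with_stage <- function(scores, stages) {
  keep <- !is.na(stages)
  scores <- scores[keep]
  st <- factor(stages[keep], levels = c("0", "I", "II", "III"))
  tab <- table(st)
  if (sum(tab >= 3) < 2)
    stop("invalid input: need >= 2 stages with >= 3 samples each",
         call. = FALSE)
  xs <- as.integer(st)
  if (stats::sd(scores) == 0)
    return(list(tau = 0, p_value = 1, n = length(scores)))
  ct <- suppressWarnings(stats::cor.test(scores, xs, method = "kendall"))
  list(tau = unname(ct$estimate), p_value = ct$p.value, n = length(scores))
}
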