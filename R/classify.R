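#' Select classifier features by t-test threshold
#'
#' The univariate feature-selection step shared by all classifiers: miRNAs
#' whose two-class (pooled-variance) t-test p-value on the *training data
#' only* is below `alpha`, with their t-statistics as weights. When detection
#' information accompanies the matrix, the t-tests are computed on detected
#' measurements only (see [two_class_test()]). When no miRNA passes, the
#' single smallest-p miRNA is used so a classifier can always be built.
#'
#' @param x A `normalized_matrix`/`normalization_result` or log2 matrix.
#' @param labels Class labels; taken from `x` when present.
#' @param alpha Significance threshold.
#' @return List with `features` (identifiers) and `weights` (their
#'   t-statistics, tumor minus normal).
#' @export
select_features <- function(x, labels = NULL, alpha = 0.001) {
  vl <- values_and_labels(x, labels)
  y <- align_labels(vl$labels, colnames(vl$values))
  if (min(table(y)) < 2) {
    stop("each class needs at least 2 samples for feature selection",
         call. = FALSE)
  }
  st <- row_t_stats(masked_values(vl), y == "tumor")
  pick_features(vl$values, st, alpha)
}

# Threshold precomputed row t statistics, with single-best-feature fallback.
pick_features <- function(v, st, alpha) {
  sel <- which(!is.na(st$p) & st$p < alpha)
  if (length(sel) == 0) {
    if (all(is.na(st$p))) {
      stop("no testable miRNAs in the training data", call. = FALSE)
    }
    sel <- which.min(st$p)
  }
  list(features = rownames(v)[sel], weights = st$t[sel])
}

ALGORITHMS <- c("ccp", "bccp", "dlda", "nc", "knn1", "knn3", "svm")

#' Train a two-class miRNA classifier
#'
#' Implements the seven-member class-prediction family. All algorithms share
#' the t-test feature-selection step ([select_features()]) at threshold
#' `alpha`:
#' \describe{
#'   \item{ccp}{Compound covariate predictor. Per-sample covariate
#'     `c_s = sum_i t_i x_is` over selected features with t-statistic weights;
#'     a sample is called tumor when `c_s` falls on the tumor side of the
#'     midpoint of the two class means of `c`.}
#'   \item{bccp}{Bayesian compound covariate predictor: one-dimensional
#'     Gaussians fitted to `c` per class, class posterior by Bayes' rule with
#'     the given priors (equal by default).}
#'   \item{dlda}{Diagonal linear discriminant analysis: per-feature pooled
#'     within-class variances; a sample goes to the class minimizing
#'     `sum_i (x_i - mu_ik)^2 / sigma_i^2`.}
#'   \item{nc}{Nearest (Euclidean) class centroid.}
#'   \item{knn1, knn3}{k-nearest neighbours, Euclidean distance, majority
#'     vote.}
#'   \item{svm}{Linear support vector machine, cost fixed at 1 (via
#'     \pkg{e1071}).}
#' }
#' Exact ties in discriminant scores or distances are broken toward class
#' `"normal"`.
#'
#' @param x Training data: `normalized_matrix`/`normalization_result` or log2
#'   matrix (features x samples).
#' @param labels Class labels; taken from `x` when present.
#' @param algorithm One of `"ccp"`, `"bccp"`, `"dlda"`, `"nc"`, `"knn1"`,
#'   `"knn3"`, `"svm"`.
#' @param alpha Feature-selection significance threshold.
#' @param priors Class prior probabilities for `bccp`, named `normal`/`tumor`,
#'   summing to 1.
#' @return An `oscc_classifier` with fields `algorithm`, `alpha`, `features`,
#'   `weights` (CCP/BCCP only), `class_stats`, and `priors` (BCCP only).
#' @export
train_classifier <- function(x, labels = NULL,
                             algorithm = c("ccp", "bccp", "dlda", "nc",
                                           "knn1", "knn3", "svm"),
                             alpha = 0.001,
                             priors = c(normal = 0.5, tumor = 0.5)) {
  algorithm <- match.arg(algorithm)
  vl <- values_and_labels(x, labels)
  y <- align_labels(vl$labels, colnames(vl$values))
  vm <- masked_values(vl)
  st <- row_t_stats(vm, y == "tumor")
  fs <- pick_features(vm, st, alpha)
  fit_model(vm, y, algorithm, fs$features, fs$weights, alpha, priors)
}

# Fit from precomputed features/weights (used by train_classifier and by
# loocv, where the t statistics are computed once per fold). Undetected /
# missing entries are imputed with the training feature mean (class-agnostic),
# which keeps dropout zeros from acting as extreme outliers in the
# discriminants; the imputation means are frozen into the model.
fit_model <- function(v, y, algorithm, features, weights, alpha,
                      priors = c(normal = 0.5, tumor = 0.5)) {
  if (abs(sum(priors) - 1) > 1e-8) stop("priors must sum to 1", call. = FALSE)
  xf <- v[features, , drop = FALSE]
  imp <- rowMeans(xf, na.rm = TRUE)
  imp[is.nan(imp)] <- 0
  if (anyNA(xf)) {
    idx <- which(is.na(xf), arr.ind = TRUE)
    xf[idx] <- imp[idx[, 1]]
  }
  is_t <- y == "tumor"
  model <- list(algorithm = algorithm, alpha = alpha, features = features,
                impute = stats::setNames(imp, features))
  if (algorithm %in% c("ccp", "bccp")) {
    model$weights <- stats::setNames(weights, features)
    cc <- colSums(model$weights * xf)
    mt <- mean(cc[is_t]); mn <- mean(cc[!is_t])
    if (algorithm == "ccp") {
      model$class_stats <- list(mean_tumor = mt, mean_normal = mn,
                                threshold = (mt + mn) / 2,
                                orient = if (mt >= mn) 1 else -1)
    } else {
      pooled <- sqrt((sum((cc[is_t] - mt)^2) + sum((cc[!is_t] - mn)^2)) /
                       max(1, length(cc) - 2))
      sdt <- if (sum(is_t) >= 2) stats::sd(cc[is_t]) else pooled
      sdn <- if (sum(!is_t) >= 2) stats::sd(cc[!is_t]) else pooled
      eps <- max(1e-8, 1e-6 * abs(mt - mn))
      model$class_stats <- list(mean_tumor = mt, mean_normal = mn,
                                sd_tumor = max(sdt, eps),
                                sd_normal = max(sdn, eps))
      model$priors <- priors
    }
  } else if (algorithm %in% c("dlda", "nc")) {
    mu_t <- rowMeans(xf[, is_t, drop = FALSE])
    mu_n <- rowMeans(xf[, !is_t, drop = FALSE])
    if (algorithm == "dlda") {
      ss <- rowSums((xf[, is_t, drop = FALSE] - mu_t)^2) +
        rowSums((xf[, !is_t, drop = FALSE] - mu_n)^2)
      s2 <- ss / max(1, ncol(xf) - 2)
      if (any(s2 == 0)) {
        s2[s2 == 0] <- if (any(s2 > 0)) min(s2[s2 > 0]) else 1e-8
      }
    } else {
      s2 <- rep(1, length(features))
    }
    model$class_stats <- list(mu_tumor = mu_t, mu_normal = mu_n, var = s2)
  } else if (algorithm %in% c("knn1", "knn3")) {
    model$k <- if (algorithm == "knn1") 1L else 3L
    model$class_stats <- list(train_x = xf, train_y = y)
  } else if (algorithm == "svm") {
    fit <- e1071::svm(t(xf), y, kernel = "linear", cost = 1, scale = FALSE)
    model$class_stats <- list(fit = fit)
  } else {
    stop("unknown algorithm '", algorithm, "'", call. = FALSE)
  }
  structure(model, class = "oscc_classifier")
}

#' @export
print.oscc_classifier <- function(x, ...) {
  cat(sprintf("oscc_classifier: %s, alpha = %g, %d feature(s)\n",
              toupper(x$algorithm), x$alpha, length(x$features)))
  invisible(x)
}

#' Predict classes for new samples
#'
#' Applies a frozen classifier: no re-selection or re-fitting. The continuous
#' score is oriented so that larger means more tumor-like: the BCCP tumor
#' posterior, the signed discriminant margin for CCP/DLDA/NC/SVM, and the
#' tumor vote fraction for kNN. Score ties (exactly on the boundary) are
#' called `"normal"`.
#'
#' @param object An `oscc_classifier`.
#' @param newdata A `normalized_matrix`/`normalization_result` or log2 matrix
#'   containing all model features (missing features are an error).
#' @param ... Unused.
#' @return Data frame with columns `sample`, `score`, `class`.
#' @export
predict.oscc_classifier <- function(object, newdata, ...) {
  vl <- values_and_labels(newdata)
  v <- masked_values(vl)
  absent <- setdiff(object$features, rownames(v))
  if (length(absent) > 0) {
    stop("model feature(s) missing from the data: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  xf <- v[object$features, , drop = FALSE]
  if (anyNA(xf)) {
    idx <- which(is.na(xf), arr.ind = TRUE)
    xf[idx] <- object$impute[idx[, 1]]
  }
  cs <- object$class_stats
  if (object$algorithm == "ccp") {
    cc <- colSums(object$weights * xf)
    score <- cs$orient * (cc - cs$threshold)
  } else if (object$algorithm == "bccp") {
    cc <- colSums(object$weights * xf)
    lt <- stats::dnorm(cc, cs$mean_tumor, cs$sd_tumor) * object$priors["tumor"]
    ln <- stats::dnorm(cc, cs$mean_normal, cs$sd_normal) *
      object$priors["normal"]
    post <- ifelse(lt + ln > 0, lt / (lt + ln), 0.5)
    score <- post - 0.5
  } else if (object$algorithm %in% c("dlda", "nc")) {
    dt <- colSums((xf - cs$mu_tumor)^2 / cs$var)
    dn <- colSums((xf - cs$mu_normal)^2 / cs$var)
    score <- (dn - dt) / 2
  } else if (object$algorithm %in% c("knn1", "knn3")) {
    tr <- cs$train_x
    k_eff <- min(object$k, ncol(tr))
    score <- apply(xf, 2, function(s) {
      d <- sqrt(colSums((tr - s)^2))
      nb <- order(d)[seq_len(k_eff)]  # distance ties: training order
      mean(cs$train_y[nb] == "tumor")
    }) - 0.5
  } else if (object$algorithm == "svm") {
    pr <- stats::predict(cs$fit, t(xf), decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # e1071 orients the decision value toward the first level of its column
    # label "A/B": positive favors A
    lab <- strsplit(colnames(dv), "/")[[1]]
    score <- if (lab[1] == "tumor") dv[, 1] else -dv[, 1]
  }
  data.frame(sample = colnames(xf),
             score = as.numeric(score),
             class = ifelse(score > 0, "tumor", "normal"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Empirical ROC curve and AUC
#'
#' Sweeps the score threshold from high to low (tumor = positive class),
#' grouping tied scores, and computes the area by the trapezoidal rule. The
#' AUC equals the normalized Mann-Whitney concordant-pair count (ties counted
#' one half).
#'
#' @param scores Finite numeric scores, larger = more tumor-like.
#' @param labels Class labels (`tumor`/`normal`), both classes present.
#' @return List with `points` (data frame `fpr`, `tpr`, starting at (0,0) and
#'   ending at (1,1)) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  y <- align_labels(labels, names(scores) %||% seq_along(scores))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  n_pos <- sum(y == "tumor")
  n_neg <- sum(y == "normal")
  if (n_pos == 0 || n_neg == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  pos <- (y == "tumor")[ord]
  grp_end <- which(!duplicated(s, fromLast = TRUE))  # last index of each tie group
  tpr <- c(0, cumsum(pos)[grp_end] / n_pos)
  fpr <- c(0, cumsum(!pos)[grp_end] / n_neg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Summarize predictions into a cv_result-style object.
summarize_predictions <- function(pred, truth) {
  correct <- pred$class == as.character(truth)
  roc <- roc_curve(stats::setNames(pred$score, pred$sample), truth)
  structure(list(
    predictions = cbind(pred, truth = as.character(truth),
                        correct = correct),
    accuracy = mean(correct),
    sensitivity = mean(pred$class[truth == "tumor"] == "tumor"),
    specificity = mean(pred$class[truth == "normal"] == "normal"),
    roc = roc$points,
    auc = roc$auc
  ), class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "cv_result: accuracy %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
    x$accuracy, x$sensitivity, x$specificity, x$auc))
  invisible(x)
}

# Choose alpha from the grid by inner leave-one-out accuracy on the training
# set only. Inner folds whose remaining samples cannot support a t-test
# (a class absent, or fewer than 3 samples) are skipped; ties and the
# no-usable-fold case resolve to the smallest alpha.
choose_alpha <- function(vm, y, algorithm, alpha_grid, priors) {
  n <- ncol(vm)
  grid <- sort(alpha_grid)
  correct <- matrix(NA, n, length(grid))
  for (k in seq_len(n)) {
    yk <- y[-k]
    if (length(unique(yk)) < 2 || length(yk) < 3) next
    vk <- vm[, -k, drop = FALSE]
    st <- row_t_stats(vk, yk == "tumor")
    if (all(is.na(st$p))) next
    for (a in seq_along(grid)) {
      fs <- pick_features(vk, st, grid[a])
      m <- fit_model(vk, yk, algorithm, fs$features, fs$weights, grid[a],
                     priors)
      pr <- predict(m, vm[, k, drop = FALSE])
      correct[k, a] <- pr$class == as.character(y[k])
    }
  }
  acc <- colMeans(correct, na.rm = TRUE)
  acc[is.nan(acc)] <- -1
  grid[which.max(acc)]  # which.max takes the first (smallest alpha) on ties
}

#' Leave-one-out cross-validation with embedded feature selection
#'
#' For each held-out sample, feature selection *and* the choice of the
#' significance threshold alpha are redone on the remaining samples only:
#' alpha is picked from `alpha_grid` by an inner leave-one-out accuracy on
#' those samples (ties toward the smaller alpha), the classifier is trained at
#' that alpha, and the held-out sample is predicted. The held-out sample never
#' influences its own fold's feature selection, threshold, or weights, so the
#' reported accuracy is unbiased by the selection step.
#'
#' @inheritParams train_classifier
#' @param alpha_grid Candidate significance thresholds.
#' @return A `cv_result`: per-sample predictions (with the fold's chosen
#'   `alpha` and selected feature count), `accuracy`, `sensitivity`,
#'   `specificity`, `roc`, `auc`, and `folds` (per-fold selected features).
#' @export
loocv <- function(x, labels = NULL,
                  algorithm = c("ccp", "bccp", "dlda", "nc", "knn1", "knn3",
                                "svm"),
                  alpha_grid = c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4),
                  priors = c(normal = 0.5, tumor = 0.5)) {
  algorithm <- match.arg(algorithm)
  vl <- values_and_labels(x, labels)
  v <- vl$values
  vm <- masked_values(vl)
  y <- align_labels(vl$labels, colnames(v))
  n <- ncol(v)
  if (n < 4) stop("leave-one-out cross-validation needs n >= 4", call. = FALSE)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  preds <- vector("list", n)
  folds <- vector("list", n)
  for (j in seq_len(n)) {
    vj <- vm[, -j, drop = FALSE]
    yj <- y[-j]
    alpha_j <- choose_alpha(vj, yj, algorithm, alpha_grid, priors)
    st <- row_t_stats(vj, yj == "tumor")
    fs <- pick_features(vj, st, alpha_j)
    m <- fit_model(vj, yj, algorithm, fs$features, fs$weights, alpha_j, priors)
    pr <- predict(m, vm[, j, drop = FALSE])
    pr$alpha <- alpha_j
    pr$n_features <- length(fs$features)
    preds[[j]] <- pr
    folds[[j]] <- list(held_out = colnames(v)[j], alpha = alpha_j,
                       features = fs$features)
  }
  pred <- do.call(rbind, preds)
  out <- summarize_predictions(pred, y)
  out$algorithm <- algorithm
  out$folds <- folds
  out
}

#' Validate a frozen classifier on an independent cohort
#'
#' Applies a trained model to every sample of an external matrix without any
#' re-selection or re-fitting, and reports accuracy, sensitivity, specificity,
#' ROC and AUC against the supplied labels.
#'
#' @param model An `oscc_classifier`.
#' @param x External data containing all model features.
#' @param labels Class labels for the external samples.
#' @return A `cv_result`.
#' @export
external_validate <- function(model, x, labels = NULL) {
  vl <- values_and_labels(x, labels)
  y <- align_labels(vl$labels, colnames(vl$values))
  pred <- predict(model, x)
  out <- summarize_predictions(pred, y)
  out$algorithm <- model$algorithm
  out
}
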