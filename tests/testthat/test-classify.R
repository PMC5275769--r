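test_that("feature selection thresholds p-values and falls back to the best", {
  nm <- toy_norm_matrix(n_mirna = 30, n_signal = 5, shift = 4, seed = 11)
  all_feats <- select_features(nm, alpha = 1)
  expect_setequal(all_feats$features, mirna_ids(nm))
  strong <- select_features(nm, alpha = 0.001)
  expect_true(all(sprintf("mir-%03d", 1:5) %in% strong$features))
  tiny <- select_features(nm, alpha = 1e-300)
  expect_length(tiny$features, 1)
  nm1 <- nm; nm1$labels[] <- "tumor"
  expect_error(select_features(nm1), "2 samples")
})

test_that("single-feature CCP reduces to the class-mean midpoint rule", {
  v <- matrix(c(10, 11, 12, 2, 3, 4), 1,
              dimnames = list("m1", paste0("s", 1:6)))
  labs <- setNames(rep(c("tumor", "normal"), each = 3), colnames(v))
  m <- train_classifier(v, labs, "ccp", alpha = 0.5)
  pr <- predict(m, matrix(c(6.9, 7.1), 1, dimnames = list("m1", c("a", "b"))))
  expect_equal(pr$class, c("normal", "tumor"))  # midpoint is 7
})

test_that("CCP compound covariate matches direct evaluation with t.test weights", {
  for (seed in 1:5) {
    set.seed(seed)
    n_feat <- sample(2:5, 1)
    v <- matrix(rnorm(n_feat * 8, 8), n_feat,
                dimnames = list(paste0("m", seq_len(n_feat)), paste0("s", 1:8)))
    labs <- setNames(rep(c("tumor", "normal"), each = 4), colnames(v))
    v[1, labs == "tumor"] <- v[1, labs == "tumor"] + 2
    m <- train_classifier(v, labs, "ccp", alpha = 1)
    # independent weights and covariate: t.test per feature, direct sum
    w <- apply(v, 1, function(x)
      unname(t.test(x[labs == "tumor"], x[labs == "normal"],
                    var.equal = TRUE)$statistic))
    cc <- colSums(w * v)
    thr <- (mean(cc[labs == "tumor"]) + mean(cc[labs == "normal"])) / 2
    orient <- sign(mean(cc[labs == "tumor"]) - mean(cc[labs == "normal"]))
    pr <- predict(m, v)
    expect_equal(pr$score, unname(orient * (cc - thr)))
    expect_equal(pr$class,
                 unname(ifelse(orient * (cc - thr) > 0, "tumor", "normal")))
  }
})

test_that("DLDA with equal per-feature variances predicts like nearest centroid", {
  # identical within-class deviations across features force equal pooled
  # variances, so the two discriminants coincide up to the variance scale
  set.seed(13)
  dev <- rnorm(8, 0, 0.7)
  v <- rbind(m1 = c(10, 10, 10, 10, 4, 4, 4, 4) + dev,
             m2 = c(3, 3, 3, 3, 9, 9, 9, 9) + dev,
             m3 = c(5, 5, 5, 5, 5.5, 5.5, 5.5, 5.5) + dev)
  colnames(v) <- paste0("s", 1:8)
  labs <- setNames(rep(c("tumor", "normal"), each = 4), colnames(v))
  newx <- matrix(rnorm(3 * 10, 6, 3), 3,
                 dimnames = list(rownames(v), paste0("x", 1:10)))
  p_dlda <- predict(train_classifier(v, labs, "dlda", alpha = 1), newx)
  p_nc <- predict(train_classifier(v, labs, "nc", alpha = 1), newx)
  expect_equal(p_dlda$class, p_nc$class)
})

test_that("BCCP is symmetric at the covariate midpoint with equal priors", {
  v <- matrix(c(10, 12, 14, 2, 4, 6), 1,
              dimnames = list("m1", paste0("s", 1:6)))
  labs <- setNames(rep(c("tumor", "normal"), each = 3), colnames(v))
  m <- train_classifier(v, labs, "bccp", alpha = 1)
  # equidistant from both class means (8 on the feature scale), equal sds
  pr <- predict(m, matrix(8, 1, dimnames = list("m1", "mid")))
  expect_equal(pr$score + 0.5, 0.5)   # posterior exactly one half
  expect_equal(pr$class, "normal")    # boundary ties resolve to normal
})

test_that("all seven algorithms separate an easy fixture and validate externally", {
  nm <- toy_norm_matrix(n_tumor = 6, n_normal = 6, n_mirna = 50, n_signal = 10,
                        shift = 5, seed = 14)
  ext <- toy_norm_matrix(n_tumor = 8, n_normal = 8, n_mirna = 50, n_signal = 10,
                         shift = 5, seed = 15)
  for (alg in c("ccp", "bccp", "dlda", "nc", "knn1", "knn3", "svm")) {
    model <- train_classifier(nm, algorithm = alg, alpha = 0.01)
    expect_gt(length(model$features), 0)
    res <- external_validate(model, ext)
    expect_equal(res$accuracy, 1.0, info = alg)
    # label-flip symmetry
    flipped <- ext
    flipped$labels[] <- ifelse(ext$labels == "tumor", "normal", "tumor")
    res_f <- external_validate(model, flipped)
    expect_equal(res_f$accuracy, 1 - res$accuracy, info = alg)
  }
  model <- train_classifier(nm, algorithm = "ccp", alpha = 0.01)
  bad <- ext
  bad$values <- bad$values[-match(model$features[1], rownames(bad$values)), ]
  expect_error(external_validate(model, bad), model$features[1])
})

test_that("resubstitution accuracy dominates LOOCV accuracy on separated data", {
  nm <- toy_norm_matrix(n_tumor = 6, n_normal = 6, n_mirna = 60, n_signal = 6,
                        shift = 1.2, seed = 16)
  cv <- loocv(nm, algorithm = "dlda")
  model <- train_classifier(nm, algorithm = "dlda", alpha = 0.01)
  resub <- external_validate(model, nm)
  expect_gte(resub$accuracy, cv$accuracy)
})

test_that("ROC and AUC match the concordant-pair oracle and edge cases", {
  labs <- rep(c("tumor", "normal"), each = 6)
  perfect <- c(7:12, 1:6)
  expect_equal(roc_curve(perfect, labs)$auc, 1.0)
  expect_equal(roc_curve(rep(1, 12), labs)$auc, 0.5)
  for (seed in 1:10) {
    set.seed(seed)
    sc <- sample(1:8, 12, replace = TRUE)  # replicates force ties
    r <- roc_curve(sc, labs)
    expect_equal(r$auc, bf_auc(sc, labs))
    expect_equal(r$points$fpr[1], 0)
    expect_equal(r$points$tpr[1], 0)
    expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
    expect_true(all(diff(r$points$fpr) >= 0) && all(diff(r$points$tpr) >= 0))
  }
  expect_error(roc_curve(1:3, rep("tumor", 3)), "both classes")
})

test_that("LOOCV runs at the n = 4 boundary and yields one prediction per sample", {
  nm <- toy_norm_matrix(n_tumor = 2, n_normal = 2, n_mirna = 15, n_signal = 3,
                        shift = 6, seed = 17)
  cv <- loocv(nm, algorithm = "ccp")
  expect_equal(nrow(cv$predictions), 4)
  expect_true(all(cv$predictions$alpha %in%
                    c(0.05, 0.01, 0.005, 0.001, 5e-4, 1e-4)))
  expect_error(loocv(nm$values[, 1:3],
                     setNames(c("tumor", "tumor", "normal"),
                              colnames(nm$values)[1:3]), "ccp"), "n >= 4")
})

test_that("mean LOOCV accuracy degrades monotonically as the effect shrinks", {
  folds <- c(8, 3, 1.5, 1)
  acc <- sapply(folds, function(f) {
    mean(sapply(1:6, function(s) {
      cfg <- sim_config(n_tumor = 8, n_normal = 8, n_mirna = 150, n_de = 10,
                        fold_changes = f, zero_inflation = 0.05,
                        seed = 600 + s)
      nr <- preprocess_counts(simulate_counts(cfg), panel_size = 20)
      loocv(nr, algorithm = "ccp")$accuracy
    }))
  })
  expect_true(all(diff(acc) <= 0.02 + 1e-9))  # non-increasing up to noise
  expect_gt(acc[1], acc[length(acc)])
})
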