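test_that("cross-validation is stratified, exhaustive, and seeded", {
  tab <- toy_table(n_classes = 4, per_class = 12, n_features = 6)
  cv <- cross_validate(tab, "icp", rf_spec(), n_folds = 4, seed = 6)
  expect_equal(nrow(cv$pvalues), nrow(tab))
  expect_false(anyNA(cv$pvalues))            # every sample tested once
  # per-class fold sizes differ by <= 1 (here exactly 3 per class)
  for (f in 1:4) {
    expect_equal(unname(table(tab$label[cv$fold == f])), rep(3L, 4),
                 ignore_attr = TRUE)
  }
  cv2 <- cross_validate(tab, "icp", rf_spec(), n_folds = 4, seed = 6)
  expect_identical(cv2$fold, cv$fold)
  expect_equal(cv2$pvalues, cv$pvalues)

  expect_error(cross_validate(tab, "icp", rf_spec(), n_folds = 20),
               "fewer samples than folds")

  acp_cv <- cross_validate(toy_table(2, 10, 4), "acp", rf_spec(ntree = 30),
                           n_folds = 2, seed = 1, K = 2)
  expect_false(anyNA(acp_cv$pvalues))
})

test_that("forced accuracy counts argmax hits overall and per fold", {
  pv <- rbind(c(0.9, 0.1, 0.1), c(0.2, 0.8, 0.1),
              c(0.1, 0.7, 0.3), c(0.6, 0.2, 0.9))
  colnames(pv) <- c("C1", "C2", "C3")
  res <- fake_cv_result(pv, c("C1", "C2", "C2", "C1"),
                        fold = c(1L, 1L, 2L, 2L))
  acc <- accuracy_forced(res)
  expect_equal(acc$accuracy, 0.75)
  expect_equal(unname(acc$per_fold), c(1, 0.5))
  expect_equal(acc$fold_mean, 0.75)

  all_right <- fake_cv_result(pv, c("C1", "C2", "C2", "C3"))
  expect_equal(accuracy_forced(all_right)$accuracy, 1)
  all_wrong <- fake_cv_result(pv, c("C2", "C3", "C1", "C2"))
  expect_equal(accuracy_forced(all_wrong)$accuracy, 0)
})

test_that("calibration and efficiency curves follow their definitions", {
  pv <- rbind(c(0.50, 0.04), c(0.20, 0.70), c(0.08, 0.90))
  colnames(pv) <- c("C1", "C2")
  res <- fake_cv_result(pv, c("C1", "C2", "C2"))
  cal <- calibration_curve(res, c(0.05, 0.3, 0.95))
  # p_true = (0.50, 0.70, 0.90)
  expect_equal(cal$error_rate, c(0, 0, 1))
  eff <- efficiency_curve(res, c(0.01, 0.3, 0.95))
  expect_equal(eff$mean_set_size, c(2, 1, 0))

  # below every p-value floor, the region holds all classes
  expect_equal(efficiency_curve(res, 0.03)$mean_set_size, 2)
  # monotonicity along a fine grid
  grid <- seq(0.01, 0.99, 0.01)
  expect_true(all(diff(efficiency_curve(res, grid)$mean_set_size) <= 0))
  expect_true(all(diff(calibration_curve(res, grid)$error_rate) >= 0))
  expect_error(calibration_curve(res, c(0, 0.5)), "grid")

  # singleton-region regime: error rate complements forced accuracy
  pv2 <- rbind(c(0.9, 0.01), c(0.02, 0.85), c(0.88, 0.03))
  colnames(pv2) <- c("C1", "C2")
  res2 <- fake_cv_result(pv2, c("C1", "C2", "C2"))
  eps <- 0.5   # every region is a singleton here
  expect_equal(efficiency_curve(res2, eps)$mean_set_size, 1)
  expect_equal(calibration_curve(res2, eps)$error_rate,
               1 - accuracy_forced(res2)$accuracy)
})

test_that("indicator summaries report mean and SD of confidence/credibility", {
  pv <- rbind(c(1, 0.2, 0.1), c(0.9, 0.4, 0.2))
  colnames(pv) <- c("C1", "C2", "C3")
  res <- fake_cv_result(pv, c("C1", "C1"))
  ind <- summarize_indicators(res)
  expect_equal(ind$mean[ind$indicator == "credibility"], mean(c(1, 0.9)))
  expect_equal(ind$mean[ind$indicator == "confidence"], mean(1 - c(0.2, 0.4)))
  expect_equal(ind$sd[ind$indicator == "credibility"], sd(c(1, 0.9)))

  single <- fake_cv_result(pv[1, , drop = FALSE], "C1")
  expect_message(ind1 <- summarize_indicators(single), "SD = 0")
  expect_equal(ind1$sd, c(0, 0))
})

test_that("PCA projection reports scores and explained variance", {
  # two perfectly correlated features: PC1 explains everything
  x <- data.frame(F1 = c(1, 2, 3, 4), F2 = c(2, 4, 6, 8))
  p <- pca_projection(x, n_components = 2)
  expect_equal(p$variance_fraction[1], 1)
  expect_true(sum(p$variance_fraction) <= 1 + 1e-12)

  # rank-1 data is reconstructed exactly from one component
  tab <- toy_table(2, 8, 5)
  pc <- pca_projection(tab, n_components = 5)
  expect_lte(sum(pc$variance_fraction), 1 + 1e-12)
  expect_identical(names(pc$scores), c(paste0("PC", 1:5), "label"))
  x1 <- as.matrix(x)
  recon <- tcrossprod(as.matrix(p$scores[, 1, drop = FALSE]),
                      prcomp(x1)$rotation[, 1, drop = FALSE]) +
    matrix(colMeans(x1), 4, 2, byrow = TRUE)
  expect_equal(unname(recon), unname(x1), tolerance = 1e-12)

  expect_error(pca_projection(x, n_components = 3), "n_components")
  expect_error(pca_projection(x[0, ]), "empty")
})

test_that("ACP outperforms ICP on average at moderate separation", {
  # comparative direction over several generator seeds (sign only)
  icp_acc <- acp_acc <- numeric(4)
  for (s in 1:4) {
    tab <- simulate_feature_table(4, 20, 20, separation = 0.45,
                                  seed = 100 + s)
    test_idx <- (seq_len(nrow(tab)) - 1L) %% 20 >= 15
    tr <- tab[!test_idx, ]
    te <- tab[test_idx, ]
    truth <- as.character(te$label)
    sp <- rf_spec(ntree = 80)
    pi <- icp_pvalues(icp_fit(tr, sp, seed = s), te)
    pa <- acp_pvalues(acp_fit(tr, sp, K = 5, seed = s), te)
    icp_acc[s] <- mean(colnames(pi)[max.col(pi, "first")] == truth)
    acp_acc[s] <- mean(colnames(pa)[max.col(pa, "first")] == truth)
  }
  expect_gte(mean(acp_acc), mean(icp_acc))
})
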