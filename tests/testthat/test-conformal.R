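test_that("underlying scorers return proper probability vectors", {
  tab <- toy_table()
  for (spec in list(underlying_spec("svm_rbf"), rf_spec())) {
    scorer <- fit_underlying(tab, spec)
    prob <- predict_scores(scorer, tab)
    expect_equal(dim(prob), c(nrow(tab), 3L))
    expect_true(all(prob >= 0))
    expect_equal(unname(rowSums(prob)), rep(1, nrow(tab)), tolerance = 1e-9)
    # well-separated classes: mass concentrates on the true label
    p_true <- prob[cbind(seq_len(nrow(tab)),
                         match(tab$label, scorer$label_set))]
    expect_gt(mean(p_true), 0.6)
    # determinism under the spec seed
    expect_equal(predict_scores(fit_underlying(tab, spec), tab), prob)
  }
  expect_error(fit_underlying(tab[tab$label == "C1", ], rf_spec()),
               "2 classes")
  rf <- fit_underlying(tab, underlying_spec("random_forest"))
  expect_equal(rf$fit$ntree, 500)
})

test_that("nonconformity is one minus the class probability", {
  tab <- toy_table()
  scorer <- fit_underlying(tab, rf_spec())
  prob <- predict_scores(scorer, tab[1:4, ])
  alpha <- nonconformity(scorer, tab[1:4, ], rep("C2", 4))
  expect_equal(unname(alpha), 1 - prob[, "C2"], ignore_attr = TRUE)
  expect_true(all(alpha >= 0 & alpha <= 1))
  expect_error(nonconformity(scorer, tab[1, ], "C9"), "unknown label")
})

test_that("conformal p-values match the counting definition", {
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3), 0.25), 0.5)
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3), 0.05), 1.0)
  expect_equal(conformal_pvalue(c(0.1, 0.2, 0.3), 0.9), 1 / 4)  # floor
  # inclusive tie counting
  expect_equal(conformal_pvalue(c(0.2, 0.2, 0.5), 0.2), (3 + 1) / 4)
  # smoothed variant stays within (0, 1] and below the unsmoothed value
  set.seed(1)
  ps <- replicate(200, conformal_pvalue(c(0.2, 0.2, 0.5), 0.2,
                                        smoothed = TRUE))
  expect_true(all(ps > 0 & ps <= 1))
  expect_lt(mean(ps), 1)
})

test_that("icp_fit makes a stratified split with calibrated score range", {
  tab <- toy_table(n_classes = 4, per_class = 25, n_features = 8)
  m <- icp_fit(tab, rf_spec(), calib_fraction = 0.3, seed = 3)
  expect_s3_class(m, "icp_model")
  # floor(0.3 * 25) = 7 per class
  expect_length(m$calib_scores, 28L)
  expect_equal(unname(table(tab$label[m$calib_idx])), rep(7L, 4),
               ignore_attr = TRUE)
  expect_true(all(m$calib_scores >= 0 & m$calib_scores <= 1))
  expect_identical(icp_fit(tab, rf_spec(), calib_fraction = 0.3,
                           seed = 3)$calib_idx, m$calib_idx)
  expect_error(icp_fit(tab, rf_spec(), calib_fraction = 1.2), "calib_fraction")
})

test_that("icp_pvalues agrees with brute-force counting on fitted models", {
  tab <- toy_table(n_classes = 3, per_class = 15, separation = 1.2)
  m <- icp_fit(tab, rf_spec(), seed = 7)
  test_rows <- tab[1:10, ]
  pv <- icp_pvalues(m, test_rows)
  prob <- predict_scores(m$scorer, test_rows)
  for (i in 1:10) {
    for (c_idx in seq_along(m$label_set)) {
      a <- 1 - prob[i, c_idx]
      n_ge <- 0L
      for (s in m$calib_scores) if (s >= a) n_ge <- n_ge + 1L
      expect_equal(unname(pv[i, c_idx]),
                   (n_ge + 1) / (length(m$calib_scores) + 1))
    }
  }
  expect_true(all(pv > 0 & pv <= 1))
  expect_true(all(pv >= 1 / (length(m$calib_scores) + 1)))
})

test_that("acp_fit builds K bootstrap folds with out-of-bag calibration", {
  tab <- toy_table(n_classes = 3, per_class = 15)
  acp <- acp_fit(tab, rf_spec(), K = 5, seed = 2)
  expect_length(acp$folds, 5L)
  for (f in acp$folds) {
    expect_length(f$boot_idx, nrow(tab))           # resample of full size
    expect_true(length(f$calib_idx) > 0)
    expect_length(intersect(f$calib_idx, f$boot_idx), 0L)  # true OOB
    # stratified resample keeps per-class draw counts fixed
    expect_equal(unname(table(tab$label[f$boot_idx])), rep(15L, 3),
                 ignore_attr = TRUE)
  }
  expect_identical(acp_fit(tab, rf_spec(), K = 5, seed = 2)$folds[[3]]$boot_idx,
                   acp$folds[[3]]$boot_idx)

  # expected OOB fraction ~ (1 - 1/n)^n per class (Monte-Carlo, 3 SE)
  oob_frac <- unlist(lapply(1:3, function(s) {
    a <- acp_fit(tab, rf_spec(ntree = 25), K = 4, seed = 10 + s)
    vapply(a$folds, function(f) length(f$calib_idx) / nrow(tab), numeric(1))
  }))
  expected <- (1 - 1 / 15)^15
  sd_fold <- sqrt(expected * (1 - expected) / nrow(tab))
  expect_lt(abs(mean(oob_frac) - expected),
            3 * sd_fold / sqrt(length(oob_frac)))
})

test_that("ACP p-values are the mean of fold ICP p-values; K = 1 is ICP-like", {
  tab <- toy_table(n_classes = 3, per_class = 15)
  acp <- acp_fit(tab, rf_spec(), K = 4, seed = 9)
  obj <- tab[c(2, 17, 31), ]
  agg <- acp_pvalues(acp, obj)
  manual <- rowMeans(vapply(acp$folds,
                            function(f) icp_pvalues(f, obj),
                            matrix(0, 3, 3)), dims = 2)
  expect_equal(agg, manual, tolerance = 1e-12)
  expect_true(all(agg > 0 & agg <= 1))

  one <- acp_fit(tab, rf_spec(), K = 1, seed = 9)
  expect_equal(acp_pvalues(one, obj), icp_pvalues(one$folds[[1]], obj))
})

test_that("prediction regions are nested and respect the strict threshold", {
  pv <- c(C1 = 0.007, C2 = 0.009, C3 = 0.813)
  expect_identical(prediction_region(pv, 0.05), "C3")
  expect_identical(prediction_region(pv, 0.9), character(0))
  expect_setequal(prediction_region(pv, 0.005), c("C1", "C2", "C3"))
  expect_identical(prediction_region(pv, 0.007), c("C2", "C3"))  # strict >
  expect_error(prediction_region(pv, 0), "epsilon")
  expect_error(prediction_region(pv, 1), "epsilon")

  # nesting over a random sweep, and the forced label leaves last
  set.seed(4)
  for (rep in 1:20) {
    p <- stats::runif(6)
    names(p) <- paste0("C", 1:6)
    grid <- sort(stats::runif(8, 0.01, 0.99))
    regions <- lapply(grid, prediction_region, pvals = p)
    for (j in 2:length(regions)) {
      expect_true(all(regions[[j]] %in% regions[[j - 1]]))
    }
    nonempty <- regions[lengths(regions) > 0]
    last <- nonempty[[length(nonempty)]]
    expect_true(forced_prediction(p) %in% last)
  }
})

test_that("forced prediction and the reliability indicators follow definitions", {
  expect_identical(forced_prediction(c(A = 0.2, B = 0.7, C = 0.1)), "B")
  expect_message(tie <- forced_prediction(c(A = 0.5, B = 0.5)), "tie")
  expect_identical(tie, "A")
  expect_identical(forced_prediction(c(only = 0.4)), "only")

  cc <- confidence_credibility(c(A = 0.1, B = 0.8, C = 0.05))
  expect_equal(cc$confidence, 0.9)
  expect_equal(cc$credibility, 0.8)
  expect_error(confidence_credibility(c(A = 0.3)), "2 candidate")
})

test_that("ICP error rate respects the significance level on exchangeable data", {
  # held-out data from the generating distribution: conformal validity
  tab <- simulate_feature_table(4, 40, 12, separation = 0.5, seed = 31)
  test_idx <- (seq_len(nrow(tab)) - 1L) %% 40 >= 30   # 10 per class
  m <- icp_fit(tab[!test_idx, ], rf_spec(ntree = 80), seed = 5)
  pv <- icp_pvalues(m, tab[test_idx, ])
  truth <- as.character(tab$label[test_idx])
  p_true <- pv[cbind(seq_len(nrow(pv)), match(truth, colnames(pv)))]
  n_test <- length(p_true)
  for (eps in seq(0.1, 0.9, 0.2)) {
    expect_lte(mean(p_true <= eps),
               eps + 3 * sqrt(eps * (1 - eps) / n_test))
  }
})
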