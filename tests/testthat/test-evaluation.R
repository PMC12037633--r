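test_that("stratified folds partition the pair set with balanced positives", {
  set.seed(4)
  LD <- matrix(0, 20, 25)
  LD[sample(500, 100)] <- 1
  ds <- assemble_dataset(LD)
  folds <- five_fold_split(ds, seed = 2)
  expect_true(all(folds %in% 1:5))
  expect_identical(as.vector(table(folds[LD == 1])), rep(20L, 5))
  expect_identical(length(folds), 500L)
  expect_identical(five_fold_split(ds, seed = 2), folds)
  expect_false(identical(five_fold_split(ds, seed = 3), folds))
  tiny <- assemble_dataset(matrix(c(1, 1, 1, 0), 2, 2))
  expect_error(five_fold_split(tiny), "at least 5")
})

test_that("metrics hit the closed-form values on separable and inverted data", {
  m <- compute_metrics(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$aupr, 1)
  expect_equal(m$f1, 1)
  expect_equal(m$mcc, 1)
  expect_equal(compute_metrics(c(0.2, 0.9), c(1, 0))$auc, 0)
  m3 <- compute_metrics(c(0.9, 0.4, 0.35, 0.1), c(1, 0, 1, 0))
  expect_equal(m3$auc, 0.75)
  expect_error(compute_metrics(c(1, 2), c(1, 1)), "both classes")
})

test_that("AUC equals the Mann-Whitney pair-counting statistic, ties included", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- sample(20:200, 1)
    scores <- round(rnorm(n), sample(1:3, 1))  # rounding forces ties
    labels <- rbinom(n, 1, 0.3)
    if (sum(labels) %in% c(0, n)) next
    expect_equal(compute_metrics(scores, labels)$auc,
                 oracle_auc_mw(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(42)
  s <- rnorm(300)
  y <- rbinom(300, 1, stats::plogis(1.5 * s))
  expect_equal(compute_metrics(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))),
               tolerance = 1e-10)
})

test_that("ranking metrics are invariant under monotone score transforms", {
  set.seed(5)
  s <- rnorm(150)
  y <- rbinom(150, 1, 0.2)
  m1 <- compute_metrics(s, y)
  m2 <- compute_metrics(10 * exp(s), y)  # strictly monotone transform
  expect_equal(m1$auc, m2$auc, tolerance = 1e-12)
  expect_equal(m1$aupr, m2$aupr, tolerance = 1e-12)
  S <- matrix(rnorm(30), 5, 6)
  LDt <- matrix(rbinom(30, 1, 0.3), 5, 6)
  expect_equal(topk_recall(S, LDt, 2), topk_recall(exp(S), LDt, 2))
})

test_that("top-k recall follows the per-disease ranking protocol", {
  S <- rbind(c(0.9, 0.1), c(0.5, 0.8), c(0.1, 0.3))
  pos <- rbind(c(1, 0), c(0, 1), c(0, 1))
  # k=1: disease 1 calls lncRNA 1 (hit); disease 2 calls lncRNA 2 (hit, miss row 3)
  expect_equal(topk_recall(S, pos, 1), 2 / 3)
  expect_equal(topk_recall(S, pos, 2), 1)
  expect_equal(topk_recall(S, pos, nrow(S)), 1)
  expect_warning(r <- topk_recall(S, pos, 10), "clamped")
  expect_equal(r, 1)
  # ties break toward the lower lncRNA index
  Stie <- matrix(1, 3, 1)
  pos1 <- matrix(c(0, 1, 0), 3, 1)
  expect_equal(topk_recall(Stie, pos1, 1), 0)  # index 1 wins the tie
  expect_equal(topk_recall(Stie, pos1, 2), 1)
  # excluded pairs are not candidates
  excl <- matrix(c(TRUE, FALSE, FALSE), 3, 1)
  expect_equal(topk_recall(Stie, pos1, 1, exclude = excl), 1)
})

test_that("cross-validation scores every pair exactly once and is deterministic", {
  ds <- generate_synthetic(synthetic_spec(nl = 20, nd = 16, nm = 6,
                                          n_blocks = 2, density = 0.15,
                                          noise_rate = 0, seed = 2))$dataset
  cfg <- tiny_config(epochs = 15L, seed = 3L)
  cv <- run_cross_validation(ds, cfg, view = "both")
  expect_false(anyNA(cv$pooled_scores))
  expect_identical(sort(unique(as.vector(cv$folds))), 1:5)
  expect_identical(nrow(cv$predictions), length(ds$LD))
  expect_true(all(cv$metrics[, c("auc", "aupr", "f1")] >= 0 &
                    cv$metrics[, c("auc", "aupr", "f1")] <= 1))
  expect_true(cv$metrics$mcc >= -1 && cv$metrics$mcc <= 1)
  cv_rep <- run_cross_validation(ds, cfg, view = "both")
  expect_identical(cv_rep$pooled_scores, cv$pooled_scores)
  expect_identical(cv_rep$metrics, cv$metrics)
})

test_that("single-view ablations run without the other view's construction", {
  ds <- generate_synthetic(synthetic_spec(nl = 18, nd = 14, nm = 5,
                                          n_blocks = 2, density = 0.15,
                                          noise_rate = 0, seed = 4))$dataset
  cfg <- tiny_config(epochs = 10L, seed = 1L)
  for (vw in c("net1", "net2")) {
    cv <- run_cross_validation(ds, cfg, view = vw)
    expect_s3_class(cv, "lnclink_cv")
    expect_identical(cv$view, vw)
    expect_false(anyNA(cv$pooled_scores))
  }
  v2 <- build_views(ds, cfg, view = "net2")
  expect_null(v2$A1)  # ablation skips the heterogeneous view entirely
})

test_that("cv tidiers and curves are well-formed", {
  ds <- generate_synthetic(synthetic_spec(nl = 16, nd = 12, nm = 4,
                                          n_blocks = 2, density = 0.2,
                                          noise_rate = 0, seed = 6))$dataset
  cfg <- tiny_config(epochs = 10L, seed = 1L)
  cv <- run_cross_validation(ds, cfg, view = "net2")
  expect_identical(tidy(cv), cv$predictions)
  expect_identical(glance(cv)$view, "net2")
  expect_s3_class(autoplot(cv), "ggplot")
  cd <- curve_data(cv$predictions$score, cv$predictions$label)
  expect_true(all(diff(cd$tpr) >= 0))
  expect_true(all(cd$precision >= 0 & cd$precision <= 1))
})
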