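# Mann-Whitney AUC, learner benchmarking, SVM-RFE and panel selection.

test_that("AUC matches forced cases and the exhaustive pair-count oracle", {
  expect_equal(auc_mann_whitney(c(0.9, 0.8, 0.2, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE)), 1.0)
  expect_equal(auc_mann_whitney(c(0.9, 0.2, 0.8, 0.1),
                                c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_equal(auc_mann_whitney(rep(1, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_error(auc_mann_whitney(1:3, c(TRUE, TRUE, TRUE)), "both classes")

  for (s in 1:25) {
    set.seed(s)
    n <- sample(6:30, 1)
    scores <- round(rnorm(n), 1)          # induce ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_equal(auc_mann_whitney(scores, labels),
                 oracle_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("AUC identities: label inversion and monotone invariance", {
  set.seed(71)
  scores <- rnorm(40)
  labels <- sample(c(TRUE, FALSE), 40, replace = TRUE)
  expect_equal(auc_mann_whitney(scores, labels) +
               auc_mann_whitney(scores, !labels), 1.0)
  expect_equal(auc_mann_whitney(exp(scores * 3), labels),
               auc_mann_whitney(scores, labels), tolerance = 1e-12)
})

test_that("benchmarking is reproducible and calibrated", {
  set.seed(73)
  n <- 60
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 20), n, 20)
  x[, 1] <- x[, 1] + ifelse(labels, 3, 0)   # one separating feature

  b1 <- benchmark_learners(x, labels, k_folds = 5, repeats = 2, seed = 11)
  b2 <- benchmark_learners(x, labels, k_folds = 5, repeats = 2, seed = 11)
  expect_identical(b1, b2)
  expect_gte(b1$mean_auc[b1$learner == "svm_linear"], 0.85)

  # a perfectly separating feature gives AUC 1 for margin/linear learners
  xp <- cbind(sig = ifelse(labels, 1, -1), noise = rnorm(n, 0, 0.1))
  bp <- benchmark_learners(xp, labels, learners = c("svm_linear", "logistic"),
                           k_folds = 5, repeats = 1, seed = 15)
  expect_equal(bp$mean_auc, c(1, 1))

  # permuted labels: every learner near chance
  set.seed(74)
  xn <- matrix(rnorm(n * 10), n, 10)
  b0 <- benchmark_learners(xn, sample(labels), k_folds = 5, repeats = 3,
                           seed = 12)
  expect_true(all(abs(b0$mean_auc - 0.5) < 0.1))
})

test_that("a feature informative only on held-out folds cannot inflate CV AUC", {
  set.seed(75)
  n <- 60
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  folds <- make_cv_folds(labels, k_folds = 5, repeats = 2, seed = 13)
  aucs <- c()
  for (r in seq_along(folds)) {
    for (f in 1:5) {
      te <- folds[[r]] == f
      leaky <- as.numeric(labels)
      leaky[!te] <- sample(leaky[!te])    # training values carry no signal
      x <- cbind(leaky, matrix(rnorm(n * 5), n, 5))
      m <- e1071::svm(x[!te, ], factor(labels[!te]), kernel = "linear",
                      scale = FALSE)
      dv <- attr(predict(m, x[te, ], decision.values = TRUE),
                 "decision.values")[, 1]
      aucs <- c(aucs, auc_mann_whitney(dv, labels[te]))
    }
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("SVM-RFE ranks a planted feature first and shares duplicated weight", {
  firsts <- sapply(1:20, function(s) {
    set.seed(s)
    n <- 60
    labels <- rep(c(TRUE, FALSE), each = n / 2)
    x <- cbind(matrix(rnorm(n * 100), n, 100))
    colnames(x) <- sprintf("f%03d", 1:100)
    x[, "f001"] <- as.numeric(labels) + rnorm(n, 0, 0.05)
    svm_rfe_rank(x, labels)[1] == "f001"
  })
  expect_gte(mean(firsts), 0.95)

  # duplicated informative features split the weight but both stay on top
  set.seed(80)
  n <- 80
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  sig <- as.numeric(labels) + rnorm(n, 0, 0.1)
  x <- cbind(a = sig, b = sig, matrix(rnorm(n * 30), n, 30))
  colnames(x)[3:32] <- sprintf("n%02d", 1:30)
  rk <- svm_rfe_rank(x, labels, drop_frac = 0.1)
  expect_true(all(c("a", "b") %in% rk[1:4]))
})

test_that("one-feature-per-round elimination takes exactly n rounds", {
  set.seed(81)
  n <- 30
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  x <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  rk <- svm_rfe_rank(x, labels, drop_frac = 0.19)  # ceil(0.19*5) = 1 per round
  expect_setequal(rk, paste0("f", 1:5))
  expect_length(rk, 5)
})

test_that("panel selection recovers planted features with honest CV AUC", {
  ds <- generate_staged_dataset(small_config(
    seed = 91, missing_rate = 0, trend_amplitude = 0, emt_drift = 0,
    sd_multiplier = 1, rho_spike = 0.1001, rho_base = 0.1))
  design <- build_stage_design(ds$annotations)
  m <- median_normalize(ds$matrix)
  ids <- design_samples(design, "L")
  labels <- ds$truth$phase_label[ids] == "post"
  xf <- panel_feature_matrix(m, ids)
  pm <- select_panel(xf, labels, rule = "fixed_k", k = 7, s_max = 10,
                     k_folds = 5, seed = 5)
  expect_length(pm$selected_panel, 7L)
  expect_gte(length(intersect(pm$selected_panel, ds$truth$panel_members)), 4)
  expect_gte(pm$cv_auc_by_size$mean_auc[7], 0.9)
  expect_identical(pm$selected_panel, pm$ranked_features[1:7])
  expect_error(select_panel(xf, labels, k = ncol(xf) + 1), "exceeds")
})

test_that("the one-SE rule prefers smaller panels on plateaued AUC curves", {
  set.seed(92)
  n <- 80
  labels <- rep(c(TRUE, FALSE), each = n / 2)
  # three strong features; AUC plateaus early
  x <- cbind(matrix(as.numeric(labels) + rnorm(n * 3, 0, 0.4), n, 3),
             matrix(rnorm(n * 40), n, 40))
  colnames(x) <- sprintf("f%02d", seq_len(ncol(x)))
  fixed <- select_panel(x, labels, rule = "fixed_k", k = 7, s_max = 10,
                        seed = 3)
  onese <- select_panel(x, labels, rule = "one_se", s_max = 10, seed = 3)
  expect_lte(length(onese$selected_panel), length(fixed$selected_panel))
})
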