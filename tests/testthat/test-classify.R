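# LS-SVM, AUC, per-state and nested LOOCV, bootstrap comparison.

two_clouds <- function(n_per = 12, p = 6, sep = 4, seed = 51) {
  withr::with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p), n_per, p),
               matrix(rnorm(n_per * p, mean = sep / sqrt(p)), n_per, p))
  })
  list(x = x, y = rep(c(-1, 1), each = n_per))
}

test_that("LS-SVM separates well-separated clouds", {
  tc <- two_clouds(sep = 8)
  fit <- lssvm_train(tc$x, tc$y, C = 0.1)
  expect_true(all(sign(lssvm_decision(fit, tc$x)) == tc$y))
  expect_error(lssvm_train(tc$x, rep(1, nrow(tc$x))), "classes")
})

test_that("LS-SVM dual solution equals the primal ridge closed form", {
  # primal oracle: min (1/2)|w|^2 + (C/2) sum (y - w'x - b)^2 via augmented
  # normal equations with an unpenalized intercept
  withr::with_seed(52, {
    for (rep in 1:5) {
      n <- sample(6:20, 1); p <- sample(2:15, 1); C <- runif(1, 0.05, 2)
      x <- matrix(rnorm(n * p), n, p)
      y <- sample(c(-1, 1), n, TRUE)
      if (length(unique(y)) < 2) y[1:2] <- c(-1, 1)
      fit <- lssvm_train(x, y, C)
      xa <- cbind(1, x)
      pen <- diag(c(0, rep(1 / C, p)))
      sol <- solve(crossprod(xa) + pen, crossprod(xa, y))
      expect_equal(fit$bias, sol[1], tolerance = 1e-8)
      expect_equal(unname(fit$weights), sol[-1], tolerance = 1e-8)
    }
  })
})

test_that("duplicating training points is equivalent to doubling C", {
  tc <- two_clouds()
  a <- lssvm_train(rbind(tc$x, tc$x), c(tc$y, tc$y), C = 0.1)
  b <- lssvm_train(tc$x, tc$y, C = 0.2)
  expect_equal(a$weights, b$weights, tolerance = 1e-8)
  expect_equal(a$bias, b$bias, tolerance = 1e-8)
})

test_that("AUC equals trapezoidal ROC integration and handles ties", {
  withr::with_seed(53, {
    scores <- rnorm(60)
    labels <- sample(c(-1, 1), 60, TRUE)
  })
  labels[1:2] <- c(-1, 1)
  trapezoid_auc <- function(scores, labels) {
    th <- sort(unique(scores), decreasing = TRUE)
    tpr <- c(0, vapply(th, function(t) mean(scores[labels == 1] >= t),
                       numeric(1)), 1)
    fpr <- c(0, vapply(th, function(t) mean(scores[labels == -1] >= t),
                       numeric(1)), 1)
    sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  }
  expect_equal(roc_auc(scores, labels), trapezoid_auc(scores, labels),
               tolerance = 1e-12)
  skip_if_not_installed("pROC")
  expect_equal(roc_auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores,
                                              levels = c(-1, 1),
                                              direction = "<",
                                              quiet = TRUE))),
               tolerance = 1e-12)
  # perfect ranking, chance, monotone invariance
  expect_equal(roc_auc(1:10, rep(c(-1, 1), each = 5)), 1)
  expect_equal(roc_auc(scores, labels),
               roc_auc(exp(3 * scores) + 2, labels), tolerance = 1e-12)
  expect_error(roc_auc(1:3, rep(1, 3)), "both classes")
})

test_that("LOOCV on duplicated class prototypes scores perfectly", {
  # prototypes far apart so the margin term dominates the per-fold class
  # imbalance that LOOCV induces in the bias
  x <- rbind(matrix(0, 2, 4), matrix(100, 2, 4))
  y <- c(-1, -1, 1, 1)
  res <- loocv_state_auc(x, y, C = 0.1)
  expect_equal(res$auc, 1)
  expect_message(expect_null(loocv_state_auc(x[1:3, ], y[1:3], C = 0.1)),
                 "untestable")
})

test_that("nested LOOCV with one state and one threshold reduces to plain LOOCV", {
  tc <- two_clouds(n_per = 10, sep = 3, seed = 55)
  ids <- sprintf("S%02d", 1:20)
  rownames(tc$x) <- ids
  ph <- data.frame(subject_id = ids,
                   group = ifelse(tc$y == 1, "mTBI", "HC"))
  rep <- sfnc_nested_loocv(tc$x, ph, thresholds = 0, C = 0.1)
  plain <- loocv_state_auc(tc$x, tc$y, C = 0.1)
  expect_equal(rep$overall_auc, plain$auc, tolerance = 1e-10)
  expect_equal(rep$pooled_scores$score, unname(plain$scores),
               tolerance = 1e-10)
  expect_true(all(rep$per_fold_choice$n_features == ncol(tc$x)))
})

test_that("candidate count is states x thresholds when all states are visited", {
  st <- small_model_fixture()
  rep <- nested_loocv(st$model, st$phenotypes, C = 0.1)
  full_rosters <- names(which(st$all_visited))
  expect_true(all(rep$n_candidates[full_rosters] ==
                    st$model$k * length(rep$thresholds)))
  # every classified subject appears exactly once
  expect_equal(sort(rep$per_fold_choice$subject_id),
               sort(names(rep$n_candidates)))
})

test_that("feature count is non-increasing in the threshold", {
  st <- small_model_fixture()
  rep <- nested_loocv(st$model, st$phenotypes, C = 0.1)
  agg <- tapply(rep$per_fold_choice$n_features, rep$per_fold_choice$threshold,
                max)
  agg <- agg[!is.na(agg)]
  if (length(agg) > 1)
    expect_true(all(diff(agg[order(as.numeric(names(agg)))]) <= 0))
  # threshold 0 always keeps the full feature set
  z <- rep$per_fold_choice$n_features[rep$per_fold_choice$threshold == 0]
  if (length(z)) expect_true(all(z == nrow(st$model$pair_index)))
})

test_that("the held-out subject cannot influence model selection (no leakage)", {
  st <- small_model_fixture()
  rep0 <- nested_loocv(st$model, st$phenotypes, C = 0.1)
  # poison one subject's features: selection for that subject's fold must
  # not change, because inner t-tests and training never see the held-out row
  victim <- rep0$per_fold_choice$subject_id[1]
  poisoned <- st$model
  for (s in names(poisoned$subject_state_means[[victim]]))
    poisoned$subject_state_means[[victim]][[s]] <-
      poisoned$subject_state_means[[victim]][[s]] + 100
  rep1 <- nested_loocv(poisoned, st$phenotypes, C = 0.1)
  ch0 <- rep0$per_fold_choice[rep0$per_fold_choice$subject_id == victim, ]
  ch1 <- rep1$per_fold_choice[rep1$per_fold_choice$subject_id == victim, ]
  expect_equal(ch1$state, ch0$state)
  expect_equal(ch1$threshold, ch0$threshold)
  expect_equal(ch1$inner_auc, ch0$inner_auc, tolerance = 1e-10)
  expect_equal(ch1$n_features, ch0$n_features)
  # but the victim's own score does change
  s0 <- rep0$pooled_scores$score[rep0$pooled_scores$subject_id == victim]
  s1 <- rep1$pooled_scores$score[rep1$pooled_scores$subject_id == victim]
  expect_false(isTRUE(all.equal(s0, s1)))
})

test_that("nested LOOCV reports are deterministic", {
  st <- small_model_fixture()
  a <- nested_loocv(st$model, st$phenotypes, C = 0.1)
  b <- nested_loocv(st$model, st$phenotypes, C = 0.1)
  expect_identical(a, b)
})

test_that("bootstrap comparison is calibrated", {
  tc <- two_clouds(n_per = 48, sep = 2, seed = 57)
  ids <- sprintf("S%02d", seq_along(tc$y))
  rownames(tc$x) <- ids
  ph <- data.frame(subject_id = ids,
                   group = ifelse(tc$y == 1, "mTBI", "HC"))
  rep <- sfnc_nested_loocv(tc$x, ph, thresholds = c(0, 1), C = 0.1)
  boot <- bootstrap_compare(rep, rep, B = 2000, seed = 5)
  expect_equal(boot$df, 2 * 2000 - 2)
  expect_gt(boot$p, 0.05)
  expect_lt(abs(mean(boot$auc_a) - rep$overall_auc), 0.02)
  b2 <- bootstrap_compare(rep, rep, B = 10000, seed = 5)
  expect_equal(b2$df, 19998)
})
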