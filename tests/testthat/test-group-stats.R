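# Two-sample t (samples and summaries), Fisher's exact, BH-FDR, state-wise
# mass-univariate testing and covariate regression.

test_that("pooled t matches stats::t.test and is antisymmetric", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      a <- rnorm(sample(5:30, 1), sd = runif(1, 0.5, 2))
      b <- rnorm(sample(5:30, 1), mean = runif(1, -1, 1))
      ours <- two_sample_t(a, b)
      ref <- stats::t.test(b, a, var.equal = TRUE)
      expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-12)
      expect_equal(ours$p, ref$p.value, tolerance = 1e-12)
      swapped <- two_sample_t(b, a)
      expect_equal(swapped$t, -ours$t)
      expect_equal(swapped$p, ours$p)
    }
  })
  x <- c(1, 2, 3, 4)
  same <- two_sample_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
})

test_that("pooled t agrees with a permutation-derived p-value", {
  withr::with_seed(42, {
    a <- rnorm(8); b <- rnorm(9, mean = 1.2)
    obs <- two_sample_t(a, b)
    pool <- c(a, b)
    n <- length(pool)
    perm_t <- replicate(20000, {
      idx <- sample.int(n, length(a))
      two_sample_t(pool[idx], pool[-idx])$t
    })
  })
  p_perm <- mean(abs(perm_t) >= abs(obs$t))
  expect_lt(abs(p_perm - obs$p), 3 * sqrt(obs$p * (1 - obs$p) / 20000) + 0.01)
})

test_that("summary-based t is identical to sample-based t", {
  withr::with_seed(43, { a <- rnorm(12); b <- rnorm(15, 0.5) })
  full <- two_sample_t(a, b)
  summ <- two_sample_t_from_summary(mean(a), sd(a), 12, mean(b), sd(b), 15)
  expect_equal(summ, full, tolerance = 1e-12)
  expect_equal(two_sample_t_from_summary(5, 1, 10, 5, 2, 10)$t, 0)
  expect_error(two_sample_t_from_summary(1, 1, 1, 2, 1, 5), "n1 >= 2")
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  enum_p <- function(tab) {
    # sum of probabilities of tables no more probable than the observed one
    m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
    support <- max(0, k - n):min(k, m)
    probs <- dhyper(support, m, n, k)
    obs <- dhyper(tab[1, 1], m, n, k)
    sum(probs[probs <= obs * (1 + 1e-7)])
  }
  tabs <- list(rbind(c(23, 25), c(23, 25)),
               rbind(c(21, 22), c(16, 21)),
               rbind(c(10, 10), c(15, 11)),
               rbind(c(3, 9), c(8, 2)))
  for (tab in tabs)
    expect_equal(fisher_exact_2x2(tab), enum_p(tab), tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(7, 5), c(7, 5))), 1)
  expect_error(fisher_exact_2x2(rbind(c(0, 0), c(1, 2))), "margins")
})

test_that("BH-FDR matches a literal step-up loop", {
  step_up <- function(p, alpha) {
    m <- length(p)
    o <- order(p)
    k_max <- 0
    for (k in seq_len(m)) if (p[o[k]] <= alpha * k / m) k_max <- k
    mask <- rep(FALSE, m)
    if (k_max > 0) mask[o[seq_len(k_max)]] <- TRUE
    mask
  }
  withr::with_seed(44, {
    p <- c(runif(1100), runif(28, 0, 1e-3))[sample(1128)]
  })
  ours <- fdr_bh(p, 0.05)
  expect_equal(ours$mask, step_up(p, 0.05))
  expect_equal(fdr_bh(rep(0, 5))$mask, rep(TRUE, 5))
  expect_equal(fdr_bh(rep(1, 5))$mask, rep(FALSE, 5))
  # never more discoveries than unadjusted thresholding
  expect_lte(sum(ours$mask), sum(p <= 0.05))
})

test_that("state-wise testing runs one family per state with roster sizes", {
  st <- effect_study()
  gs <- statewise_group_diff(st$model, st$cohort$phenotypes)
  expect_length(gs, 4)
  for (r in gs) {
    expect_true(r$tested)
    expect_length(r$t_values, 1128)
    expect_length(r$fdr_mask, 1128)
    expect_equal(r$n_hc + r$n_mtbi,
                 st$model$subject_counts[r$state])
    expect_true(all(r$p_values[r$fdr_mask] <= 0.05))
  }
})

test_that("states with too few subjects per group are reported untested", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  windows <- cohort_windows(co)[1:3]          # 3 subjects only
  allw <- do.call(rbind, lapply(windows, `[[`, "vectors"))
  fit <- kmeans_states(allw, 3, seed = 1)
  model <- summarize_states(windows, fit$labels, fit$centroids)
  expect_message(gs <- statewise_group_diff(model, co$phenotypes),
                 "untested")
  expect_true(any(!vapply(gs, `[[`, logical(1), "tested")))
})

test_that("covariate regression recovers exact fits and matches the normal equations", {
  withr::with_seed(45, {
    ph <- data.frame(subject_id = sprintf("S%02d", 1:30),
                     group = rep(c("HC", "mTBI"), 15),
                     sex = sample(c("M", "F"), 30, TRUE),
                     age = rnorm(30, 28, 8), edu = rnorm(30, 14, 2),
                     wtar = rnorm(30, 52, 8))
  })
  exact <- suppressWarnings(covariate_regression(2 * ph$age, ph))
  expect_equal(unname(exact$betas["age"]), 2, tolerance = 1e-10)
  expect_lt(max(abs(exact$betas[c("sex", "edu", "wtar")])), 1e-10)

  withr::with_seed(46, y <- rnorm(30))
  ours <- covariate_regression(y, ph)
  xmat <- cbind(1, as.numeric(factor(ph$sex, c("F", "M"))) - 1,
                ph$age, ph$edu, ph$wtar)
  beta_ne <- solve(crossprod(xmat), crossprod(xmat, y))
  expect_equal(unname(ours$betas), drop(beta_ne), tolerance = 1e-10)

  ph2 <- ph; ph2$wtar <- ph2$age  # collinear
  expect_error(covariate_regression(y, ph2), "collinear")
})

test_that("regression p-values are approximately uniform under the null", {
  withr::with_seed(47, {
    ph <- data.frame(subject_id = sprintf("S%02d", 1:40),
                     group = "HC",
                     sex = sample(c("M", "F"), 40, TRUE),
                     age = rnorm(40, 28, 8), edu = rnorm(40, 14, 2),
                     wtar = rnorm(40, 52, 8))
    p_age <- replicate(200, covariate_regression(rnorm(40), ph)$p_values["age"])
  })
  expect_lt(abs(mean(p_age < 0.05) - 0.05), 0.05)
  expect_gt(stats::ks.test(p_age, "punif")$p.value, 0.001)
})

test_that("demographics table reproduces the expected layout", {
  st <- effect_study()
  demo <- demographics_table(st$model, st$cohort$phenotypes)
  expect_equal(unique(demo$scope),
               c("All subjects", paste("State", 1:4)))
  expect_setequal(unique(demo$variable), c("sex", "age", "edu", "wtar"))
  # WTAR was generated with a group gap: strongly negative t on all subjects
  expect_lt(demo$t[demo$scope == "All subjects" & demo$variable == "wtar"], -2)
})
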