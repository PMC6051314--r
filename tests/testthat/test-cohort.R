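# Synthetic cohort generator: state correlation construction, Markov state
# sequences, subject emission, and cohort assembly.

test_that("state correlation matrices are valid and the group effect is focal", {
  cfg <- tiny_config(effect_delta = 0.3, trend_delta = 0,
                     effect_pairs = rbind(c(1, 5), c(2, 6)))
  sc <- build_state_correlations(cfg)
  for (m in c(sc$hc, sc$case)) {
    expect_equal(m, t(m))
    expect_equal(unname(diag(m)), rep(1, ncol(m)))
    expect_gt(min(eigen(m, TRUE, only.values = TRUE)$values), 0)
  }
  # difference matrix oracle: direct subtraction
  d <- sc$case[[cfg$effect_state]] - sc$hc[[cfg$effect_state]]
  expect_equal(sum(d != 0), 4)
  expect_equal(unique(d[d != 0]), 0.3)
  for (s in setdiff(seq_len(cfg$n_states), cfg$effect_state))
    expect_identical(sc$case[[s]], sc$hc[[s]])
})

test_that("null effect gives identical group matrices in every state", {
  sc <- build_state_correlations(tiny_config(effect_delta = 0))
  expect_identical(sc$hc, sc$case)
})

test_that("identity block spec yields identity matrices", {
  spec <- replicate(3, data.frame(block_a = 1, block_b = 1, level = 0),
                    simplify = FALSE)
  cfg <- tiny_config(state_block_spec = spec, base_within = 0,
                     effect_delta = 0)
  sc <- build_state_correlations(cfg)
  for (m in sc$hc) expect_equal(m, diag(cfg$n_components))
})

test_that("infeasible block specs fail with a named entry", {
  spec <- replicate(3, data.frame(block_a = c(1, 2, 1), block_b = c(1, 2, 2),
                                  level = c(0.05, 0.05, 0.98)),
                    simplify = FALSE)
  cfg <- tiny_config(state_block_spec = spec, effect_delta = 0)
  expect_error(build_state_correlations(cfg), "PD repair moved entry")
})

test_that("state sequences have Markov dwell structure", {
  cfg <- tiny_config(n_states = 1)
  expect_equal(simulate_state_sequence(cfg, 50), rep(1, 50))

  cfg2 <- tiny_config(dwell_mean = 1e12)
  lab <- simulate_state_sequence(cfg2, 200, seed = 1)
  expect_equal(length(unique(lab)), 1)

  cfg3 <- cohort_config(n_per_group = 2, n_components = 4, n_states = 4,
                        dwell_mean = 10, state_visit_sparsity = 0)
  lab <- simulate_state_sequence(cfg3, 10000, seed = 7)
  runs <- rle(lab)$lengths
  expect_lt(abs(mean(runs) - 10) / 10, 0.15)
  expect_setequal(unique(lab), 1:4)

  expect_error(simulate_state_sequence(cfg3, 10, allowed = integer(0)),
               "excluded")
  # excluded states never appear
  lab <- simulate_state_sequence(cfg3, 2000, allowed = c(1, 3), seed = 2)
  expect_setequal(unique(lab), c(1, 3))
})

test_that("subject emission matches the state correlation structure", {
  cfg <- cohort_config(n_per_group = 1, n_components = 6, n_states = 2,
                       n_timepoints = 50000, state_visit_sparsity = 0,
                       effect_delta = 0, seed = 3)
  sc <- build_state_correlations(cfg)
  x <- simulate_subject(cfg, "HC", sc, rep(1L, 50000), seed = 11)
  expect_lt(max(abs(cor(x) - sc$hc[[1]])), 0.03)
})

test_that("uncorrelated components show near-zero sample correlation", {
  spec <- replicate(2, data.frame(block_a = 1, block_b = 1, level = 0),
                    simplify = FALSE)
  cfg <- cohort_config(n_per_group = 1, n_components = 2, n_states = 2,
                       n_timepoints = 10000, base_within = 0,
                       state_block_spec = spec, blocks = c(1, 2),
                       effect_pairs = rbind(c(1, 2)), effect_delta = 0,
                       state_visit_sparsity = 0, seed = 5)
  sc <- build_state_correlations(cfg)
  x <- simulate_subject(cfg, "HC", sc, rep(1L, 10000), seed = 6)
  expect_lt(abs(cor(x)[1, 2]), 3 / sqrt(10000))
})

test_that("null-effect groups are exchangeable in distribution", {
  # two-sample test on a summary statistic over replicate subjects
  cfg <- cohort_config(n_per_group = 1, n_components = 8, n_states = 2,
                       n_timepoints = 200, effect_delta = 0,
                       state_visit_sparsity = 0, seed = 1)
  sc <- build_state_correlations(cfg)
  lab <- rep(c(1L, 2L), each = 100)
  stat <- function(group, seed) {
    x <- simulate_subject(cfg, group, sc, lab, seed = seed)
    mean(vectorize_conn(cor(x)))
  }
  hc <- vapply(1:40, function(i) stat("HC", 100 + i), numeric(1))
  tb <- vapply(1:40, function(i) stat("mTBI", 200 + i), numeric(1))
  expect_gt(two_sample_t(hc, tb)$p, 0.01)
})

test_that("cohort assembly has the right size, phenotypes and ground truth", {
  cfg <- tiny_config()
  co <- generate_cohort(cfg)
  expect_length(co$subjects, 16)
  expect_equal(table(co$phenotypes$group), table(rep(c("HC", "mTBI"), 8)),
               ignore_attr = TRUE)
  expect_equal(dim(co$truth$state_labels), c(16, cfg$n_timepoints))
  expect_true(all(co$truth$state_labels %in% seq_len(cfg$n_states)))
  expect_false(anyNA(co$phenotypes))

  co1 <- generate_cohort(cohort_config(n_per_group = 1, n_components = 6,
                                       n_states = 2, n_timepoints = 60))
  expect_length(co1$subjects, 2)
})

test_that("state-visit sparsity leaves some subjects with a strict label subset", {
  cfg <- cohort_config(n_per_group = 10, n_components = 6, n_timepoints = 80,
                       n_states = 4, state_visit_sparsity = 0.3, seed = 21)
  co <- generate_cohort(cfg)
  visited <- apply(co$truth$state_labels, 1, function(l) length(unique(l)))
  expect_true(any(visited < cfg$n_states))
  # allowed-set bookkeeping is consistent with emitted labels
  for (i in seq_along(co$subjects))
    expect_true(all(co$truth$state_labels[i, ] %in% co$truth$allowed[[i]]))
})

test_that("cohort generation is bit-identical under a fixed seed", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  c <- generate_cohort(tiny_config(seed = 43))
  expect_false(identical(a$subjects[[1]]$timecourses,
                         c$subjects[[1]]$timecourses))
})

test_that("cohort files round-trip through the text writer", {
  co <- generate_cohort(cohort_config(n_per_group = 2, n_components = 5,
                                      n_states = 2, n_timepoints = 40))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  rt <- read_cohort_dir(file.path(dir, "timecourses"),
                        file.path(dir, "phenotypes.tsv"))
  expect_equal(length(rt$subjects), 4)
  expect_equal(rt$phenotypes, co$phenotypes)
  i <- match(co$subjects[[1]]$subject_id,
             vapply(rt$subjects, `[[`, character(1), "subject_id"))
  expect_equal(rt$subjects[[i]]$timecourses, co$subjects[[1]]$timecourses,
               tolerance = 1e-6, ignore_attr = TRUE)
})
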