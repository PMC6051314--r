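# Shared fixtures, generated in code. The study-scale pipeline is expensive,
# so it is built once per test run and cached for all test files.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# A small, fast cohort for unit tests: 3 states, 12 components, 16 subjects.
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_per_group = 8, n_components = 12, n_timepoints = 120,
         n_states = 3, dwell_mean = 40, state_visit_sparsity = 0.3,
         seed = 42),
    list(...))
  do.call(cohort_config, args)
}

# Run filter + dFNC for every subject of a cohort.
cohort_windows <- function(cohort) {
  fs <- filter_spec(tr_seconds = cohort$config$tr_seconds)
  lapply(cohort$subjects, function(s)
    compute_dfnc(bandpass(s$timecourses, fs), taper_spec(),
                 subject_id = s$subject_id))
}

# Majority-taper-weight ground-truth label for each window of a cohort.
window_truth <- function(cohort, windows) {
  tapw <- make_taper(taper_spec())
  l <- length(tapw)
  unlist(lapply(seq_along(windows), function(i) {
    lab <- cohort$truth$state_labels[i, ]
    vapply(windows[[i]]$window_starts, function(st) {
      seg <- lab[st:(st + l - 1)]
      ws <- tapply(tapw, seg, sum)
      as.integer(names(ws)[which.max(ws)])
    }, integer(1))
  }))
}

# Study-scale cohort with the default group effect, clustered at the true K
# and with the elbow curve; shared by the recovery/effect/classification
# acceptance tests.
effect_study <- function() {
  cached("effect_study", {
    cfg <- cohort_config(seed = 1001)
    cohort <- generate_cohort(cfg)
    windows <- cohort_windows(cohort)
    allw <- do.call(rbind, lapply(windows, `[[`, "vectors"))
    sel <- elbow_select_k(allw, 2:9, seed = 8)
    fit <- sel$models[[as.character(4)]]
    model <- summarize_states(windows, fit$labels, fit$centroids,
                              sel$validity_curve)
    truth_win <- window_truth(cohort, windows)
    mm <- match_state_labels(fit$labels, truth_win, k = 4)
    list(config = cfg, cohort = cohort, windows = windows, elbow = sel,
         model = model, truth_win = truth_win, match = mm,
         est_effect_state = which(mm$perm == cfg$effect_state))
  })
}

# Null study cohort (no group effect), clustered at pinned k = 4.
null_study <- function() {
  cached("null_study", {
    cfg <- cohort_config(effect_delta = 0, seed = 1002)
    cohort <- generate_cohort(cfg)
    windows <- cohort_windows(cohort)
    allw <- do.call(rbind, lapply(windows, `[[`, "vectors"))
    fit <- kmeans_states(allw, 4, seed = 8)
    model <- summarize_states(windows, fit$labels, fit$centroids)
    list(config = cfg, cohort = cohort, windows = windows, model = model)
  })
}

# Small clustered 4-state model with phenotypes for classification tests;
# sparsity 0 so most subjects visit all states.
small_model_fixture <- function() {
  cached("small_model", {
    cfg <- cohort_config(n_per_group = 8, n_components = 12,
                         n_timepoints = 145, n_states = 4, dwell_mean = 30,
                         state_visit_sparsity = 0, seed = 77)
    co <- generate_cohort(cfg)
    windows <- cohort_windows(co)
    allw <- do.call(rbind, lapply(windows, `[[`, "vectors"))
    fit <- kmeans_states(allw, 4, seed = 9)
    model <- summarize_states(windows, fit$labels, fit$centroids)
    all_visited <- vapply(model$subject_state_means,
                          function(m) length(m) == 4, logical(1))
    list(config = cfg, cohort = co, model = model,
         phenotypes = co$phenotypes, all_visited = all_visited)
  })
}

# Map generator effect pairs to column indices of the connectivity vectors.
injected_pair_cols <- function(config, pidx) {
  match(paste(config$effect_pairs[, 1], config$effect_pairs[, 2]),
        paste(pidx[, 1], pidx[, 2]))
}
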