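# End-to-end orchestration: simulate -> filter -> dFNC/sFNC -> states ->
# group stats -> classification -> bootstrap comparison, with delimited-text
# artifacts and a manifest.

#' Pipeline run configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param cohort a [cohort_config()] to simulate, or NULL when reading an
#'   existing cohort from `timecourse_dir`/`phenotype_path`.
#' @param timecourse_dir directory of per-subject time-course TSVs (ignored
#'   when `cohort` is given).
#' @param phenotype_path phenotype TSV path (ignored when `cohort` is given).
#' @param filter a [filter_spec()]; NULL builds one from the TR.
#' @param taper a [taper_spec()].
#' @param k number of states to pin, or NULL to select by the elbow
#'   criterion over `k_range`.
#' @param k_range candidate k values for elbow selection.
#' @param thresholds feature-selection t-thresholds.
#' @param C LS-SVM regularization.
#' @param alpha FDR level.
#' @param cluster_seed,bootstrap_seed seeds for clustering and bootstrap.
#' @param bootstrap_B bootstrap iterations.
#' @param t_mode nested-LOOCV t-value mode, see [nested_loocv()].
#' @param write_windows write each subject's windowed-connectivity TSV
#'   (large; default TRUE).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir,
                            cohort = cohort_config(),
                            timecourse_dir = NULL,
                            phenotype_path = NULL,
                            filter = NULL,
                            taper = taper_spec(),
                            k = NULL,
                            k_range = 2:9,
                            thresholds = c(0, 0.25, 0.5, 0.75, 1, 2),
                            C = 0.1,
                            alpha = 0.05,
                            cluster_seed = 7,
                            bootstrap_seed = 11,
                            bootstrap_B = 10000,
                            t_mode = "inner",
                            write_windows = TRUE) {
  structure(list(out_dir = out_dir, cohort = cohort,
                 timecourse_dir = timecourse_dir,
                 phenotype_path = phenotype_path,
                 filter = filter, taper = taper, k = k, k_range = k_range,
                 thresholds = thresholds, C = C, alpha = alpha,
                 cluster_seed = cluster_seed,
                 bootstrap_seed = bootstrap_seed,
                 bootstrap_B = bootstrap_B, t_mode = t_mode,
                 write_windows = write_windows),
            class = "pipeline_config")
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Read a cohort from delimited-text inputs
#'
#' @param timecourse_dir directory of per-subject TSV matrices (T rows, R
#'   named columns; file name stem = subject id).
#' @param phenotype_path TSV with subject_id, group, sex, age, edu, wtar.
#' @return a list with `subjects` and `phenotypes` as in [generate_cohort()].
#' @export
read_cohort_dir <- function(timecourse_dir, phenotype_path) {
  phen <- utils::read.delim(phenotype_path, stringsAsFactors = FALSE)
  files <- list.files(timecourse_dir, pattern = "\\.tsv$", full.names = TRUE)
  ids <- sub("\\.tsv$", "", basename(files))
  grp <- stats::setNames(phen$group, phen$subject_id)
  subjects <- lapply(seq_along(files), function(i) {
    tc <- as.matrix(utils::read.delim(files[i], check.names = FALSE))
    list(subject_id = ids[i], group = unname(grp[ids[i]]), timecourses = tc)
  })
  list(subjects = subjects, phenotypes = phen)
}

#' Validate pipeline inputs
#'
#' Checks that all time-course matrices share the same shape and finite
#' values, that every subject has a complete phenotype row, and that the
#' group labels are the two expected classes. Returns a machine-readable
#' report rather than failing.
#'
#' @param timecourse_dir directory of per-subject TSVs.
#' @param phenotype_path phenotype TSV.
#' @return list with `ok` (logical) and `issues` (data frame subject_id /
#'   issue).
#' @export
validate_inputs <- function(timecourse_dir, phenotype_path) {
  issues <- list()
  note <- function(id, what)
    issues[[length(issues) + 1]] <<- data.frame(subject_id = id, issue = what)
  phen <- tryCatch(utils::read.delim(phenotype_path,
                                     stringsAsFactors = FALSE),
                   error = function(e) NULL)
  if (is.null(phen)) {
    note("<table>", "phenotype table unreadable")
  } else {
    need <- c("subject_id", "group", "sex", "age", "edu", "wtar")
    miss <- setdiff(need, names(phen))
    if (length(miss))
      note("<table>", paste("missing phenotype columns:",
                            paste(miss, collapse = ", ")))
    if ("group" %in% names(phen) &&
        !all(phen$group %in% c("HC", "mTBI")))
      note("<table>", "group labels not in {HC, mTBI}")
    for (v in intersect(c("age", "edu", "wtar"), names(phen)))
      for (i in which(is.na(phen[[v]])))
        note(phen$subject_id[i], paste("missing", v))
  }
  files <- list.files(timecourse_dir, pattern = "\\.tsv$", full.names = TRUE)
  if (length(files) == 0) note("<dir>", "no time-course files found")
  mats <- lapply(files, function(f)
    tryCatch(as.matrix(utils::read.delim(f, check.names = FALSE)),
             error = function(e) NULL))
  dim_str <- vapply(mats, function(m)
    if (is.null(m)) "" else paste(dim(m), collapse = "x"), character(1))
  ref_dim <- names(sort(table(dim_str[nzchar(dim_str)]),
                        decreasing = TRUE))[1]
  for (q in seq_along(files)) {
    id <- sub("\\.tsv$", "", basename(files[q]))
    tc <- mats[[q]]
    if (is.null(tc)) { note(id, "unreadable time-course file"); next }
    if (!all(is.finite(tc))) note(id, "non-finite values")
    if (!identical(dim_str[q], ref_dim))
      note(id, sprintf("shape %s differs from majority shape %s",
                       dim_str[q], ref_dim))
    if (!is.null(phen) && !(id %in% phen$subject_id))
      note(id, "no phenotype row")
  }
  issues <- if (length(issues)) do.call(rbind, issues)
    else data.frame(subject_id = character(0), issue = character(0))
  list(ok = nrow(issues) == 0, issues = issues)
}

#' Run the full dFNC pipeline
#'
#' Executes simulate (optional) -> band-pass filter -> dFNC/sFNC -> state
#' clustering -> per-state group statistics -> per-state and nested LOOCV
#' classification -> bootstrap comparison against the sFNC baseline, writing
#' every artifact under `config$out_dir` together with a manifest. Fully
#' reproducible for fixed seeds.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with the in-memory results of every stage and
#'   the manifest.
#' @export
run_full_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package_version =
                     as.character(utils::packageVersion("dfncstates")),
                   stages = list())
  stage <- function(name, outputs)
    manifest$stages[[name]] <<- list(outputs = as.character(outputs))
  run <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))

  # -- simulate (or load) ----------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- run("simulate", {
      co <- generate_cohort(config$cohort)
      sim_dir <- file.path(out, "cohort")
      write_cohort(co, sim_dir)
      stage("simulate", sim_dir)
      co
    })
    tr <- config$cohort$tr_seconds
  } else {
    cohort <- run("load", read_cohort_dir(config$timecourse_dir,
                                          config$phenotype_path))
    stage("load", c(config$timecourse_dir, config$phenotype_path))
    tr <- if (!is.null(config$filter)) config$filter$tr_seconds else 2
  }
  phen <- cohort$phenotypes

  # -- filter ----------------------------------------------------------------
  fspec <- if (is.null(config$filter)) filter_spec(tr_seconds = tr)
    else config$filter
  filtered <- run("filter", lapply(cohort$subjects, function(s) {
    s$timecourses <- bandpass(s$timecourses, fspec)
    s
  }))
  stage("filter", write_tsv(
    data.frame(low_hz = fspec$low_hz, high_hz = fspec$high_hz,
               order = fspec$order, tr_seconds = fspec$tr_seconds),
    file.path(out, "filter_spec.tsv")))

  # -- dFNC / sFNC -----------------------------------------------------------
  dfnc_res <- run("dfnc", {
    windows <- lapply(filtered, function(s)
      compute_dfnc(s$timecourses, config$taper, subject_id = s$subject_id))
    sfnc <- t(vapply(filtered, function(s) compute_sfnc(s$timecourses),
                     numeric(nrow(windows[[1]]$pair_index))))
    rownames(sfnc) <- vapply(filtered, `[[`, character(1), "subject_id")
    colnames(sfnc) <- colnames(windows[[1]]$vectors)
    list(windows = windows, sfnc = sfnc)
  })
  outs <- character(0)
  if (isTRUE(config$write_windows)) {
    wdir <- file.path(out, "dfnc_windows")
    dir.create(wdir, showWarnings = FALSE)
    for (w in dfnc_res$windows)
      outs <- c(outs, write_tsv(
        data.frame(window_start = w$window_starts, w$vectors,
                   check.names = FALSE),
        file.path(wdir, paste0(w$subject_id, ".tsv"))))
  }
  outs <- c(outs, write_tsv(
    data.frame(subject_id = rownames(dfnc_res$sfnc), dfnc_res$sfnc,
               check.names = FALSE),
    file.path(out, "sfnc.tsv")))
  stage("dfnc", outs)

  # -- states ----------------------------------------------------------------
  states_res <- run("states", {
    allw <- do.call(rbind, lapply(dfnc_res$windows, `[[`, "vectors"))
    if (is.null(config$k)) {
      sel <- elbow_select_k(allw, config$k_range, seed = config$cluster_seed)
      fit <- sel$models[[as.character(sel$k)]]
      model <- summarize_states(dfnc_res$windows, fit$labels, fit$centroids,
                                validity_curve = sel$validity_curve)
      list(model = model, k_mode = "elbow", curve = sel$validity_curve)
    } else {
      fit <- kmeans_states(allw, config$k, seed = config$cluster_seed)
      model <- summarize_states(dfnc_res$windows, fit$labels, fit$centroids)
      list(model = model, k_mode = "pinned", curve = NULL)
    }
  })
  model <- states_res$model
  outs <- character(0)
  for (s in seq_len(model$k))
    outs <- c(outs, write_tsv(
      as.data.frame(devectorize_conn(model$centroids[s, ])),
      file.path(out, sprintf("state_%d_centroid.tsv", s))))
  outs <- c(outs, write_tsv(model$labels, file.path(out, "window_labels.tsv")))
  occ <- list(k = model$k, k_mode = states_res$k_mode,
              occupancy = model$occupancy,
              subject_counts = model$subject_counts)
  jsonlite::write_json(occ, file.path(out, "state_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  outs <- c(outs, file.path(out, "state_summary.json"))
  if (!is.null(states_res$curve))
    outs <- c(outs, write_tsv(
      data.frame(k = as.integer(names(states_res$curve)),
                 validity = as.numeric(states_res$curve)),
      file.path(out, "validity_curve.tsv")))
  stage("states", outs)

  # -- group stats -----------------------------------------------------------
  stats_res <- run("stats", statewise_group_diff(model, phen, config$alpha))
  outs <- character(0)
  pl <- pair_labels(sprintf("comp%02d", seq_len(max(model$pair_index))))
  for (r in stats_res) {
    if (!isTRUE(r$tested)) next
    outs <- c(outs, write_tsv(
      data.frame(pair = pl, t = r$t_values, p = r$p_values,
                 p_fdr = r$adjusted, significant = r$fdr_mask),
      file.path(out, sprintf("state_%d_group_stats.tsv", r$state))))
  }
  demo <- demographics_table(model, phen)
  outs <- c(outs, write_tsv(demo, file.path(out, "demographics.tsv")))
  sig <- do.call(rbind, lapply(stats_res, function(r)
    if (isTRUE(r$tested) && any(r$fdr_mask))
      data.frame(state = r$state, pair = pl[r$fdr_mask],
                 pair_idx = which(r$fdr_mask),
                 t = r$t_values[r$fdr_mask], p = r$p_values[r$fdr_mask])))
  regress <- NULL
  if (!is.null(sig) && nrow(sig) > 0) {
    outs <- c(outs, write_tsv(sig, file.path(out, "significant_pairs.tsv")))
    regress <- lapply(seq_len(nrow(sig)), function(q) {
      fm <- state_feature_matrix(model, sig$state[q])
      vals <- stats::setNames(fm$x[, sig$pair_idx[q]], fm$subject_id)
      cr <- covariate_regression(vals, phen)
      data.frame(state = sig$state[q], pair = sig$pair[q],
                 coef = names(cr$betas), beta = unname(cr$betas),
                 p = unname(cr$p_values))
    })
    regress <- do.call(rbind, regress)
    outs <- c(outs, write_tsv(regress,
                              file.path(out, "covariate_regression.tsv")))
  }
  stage("stats", outs)

  # -- classification --------------------------------------------------------
  classify_res <- run("classify", {
    per_state <- per_state_loocv_auc(model, phen, config$C)
    nested <- nested_loocv(model, phen, config$thresholds, config$C,
                           t_mode = config$t_mode)
    list(per_state = per_state, nested = nested)
  })
  outs <- character(0)
  auc_tab <- data.frame(
    state = seq_len(model$k),
    n = model$subject_counts,
    auc = vapply(classify_res$per_state, function(r)
      if (is.null(r)) NA_real_ else r$auc, numeric(1)))
  outs <- c(outs, write_tsv(auc_tab, file.path(out, "per_state_auc.tsv")))
  outs <- c(outs, write_tsv(classify_res$nested$per_fold_choice,
                            file.path(out, "nested_per_fold_choice.tsv")))
  outs <- c(outs, write_tsv(
    as.data.frame(classify_res$nested$selection_histogram),
    file.path(out, "nested_selection_histogram.tsv")))
  jsonlite::write_json(
    list(overall_auc = classify_res$nested$overall_auc,
         n_subjects = nrow(classify_res$nested$pooled_scores)),
    file.path(out, "nested_cv_report.json"), auto_unbox = TRUE, digits = NA)
  outs <- c(outs, file.path(out, "nested_cv_report.json"))
  stage("classify", outs)

  # -- compare to static FNC -------------------------------------------------
  compare_res <- run("compare", {
    sfnc_report <- sfnc_nested_loocv(dfnc_res$sfnc, phen, config$thresholds,
                                     config$C, t_mode = config$t_mode)
    boot <- bootstrap_compare(classify_res$nested, sfnc_report,
                              B = config$bootstrap_B,
                              seed = config$bootstrap_seed)
    list(sfnc_report = sfnc_report, bootstrap = boot)
  })
  jsonlite::write_json(
    list(dfnc_auc = classify_res$nested$overall_auc,
         sfnc_auc = compare_res$sfnc_report$overall_auc,
         bootstrap = list(B = config$bootstrap_B, t = compare_res$bootstrap$t,
                          df = compare_res$bootstrap$df,
                          p = compare_res$bootstrap$p)),
    file.path(out, "comparison.json"), auto_unbox = TRUE, digits = NA)
  boot_tab <- write_tsv(
    data.frame(iteration = seq_len(config$bootstrap_B),
               auc_dfnc = compare_res$bootstrap$auc_a,
               auc_sfnc = compare_res$bootstrap$auc_b),
    file.path(out, "bootstrap_auc_samples.tsv"))
  stage("compare", c(file.path(out, "comparison.json"), boot_tab))

  # -- manifest --------------------------------------------------------------
  cfg_path <- file.path(out, "run_config.yaml")
  cfg_echo <- rapply(unclass(config), unclass, how = "replace")
  cfg_echo$cohort <- if (!is.null(config$cohort))
    lapply(unclass(config$cohort), function(v)
      if (is.matrix(v)) apply(v, 1, as.list) else v)
  yaml::write_yaml(cfg_echo, cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, filter = fspec, dfnc = dfnc_res,
                 states = states_res, stats = stats_res,
                 classify = classify_res, compare = compare_res,
                 manifest = manifest))
}
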