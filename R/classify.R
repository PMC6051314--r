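# Least-squares linear SVM classification of subjects from per-state
# connectivity features, with leave-one-out and nested leave-one-out
# cross-validation and a bootstrap comparison against the static-FNC
# baseline.

# Solve the LS-SVM linear system in (bias, dual coefficients) for a linear
# kernel matrix K: [0, y'; y, y y' * K + I/C] [b; alpha] = [0; 1].
lssvm_solve_kernel <- function(kmat, y, C) {
  n <- length(y)
  omega <- kmat * tcrossprod(y) + diag(n) / C
  a <- rbind(c(0, y), cbind(y, omega))
  sol <- unname(solve(a, c(0, rep(1, n))))
  list(bias = sol[1], alpha = sol[-1])
}

#' Train a least-squares linear SVM
#'
#' LS-SVM with linear kernel and squared-slack (equality-constraint)
#' formulation: the dual is a single linear system, so training is
#' deterministic. Equivalent to ridge regression on +/-1 targets with an
#' unpenalized intercept and penalty 1/C; the per-point penalty convention
#' means duplicating every training point is the same as doubling C.
#'
#' @param x n x P feature matrix.
#' @param y labels in {-1, +1} (numeric) with both classes present.
#' @param C soft-margin regularization (default 0.1).
#' @param feature_index optional indices of the columns of the original
#'   feature space that `x` represents (bookkeeping only).
#' @return object of class `lssvm`: list with `weights`, `bias`, `C`,
#'   `feature_index`.
#' @export
lssvm_train <- function(x, y, C = 0.1, feature_index = NULL) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y), nrow(x) >= 2, all(y %in% c(-1, 1)))
  if (length(unique(y)) < 2) stop("both classes must be present")
  sol <- lssvm_solve_kernel(tcrossprod(x), y, C)
  w <- drop(crossprod(x, sol$alpha * y))
  structure(list(weights = w, bias = sol$bias, C = C,
                 feature_index = feature_index),
            class = "lssvm")
}

#' Decision values of a trained LS-SVM
#'
#' @param model an `lssvm` model.
#' @param x feature matrix (columns matching the training features).
#' @return numeric decision values `x %*% weights + bias`.
#' @export
lssvm_decision <- function(model, x) {
  stopifnot(inherits(model, "lssvm"))
  x <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  drop(x %*% model$weights + model$bias)
}

#' Area under the ROC curve
#'
#' Rank-based AUC, identical to the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`, with ties counted one half.
#'
#' @param scores numeric decision values (higher = more positive-like).
#' @param labels numeric +/-1 labels (+1 is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(-1, 1)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == -1)
  if (n_pos == 0 || n_neg == 0) stop("both classes required for AUC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

group_to_y <- function(group) {
  stopifnot(all(group %in% c("HC", "mTBI")))
  ifelse(group == "mTBI", 1, -1)
}

#' Leave-one-out LS-SVM AUC for one state
#'
#' For every subject in the state's roster: train on the rest using all
#' connectivity features, score the held-out subject; the AUC is computed on
#' the pooled held-out decision values. Also returns the fold-averaged
#' weight vector.
#'
#' @param x n x P matrix of subject representative vectors for the state.
#' @param y numeric +/-1 labels.
#' @param C regularization (default 0.1).
#' @return list with `auc`, `scores`, `mean_weights`; `NULL` (with a
#'   message) if the roster has fewer than 4 subjects or one class.
#' @export
loocv_state_auc <- function(x, y, C = 0.1) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 4 || length(unique(y)) < 2) {
    message("state untestable: roster < 4 subjects or single class")
    return(NULL)
  }
  kmat <- tcrossprod(x)
  scores <- numeric(n)
  wsum <- numeric(ncol(x))
  for (i in seq_len(n)) {
    sol <- lssvm_solve_kernel(kmat[-i, -i, drop = FALSE], y[-i], C)
    scores[i] <- sum(kmat[i, -i] * (sol$alpha * y[-i])) + sol$bias
    wsum <- wsum + drop(crossprod(x[-i, , drop = FALSE], sol$alpha * y[-i]))
  }
  list(auc = roc_auc(scores, y), scores = scores, mean_weights = wsum / n)
}

#' Per-state LOOCV AUCs for a state model
#'
#' @param model a `dfnc_state_model`.
#' @param phenotypes phenotype data frame with subject_id and group.
#' @param C regularization.
#' @return list per state with `auc`, `scores`, `mean_weights`,
#'   `subject_id` (NULL entries for untestable states).
#' @export
per_state_loocv_auc <- function(model, phenotypes, C = 0.1) {
  grp <- stats::setNames(phenotypes$group, phenotypes$subject_id)
  out <- vector("list", model$k)
  for (s in seq_len(model$k)) {
    fm <- state_feature_matrix(model, s)
    if (is.null(fm$x)) { out[s] <- list(NULL); next }
    res <- loocv_state_auc(fm$x, group_to_y(grp[fm$subject_id]), C)
    if (!is.null(res)) res$subject_id <- fm$subject_id
    out[s] <- list(res)
  }
  out
}

# Column-wise pooled t downdated by removing one row; sums-based so the
# inner CV loop stays O(P) per fold.
t_from_sums <- function(s_pos, q_pos, n_pos, s_neg, q_neg, n_neg) {
  m_pos <- s_pos / n_pos; m_neg <- s_neg / n_neg
  v_pos <- q_pos - n_pos * m_pos^2
  v_neg <- q_neg - n_neg * m_neg^2
  df <- n_pos + n_neg - 2
  sp2 <- (v_pos + v_neg) / df
  sp2[sp2 <= 0] <- Inf
  (m_pos - m_neg) / sqrt(sp2 * (1 / n_pos + 1 / n_neg))
}

# Nested LOOCV engine shared by the dFNC (multi-state) and sFNC
# (single-state) front ends. state_x: list of per-state feature matrices
# with rownames = subject ids; subjects: outer-loop subject ids; y_all:
# named +/-1 labels.
nested_loocv_engine <- function(state_x, subjects, y_all, thresholds, C,
                                t_mode = c("inner", "outer")) {
  t_mode <- match.arg(t_mode)
  thresholds <- sort(thresholds)
  n_states <- length(state_x)
  visited <- lapply(state_x, rownames)
  can_do <- vapply(subjects, function(id)
    any(vapply(visited, function(v) id %in% v, logical(1))), logical(1))
  if (any(!can_do))
    warning(sprintf("%d subject(s) visit no state and are excluded: %s",
                    sum(!can_do),
                    paste(subjects[!can_do], collapse = ", ")))
  subjects <- subjects[can_do]
  choices <- list()
  scores <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  wsum <- vector("list", n_states)
  wcnt <- integer(n_states)
  n_candidates <- integer(length(subjects))
  for (oi in seq_along(subjects)) {
    id <- subjects[oi]
    best <- NULL
    for (s in seq_len(n_states)) {
      if (!(id %in% visited[[s]])) next
      xs <- state_x[[s]]
      tr_ids <- setdiff(rownames(xs), id)
      xtr <- xs[tr_ids, , drop = FALSE]
      ytr <- y_all[tr_ids]
      if (length(tr_ids) < 3 || length(unique(ytr)) < 2) next
      inner <- nested_inner_aucs(xtr, ytr, thresholds, C, t_mode)
      n_candidates[oi] <- n_candidates[oi] + length(thresholds)
      for (ti in seq_along(thresholds)) {
        auc <- inner[ti]
        if (is.na(auc)) next
        take <- is.null(best) || auc > best$auc + 1e-12 ||
          (abs(auc - best$auc) <= 1e-12 &&
             (thresholds[ti] > best$tau ||
                (thresholds[ti] == best$tau && s < best$state)))
        if (take) best <- list(state = s, tau = thresholds[ti], auc = auc)
      }
    }
    if (is.null(best)) {
      warning(sprintf("no trainable candidate for subject %s; skipped", id))
      next
    }
    xs <- state_x[[best$state]]
    tr_ids <- setdiff(rownames(xs), id)
    xtr <- xs[tr_ids, , drop = FALSE]
    ytr <- y_all[tr_ids]
    tt <- col_group_ttest(xtr[ytr == -1, , drop = FALSE],
                          xtr[ytr == 1, , drop = FALSE])
    sel <- which(abs(tt$t) > best$tau)
    if (length(sel) == 0) {
      fit <- list(weights = numeric(0), bias = mean(ytr))
      scores[oi] <- fit$bias
      n_feat <- 0L
    } else {
      fit <- lssvm_train(xtr[, sel, drop = FALSE], ytr, C,
                         feature_index = sel)
      scores[oi] <- lssvm_decision(fit, xs[id, sel, drop = FALSE])
      n_feat <- length(sel)
      wfull <- numeric(ncol(xs)); wfull[sel] <- fit$weights
      if (is.null(wsum[[best$state]])) wsum[[best$state]] <- wfull
      else wsum[[best$state]] <- wsum[[best$state]] + wfull
      wcnt[best$state] <- wcnt[best$state] + 1L
    }
    choices[[length(choices) + 1]] <- data.frame(
      subject_id = id, state = best$state, threshold = best$tau,
      inner_auc = best$auc, n_features = n_feat)
  }
  per_fold <- do.call(rbind, choices)
  keep <- !is.na(scores)
  y_out <- y_all[subjects[keep]]
  overall <- roc_auc(scores[keep], y_out)
  hist <- table(state = factor(per_fold$state, levels = seq_len(n_states)),
                threshold = factor(per_fold$threshold, levels = thresholds))
  mean_weights <- lapply(seq_len(n_states), function(s)
    if (wcnt[s] > 0) wsum[[s]] / wcnt[s] else NULL)
  structure(list(overall_auc = overall,
                 pooled_scores = data.frame(subject_id = subjects[keep],
                                            score = scores[keep],
                                            label = y_out),
                 per_fold_choice = per_fold,
                 selection_histogram = hist,
                 n_candidates = stats::setNames(n_candidates, subjects),
                 mean_weights = mean_weights,
                 thresholds = thresholds, C = C,
                 excluded_subjects = names(can_do)[!can_do]),
            class = "cv_report")
}

# Inner LOOCV AUC for each threshold within one (outer fold, state)
# candidate. Feature-selection t-values are recomputed on each inner
# training subset (t_mode = "inner", the leakage-safe default) or once on
# the outer training set (t_mode = "outer"). Kernels for the nested feature
# sets are built incrementally from the largest threshold down.
nested_inner_aucs <- function(xtr, ytr, thresholds, C, t_mode) {
  n <- nrow(xtr)
  pos <- ytr == 1; neg <- !pos
  if (sum(pos) < 2 || sum(neg) < 2) return(rep(NA_real_, length(thresholds)))
  s_pos <- colSums(xtr[pos, , drop = FALSE])
  q_pos <- colSums(xtr[pos, , drop = FALSE]^2)
  s_neg <- colSums(xtr[neg, , drop = FALSE])
  q_neg <- colSums(xtr[neg, , drop = FALSE]^2)
  if (t_mode == "outer")
    t_outer <- t_from_sums(s_pos, q_pos, sum(pos), s_neg, q_neg, sum(neg))
  ord_thr <- order(thresholds, decreasing = TRUE)
  inner_scores <- matrix(NA_real_, n, length(thresholds))
  for (j in seq_len(n)) {
    if (pos[j] && sum(pos) - 1 < 2) next
    if (neg[j] && sum(neg) - 1 < 2) next
    if (t_mode == "inner") {
      xj <- xtr[j, ]
      if (pos[j]) {
        tv <- t_from_sums(s_pos - xj, q_pos - xj^2, sum(pos) - 1,
                          s_neg, q_neg, sum(neg))
      } else {
        tv <- t_from_sums(s_pos, q_pos, sum(pos),
                          s_neg - xj, q_neg - xj^2, sum(neg) - 1)
      }
    } else {
      tv <- t_outer
    }
    at <- abs(tv)
    ord <- order(at, decreasing = TRUE)
    at_sorted <- at[ord]
    kacc <- matrix(0, n, n)
    used <- 0L
    yj <- ytr[-j]
    for (q in ord_thr) {
      m <- sum(at_sorted > thresholds[q])
      if (m > used) {
        new_idx <- ord[(used + 1L):m]
        kacc <- kacc + tcrossprod(xtr[, new_idx, drop = FALSE])
        used <- m
      }
      sol <- lssvm_solve_kernel(kacc[-j, -j, drop = FALSE], yj, C)
      inner_scores[j, q] <- sum(kacc[j, -j] * (sol$alpha * yj)) + sol$bias
    }
  }
  vapply(seq_along(thresholds), function(q) {
    ok <- !is.na(inner_scores[, q])
    if (sum(ytr[ok] == 1) == 0 || sum(ytr[ok] == -1) == 0) return(NA_real_)
    roc_auc(inner_scores[ok, q], ytr[ok])
  }, numeric(1))
}

#' Nested leave-one-out cross-validation with joint state and threshold
#' selection
#'
#' Outer loop over subjects. For each outer fold the candidate set is every
#' (state, t-threshold) combination for a state the left-out subject
#' visited; each candidate is evaluated by an inner LOOCV over the outer
#' training subjects of that state, with features restricted to pairs whose
#' group-difference |t| (computed on the inner training subset) exceeds the
#' threshold. The candidate with the largest inner AUC (ties: larger
#' threshold, then lower state index) is retrained on the full outer
#' training roster and scores the left-out subject. The overall AUC pools
#' the outer held-out scores.
#'
#' @param model a `dfnc_state_model`.
#' @param phenotypes phenotype data frame with subject_id and group.
#' @param thresholds t-value thresholds (default c(0, 0.25, 0.5, 0.75, 1, 2)).
#' @param C LS-SVM regularization (default 0.1).
#' @param t_mode `"inner"` (recompute selection t-values inside each inner
#'   fold; leakage-safe default) or `"outer"` (compute once per outer
#'   training set).
#' @return object of class `cv_report`: `overall_auc`, `pooled_scores`,
#'   `per_fold_choice`, `selection_histogram`, `n_candidates`,
#'   `mean_weights`, `excluded_subjects`.
#' @export
nested_loocv <- function(model, phenotypes,
                         thresholds = c(0, 0.25, 0.5, 0.75, 1, 2),
                         C = 0.1, t_mode = c("inner", "outer")) {
  stopifnot(inherits(model, "dfnc_state_model"))
  grp <- stats::setNames(phenotypes$group, phenotypes$subject_id)
  state_x <- lapply(seq_len(model$k), function(s) {
    fm <- state_feature_matrix(model, s)
    if (is.null(fm$x)) return(matrix(numeric(0), 0, nrow(model$pair_index)))
    rownames(fm$x) <- fm$subject_id
    fm$x
  })
  subjects <- names(model$subject_state_means)
  nested_loocv_engine(state_x, subjects, group_to_y(grp)[subjects],
                      thresholds, C, match.arg(t_mode))
}

#' Nested LOOCV for the static-FNC baseline
#'
#' Same procedure as [nested_loocv()] with a single "state" containing all
#' subjects, so the selection is over t-thresholds only.
#'
#' @param sfnc_x n x P matrix of per-subject static connectivity vectors
#'   with subject ids as rownames.
#' @param phenotypes phenotype data frame.
#' @inheritParams nested_loocv
#' @return a `cv_report`.
#' @export
sfnc_nested_loocv <- function(sfnc_x, phenotypes,
                              thresholds = c(0, 0.25, 0.5, 0.75, 1, 2),
                              C = 0.1, t_mode = c("inner", "outer")) {
  sfnc_x <- as.matrix(sfnc_x)
  stopifnot(!is.null(rownames(sfnc_x)))
  grp <- stats::setNames(phenotypes$group, phenotypes$subject_id)
  subjects <- rownames(sfnc_x)
  nested_loocv_engine(list(sfnc_x), subjects, group_to_y(grp)[subjects],
                      thresholds, C, match.arg(t_mode))
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("cv_report: overall AUC = %.3f over %d subjects\n",
              x$overall_auc, nrow(x$pooled_scores)))
  print(x$selection_histogram)
  invisible(x)
}

#' Bootstrap comparison of two cross-validated classifiers
#'
#' Resamples each report's pooled held-out (score, label) pairs B times
#' (subjects drawn with replacement, stratified by class so every resample
#' contains both classes), computes the AUC of each resample, and compares
#' the two bootstrap AUC samples with a pooled two-sample t-test
#' (df = 2B - 2).
#'
#' @param report_a,report_b `cv_report` objects.
#' @param B bootstrap iterations (default 10000).
#' @param seed integer seed.
#' @return list with `auc_a`, `auc_b` (B-vectors), `t`, `df`, `p`,
#'   `sd_pooled`.
#' @export
bootstrap_compare <- function(report_a, report_b, B = 10000, seed = 1) {
  stopifnot(inherits(report_a, "cv_report"), inherits(report_b, "cv_report"))
  boot_aucs <- function(report) {
    sc <- report$pooled_scores$score
    lb <- report$pooled_scores$label
    pos <- which(lb == 1); neg <- which(lb == -1)
    vapply(seq_len(B), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      roc_auc(sc[idx], lb[idx])
    }, numeric(1))
  }
  withr::with_seed(seed, {
    auc_a <- boot_aucs(report_a)
    auc_b <- boot_aucs(report_b)
    if (stats::var(auc_a) + stats::var(auc_b) == 0) {
      # both classifiers at a fixed AUC in every resample (tiny cohorts)
      warning("degenerate bootstrap: zero AUC variance in both samples")
      tt <- list(t = if (mean(auc_a) == mean(auc_b)) 0 else
        sign(mean(auc_b) - mean(auc_a)) * Inf,
        p = if (mean(auc_a) == mean(auc_b)) 1 else 0, df = 2 * B - 2)
    } else {
      tt <- two_sample_t(auc_a, auc_b)
    }
    list(auc_a = auc_a, auc_b = auc_b, t = tt$t, df = tt$df, p = tt$p,
         sd_pooled = sqrt(((B - 1) * stats::var(auc_a) +
                             (B - 1) * stats::var(auc_b)) / tt$df))
  })
}
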