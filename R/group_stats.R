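# Per-state mass-univariate group comparison, demographic statistics and
# covariate regression.

#' Pooled-variance two-sample t-test
#'
#' Two-sided t-test with pooled variance and df = n_a + n_b - 2. The sign
#' convention is `mean(b) - mean(a)`: with a = controls and b = patients the
#' statistic reads patient minus control.
#'
#' @param a,b numeric sample vectors (each of length >= 2).
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2, all(is.finite(c(a, b))))
  two_sample_t_from_summary(mean(a), stats::sd(a), length(a),
                            mean(b), stats::sd(b), length(b))
}

#' Pooled-variance two-sample t-test from summary statistics
#'
#' Same statistic as [two_sample_t()] computed from per-group means,
#' standard deviations and counts; sign is `m2 - m1`.
#'
#' @param m1,s1,n1 mean, sd, count of group 1.
#' @param m2,s2,n2 mean, sd, count of group 2.
#' @return list with `t`, `p`, `df`.
#' @export
two_sample_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, s1 >= 0, s2 >= 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / df
  if (sp2 <= 0) stop("zero pooled variance")
  t <- (m2 - m1) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

# Column-wise pooled t over two row-blocks; returns t and p vectors.
# Zero-pooled-variance columns get t = 0, p = 1 with a warning.
col_group_ttest <- function(xa, xb) {
  na <- nrow(xa); nb <- nrow(xb)
  stopifnot(na >= 2, nb >= 2, ncol(xa) == ncol(xb))
  ma <- colMeans(xa); mb <- colMeans(xb)
  va <- colSums(sweep(xa, 2, ma)^2)
  vb <- colSums(sweep(xb, 2, mb)^2)
  df <- na + nb - 2
  sp2 <- (va + vb) / df
  bad <- sp2 <= 0
  if (any(bad)) {
    warning(sprintf("%d zero-variance pair(s); t set to 0", sum(bad)))
    sp2[bad] <- 1
  }
  t <- (mb - ma) / sqrt(sp2 * (1 / na + 1 / nb))
  t[bad] <- 0
  list(t = t, p = 2 * stats::pt(-abs(t), df), df = df)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability method: the sum of
#' hypergeometric probabilities of tables no more probable than the observed
#' one (the convention of `stats::fisher.test`, which performs the
#' computation).
#'
#' @param tab 2x2 matrix of nonnegative integer counts with positive margins.
#' @return p-value in (0, 1].
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(dim(tab) == 2), all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("table margins must be positive")
  stats::fisher.test(tab)$p.value
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment; the mask flags hypotheses whose adjusted p-value
#' is at or below `alpha`.
#'
#' @param p_values vector of p-values in `[0, 1]`.
#' @param alpha FDR level (default 0.05).
#' @return list with `mask` (logical) and `adjusted` (numeric).
#' @export
fdr_bh <- function(p_values, alpha = 0.05) {
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adjusted <- stats::p.adjust(p_values, method = "BH")
  list(mask = adjusted <= alpha, adjusted = adjusted)
}

#' Per-state mass-univariate group differences with FDR control
#'
#' For each state, runs a pooled two-sample t-test (patient minus control)
#' on every connectivity pair using the subjects who visited the state, and
#' applies Benjamini-Hochberg FDR within that state's family of
#' R(R-1)/2 tests. States with fewer than two subjects in either group are
#' reported as untested.
#'
#' @param model a `dfnc_state_model`.
#' @param phenotypes phenotype data frame with `subject_id` and `group`
#'   (`"HC"` / `"mTBI"`).
#' @param alpha FDR level (default 0.05).
#' @return list (one element per state) of `group_stats_result` lists:
#'   `state`, `tested`, `t_values`, `p_values`, `fdr_mask`, `adjusted`,
#'   `alpha`, `n_hc`, `n_mtbi`.
#' @export
statewise_group_diff <- function(model, phenotypes, alpha = 0.05) {
  stopifnot(inherits(model, "dfnc_state_model"))
  grp <- stats::setNames(phenotypes$group, phenotypes$subject_id)
  out <- vector("list", model$k)
  for (s in seq_len(model$k)) {
    fm <- state_feature_matrix(model, s)
    g <- grp[fm$subject_id]
    n_hc <- sum(g == "HC"); n_mtbi <- sum(g == "mTBI")
    if (is.null(fm$x) || n_hc < 2 || n_mtbi < 2) {
      message(sprintf("state %d untested (HC = %d, mTBI = %d)",
                      s, n_hc, n_mtbi))
      out[[s]] <- list(state = s, tested = FALSE, n_hc = n_hc,
                       n_mtbi = n_mtbi, alpha = alpha)
      next
    }
    tt <- col_group_ttest(fm$x[g == "HC", , drop = FALSE],
                          fm$x[g == "mTBI", , drop = FALSE])
    fdr <- fdr_bh(tt$p, alpha)
    out[[s]] <- list(state = s, tested = TRUE, t_values = tt$t,
                     p_values = tt$p, fdr_mask = fdr$mask,
                     adjusted = fdr$adjusted, alpha = alpha,
                     n_hc = n_hc, n_mtbi = n_mtbi)
  }
  out
}

#' Covariate regression of a connectivity value on phenotypes
#'
#' Ordinary least squares of one pair's per-subject connectivity value on
#' intercept + sex + age + education + WTAR, with per-coefficient two-sided
#' t-tests.
#'
#' @param values named numeric vector of per-subject connectivity values
#'   (names are subject ids) or unnamed vector aligned with `phenotypes`.
#' @param phenotypes phenotype data frame (subject_id, sex, age, edu, wtar).
#' @return list with `betas` and `p_values` (named by coefficient), and the
#'   fitted `lm` object.
#' @export
covariate_regression <- function(values, phenotypes) {
  ph <- phenotypes
  if (!is.null(names(values))) {
    ph <- ph[match(names(values), ph$subject_id), , drop = FALSE]
  }
  stopifnot(length(values) == nrow(ph),
            !anyNA(ph[, c("sex", "age", "edu", "wtar")]))
  dat <- data.frame(y = as.numeric(values),
                    sex = as.numeric(factor(ph$sex, levels = c("F", "M"))) - 1,
                    age = ph$age, edu = ph$edu, wtar = ph$wtar)
  fit <- stats::lm(y ~ sex + age + edu + wtar, data = dat)
  cf <- stats::coef(fit)
  if (anyNA(cf))
    stop("rank-deficient design; collinear columns: ",
         paste(names(cf)[is.na(cf)], collapse = ", "))
  sm <- summary(fit)$coefficients
  list(betas = cf, p_values = sm[, "Pr(>|t|)"], fit = fit)
}

#' Demographic table statistics per state
#'
#' Reproduces the layout of a per-state demographics table: Fisher's exact
#' test on the sex split and pooled two-sample t-tests (patient minus
#' control) on age, education and WTAR, for the full cohort and for each
#' state's roster.
#'
#' @param model a `dfnc_state_model` (or NULL for the all-subjects rows
#'   only).
#' @param phenotypes phenotype data frame.
#' @return data frame with one row per (scope, variable).
#' @export
demographics_table <- function(model = NULL, phenotypes) {
  scopes <- list(`All subjects` = phenotypes$subject_id)
  if (!is.null(model))
    for (s in seq_len(model$k))
      scopes[[sprintf("State %d", s)]] <- model$rosters[[s]]
  rows <- list()
  for (nm in names(scopes)) {
    ph <- phenotypes[phenotypes$subject_id %in% scopes[[nm]], , drop = FALSE]
    hc <- ph[ph$group == "HC", ]; tb <- ph[ph$group == "mTBI", ]
    tab <- table(factor(ph$group, c("HC", "mTBI")),
                 factor(ph$sex, c("M", "F")))
    p_sex <- if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      NA_real_ else fisher_exact_2x2(tab)
    rows[[length(rows) + 1]] <- data.frame(
      scope = nm, variable = "sex", t = NA_real_, p = p_sex)
    for (v in c("age", "edu", "wtar")) {
      tt <- if (nrow(hc) >= 2 && nrow(tb) >= 2)
        two_sample_t(hc[[v]], tb[[v]]) else list(t = NA_real_, p = NA_real_)
      rows[[length(rows) + 1]] <- data.frame(
        scope = nm, variable = v, t = tt$t, p = tt$p)
    }
  }
  do.call(rbind, rows)
}
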