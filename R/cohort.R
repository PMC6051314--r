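# Synthetic state-switching cohort generator.
#
# Emulates a resting-state study cohort: per subject a T x R matrix of
# component time courses whose correlation structure switches among K latent
# "brain states" following a first-order Markov chain, plus a phenotype table
# (group, sex, age, education, WTAR). One state can carry a group effect on a
# configurable set of component pairs (e.g. a cerebellum x sensorimotor-like
# block), which downstream group statistics and classifiers should recover.

#' Configuration for the synthetic cohort generator
#'
#' Defaults mirror a 96-subject case-control resting-state cohort: 48
#' subjects per group, R = 48 components, T = 145 timepoints at TR = 2 s,
#' and K = 4 latent connectivity states. Components are partitioned into
#' network-like blocks; each state elevates the correlations of a distinct
#' pair of blocks, so states are well separated in connectivity space. The
#' patient group additionally receives `effect_delta` extra correlation on
#' `effect_pairs` but only while in `effect_state`.
#'
#' @param n_per_group subjects per group (HC and patient), default 48.
#' @param n_components number of components R, default 48.
#' @param n_timepoints scan length T in timepoints, default 145.
#' @param tr_seconds sampling interval in seconds, default 2.
#' @param n_states number of latent states K, default 4.
#' @param dwell_mean mean state dwell time in timepoints (geometric dwell of
#'   a Markov chain with self-transition probability `1 - 1/dwell_mean`),
#'   scalar or per-state vector. The K = 4 default `c(40, 50, 75, 75)`
#'   keeps every dwell comfortably above the sliding-window length and
#'   gives the two rarely-visited states longer dwells, so that population
#'   occupancy stays roughly balanced even though their rosters are small
#'   (per-state dwell differences of this size are a routine empirical
#'   finding for connectivity states); other K default to 50 everywhere.
#' @param blocks integer vector of length R assigning components to
#'   network-like blocks; defaults to up to 2K near-equal blocks.
#' @param state_block_spec list of K data frames with columns `block_a`,
#'   `block_b`, `level` giving the target correlation between (or within,
#'   when equal) blocks for each state; `NULL` builds a default in which
#'   every state elevates a distinct block pair.
#' @param base_within background within-block correlation shared by all
#'   states, default 0.10.
#' @param state_factor_var variance of a dense rank-one signature added to
#'   each state's correlation matrix (entries of the factor are
#'   `+/- sqrt(state_factor_var)` in a fixed per-state sign pattern, the
#'   same for both groups; the matrix is renormalized to unit diagonal).
#'   Scalar or per-state vector. This gives every state a broad,
#'   state-specific correlation pattern on top of the shared modular
#'   backbone — the way empirical connectivity states differ — and
#'   separates the states far enough that window assignment and
#'   elbow-based model selection are limited by the effect structure, not
#'   by state confusability. The K = 4 default `c(0.375, 0.25, 0.25,
#'   0.25)` gives the dominant state a somewhat stronger signature, so the
#'   state geometry is not perfectly regular (coarse clusterings are then
#'   unique instead of degenerate ties); other K default to 0.
#' @param effect_state index of the state carrying the group effect
#'   (default: state 2, or state 1 when only one state exists).
#' @param effect_pairs two-column matrix of component pairs (i < j) receiving
#'   the group effect; `NULL` picks 4 pairs spanning the two blocks elevated
#'   in `effect_state`.
#' @param effect_delta correlation-scale increment added for patients in
#'   `effect_state`, default 0.3.
#' @param trend_delta strength of a broad, weak connectivity increase for
#'   patients in `effect_state`, implemented as a rank-one shared-signal
#'   factor loading 1 on `trend_block` components and 1/2 elsewhere, scaled
#'   so pairs linking `trend_block` to the rest of the brain gain about
#'   `trend_delta` correlation (remaining pairs gain `trend_delta/2`).
#'   Being a positive-semidefinite increment it cannot break positive
#'   definiteness. Emulates a diffuse sub-threshold trend surrounding a few
#'   strong focal effects: individually too weak to survive FDR, but
#'   jointly informative for a multivariate classifier. Defaults to
#'   `effect_delta / 4` (so a null focal effect implies no trend); set to 0
#'   for a purely focal effect.
#' @param trend_block block whose connections carry the weak trend; defaults
#'   to the first block of the effect state's cross-block pair.
#' @param state_visit_sparsity probability that a subject never enters a
#'   given non-dominant state; a scalar (recycled) or a length-K vector.
#'   The K = 4 default `c(0, 0.03, 0.40, 0.35)` emulates a cohort where
#'   nearly everyone visits the two high-occupancy states while only about
#'   half the subjects enter each of the two low-occupancy states; other K
#'   default to 0.25 for all non-dominant states.
#' @param dominant_state state every subject may visit, default 1.
#' @param phenotype_params list of phenotype distribution parameters; see
#'   defaults in the function body (age/education/WTAR means and sds per
#'   group, male fraction).
#' @param smooth_ma moving-average length applied to the innovations before
#'   imposing state covariance; 1 disables (default; the emission model is
#'   then conditionally independent Gaussian given the state).
#' @param pd_repair_tol maximum tolerated change of a requested entry when a
#'   state correlation matrix needs nearest-positive-definite repair.
#' @param seed integer seed making the cohort reproducible.
#' @return an object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_per_group = 48,
                          n_components = 48,
                          n_timepoints = 145,
                          tr_seconds = 2,
                          n_states = 4,
                          dwell_mean = NULL,
                          blocks = NULL,
                          state_block_spec = NULL,
                          base_within = 0.10,
                          state_factor_var = NULL,
                          effect_state = NULL,
                          effect_pairs = NULL,
                          effect_delta = 0.3,
                          trend_delta = NULL,
                          trend_block = NULL,
                          state_visit_sparsity = NULL,
                          dominant_state = 1,
                          phenotype_params = NULL,
                          smooth_ma = 1,
                          pd_repair_tol = 0.01,
                          seed = 1001) {
  if (is.null(effect_state)) effect_state <- min(2L, n_states)
  if (is.null(dwell_mean))
    dwell_mean <- if (n_states == 4) c(40, 50, 75, 75) else 50
  dwell_mean <- rep_len(dwell_mean, n_states)
  stopifnot(n_per_group >= 1, n_components >= 2, n_timepoints >= 2,
            tr_seconds > 0, n_states >= 1, all(dwell_mean >= 1),
            effect_state >= 1, effect_state <= n_states,
            dominant_state >= 1, dominant_state <= n_states,
            smooth_ma >= 1)
  if (is.null(state_visit_sparsity))
    state_visit_sparsity <- if (n_states == 4) c(0, 0.03, 0.40, 0.35)
      else 0.25
  state_visit_sparsity <- rep_len(state_visit_sparsity, n_states)
  stopifnot(all(state_visit_sparsity >= 0), all(state_visit_sparsity < 1))
  if (abs(effect_delta) >= 1)
    stop("effect_delta must keep correlations inside (-1, 1)")
  if (is.null(blocks)) {
    n_blocks <- min(2L * n_states, max(2L, n_components %/% 2L))
    blocks <- sort(rep_len(seq_len(n_blocks), n_components))
  }
  stopifnot(length(blocks) == n_components)
  if (is.null(state_block_spec))
    state_block_spec <- default_state_block_spec(n_states, max(blocks))
  stopifnot(length(state_block_spec) == n_states)
  if (is.null(state_factor_var))
    state_factor_var <- if (n_states == 4) c(0.375, 0.25, 0.25, 0.25) else 0
  state_factor_var <- rep_len(state_factor_var, n_states)
  stopifnot(all(state_factor_var >= 0), all(state_factor_var < 1))
  sp <- state_block_spec[[effect_state]]
  cross <- sp[sp$block_a != sp$block_b, , drop = FALSE]
  if (nrow(cross) == 0) cross <- sp[1, , drop = FALSE]
  # use the state's last (most specific) cross link for the group effect
  cross <- cross[nrow(cross), , drop = FALSE]
  if (is.null(effect_pairs)) {
    a <- which(blocks == cross$block_a[1])
    b <- which(blocks == cross$block_b[1])
    if (cross$block_a[1] == cross$block_b[1]) {
      # degenerate spec with no cross-block link: place the effect on
      # pairs inside the single block
      cmb <- utils::combn(a, 2)
      keep <- seq_len(min(4L, ncol(cmb)))
      effect_pairs <- cbind(i = cmb[1, keep], j = cmb[2, keep])
    } else {
      # pair distinct components so no 2x2 effect sub-block concentrates
      # the perturbation (kinder to positive definiteness)
      n_eff <- min(4L, length(a), length(b))
      effect_pairs <- cbind(i = pmin(a[1:n_eff], b[1:n_eff]),
                            j = pmax(a[1:n_eff], b[1:n_eff]))
    }
  }
  if (is.null(trend_block)) trend_block <- cross$block_a[1]
  if (is.null(trend_delta)) trend_delta <- effect_delta / 4
  stopifnot(trend_delta >= 0, trend_delta < 0.5, trend_block %in% blocks)
  effect_pairs <- as.matrix(effect_pairs)
  stopifnot(ncol(effect_pairs) == 2, all(effect_pairs >= 1),
            all(effect_pairs <= n_components),
            all(effect_pairs[, 1] < effect_pairs[, 2]))
  if (is.null(phenotype_params)) {
    phenotype_params <- list(
      age  = c(mean = 27.5, sd = 9.0),
      edu_hc    = c(mean = 13.9, sd = 2.1),
      edu_case  = c(mean = 13.1, sd = 2.3),
      wtar_hc   = c(mean = 55.5, sd = 7.4),
      wtar_case = c(mean = 50.1, sd = 8.7),
      male_frac = 23 / 48)
  }
  cfg <- list(n_per_group = as.integer(n_per_group),
              n_components = as.integer(n_components),
              n_timepoints = as.integer(n_timepoints),
              tr_seconds = tr_seconds,
              n_states = as.integer(n_states),
              dwell_mean = dwell_mean,
              blocks = as.integer(blocks),
              state_block_spec = state_block_spec,
              base_within = base_within,
              state_factor_var = state_factor_var,
              effect_state = as.integer(effect_state),
              effect_pairs = effect_pairs,
              effect_delta = effect_delta,
              trend_delta = trend_delta,
              trend_block = as.integer(trend_block),
              state_visit_sparsity = state_visit_sparsity,
              dominant_state = as.integer(dominant_state),
              phenotype_params = phenotype_params,
              smooth_ma = as.integer(smooth_ma),
              pd_repair_tol = pd_repair_tol,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

# Default per-state block structure. Every state elevates its own distinct
# block pair, so the K states are mutually equidistant and windows classify
# cleanly. For K = 4 (8+ blocks) the effect state additionally gets a
# mildly coupled cross-network site, away from its dense defining blocks,
# where the group effect can sit without straining positive definiteness.
default_state_block_spec <- function(n_states, n_blocks,
                                     level_within = 0.50,
                                     level_between = 0.35,
                                     level_effect_site = 0.10) {
  if (n_states == 4 && n_blocks >= 8) {
    own <- list(c(1L, 2L), c(3L, 4L), c(5L, 6L), c(7L, 8L))
    return(lapply(1:4, function(s) {
      a <- own[[s]][1]; b <- own[[s]][2]
      df <- data.frame(block_a = c(a, b, a), block_b = c(a, b, b),
                       level = c(level_within, level_within, level_between))
      if (s == 2L)
        df <- rbind(df, data.frame(block_a = 3L, block_b = 5L,
                                   level = level_effect_site))
      df
    }))
  }
  pairs <- t(utils::combn(n_blocks, 2L))
  usage <- integer(n_blocks)
  spec <- vector("list", n_states)
  taken <- rep(FALSE, nrow(pairs))
  for (s in seq_len(n_states)) {
    cost <- usage[pairs[, 1]] + usage[pairs[, 2]] + ifelse(taken, 0.5, 0)
    k <- which.min(cost)
    a <- pairs[k, 1]; b <- pairs[k, 2]
    taken[k] <- TRUE
    usage[c(a, b)] <- usage[c(a, b)] + 1L
    spec[[s]] <- data.frame(block_a = c(a, b, a),
                            block_b = c(a, b, b),
                            level = c(level_within, level_within,
                                      level_between))
  }
  spec
}

# Force positive definiteness, tolerating only tiny changes to requested
# entries. Returns the (possibly repaired) correlation matrix.
ensure_pd <- function(m, tol, floor = 1e-6, label = "state matrix") {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > floor) return(m)
  rep_m <- as.matrix(Matrix::nearPD(m, corr = TRUE, eig.tol = 1e-8,
                                    posd.tol = 1e-6)$mat)
  delta <- abs(rep_m - m)
  if (max(delta) > tol) {
    w <- which(delta == max(delta), arr.ind = TRUE)[1, ]
    stop(sprintf(
      "infeasible block spec for %s: PD repair moved entry (%d,%d) by %.4f",
      label, w[1], w[2], max(delta)))
  }
  rep_m
}

#' Per-state, per-group true correlation matrices
#'
#' Builds the K control-group correlation matrices from the block spec, then
#' adds `effect_delta` at `effect_pairs` in `effect_state` for the patient
#' group. Matrices are symmetric with unit diagonal and are repaired to the
#' nearest positive-definite correlation matrix only if needed; a repair that
#' moves any requested entry by more than `pd_repair_tol` is an error.
#'
#' @param config a [cohort_config()].
#' @return list with elements `hc` and `case`, each a list of K correlation
#'   matrices.
#' @export
build_state_correlations <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  r <- config$n_components
  blocks <- config$blocks
  hc <- vector("list", config$n_states)
  case <- vector("list", config$n_states)
  same_block <- outer(blocks, blocks, "==")
  for (s in seq_len(config$n_states)) {
    m <- matrix(0, r, r)
    m[same_block] <- config$base_within
    sp <- config$state_block_spec[[s]]
    for (q in seq_len(nrow(sp))) {
      sel <- outer(blocks == sp$block_a[q], blocks == sp$block_b[q], "&")
      sel <- sel | t(sel)
      if (abs(sp$level[q]) >= 1)
        stop("block level must lie in (-1, 1)")
      m[sel] <- sp$level[q]
    }
    diag(m) <- 1
    if (config$state_factor_var[s] > 0) {
      # dense state-specific signature: fixed sign pattern (independent of
      # the cohort seed, so the state geometry is part of the design), PSD
      # increment + renormalization keep the matrix positive definite
      g <- withr::with_seed(83741L + s, sample(c(-1, 1), r, replace = TRUE))
      g <- g * sqrt(config$state_factor_var[s])
      m <- stats::cov2cor(m + tcrossprod(g))
    }
    m <- ensure_pd(m, config$pd_repair_tol,
                   label = sprintf("control state %d", s))
    hc[[s]] <- m
    pm <- m
    if (s == config$effect_state &&
        (config$effect_delta != 0 || config$trend_delta != 0)) {
      if (config$trend_delta != 0) {
        # rank-one shared-signal increment, renormalized to unit diagonal;
        # PSD increment + congruence renormalization keep the matrix PD
        g <- ifelse(config$blocks == config$trend_block, 1, 0.5)
        g <- g * sqrt(2 * config$trend_delta)
        pm <- stats::cov2cor(pm + tcrossprod(g))
        if (max(abs(pm[upper.tri(pm)])) >= 1)
          stop("trend_delta pushes a correlation outside (-1, 1)")
      }
      ep <- config$effect_pairs
      tgt <- pm[ep] + config$effect_delta
      if (any(abs(tgt) >= 1))
        stop("effect_delta pushes a correlation outside (-1, 1)")
      pm[ep] <- tgt
      pm[ep[, c(2, 1), drop = FALSE]] <- tgt
      pm <- ensure_pd(pm, config$pd_repair_tol,
                      label = sprintf("patient state %d", s))
    }
    case[[s]] <- pm
  }
  list(hc = hc, case = case)
}

#' Simulate a latent state sequence
#'
#' First-order Markov chain over the subject's allowed states with
#' self-transition probability `1 - 1/dwell_mean[state]` and the remaining
#' mass spread uniformly over the other allowed states; the initial state
#' is uniform over allowed states.
#'
#' @param config a [cohort_config()].
#' @param n_timepoints sequence length (defaults to the config's T).
#' @param allowed integer vector of states this subject may visit.
#' @param seed optional seed for reproducibility (the global RNG is left
#'   untouched when given).
#' @return integer vector of state labels in `allowed`.
#' @export
simulate_state_sequence <- function(config,
                                    n_timepoints = config$n_timepoints,
                                    allowed = seq_len(config$n_states),
                                    seed = NULL) {
  stopifnot(inherits(config, "cohort_config"), n_timepoints >= 1)
  allowed <- sort(unique(as.integer(allowed)))
  if (length(allowed) == 0) stop("all states excluded for this subject")
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_state_sequence(
      config, n_timepoints, allowed)))
  if (length(allowed) == 1) return(rep(allowed, n_timepoints))
  p_self <- 1 - 1 / rep_len(config$dwell_mean, config$n_states)
  labels <- integer(n_timepoints)
  labels[1] <- sample(allowed, 1)
  if (n_timepoints == 1) return(labels)
  u <- stats::runif(n_timepoints - 1)
  for (t in 2:n_timepoints) {
    if (u[t - 1] < p_self[labels[t - 1]]) {
      labels[t] <- labels[t - 1]
    } else {
      others <- allowed[allowed != labels[t - 1]]
      labels[t] <- if (length(others) == 1) others else sample(others, 1)
    }
  }
  labels
}

#' Simulate one subject's component time courses
#'
#' Row t is drawn from a zero-mean multivariate normal whose correlation
#' matrix is the subject group's matrix for the latent state at time t; rows
#' are independent given the state sequence (optionally smoothed innovations
#' when `config$smooth_ma > 1`).
#'
#' @param config a [cohort_config()].
#' @param group `"HC"` or `"mTBI"`.
#' @param state_corrs output of [build_state_correlations()].
#' @param labels integer state sequence of length T.
#' @param seed optional seed.
#' @return T x R numeric matrix of time courses.
#' @export
simulate_subject <- function(config, group, state_corrs, labels,
                             seed = NULL) {
  stopifnot(inherits(config, "cohort_config"),
            group %in% c("HC", "mTBI"),
            length(labels) >= 1)
  if (!is.null(seed))
    return(withr::with_seed(seed, simulate_subject(
      config, group, state_corrs, labels)))
  tt <- length(labels)
  r <- config$n_components
  z <- matrix(stats::rnorm(tt * r), tt, r)
  if (config$smooth_ma > 1) {
    w <- rep(1 / config$smooth_ma, config$smooth_ma)
    z <- apply(z, 2, function(col) {
      sm <- stats::filter(col, w, sides = 2)
      sm[is.na(sm)] <- col[is.na(sm)]
      as.numeric(sm)
    })
    z <- z / sqrt(sum(w^2))
  }
  mats <- if (group == "HC") state_corrs$hc else state_corrs$case
  x <- matrix(0, tt, r)
  for (s in unique(labels)) {
    idx <- which(labels == s)
    x[idx, ] <- z[idx, , drop = FALSE] %*% chol(mats[[s]])
  }
  colnames(x) <- sprintf("comp%02d", seq_len(r))
  x
}

#' Generate the full synthetic cohort
#'
#' Produces `2 * n_per_group` subjects (HC then mTBI), a phenotype table and
#' the ground truth (latent labels, allowed-state sets, true correlation
#' matrices) needed for parameter-recovery tests. Pure: writes nothing.
#'
#' @param config a [cohort_config()].
#' @return object of class `dfnc_cohort`: list with `subjects` (each having
#'   `subject_id`, `group`, `timecourses`), `phenotypes` (data frame with
#'   subject_id, group, sex, age, edu, wtar), and `truth` (list with
#'   `state_labels` an n x T integer matrix, `allowed` a list of allowed
#'   state sets, and `state_corrs`).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  withr::with_seed(config$seed, {
    state_corrs <- build_state_correlations(config)
    n <- 2L * config$n_per_group
    groups <- rep(c("HC", "mTBI"), each = config$n_per_group)
    ids <- sprintf("S%03d", seq_len(n))
    pp <- config$phenotype_params
    labels_mat <- matrix(0L, n, config$n_timepoints)
    allowed_list <- vector("list", n)
    subjects <- vector("list", n)
    sex <- age <- edu <- wtar <- rep(NA_real_, n)
    sex <- character(n)
    for (i in seq_len(n)) {
      allowed <- seq_len(config$n_states)
      if (config$n_states > 1 && any(config$state_visit_sparsity > 0)) {
        drop <- stats::runif(config$n_states) < config$state_visit_sparsity
        drop[config$dominant_state] <- FALSE
        allowed <- allowed[!drop]
      }
      allowed_list[[i]] <- allowed
      lab <- simulate_state_sequence(config, allowed = allowed)
      labels_mat[i, ] <- lab
      tc <- simulate_subject(config, groups[i], state_corrs, lab)
      subjects[[i]] <- list(subject_id = ids[i], group = groups[i],
                            timecourses = tc)
      sex[i] <- if (stats::runif(1) < pp$male_frac) "M" else "F"
      age[i] <- round(max(18, stats::rnorm(1, pp$age["mean"], pp$age["sd"])), 1)
      ep <- if (groups[i] == "HC") pp$edu_hc else pp$edu_case
      wp <- if (groups[i] == "HC") pp$wtar_hc else pp$wtar_case
      edu[i] <- round(max(8, stats::rnorm(1, ep["mean"], ep["sd"])), 1)
      wtar[i] <- round(stats::rnorm(1, wp["mean"], wp["sd"]), 1)
    }
    phenotypes <- data.frame(subject_id = ids, group = groups, sex = sex,
                             age = age, edu = edu, wtar = wtar,
                             stringsAsFactors = FALSE)
    structure(list(subjects = subjects, phenotypes = phenotypes,
                   truth = list(state_labels = labels_mat,
                                allowed = allowed_list,
                                state_corrs = state_corrs),
                   config = config),
              class = "dfnc_cohort")
  })
}

#' @export
print.dfnc_cohort <- function(x, ...) {
  cat(sprintf("dfnc_cohort: %d subjects (%d HC / %d mTBI), T = %d, R = %d, K = %d\n",
              length(x$subjects), sum(x$phenotypes$group == "HC"),
              sum(x$phenotypes$group == "mTBI"), x$config$n_timepoints,
              x$config$n_components, x$config$n_states))
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' One TSV time-course matrix per subject (T rows, R named columns), a
#' phenotype TSV, a ground-truth label TSV (subject_id, timepoint, state)
#' and the configuration echoed as YAML.
#'
#' @param cohort a `dfnc_cohort`.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "dfnc_cohort"))
  dir.create(file.path(dir, "timecourses"), recursive = TRUE,
             showWarnings = FALSE)
  paths <- character(0)
  for (s in cohort$subjects) {
    p <- file.path(dir, "timecourses", paste0(s$subject_id, ".tsv"))
    utils::write.table(s$timecourses, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  pp <- file.path(dir, "phenotypes.tsv")
  utils::write.table(cohort$phenotypes, pp, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lab <- cohort$truth$state_labels
  gt <- data.frame(
    subject_id = rep(cohort$phenotypes$subject_id, each = ncol(lab)),
    timepoint = rep(seq_len(ncol(lab)), times = nrow(lab)),
    state = as.integer(t(lab)))
  gp <- file.path(dir, "ground_truth_states.tsv")
  utils::write.table(gt, gp, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- cohort$config
  cfg_out <- cfg
  cfg_out$state_block_spec <- lapply(cfg$state_block_spec, as.list)
  cfg_out$effect_pairs <- apply(cfg$effect_pairs, 1, as.list)
  cp <- file.path(dir, "cohort_config.yaml")
  yaml::write_yaml(unclass(cfg_out), cp)
  invisible(c(paths, pp, gp, cp))
}
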