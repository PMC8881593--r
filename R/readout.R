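#' Population-vector heading decoder
#'
#' The heading estimate is the angle of the activity-weighted sum of unit
#' vectors at each E-PG neuron's preferred angle, applied to the filtered
#' spike traces; the two hemispheres (identical preferred angles) sum
#' naturally.  Confidence is the resultant length normalised by total
#' activity.
#'
#' @param traces E-PG activation traces: a length-18 vector or a T x 18
#'   matrix.
#' @param preferred_angles radians, one per trace column.
#' @return for a vector input, a list `(heading, confidence)`; for a
#'   matrix, a data frame with one row per timestep.  All-zero traces give
#'   `NA` heading with a warning (undecodable, flagged not silent).
#' @export
decode_heading <- function(traces, preferred_angles = epg_preferred_angles()) {
  one <- is.null(dim(traces))
  tr <- if (one) matrix(traces, 1) else as.matrix(traces)
  if (ncol(tr) != length(preferred_angles))
    stop("trace length must match number of preferred angles")
  if (any(tr < 0)) stop("traces must be non-negative")
  cx <- tr %*% cos(preferred_angles)
  sx <- tr %*% sin(preferred_angles)
  tot <- rowSums(tr)
  dead <- tot == 0
  if (any(dead)) warning("all-zero E-PG traces: heading undecodable at ",
                         sum(dead), " timestep(s)")
  heading <- ifelse(dead, NA_real_, atan2(sx, cx))
  confidence <- ifelse(dead, 0, sqrt(cx^2 + sx^2) / tot)
  if (one) list(heading = heading[1], confidence = confidence[1])
  else data.frame(heading = heading, confidence = confidence)
}

#' Dead-reckoned positions from headings and linear speed
#'
#' `position(t+dt) = position(t) + dt * speed(t) * (cos h(t), sin h(t))`.
#'
#' @param headings radians.
#' @param linear_speed m/s, same length.
#' @param dt timestep, seconds.
#' @param origin starting position.
#' @return T x 2 matrix of positions (the position *before* each step's
#'   displacement, so row 1 is the origin).
#' @export
path_integrate <- function(headings, linear_speed, dt, origin = c(0, 0)) {
  if (length(headings) != length(linear_speed))
    stop("headings and linear_speed must have the same length")
  dx <- dt * linear_speed * cos(headings)
  dy <- dt * linear_speed * sin(headings)
  cbind(x = origin[1] + c(0, cumsum(dx[-length(dx)])),
        y = origin[2] + c(0, cumsum(dy[-length(dy)])))
}

#' Circular root-mean-squared heading error
#'
#' Errors are wrapped to (-pi, pi] before squaring, so a constant error of
#' pi gives exactly pi.
#'
#' @param est,truth aligned heading series, radians.
#' @param na.rm drop timesteps with `NA` estimates.
#' @return RMSE in radians.
#' @export
circular_rmse <- function(est, truth, na.rm = FALSE) {
  if (length(est) == 0) stop("empty heading series")
  if (length(est) != length(truth)) stop("series length mismatch")
  sqrt(mean(angle_diff(est, truth)^2, na.rm = na.rm))
}

#' Mean position error as a percentage of path length
#'
#' Mean over time of the Euclidean distance between estimated and true
#' positions, normalised by the total true path length, times 100.
#'
#' @param est,truth T x 2 position matrices (metres).
#' @return percent.
#' @export
position_error_pct <- function(est, truth) {
  est <- as.matrix(est); truth <- as.matrix(truth)
  if (!all(dim(est) == dim(truth))) stop("position series length mismatch")
  len <- sum(sqrt(rowSums(diff(truth)^2)))
  if (len <= 0) stop("zero-length ground-truth path")
  100 * mean(sqrt(rowSums((est - truth)^2))) / len
}

#' Element-wise correlation between two weight matrices
#'
#' Product-moment correlation over the flattened elements; the standard
#' similarity measure between online-learned and offline-optimised
#' ring-to-E-PG weights.
#'
#' @param w_learned,w_optimal equal-shape matrices.
#' @return correlation in `[-1, 1]`.
#' @export
weight_correlation <- function(w_learned, w_optimal) {
  if (!all(dim(w_learned) == dim(w_optimal))) stop("weight shape mismatch")
  if (stats::sd(w_learned) == 0 || stats::sd(w_optimal) == 0)
    stop("undefined correlation: constant weight matrix")
  stats::cor(as.vector(w_learned), as.vector(w_optimal))
}

#' Metrics for a single simulated run
#'
#' Decodes the heading, path-integrates with the ground-truth linear
#' speed, and computes the orientation RMSE (wrapped, plus the
#' cumulative-unwrapped variant) and position error.
#'
#' @param run a `cx_run` from [simulate_trial()].
#' @param w_optimal optional offline solution for weight-correlation
#'   series.
#' @param skip_s initial seconds excluded from the error metrics (bump
#'   initialisation transient).
#' @return list of metrics.
#' @export
run_metrics <- function(run, w_optimal = NULL, skip_s = 0.5) {
  dec <- decode_heading(run$epg_trace, run$preferred_angles)
  traj <- run$traj
  keep <- traj$t >= skip_s
  est <- dec$heading
  # the first few milliseconds can be undecodable (no spikes yet); hold the
  # initial true heading until the bump ignites
  if (anyNA(est)) {
    na <- is.na(est)
    est[na] <- traj$heading[1]
    if (any(na & keep)) warning("undecodable headings inside the scored window")
  }
  rmse <- circular_rmse(est[keep], traj$heading[keep])
  # cumulative-unwrapped variant: compare accumulated angle, not wrapped
  rmse_unwrapped <- sqrt(mean((unwrap_angle(est)[keep] -
                               unwrap_angle(traj$heading)[keep])^2))
  pos_est <- path_integrate(est, traj$linear_speed, run$dt,
                            origin = c(traj$x[1], traj$y[1]))
  pos_truth <- cbind(traj$x, traj$y)
  pos_err <- if (path_length(traj) > 0)
    position_error_pct(pos_est[keep, ], pos_truth[keep, ]) else NA_real_
  out <- list(rmse = rmse, rmse_unwrapped = rmse_unwrapped,
              position_error_pct = pos_err,
              mean_confidence = mean(dec$confidence[keep]),
              positions = pos_est)
  if (!is.null(w_optimal) && length(run$w_snaps) > 0) {
    out$weight_correlation <- vapply(run$w_snaps, weight_correlation,
                                     numeric(1), w_optimal = w_optimal)
    out$weight_correlation_t <- run$snap_t
    out$final_weight_correlation <-
      weight_correlation(run$w_final, w_optimal)
  }
  out
}

#' Percentile bootstrap confidence interval of a mean
#'
#' @param x numeric vector (per-seed metric values).
#' @param n_boot resamples.
#' @param conf confidence level.
#' @return `c(lower, upper)`.
#' @export
bootstrap_ci <- function(x, n_boot = 1000, conf = 0.95) {
  means <- vapply(seq_len(n_boot),
                  function(i) mean(sample(x, replace = TRUE)), numeric(1))
  stats::quantile(means, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                  names = FALSE)
}

#' Experiment configuration
#'
#' @param trial `"rotation"` or `"translation"` (the packaged default
#'   trials), or a list `list(world =, traj =)` for custom conditions.
#' @param configurations which weight configurations to run.
#' @param n_seeds simulation seeds per configuration.
#' @param rule online learning rule.
#' @param mode ring-activation mode passed to [simulate_trial()].
#' @param duration_s trial duration for the packaged trials.
#' @return a `cx_experiment_config`.
#' @export
experiment_config <- function(trial = "rotation",
                              configurations = c("optimal", "online", "av_only"),
                              n_seeds = 50, rule = "hebbian", mode = "rate",
                              duration_s = 60) {
  structure(list(trial = trial, configurations = configurations,
                 n_seeds = n_seeds, rule = rule, mode = mode,
                 duration_s = duration_s),
            class = "cx_experiment_config")
}

experiment_world_traj <- function(cfg) {
  if (is.list(cfg$trial)) return(cfg$trial)
  switch(cfg$trial,
         rotation = list(world = default_rotation_world(),
                         traj = default_rotation_trajectory(cfg$duration_s)),
         translation = list(world = default_translation_world(),
                            traj = default_translation_trajectory(cfg$duration_s)),
         stop("unknown trial type: ", cfg$trial))
}

#' Run the multi-seed, multi-configuration experiment
#'
#' For every seed and every configuration, simulates the trial, decodes
#' and scores it, then aggregates means with percentile-bootstrap 95%
#' intervals and pairwise Wilcoxon rank-sum tests between configurations.
#' The offline solution is fitted once per trial (it is deterministic
#' given the trajectory) and reused across seeds.  Everything is
#' reproducible from `seed`.
#'
#' @param cfg an [experiment_config()].
#' @param seed top-level seed; seed i of the run derives from it.
#' @param w_optimal optionally precomputed offline solution (list from
#'   [fit_optimal_weights()]); fitted if missing and needed.
#' @param lambda passed to the offline fit (default cross-validated).
#' @param verbose print one line per seed.
#' @return a `cx_run_metrics` list: `per_seed` (data frame),
#'   `weight_correlation` (mean series over seeds), `aggregate` (means,
#'   CIs), `tests` (rank-sum p-values), `w_optimal`, `failures`.
#' @export
run_experiment <- function(cfg = experiment_config(), seed = 1,
                           w_optimal = NULL, lambda = "cv",
                           verbose = FALSE) {
  wt <- experiment_world_traj(cfg)
  need_opt <- any(cfg$configurations %in% c("optimal", "online"))
  if (is.null(w_optimal) && need_opt) {
    set.seed(seed)
    w_optimal <- fit_optimal_weights(wt$world, wt$traj, lambda = lambda)
  }

  rows <- list(); corr_series <- list(); failures <- list()
  for (config in cfg$configurations) {
    for (s in seq_len(cfg$n_seeds)) {
      # per-seed stream derived from the top-level seed (kept below 2^31)
      set.seed((seed %% 100000L) * 10000L + s)
      m <- tryCatch({
        run <- simulate_trial(wt$world, wt$traj, config = config,
                              w_rc = if (config == "optimal") w_optimal$w else NULL,
                              rule = if (cfg$rule == "eq4") "errmin" else "hebbian",
                              mode = cfg$mode,
                              snapshot_every_s = if (config == "online") 2 else 0)
        run_metrics(run, w_optimal = if (config == "online") w_optimal$w else NULL)
      }, error = function(e) e)
      if (inherits(m, "error")) {
        failures[[length(failures) + 1]] <-
          list(config = config, seed = s, message = conditionMessage(m))
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        config = config, seed = s, rmse = m$rmse,
        rmse_unwrapped = m$rmse_unwrapped,
        position_error_pct = m$position_error_pct,
        final_weight_correlation =
          if (!is.null(m$final_weight_correlation))
            m$final_weight_correlation else NA_real_)
      if (!is.null(m$weight_correlation))
        corr_series[[length(corr_series) + 1]] <- m$weight_correlation
      if (verbose)
        message(sprintf("%s seed %d: rmse %.3f", config, s, m$rmse))
    }
  }
  per_seed <- do.call(rbind, rows)

  agg <- do.call(rbind, lapply(split(per_seed, per_seed$config), function(d) {
    ci <- bootstrap_ci(d$rmse)
    pe <- d$position_error_pct
    pci <- if (all(is.na(pe))) c(NA_real_, NA_real_) else bootstrap_ci(pe)
    data.frame(config = d$config[1], n = nrow(d),
               rmse_mean = mean(d$rmse),
               rmse_lo = ci[1], rmse_hi = ci[2],
               pos_err_mean = mean(pe),
               pos_err_lo = pci[1], pos_err_hi = pci[2])
  }))
  rownames(agg) <- NULL

  tests <- list()
  cfgs <- unique(per_seed$config)
  if (length(cfgs) > 1) {
    for (i in seq_along(cfgs)) for (j in seq_along(cfgs)) if (i < j) {
      a <- per_seed$rmse[per_seed$config == cfgs[i]]
      b <- per_seed$rmse[per_seed$config == cfgs[j]]
      tests[[paste(cfgs[i], cfgs[j], sep = "_vs_")]] <-
        stats::wilcox.test(a, b)$p.value
    }
  }

  corr_mat <- if (length(corr_series) > 0) do.call(rbind, corr_series) else NULL
  structure(list(per_seed = per_seed, aggregate = agg, tests = tests,
                 weight_correlation =
                   if (!is.null(corr_mat)) colMeans(corr_mat) else NULL,
                 weight_correlation_per_seed = corr_mat,
                 w_optimal = w_optimal, failures = failures,
                 config = cfg, seed = seed),
            class = "cx_run_metrics")
}
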