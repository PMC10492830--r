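#' Committed clustered-classification transfer benchmark
#'
#' Runs the end-to-end projection experiment on the clustered
#' classification generator: fit a kernel source model on the many-class
#' source task, transfer it by projection to the few-class target task,
#' and compare test accuracy against the baseline kernel fit directly on
#' the target data. The default configuration (20 source classes refined
#' into 5 target classes of 4 blobs each, d = 30, blob sd 0.35, 2000
#' source and 50 target samples) is the committed benchmark; the Laplace
#' bandwidth of 3 is of the order of the typical inter-point distance at
#' this data scale.
#'
#' @param seed Integer seed controlling data generation.
#' @param n_t Target training-sample count.
#' @param spec Kernel spec for both the source model and the baseline.
#' @param head_spec Head spec for the projection (a Laplace kernel applied
#'   to the source-model outputs, mirroring the image experiments).
#' @param source_ridge Small ridge for the source fit, which keeps the
#'   large source solve numerically safe.
#' @param ... Passed to [gen_clustered_classification()].
#' @return A list with \code{projected} and \code{baseline} test
#'   accuracies.
#' @export
classification_transfer_benchmark <- function(seed = 1L, n_t = 50,
                                              spec = laplace_kernel(3),
                                              head_spec = laplace_kernel(3),
                                              source_ridge = 1e-4, ...) {
  data <- gen_clustered_classification(n_t = n_t, seed = seed, ...)
  src <- fit_kernel(spec, data$source$X, data$source$Y, ridge = source_ridge)
  proj <- fit_projected(src, data$target$X, data$target$Y,
                        head_spec = head_spec, ridge = 0)
  base <- fit_kernel(spec, data$target$X, data$target$Y, ridge = 0)
  list(projected = evaluate_classification(proj, data$test$X, data$test$Y),
       baseline = evaluate_classification(base, data$test$X, data$test$Y))
}

#' Learning curves for the clustered-classification benchmark
#'
#' Computes projected and baseline test accuracy as a function of the
#' number of target samples, averaged over seeds. Within one seed the
#' target training sets are nested (the first \eqn{n} samples of a common
#' pool) and the source model is fit once, so the curve isolates the
#' effect of target sample count.
#'
#' @param n_grid Increasing target sample counts (curve points).
#' @param seeds Integer seeds to average over.
#' @inheritParams classification_transfer_benchmark
#' @return A data frame with columns \code{n}, \code{projected},
#'   \code{baseline} (accuracies averaged over seeds).
#' @export
classification_learning_curve <- function(n_grid = seq(10, 255, by = 5),
                                          seeds = 1:3,
                                          spec = laplace_kernel(3),
                                          head_spec = laplace_kernel(3),
                                          source_ridge = 1e-4, ...) {
  n_max <- max(n_grid)
  acc <- array(0, dim = c(length(n_grid), 2L, length(seeds)))
  for (si in seq_along(seeds)) {
    data <- gen_clustered_classification(n_t = n_max, seed = seeds[si], ...)
    src <- fit_kernel(spec, data$source$X, data$source$Y,
                      ridge = source_ridge)
    for (ni in seq_along(n_grid)) {
      idx <- seq_len(n_grid[ni])
      Xt <- data$target$X[idx, , drop = FALSE]
      Yt <- data$target$Y[idx, , drop = FALSE]
      proj <- fit_projected(src, Xt, Yt, head_spec = head_spec, ridge = 0)
      base <- fit_kernel(spec, Xt, Yt, ridge = 0)
      acc[ni, 1L, si] <- evaluate_classification(proj, data$test$X,
                                                 data$test$Y)
      acc[ni, 2L, si] <- evaluate_classification(base, data$test$X,
                                                 data$test$Y)
    }
  }
  m <- apply(acc, c(1L, 2L), mean)
  data.frame(n = n_grid, projected = m[, 1L], baseline = m[, 2L])
}

mean_imputation_predictions <- function(Y_train, n_new) {
  matrix(colMeans(Y_train), n_new, ncol(Y_train), byrow = TRUE)
}

drug_screen_metrics <- function(pred, truth) {
  c(pearson_r = pearson_r(pred, truth),
    mean_r2 = mean_r2(pred, truth),
    mean_cosine = mean_cosine_centered(pred, truth))
}

#' Committed drug-screen transfer benchmark
#'
#' End-to-end evaluation on the synthetic drug screen: an NTK source model
#' (1 hidden layer, with an offset term — the architecture used for
#' expression imputation) is fit on the source cell lines, then transferred
#' to each held-out cell line with the combined projection + translation
#' operator (NTK head). It is compared against the baseline NTK fit
#' directly on the target training samples and against imputation by the
#' mean expression over the target cell line's training samples. Ridge
#' defaults keep the same proportion to the kernel scale as the expression
#' imputation experiments (a few percent of the Gram diagonal for the
#' source and transfer fits, ten times less for the baseline), with the
#' source/transfer-to-baseline ratio of ten preserved. Target training samples are drawn from the seen-drug stratum;
#' evaluation covers the remaining seen-drug samples and the entire
#' unseen-drug stratum, scored with the three screening metrics.
#'
#' @param seed Integer seed (drives both the generator and the train
#'   split).
#' @param n_target_train Target training-sample count per held-out cell
#'   line.
#' @param sim_args Named list of overrides for [drug_screen_sim()].
#' @param held_out_cells,held_out_drugs Passed to [gen_drug_screen()].
#' @param ridge_source,ridge_transfer,ridge_baseline Ridge coefficients.
#' @return A data frame with one row per (model, stratum) and the three
#'   metric columns, averaged over held-out cell lines.
#' @export
drug_screen_benchmark <- function(seed = 1L, n_target_train = 16,
                                  sim_args = list(),
                                  held_out_cells = 2, held_out_drugs = 24,
                                  ridge_source = 10,
                                  ridge_transfer = 10,
                                  ridge_baseline = 1) {
  sim <- do.call(drug_screen_sim, c(sim_args, list(seed = seed)))
  screen <- gen_drug_screen(sim, held_out_cells, held_out_drugs)
  spec <- ntk_kernel(depth = 1, offset = TRUE)
  src <- fit_kernel(spec, screen$source$X, screen$source$Y,
                    ridge = ridge_source)
  set.seed(seed)
  rows <- list()
  for (tg in screen$targets) {
    n_seen <- nrow(tg$seen$X)
    if (n_target_train >= n_seen) {
      stop("`n_target_train` must leave seen-drug samples for evaluation",
           call. = FALSE)
    }
    train_idx <- sample.int(n_seen, n_target_train)
    Xtr <- tg$seen$X[train_idx, , drop = FALSE]
    Ytr <- tg$seen$Y[train_idx, , drop = FALSE]
    strata <- list(
      seen = list(X = tg$seen$X[-train_idx, , drop = FALSE],
                  Y = tg$seen$Y[-train_idx, , drop = FALSE]),
      unseen = list(X = tg$unseen$X, Y = tg$unseen$Y))
    transferred <- fit_projected_translated(src, Xtr, Ytr, head_spec = spec,
                                            ridge = ridge_transfer)
    baseline <- fit_kernel(spec, Xtr, Ytr, ridge = ridge_baseline)
    for (s in names(strata)) {
      st <- strata[[s]]
      preds <- list(
        transferred = predict(transferred, st$X),
        baseline = predict(baseline, st$X),
        mean_imputation = mean_imputation_predictions(Ytr, nrow(st$X)))
      for (m in names(preds)) {
        rows[[length(rows) + 1L]] <- data.frame(
          cell = tg$cell, model = m, stratum = s,
          t(drug_screen_metrics(preds[[m]], st$Y)))
      }
    }
  }
  out <- do.call(rbind, rows)
  stats::aggregate(out[c("pearson_r", "mean_r2", "mean_cosine")],
                   by = out[c("model", "stratum")], FUN = mean)
}

#' Learning curves for the drug-screen benchmark
#'
#' Mean per-sample \eqn{R^2} on the held-out seen-drug stratum for the
#' transferred and baseline NTK models as a function of the target
#' training-sample count, averaged over seeds and held-out cell lines.
#' Training sets are nested within each seed.
#'
#' @param n_grid Increasing target training-sample counts.
#' @param seeds Integer seeds to average over.
#' @inheritParams drug_screen_benchmark
#' @return A data frame with columns \code{n}, \code{transferred},
#'   \code{baseline}.
#' @export
drug_screen_learning_curve <- function(n_grid = c(6, 8, 11, 16, 22, 32, 45),
                                       seeds = 1:3,
                                       sim_args = list(),
                                       held_out_cells = 2,
                                       held_out_drugs = 24,
                                       ridge_source = 10,
                                       ridge_transfer = 10,
                                       ridge_baseline = 1) {
  spec <- ntk_kernel(depth = 1, offset = TRUE)
  n_max <- max(n_grid)
  res <- array(0, dim = c(length(n_grid), 2L, length(seeds)))
  for (si in seq_along(seeds)) {
    sim <- do.call(drug_screen_sim, c(sim_args, list(seed = seeds[si])))
    screen <- gen_drug_screen(sim, held_out_cells, held_out_drugs)
    src <- fit_kernel(spec, screen$source$X, screen$source$Y,
                      ridge = ridge_source)
    set.seed(seeds[si])
    per_cell <- array(0, dim = c(length(n_grid), 2L, length(screen$targets)))
    for (ti in seq_along(screen$targets)) {
      tg <- screen$targets[[ti]]
      n_seen <- nrow(tg$seen$X)
      pool <- sample.int(n_seen, n_max)
      eval_idx <- setdiff(seq_len(n_seen), pool)
      Xev <- tg$seen$X[eval_idx, , drop = FALSE]
      Yev <- tg$seen$Y[eval_idx, , drop = FALSE]
      for (ni in seq_along(n_grid)) {
        idx <- pool[seq_len(n_grid[ni])]
        Xtr <- tg$seen$X[idx, , drop = FALSE]
        Ytr <- tg$seen$Y[idx, , drop = FALSE]
        transferred <- fit_projected_translated(src, Xtr, Ytr,
                                                head_spec = spec,
                                                ridge = ridge_transfer)
        baseline <- fit_kernel(spec, Xtr, Ytr, ridge = ridge_baseline)
        per_cell[ni, 1L, ti] <- mean_r2(predict(transferred, Xev), Yev)
        per_cell[ni, 2L, ti] <- mean_r2(predict(baseline, Xev), Yev)
      }
    }
    res[, , si] <- apply(per_cell, c(1L, 2L), mean)
  }
  m <- apply(res, c(1L, 2L), mean)
  data.frame(n = n_grid, transferred = m[, 1L], baseline = m[, 2L])
}

#' Closed-form versus Monte-Carlo risk over a parameter grid
#'
#' For each grid cell, constructs oracle weight matrices with the requested
#' task-similarity, evaluates the closed-form risk, runs the Monte-Carlo
#' risk oracle, and reports the z-score of the disagreement. This is the
#' numerical verification of the exact risk formulas.
#'
#' @param estimator \code{"projected"} (grid over \code{n_s}, \code{n_t},
#'   \code{c_s}, \code{eps}) or \code{"translated"} (grid over \code{n_s},
#'   \code{n_t}, \code{norm_diff_sq}).
#' @param d Ambient dimension of the grid.
#' @param n_s_grid,n_t_grid,c_s_grid Grid values.
#' @param eps_grid Task-similarity values (projected; squared Frobenius
#'   units, with \eqn{\|\omega_t\|_F = 1}).
#' @param diff_grid Values of \eqn{\|\omega_s - \omega_t\|_F^2}
#'   (translated).
#' @param c_t Target label dimension.
#' @param trials Monte-Carlo trials per cell.
#' @param seed Root seed; per-cell seeds are derived deterministically.
#' @return A data frame with the grid coordinates, \code{closed_form},
#'   \code{mc_mean}, \code{mc_se} and \code{z_score}.
#' @export
theory_closure_grid <- function(estimator = c("projected", "translated"),
                                d = 16,
                                n_s_grid = c(4, 8, 12, 16),
                                n_t_grid = c(2, 4, 8),
                                c_s_grid = c(2, 4, 8),
                                eps_grid = c(0, 0.25),
                                diff_grid = c(0.25, 1),
                                c_t = 3, trials = 20000L, seed = 1L) {
  estimator <- match.arg(estimator)
  grid <- if (estimator == "projected") {
    expand.grid(n_s = n_s_grid, n_t = n_t_grid, c_s = c_s_grid,
                eps = eps_grid)
  } else {
    expand.grid(n_s = n_s_grid, n_t = n_t_grid, diff = diff_grid)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    cell_seed <- (seed * 131L + i) %% .Machine$integer.max
    if (estimator == "projected") {
      w <- gen_weights_with_epsilon(d, g$c_s, c_t, eps_target = g$eps,
                                    norm_wt = 1, seed = cell_seed)
      closed <- risk_projected(d, g$n_s, g$n_t, g$c_s,
                               norm_wt_sq = sum(w$omega_t^2),
                               epsilon = epsilon_similarity(w$omega_t,
                                                            w$omega_s))$risk
      task <- linear_transfer_task(d, g$n_s, g$n_t, w$omega_s, w$omega_t)
    } else {
      set.seed(cell_seed)
      omega_t <- matrix(stats::rnorm(c_t * d), c_t, d)
      omega_t <- omega_t / sqrt(sum(omega_t^2))
      delta <- matrix(stats::rnorm(c_t * d), c_t, d)
      delta <- delta * sqrt(g$diff / sum(delta^2))
      omega_s <- omega_t + delta
      closed <- risk_translated(d, g$n_s, g$n_t,
                                norm_diff_sq = sum((omega_s - omega_t)^2),
                                norm_wt_sq = sum(omega_t^2))
      task <- linear_transfer_task(d, g$n_s, g$n_t, omega_s, omega_t)
    }
    mc <- mc_risk(task, estimator, trials = trials, seed = cell_seed + 1L)
    data.frame(g, closed_form = closed, mc_mean = mc$mean, mc_se = mc$se,
               z_score = (mc$mean - closed) / mc$se)
  })
  do.call(rbind, rows)
}

#' Committed scaling-law protocol for the classification benchmark
#'
#' Runs the full logarithmic-scaling analysis of the projected predictor on
#' the clustered-classification generator, in the slow-learning variant used
#' for curve experiments (blob sd 0.5, 1500 source samples, 2000 test
#' samples): (i) a 50-point learning curve with target sample counts evenly
#' spaced from 10 to 400, averaged over \code{r2_seeds}, fit by
#' [fit_log_law()]; (ii) head-fit extrapolation — for each replicate, the
#' five smallest-n curve points (averaged over \code{sub_seeds} fresh seeds)
#' are fit and the fitted law is extrapolated to the final curve point,
#' recording the error in accuracy percentage points.
#'
#' @param r2_seeds Seeds averaged into the 50-point curve.
#' @param extrap_reps Number of extrapolation replicates.
#' @param sub_seeds Seeds averaged into each replicate's curve points.
#' @param n_grid Curve grid (defaults to the committed 50-point grid).
#' @param base_seed Offset added to every internal seed.
#' @return A list with \code{curve} (data frame), \code{fit_projected} and
#'   \code{fit_baseline} ([fit_log_law()] objects), and \code{extrapolation}
#'   (data frame with \code{rep}, \code{predicted}, \code{actual},
#'   \code{abs_err_points}).
#' @export
classification_scaling_benchmark <- function(r2_seeds = 1:10,
                                             extrap_reps = 5,
                                             sub_seeds = 40,
                                             n_grid = round(seq(10, 400,
                                                                length.out = 50)),
                                             base_seed = 0L) {
  args <- list(cluster_sd = 0.5, n_s = 1500, n_test = 2000)
  curve <- do.call(classification_learning_curve,
                   c(list(n_grid = n_grid, seeds = base_seed + r2_seeds),
                     args))
  fit_p <- fit_log_law(curve$n, curve$projected)
  fit_b <- fit_log_law(curve$n, curve$baseline)
  head_grid <- n_grid[c(1:5, length(n_grid))]
  rows <- lapply(seq_len(extrap_reps), function(r) {
    seeds <- base_seed + 1000L + (r - 1L) * sub_seeds + seq_len(sub_seeds)
    cs <- do.call(classification_learning_curve,
                  c(list(n_grid = head_grid, seeds = seeds), args))
    hf <- fit_log_law(cs$n[1:5], cs$projected[1:5])
    pred <- extrapolate_log_law(hf, cs$n[6])
    data.frame(rep = r, predicted = pred, actual = cs$projected[6],
               abs_err_points = abs(pred - cs$projected[6]) * 100)
  })
  list(curve = curve, fit_projected = fit_p, fit_baseline = fit_b,
       extrapolation = do.call(rbind, rows))
}
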