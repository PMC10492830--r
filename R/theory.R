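#' Task similarity between linear source and target maps
#'
#' Returns \eqn{\varepsilon = \|\omega_t (I - \omega_s^\dagger \omega_s)\|_F^2},
#' the squared Frobenius mass of the target map outside the row space of the
#' source map. It is zero exactly when every row of \eqn{\omega_t} lies in
#' the row space of \eqn{\omega_s}, i.e. when the target map factors through
#' the source map.
#'
#' @param omega_t Target map, a \eqn{c_t \times d} matrix.
#' @param omega_s Source map, a \eqn{c_s \times d} matrix with the same
#'   column count.
#' @return A non-negative scalar.
#' @export
epsilon_similarity <- function(omega_t, omega_s) {
  omega_t <- as.matrix(omega_t)
  omega_s <- as.matrix(omega_s)
  if (ncol(omega_t) != ncol(omega_s)) {
    stop("`omega_t` and `omega_s` must have the same number of columns",
         call. = FALSE)
  }
  proj <- pinv(omega_s) %*% omega_s        # projector onto row space
  off <- omega_t - omega_t %*% proj
  sum(off^2)
}

check_regime <- function(d, n_s = NULL, n_t = NULL) {
  if (!is.null(n_t) && (n_t < 0 || n_t > d)) {
    stop(sprintf("closed forms are asserted only for 0 <= n_t <= d (got n_t = %g, d = %g)",
                 n_t, d), call. = FALSE)
  }
  if (!is.null(n_s) && (n_s < 0 || n_s > d)) {
    stop(sprintf("closed forms are asserted only for 0 <= n_s <= d (got n_s = %g, d = %g)",
                 n_s, d), call. = FALSE)
  }
}

#' Exact risk of the baseline minimum-norm linear predictor
#'
#' In the over-parameterized linear setting with isotropic inputs and
#' noiseless labels \eqn{y_t = \omega_t X_t}, the minimum-norm baseline
#' predictor \eqn{\hat\omega_b = y_t X_t^\dagger} has risk
#' \eqn{(1 - n_t/d)\,\|\omega_t\|_F^2}.
#'
#' @param d Ambient input dimension.
#' @param n_t Number of target samples, \eqn{0 \le n_t \le d}.
#' @param norm_wt_sq Squared Frobenius norm \eqn{\|\omega_t\|_F^2}.
#' @return The exact risk, a non-negative scalar.
#' @export
risk_baseline <- function(d, n_t, norm_wt_sq) {
  check_regime(d, n_t = n_t)
  (1 - n_t / d) * norm_wt_sq
}

#' Exact risk of the projected minimum-norm linear predictor
#'
#' Closed form for the risk of \eqn{\hat\omega_p \hat\omega_s} where
#' \eqn{\hat\omega_s = y_s X_s^\dagger} and
#' \eqn{\hat\omega_p = y_t (\hat\omega_s X_t)^\dagger}, under independent
#' isotropic source/target input laws and noiseless linear labels:
#' \deqn{R = [(C_1 + C_2 K_1)(1 - n_t/d) + (1 - C_1 - C_2)]\,\|\omega_t\|_F^2
#'       + C_2 K_2\,\varepsilon,}
#' with
#' \eqn{C_1 = n_s c_s (d - n_s) / (d(d-1)(d+2))},
#' \eqn{C_2 = n_s [d(n_s + 1) - 2] / (d(d-1)(d+2))},
#' \eqn{K_1 = 1 - n_t (d - c_s) / ((d-1)(d+2))},
#' \eqn{K_2 = n_t/d + n_t (d - n_t) / ((d-1)(d+2))}.
#'
#' @param d Ambient dimension, at least 3.
#' @param n_s,n_t Source and target sample counts, each in \eqn{[1, d]}.
#' @param c_s Source label dimension, at least 1.
#' @param norm_wt_sq Squared Frobenius norm of the target map.
#' @param epsilon Task-similarity term, see [epsilon_similarity()].
#' @return An object of class \code{risk_breakdown}: a list with the
#'   intermediate constants \code{C1}, \code{C2}, \code{K1}, \code{K2},
#'   \code{epsilon} and the resulting \code{risk}.
#' @export
risk_projected <- function(d, n_s, n_t, c_s, norm_wt_sq, epsilon = 0) {
  if (d < 3) stop("`d` must be at least 3", call. = FALSE)
  if (c_s < 1) stop("`c_s` must be at least 1", call. = FALSE)
  if (n_s < 1 || n_t < 1) {
    stop("`n_s` and `n_t` must be at least 1", call. = FALSE)
  }
  check_regime(d, n_s = n_s, n_t = n_t)
  if (epsilon < 0) stop("`epsilon` must be non-negative", call. = FALSE)
  den <- d * (d - 1) * (d + 2)
  C1 <- n_s * c_s * (d - n_s) / den
  C2 <- n_s * (d * (n_s + 1) - 2) / den
  K1 <- 1 - n_t * (d - c_s) / ((d - 1) * (d + 2))
  K2 <- n_t / d + n_t * (d - n_t) / ((d - 1) * (d + 2))
  risk <- ((C1 + C2 * K1) * (1 - n_t / d) + (1 - C1 - C2)) * norm_wt_sq +
    C2 * K2 * epsilon
  structure(list(C1 = C1, C2 = C2, K1 = K1, K2 = K2,
                 epsilon = epsilon, risk = risk),
            class = "risk_breakdown")
}

#' @export
print.risk_breakdown <- function(x, ...) {
  cat(sprintf("Projected-predictor risk: %.6g\n", x$risk))
  cat(sprintf("  C1 = %.6g, C2 = %.6g, K1 = %.6g, K2 = %.6g, epsilon = %.6g\n",
              x$C1, x$C2, x$K1, x$K2, x$epsilon))
  invisible(x)
}

#' Exact risk of the translated minimum-norm linear predictor
#'
#' Closed form for the risk of \eqn{\hat\omega_s + \hat\omega_c} where
#' \eqn{\hat\omega_c = (y_t - \hat\omega_s X_t) X_t^\dagger}:
#' \deqn{R = [A + (1 - n_s/d)(1 - A)] \; R(\hat\omega_b), \quad
#'       A = \|\omega_s - \omega_t\|_F^2 / \|\omega_t\|_F^2,}
#' a weighted average (with weight \eqn{n_s/d}) of the baseline risk and the
#' risk when the source map is recovered exactly.
#'
#' @param d Ambient dimension.
#' @param n_s,n_t Source and target sample counts, in \eqn{[0, d]}.
#' @param norm_diff_sq Squared Frobenius norm \eqn{\|\omega_s - \omega_t\|_F^2}.
#' @param norm_wt_sq Squared Frobenius norm \eqn{\|\omega_t\|_F^2 > 0}.
#' @return The exact risk, a scalar.
#' @export
risk_translated <- function(d, n_s, n_t, norm_diff_sq, norm_wt_sq) {
  check_regime(d, n_s = n_s, n_t = n_t)
  if (norm_wt_sq <= 0) stop("`norm_wt_sq` must be positive", call. = FALSE)
  A <- norm_diff_sq / norm_wt_sq
  (A + (1 - n_s / d) * (1 - A)) * risk_baseline(d, n_t, norm_wt_sq)
}

#' Linear transfer task description
#'
#' Bundles the dimensions and oracle weight matrices of the linear-theory
#' world: inputs are isotropic (standard Gaussian) in dimension \code{d},
#' source labels are \eqn{\omega_s x} and target labels \eqn{\omega_t x}.
#'
#' @param d Ambient dimension.
#' @param n_s,n_t Source and target training-sample counts (at most
#'   \code{d}; the closed forms are asserted only in the over-parameterized
#'   regime).
#' @param omega_s,omega_t Oracle weight matrices (\eqn{c_s \times d} and
#'   \eqn{c_t \times d}).
#' @return An object of class \code{linear_transfer_task}.
#' @export
linear_transfer_task <- function(d, n_s, n_t, omega_s, omega_t) {
  omega_s <- as.matrix(omega_s)
  omega_t <- as.matrix(omega_t)
  if (ncol(omega_s) != d || ncol(omega_t) != d) {
    stop("`omega_s` and `omega_t` must have d columns", call. = FALSE)
  }
  if (n_s < 0 || n_t < 1) {
    stop("need n_s >= 0 and n_t >= 1", call. = FALSE)
  }
  if (n_s > d || n_t > d) {
    warning("n_s or n_t exceeds d: outside the over-parameterized regime the closed forms are not asserted",
            call. = FALSE)
  }
  structure(list(d = d, n_s = n_s, n_t = n_t,
                 c_s = nrow(omega_s), c_t = nrow(omega_t),
                 omega_s = omega_s, omega_t = omega_t,
                 distribution = "gaussian"),
            class = "linear_transfer_task")
}

#' Monte-Carlo risk of the linear transfer estimators
#'
#' Estimates by simulation the risk that [risk_baseline()],
#' [risk_projected()] and [risk_translated()] give in closed form. Per
#' trial, source and target design matrices are drawn with i.i.d. standard
#' normal entries (columns are samples), noiseless labels are formed from
#' the oracle maps, the requested estimator is built from its defining
#' pseudoinverse formula, and the exact conditional risk
#' \eqn{\|\omega_t - \hat w\|_F^2} is recorded — under unit input covariance
#' this equals the expectation over a fresh test point, so no test sampling
#' noise enters.
#'
#' @param task A [linear_transfer_task()].
#' @param estimator One of \code{"baseline"}, \code{"source"},
#'   \code{"projected"}, \code{"translated"}.
#' @param trials Number of independent training draws.
#' @param seed Integer seed; results are reproducible given the seed.
#' @return A list with \code{mean}, \code{se} (standard error of the mean)
#'   and \code{trials}.
#' @export
mc_risk <- function(task, estimator = c("baseline", "source", "projected",
                                        "translated"),
                    trials = 1000L, seed = 1L) {
  stopifnot(inherits(task, "linear_transfer_task"), trials >= 1)
  estimator <- match.arg(estimator)
  if (estimator %in% c("source", "translated") && task$c_s != task$c_t) {
    stop(sprintf("the %s estimator needs c_s = c_t", estimator),
         call. = FALSE)
  }
  d <- task$d; n_s <- task$n_s; n_t <- task$n_t
  ws <- task$omega_s; wt <- task$omega_t
  set.seed(seed)
  risks <- vapply(seq_len(trials), function(i) {
    Xt <- matrix(rnorm(d * n_t), d, n_t)
    if (n_s > 0) {
      Xs <- matrix(rnorm(d * n_s), d, n_s)
      ws_hat <- (ws %*% Xs) %*% pinv(Xs)     # y_s X_s^+
    } else {
      ws_hat <- matrix(0, nrow(ws), d)
    }
    yt <- wt %*% Xt
    w_hat <- switch(estimator,
      baseline = yt %*% pinv(Xt),
      source = ws_hat,
      projected = (yt %*% pinv(ws_hat %*% Xt)) %*% ws_hat,
      translated = ws_hat + (yt - ws_hat %*% Xt) %*% pinv(Xt))
    sum((wt - w_hat)^2)
  }, numeric(1))
  list(mean = mean(risks),
       se = stats::sd(risks) / sqrt(trials),
       trials = trials)
}

#' Limiting risk of the projected predictor as the dimension grows
#'
#' With \eqn{S = n_s/d}, \eqn{T = n_t/d}, \eqn{C = c_s/d} held fixed as
#' \eqn{d \to \infty}, the closed-form projected risk converges to
#' \deqn{[(SC(1-S) + S^2(1 - T(1-C)))(1-T) + 1 - SC(1-S) - S^2]
#'       \|\omega_t\|_F^2 + S^2 T(2-T)\,\varepsilon.}
#' At \eqn{S = 1} this reduces to
#' \eqn{(1 - T + TC)(1-T)\|\omega_t\|_F^2 + \varepsilon T(2-T)}.
#'
#' @param S,T,C Source samples, target samples and source label dimension,
#'   each divided by the ambient dimension; all in \eqn{[0, 1]}.
#' @param epsilon Task-similarity term (squared Frobenius units).
#' @param norm_wt_sq Squared Frobenius norm of the target map.
#' @return The limiting risk, a scalar.
#' @seealso [projected_risk_limit_parts()] for the regime predicates and the small
#'   \eqn{T, C} expansion.
#' @export
projected_risk_limit <- function(S, T, C, epsilon = 0, norm_wt_sq = 1) {
  for (v in list(S = S, T = T, C = C)) {
    if (v < 0 || v > 1) stop("`S`, `T`, `C` must lie in [0, 1]", call. = FALSE)
  }
  C1 <- S * C * (1 - S)
  C2 <- S^2
  K1 <- 1 - T * (1 - C)
  K2 <- T * (2 - T)
  ((C1 + C2 * K1) * (1 - T) + 1 - C1 - C2) * norm_wt_sq + C2 * K2 * epsilon
}

#' Regime predicates and expansions for the limiting projected risk
#'
#' Exposes the qualitative statements that accompany the large-dimension
#' limit:
#' \itemize{
#'   \item \code{monotone_in_S}: the limiting risk is monotonically
#'     decreasing in \eqn{S} on \eqn{[0, 1]} when
#'     \eqn{\varepsilon < (1 - C)\|\omega_t\|_F} (as printed, comparing a
#'     squared norm against an unsquared one; \code{monotone_in_S_sq} gives
#'     the homogeneous variant \eqn{\varepsilon < (1 - C)\|\omega_t\|_F^2}).
#'   \item \code{C_decreases_risk}: increasing \eqn{C} decreases the
#'     limiting risk when \eqn{2S - 1 - ST < 0}; when the sign is reversed,
#'     adding source classes at a fixed source sample count can hurt.
#'   \item \code{small_TC_risk}: the first-order expansion
#'     \eqn{(1 - 2T)\|\omega_t\|_F^2 + 2T\varepsilon} at \eqn{S = 1} for
#'     small \eqn{T} and \eqn{C}.
#' }
#'
#' @inheritParams projected_risk_limit
#' @return A list with the three components above.
#' @export
projected_risk_limit_parts <- function(S, T, C, epsilon = 0, norm_wt_sq = 1) {
  list(monotone_in_S = epsilon < (1 - C) * sqrt(norm_wt_sq),
       monotone_in_S_sq = epsilon < (1 - C) * norm_wt_sq,
       C_decreases_risk = (2 * S - 1 - S * T) < 0,
       small_TC_risk = (1 - 2 * T) * norm_wt_sq + 2 * T * epsilon)
}
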