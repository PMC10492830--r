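#' Drug-screening regression metrics
#'
#' Three metrics used to score imputed expression profiles against held-out
#' measurements; each has a maximum of 1. Rows of \code{pred} and
#' \code{truth} are samples (drug and cell-line combinations), columns are
#' genes.
#'
#' \describe{
#'   \item{\code{pearson_r}}{the uncentered correlation of the two matrices
#'     flattened to vectors,
#'     \eqn{\langle \hat y_v, y^*_v\rangle / (\|\hat y_v\| \|y^*_v\|)}.
#'     No mean is subtracted.}
#'   \item{\code{mean_r2}}{the per-sample coefficient of determination
#'     averaged over samples, with the per-sample mean of the true profile
#'     as the null model:
#'     \eqn{\frac1n \sum_i \big(1 - \sum_j (\hat y_j^{(i)} - y_j^{*(i)})^2 /
#'     \sum_j (y_j^{*(i)} - \bar y^{(i)})^2\big)}. Samples whose true
#'     profile is constant are excluded with a warning. Raw (possibly
#'     negative) per-sample values are averaged without clipping.}
#'   \item{\code{mean_cosine_centered}}{the per-sample cosine similarity
#'     averaged over samples, after subtracting a per-group (e.g. per cell
#'     line) mean profile so that distance from the origin does not inflate
#'     the score. By default the group mean of the \emph{truth} is
#'     subtracted from both matrices; \code{center = "own"} instead centers
#'     each matrix by its own group mean. Samples whose centered vector has
#'     zero norm are excluded with a warning.}
#' }
#'
#' @param pred,truth Numeric matrices of equal shape, samples in rows.
#' @param groups For \code{mean_cosine_centered}: a vector of group labels,
#'   one per sample (all samples in one group if omitted).
#' @param center Which matrix's group mean is subtracted: \code{"truth"}
#'   (default; the same vector is removed from both matrices) or
#'   \code{"own"}.
#' @return A scalar metric value.
#' @export
pearson_r <- function(pred, truth) {
  m <- check_metric_pair(pred, truth)
  p <- as.vector(m$pred); y <- as.vector(m$truth)
  np <- sqrt(sum(p^2)); ny <- sqrt(sum(y^2))
  if (np == 0 || ny == 0) {
    stop("pearson_r is undefined for an all-zero matrix", call. = FALSE)
  }
  sum(p * y) / (np * ny)
}

#' @rdname pearson_r
#' @export
mean_r2 <- function(pred, truth) {
  m <- check_metric_pair(pred, truth)
  pred <- m$pred; truth <- m$truth
  centers <- rowMeans(truth)
  ss_tot <- rowSums((truth - centers)^2)
  ok <- ss_tot > 0
  if (!any(ok)) {
    stop("mean_r2 is undefined: every truth row is constant", call. = FALSE)
  }
  if (!all(ok)) {
    warning(sprintf("excluding %d sample(s) with constant truth profiles from mean_r2",
                    sum(!ok)), call. = FALSE)
  }
  ss_res <- rowSums((pred - truth)^2)
  mean(1 - ss_res[ok] / ss_tot[ok])
}

#' @rdname pearson_r
#' @export
mean_cosine_centered <- function(pred, truth, groups = NULL,
                                 center = c("truth", "own")) {
  center <- match.arg(center)
  m <- check_metric_pair(pred, truth)
  pred <- m$pred; truth <- m$truth
  n <- nrow(truth)
  if (is.null(groups)) groups <- rep(1L, n)
  if (length(groups) != n) {
    stop("`groups` must supply one label per sample", call. = FALSE)
  }
  for (g in unique(groups)) {
    idx <- which(groups == g)
    mu_t <- colMeans(truth[idx, , drop = FALSE])
    mu_p <- if (center == "truth") mu_t
            else colMeans(pred[idx, , drop = FALSE])
    truth[idx, ] <- sweep(truth[idx, , drop = FALSE], 2L, mu_t)
    pred[idx, ] <- sweep(pred[idx, , drop = FALSE], 2L, mu_p)
  }
  np <- sqrt(rowSums(pred^2)); ny <- sqrt(rowSums(truth^2))
  ok <- np > 0 & ny > 0
  if (!any(ok)) {
    stop("mean_cosine_centered is undefined: all centered rows have zero norm",
         call. = FALSE)
  }
  if (!all(ok)) {
    warning(sprintf("excluding %d sample(s) with zero-norm centered profiles from mean_cosine_centered",
                    sum(!ok)), call. = FALSE)
  }
  mean(rowSums(pred[ok, , drop = FALSE] * truth[ok, , drop = FALSE]) /
         (np[ok] * ny[ok]))
}

check_metric_pair <- function(pred, truth) {
  if (is.vector(pred)) pred <- matrix(pred, nrow = 1L)
  if (is.vector(truth)) truth <- matrix(truth, nrow = 1L)
  if (!identical(dim(pred), dim(truth))) {
    stop("`pred` and `truth` must have the same shape", call. = FALSE)
  }
  if (any(!is.finite(pred)) || any(!is.finite(truth))) {
    stop("metric inputs must be finite", call. = FALSE)
  }
  list(pred = pred, truth = truth)
}

#' Fit a logarithmic learning-curve (scaling-law) model
#'
#' Transfer-learned predictors empirically follow a logarithmic learning
#' curve: performance as a function of the number of target samples \eqn{n}
#' is well described by \eqn{y = a \log_2 n + b}. This fits \eqn{a, b} by
#' ordinary least squares and reports the coefficient of determination. In
#' the degenerate case of zero residual and zero score variance (constant
#' scores), \eqn{R^2} is defined as 1 by continuity.
#'
#' @param n_values Positive integers (target sample counts); at least two
#'   distinct values.
#' @param scores Numeric scores (accuracy, \eqn{R^2}, ...), one per entry of
#'   \code{n_values}. Scores at the same \code{n} averaged over seeds are
#'   the intended curve points.
#' @return An object of class \code{scaling_fit} with fields \code{a}
#'   (slope per doubling of \eqn{n}), \code{b} (intercept) and
#'   \code{r_squared}.
#' @seealso [extrapolate_log_law()]
#' @export
fit_log_law <- function(n_values, scores) {
  if (length(n_values) != length(scores)) {
    stop("`n_values` and `scores` must have equal length", call. = FALSE)
  }
  if (any(n_values <= 0)) stop("`n_values` must be positive", call. = FALSE)
  if (length(unique(n_values)) < 2L) {
    stop("need at least 2 distinct n values to fit a scaling law",
         call. = FALSE)
  }
  x <- log2(n_values)
  fit <- stats::lm.fit(cbind(1, x), scores)
  b <- unname(fit$coefficients[1L])
  a <- unname(fit$coefficients[2L])
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((scores - mean(scores))^2)
  r2 <- if (ss_tot == 0) {
    if (ss_res < 1e-24) 1 else -Inf
  } else {
    1 - ss_res / ss_tot
  }
  structure(list(a = a, b = b, r_squared = r2), class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("Scaling law: score = %.4g * log2(n) + %.4g  (R^2 = %.4f)\n",
              x$a, x$b, x$r_squared))
  invisible(x)
}

#' Extrapolate a fitted scaling law
#'
#' @param fit A \code{scaling_fit} from [fit_log_law()].
#' @param n Positive target sample count(s) at which to predict.
#' @return Predicted score(s) \eqn{a \log_2 n + b}.
#' @export
extrapolate_log_law <- function(fit, n) {
  stopifnot(inherits(fit, "scaling_fit"))
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  fit$a * log2(n) + fit$b
}
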