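#' Transfer a fitted source model to a target task
#'
#' Three operators adapt a frozen source predictor \eqn{\hat f_s} to a target
#' dataset \eqn{(X_t, Y_t)}:
#' \describe{
#'   \item{projection (\code{fit_projected})}{fits a secondary model (the
#'     head) on the source predictions \eqn{\hat f_s(X_t)} against the target
#'     labels; the transferred predictor is
#'     \eqn{x \mapsto \hat f_p(\hat f_s(x))}. Suited to tasks whose label
#'     sets differ, e.g. many source classes refined into few target
#'     classes.}
#'   \item{translation (\code{fit_translated})}{fits the head on the raw
#'     target inputs against the residuals \eqn{Y_t - \hat f_s(X_t)}; the
#'     transferred predictor is \eqn{x \mapsto \hat f_s(x) + \hat f_c(x)}.
#'     Requires matching label dimensions and suits feature-distribution
#'     shift.}
#'   \item{combined (\code{fit_projected_translated})}{fits the head on the
#'     column-concatenation \eqn{[\hat f_s(x) \,|\, x]}; natural when source
#'     outputs and target inputs live in the same space, as in expression
#'     imputation where both are gene-expression vectors.}
#' }
#' In every case the head is the minimum-norm solution when \code{ridge = 0}
#' and the head family admits infinitely many minimizers; the source model is
#' frozen and never refit.
#'
#' @param source A fitted \code{kernel_model} or \code{linear_model}.
#' @param X_t Target inputs, samples in rows.
#' @param Y_t Target labels, samples in rows.
#' @param head_spec Either a \code{kernel_spec} for a kernel head or the
#'   string \code{"linear"} for a linear head.
#' @param ridge Non-negative ridge coefficient for the head fit.
#' @param blocks For the combined operator only: which blocks of
#'   \eqn{[\hat f_s(x) \,|\, x]} the head consumes. Dropping
#'   \code{"features"} recovers projection; the default uses both.
#' @return An object of class \code{transfer_model} with fields \code{mode},
#'   \code{source} and \code{head}.
#' @seealso [predict.transfer_model()], [evaluate_classification()]
#' @export
fit_projected <- function(source, X_t, Y_t, head_spec = laplace_kernel(),
                          ridge = 0) {
  X_t <- check_sample_matrix(X_t, "X_t")
  Y_t <- as_label_matrix(Y_t, nrow(X_t), "Y_t")
  P <- predict(source, X_t)
  warn_if_degenerate(P)
  head <- fit_head(head_spec, P, Y_t, ridge)
  new_transfer_model("projected", source, head)
}

#' @rdname fit_projected
#' @export
fit_translated <- function(source, X_t, Y_t, head_spec = laplace_kernel(),
                           ridge = 0) {
  X_t <- check_sample_matrix(X_t, "X_t")
  Y_t <- as_label_matrix(Y_t, nrow(X_t), "Y_t")
  P <- predict(source, X_t)
  if (ncol(P) != ncol(Y_t)) {
    stop(sprintf(paste0(
      "translation requires matching label dimensions (source predicts %d ",
      "outputs, target has %d); use the projected or combined operator for ",
      "differing label sets"), ncol(P), ncol(Y_t)), call. = FALSE)
  }
  head <- fit_head(head_spec, X_t, Y_t - P, ridge)
  new_transfer_model("translated", source, head)
}

#' @rdname fit_projected
#' @export
fit_projected_translated <- function(source, X_t, Y_t,
                                     head_spec = laplace_kernel(),
                                     ridge = 0,
                                     blocks = c("source", "features")) {
  blocks <- match.arg(blocks, c("source", "features"), several.ok = TRUE)
  X_t <- check_sample_matrix(X_t, "X_t")
  Y_t <- as_label_matrix(Y_t, nrow(X_t), "Y_t")
  P <- predict(source, X_t)
  if ("source" %in% blocks) warn_if_degenerate(P)
  Z <- concat_blocks(P, X_t, blocks)
  head <- fit_head(head_spec, Z, Y_t, ridge)
  new_transfer_model("projected_translated", source, head, blocks = blocks)
}

new_transfer_model <- function(mode, source, head,
                               blocks = c("source", "features")) {
  structure(list(mode = mode, source = source, head = head, blocks = blocks),
            class = "transfer_model")
}

fit_head <- function(head_spec, X, Y, ridge) {
  if (identical(head_spec, "linear")) {
    fit_linear(X, Y, ridge)
  } else {
    fit_kernel(as_kernel_spec(head_spec), X, Y, ridge)
  }
}

# The two blocks are concatenated raw, without per-block rescaling: in the
# drug-screening application both carry expression-scale units.
concat_blocks <- function(P, X, blocks) {
  parts <- list()
  if ("source" %in% blocks) parts <- c(parts, list(P))
  if ("features" %in% blocks) parts <- c(parts, list(X))
  do.call(cbind, parts)
}

warn_if_degenerate <- function(P) {
  if (nrow(P) > 1L && all(abs(sweep(P, 2L, P[1L, ])) < 1e-12)) {
    warning("source predictions are constant across target samples; the projection head can only fit a constant",
            call. = FALSE)
  }
}

#' Predict from a transfer model
#'
#' @param object A \code{transfer_model}.
#' @param newdata New inputs, samples in rows (target feature space).
#' @param ... Unused.
#' @return A matrix of predictions, one row per sample.
#' @export
predict.transfer_model <- function(object, newdata, ...) {
  newdata <- check_sample_matrix(newdata, "newdata")
  switch(object$mode,
         projected = predict(object$head, predict(object$source, newdata)),
         translated = predict(object$source, newdata) +
           predict(object$head, newdata),
         projected_translated = {
           P <- predict(object$source, newdata)
           predict(object$head, concat_blocks(P, newdata, object$blocks))
         })
}

#' @export
print.transfer_model <- function(x, ...) {
  cat(sprintf("Transfer model (%s)\n  source: ", x$mode))
  print(x$source)
  cat("  head: ")
  print(x$head)
  invisible(x)
}

#' Classification accuracy of a regression-on-one-hot model
#'
#' Kernel classifiers here are regressors trained on one-hot class labels;
#' the decoded class is the argmax over outputs, ties broken by the lowest
#' class index.
#'
#' @param model Any fitted model with a \code{predict} method returning one
#'   row per sample.
#' @param X Inputs, samples in rows; must be non-empty.
#' @param Y One-hot label matrix, samples in rows.
#' @return The fraction of samples whose predicted argmax matches the label
#'   argmax, in \eqn{[0, 1]}.
#' @export
evaluate_classification <- function(model, X, Y) {
  X <- check_sample_matrix(X, "X")
  if (nrow(X) == 0L) stop("`X` must contain at least one sample", call. = FALSE)
  Y <- as_label_matrix(Y, nrow(X))
  P <- predict(model, X)
  mean(max.col(P, ties.method = "first") ==
         max.col(Y, ties.method = "first"))
}

#' One-hot encode integer class labels
#'
#' @param classes Integer class indices in \code{1:n_classes}.
#' @param n_classes Number of classes (defaults to \code{max(classes)}).
#' @return An \code{length(classes)} by \code{n_classes} 0/1 matrix.
#' @export
one_hot <- function(classes, n_classes = max(classes)) {
  classes <- as.integer(classes)
  if (any(classes < 1L | classes > n_classes)) {
    stop("`classes` must lie in 1:n_classes", call. = FALSE)
  }
  Y <- matrix(0, length(classes), n_classes)
  Y[cbind(seq_along(classes), classes)] <- 1
  Y
}
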