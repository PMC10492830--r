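#' Moore-Penrose pseudoinverse
#'
#' Singular values below \code{max(dim(A)) * eps * max(sv)} are treated as
#' zero, the standard reproducible rank cutoff.
#'
#' @param A A numeric matrix.
#' @param tol Optional absolute singular-value cutoff; by default derived
#'   from the machine epsilon as described above.
#' @return The pseudoinverse of \code{A}.
#' @export
pinv <- function(A, tol = NULL) {
  A <- as.matrix(A)
  if (length(A) == 0L) return(t(A))
  s <- svd(A)
  if (is.null(tol)) tol <- max(dim(A)) * .Machine$double.eps * max(s$d, 0)
  keep <- s$d > tol
  if (!any(keep)) return(matrix(0, ncol(A), nrow(A)))
  s$v[, keep, drop = FALSE] %*%
    (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

as_label_matrix <- function(Y, n, name = "Y") {
  if (is.vector(Y) && is.numeric(Y)) Y <- matrix(Y, ncol = 1L)
  if (!is.matrix(Y) || !is.numeric(Y)) {
    stop(sprintf("`%s` must be a numeric matrix (rows are samples)", name),
         call. = FALSE)
  }
  if (nrow(Y) != n) {
    stop(sprintf("`%s` has %d rows but there are %d samples", name,
                 nrow(Y), n), call. = FALSE)
  }
  if (any(!is.finite(Y))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  Y
}

#' Fit a kernel regressor
#'
#' Solves kernel ridge regression on a training set, or the minimum-norm
#' interpolating solution when \code{ridge = 0}. With Gram matrix
#' \eqn{K_n} and labels \eqn{Y} (rows are samples), the coefficient matrix is
#' \eqn{\alpha = Y^\top (K_n + \lambda I)^{-1}} for \eqn{\lambda > 0} and
#' \eqn{\alpha = Y^\top K_n^\dagger} for \eqn{\lambda = 0}. The ridge
#' \eqn{\lambda} is added to the Gram diagonal unscaled by the sample count.
#'
#' @param spec A \code{kernel_spec}.
#' @param X Training inputs, samples in rows (\eqn{n \times d}).
#' @param Y Training labels, samples in rows (\eqn{n \times c}); a vector is
#'   treated as a single output column.
#' @param ridge Non-negative ridge coefficient \eqn{\lambda}.
#' @return An object of class \code{kernel_model} with fields \code{spec},
#'   \code{X_train}, \code{alpha} (a \eqn{c \times n} matrix) and
#'   \code{ridge}.
#' @seealso [predict.kernel_model()], [fit_linear()]
#' @export
fit_kernel <- function(spec, X, Y, ridge = 0) {
  spec <- as_kernel_spec(spec)
  X <- check_sample_matrix(X, "X")
  Y <- as_label_matrix(Y, nrow(X))
  if (!is.numeric(ridge) || length(ridge) != 1L || !is.finite(ridge) ||
      ridge < 0) {
    stop("`ridge` must be a single non-negative number", call. = FALSE)
  }
  K <- gram_matrix(spec, X)
  alpha <- t(solve_coefficients(K, Y, ridge))
  structure(list(spec = spec, X_train = X, alpha = alpha,
                 ridge = as.numeric(ridge)),
            class = "kernel_model")
}

# returns the n x c matrix (K + ridge I)^{-1} Y, falling back to the
# pseudoinverse (with a warning) when the direct solve fails
solve_coefficients <- function(K, Y, ridge) {
  n <- nrow(K)
  if (ridge > 0) {
    Kr <- K + diag(ridge, n)
    out <- tryCatch(solve(Kr, Y), error = function(e) NULL)
    if (is.null(out)) {
      warning("regularized Gram matrix is numerically singular; using the pseudoinverse",
              call. = FALSE)
      out <- pinv(Kr) %*% Y
    }
    out
  } else {
    pinv(K) %*% Y
  }
}

#' Predict from a fitted kernel model
#'
#' Evaluates \eqn{\hat f(x) = \alpha K(X_{train}, x)} at new inputs.
#'
#' @param object A \code{kernel_model}.
#' @param newdata New inputs, samples in rows.
#' @param ... Unused.
#' @return A matrix of predictions with one row per row of \code{newdata}
#'   and one column per output.
#' @export
predict.kernel_model <- function(object, newdata, ...) {
  newdata <- check_sample_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$X_train)) {
    stop(sprintf("`newdata` has %d features but the model was trained on %d",
                 ncol(newdata), ncol(object$X_train)), call. = FALSE)
  }
  if (nrow(newdata) == 0L) {
    return(matrix(numeric(0), nrow = 0L, ncol = nrow(object$alpha)))
  }
  K <- gram_matrix(object$spec, object$X_train, newdata)   # n x m
  t(object$alpha %*% K)                                    # m x c
}

#' @export
print.kernel_model <- function(x, ...) {
  cat(sprintf("Kernel regression model: %d samples, %d features, %d outputs, ridge = %g\n",
              nrow(x$X_train), ncol(x$X_train), nrow(x$alpha), x$ridge))
  print(x$spec)
  invisible(x)
}

#' Minimum-norm linear regression (columns are samples)
#'
#' Returns \eqn{\hat w = Y X^\dagger}, the minimizer of
#' \eqn{\|Y - W X\|_F^2} of smallest Frobenius norm. This is the orientation
#' used by the linear risk theory: \code{X} is \eqn{d \times n} with samples
#' in columns and \code{Y} is \eqn{c \times n}.
#'
#' @param X A \eqn{d \times n} matrix, samples in columns.
#' @param Y A \eqn{c \times n} matrix of labels, samples in columns; a
#'   vector is treated as a single output row.
#' @return An object of class \code{linear_model} whose \code{weights} field
#'   is the \eqn{c \times d} matrix \eqn{Y X^\dagger}.
#' @seealso [fit_linear()] for the rows-are-samples convention.
#' @export
min_norm_linear <- function(X, Y) {
  X <- as.matrix(X)
  if (is.vector(Y)) Y <- matrix(Y, nrow = 1L)
  Y <- as.matrix(Y)
  if (ncol(Y) != ncol(X)) {
    stop("`X` and `Y` must have the same number of columns (samples)",
         call. = FALSE)
  }
  linear_model(Y %*% pinv(X))
}

#' Construct a linear model from a weight matrix
#'
#' @param weights A \eqn{c \times d} numeric matrix with finite entries.
#' @return An object of class \code{linear_model}.
#' @export
linear_model <- function(weights) {
  weights <- as.matrix(weights)
  if (any(!is.finite(weights))) {
    stop("`weights` must have finite entries", call. = FALSE)
  }
  structure(list(weights = weights), class = "linear_model")
}

#' Fit a linear regressor (rows are samples)
#'
#' Rows-are-samples counterpart of [min_norm_linear()]: fits
#' \eqn{\min_W \|Y - X W^\top\|_F^2}, returning the minimum-norm solution
#' when \code{ridge = 0} and the ridge solution
#' \eqn{W^\top = (X^\top X + \lambda I)^{-1} X^\top Y} otherwise.
#'
#' @param X Inputs, samples in rows (\eqn{n \times d}).
#' @param Y Labels, samples in rows (\eqn{n \times c}).
#' @param ridge Non-negative ridge coefficient.
#' @return A \code{linear_model} with a \eqn{c \times d} weight matrix.
#' @export
fit_linear <- function(X, Y, ridge = 0) {
  X <- check_sample_matrix(X, "X")
  Y <- as_label_matrix(Y, nrow(X))
  if (ridge < 0) stop("`ridge` must be non-negative", call. = FALSE)
  if (ridge > 0) {
    A <- crossprod(X) + diag(ridge, ncol(X))
    W <- tryCatch(t(solve(A, crossprod(X, Y))), error = function(e) NULL)
    if (is.null(W)) {
      warning("regularized normal equations are numerically singular; using the pseudoinverse",
              call. = FALSE)
      W <- t(pinv(A) %*% crossprod(X, Y))
    }
    linear_model(W)
  } else {
    min_norm_linear(t(X), t(Y))
  }
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  newdata <- check_sample_matrix(newdata, "newdata")
  if (ncol(newdata) != ncol(object$weights)) {
    stop(sprintf("`newdata` has %d features but the model expects %d",
                 ncol(newdata), ncol(object$weights)), call. = FALSE)
  }
  tcrossprod(newdata, object$weights)
}

#' @export
print.linear_model <- function(x, ...) {
  cat(sprintf("Linear model: %d outputs, %d features\n",
              nrow(x$weights), ncol(x$weights)))
  invisible(x)
}

n_outputs <- function(model) {
  if (inherits(model, "kernel_model")) nrow(model$alpha)
  else if (inherits(model, "linear_model")) nrow(model$weights)
  else if (inherits(model, "transfer_model")) n_outputs(model$head)
  else stop("unsupported model type", call. = FALSE)
}

#' Save / load fitted models as plain-text directories
#'
#' A model is stored as a directory of delimited matrices plus a JSON config
#' block, so fitted predictors can be exchanged between runs and with the
#' command-line interface.
#'
#' @param model A \code{kernel_model} or \code{linear_model}.
#' @param path Directory to create (or read).
#' @return \code{save_model} returns \code{path} invisibly;
#'   \code{load_model} returns the model.
#' @export
save_model <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  if (inherits(model, "kernel_model")) {
    cfg <- list(type = "kernel_model", spec = kernel_spec_to_list(model$spec),
                ridge = model$ridge)
    write_matrix(model$X_train, file.path(path, "X_train.csv"))
    write_matrix(model$alpha, file.path(path, "alpha.csv"))
  } else if (inherits(model, "linear_model")) {
    cfg <- list(type = "linear_model")
    write_matrix(model$weights, file.path(path, "weights.csv"))
  } else {
    stop("only kernel_model and linear_model objects can be saved",
         call. = FALSE)
  }
  jsonlite::write_json(cfg, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  cfg <- jsonlite::read_json(file.path(path, "model.json"),
                             simplifyVector = TRUE)
  if (identical(cfg$type, "kernel_model")) {
    structure(list(spec = as_kernel_spec(as.list(cfg$spec)),
                   X_train = read_matrix(file.path(path, "X_train.csv")),
                   alpha = read_matrix(file.path(path, "alpha.csv")),
                   ridge = cfg$ridge),
              class = "kernel_model")
  } else if (identical(cfg$type, "linear_model")) {
    linear_model(read_matrix(file.path(path, "weights.csv")))
  } else {
    stop(sprintf("unknown model type '%s' in %s", cfg$type, path),
         call. = FALSE)
  }
}
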