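#' Kernel specifications
#'
#' A kernel spec is a small declarative object naming a kernel family and its
#' hyperparameters. Two families are supported:
#' \describe{
#'   \item{laplace}{\eqn{K(x, z) = \exp(-\|x - z\|_2 / L)} with bandwidth
#'     \eqn{L > 0} in units of input distance.}
#'   \item{ntk_fc}{The neural tangent kernel of an infinitely wide
#'     fully-connected ReLU network with \code{depth} hidden layers,
#'     optionally with a constant bias (offset) feature appended to the
#'     input.}
#' }
#'
#' @param bandwidth Positive bandwidth \eqn{L} of the Laplace kernel. The
#'   default of 10 is the value commonly used for image-scale inputs.
#' @param depth Number of hidden layers of the ReLU network, a positive
#'   integer.
#' @param offset Logical; if \code{TRUE} a constant feature equal to 1 is
#'   appended to every input before the NTK recursion, which corresponds to a
#'   network with a bias-like offset term.
#' @return An object of class \code{kernel_spec}.
#' @examples
#' laplace_kernel(10)
#' ntk_kernel(depth = 1, offset = TRUE)
#' @export
laplace_kernel <- function(bandwidth = 10) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop("`bandwidth` must be a single positive finite number", call. = FALSE)
  }
  structure(list(family = "laplace", bandwidth = as.numeric(bandwidth)),
            class = "kernel_spec")
}

#' @rdname laplace_kernel
#' @export
ntk_kernel <- function(depth = 5, offset = FALSE) {
  if (!is.numeric(depth) || length(depth) != 1L || !is.finite(depth) ||
      depth < 1 || depth != round(depth)) {
    stop("`depth` must be a positive integer", call. = FALSE)
  }
  if (!is.logical(offset) || length(offset) != 1L || is.na(offset)) {
    stop("`offset` must be TRUE or FALSE", call. = FALSE)
  }
  structure(list(family = "ntk_fc", depth = as.integer(depth),
                 offset = offset),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  if (x$family == "laplace") {
    cat(sprintf("Laplace kernel (bandwidth L = %g)\n", x$bandwidth))
  } else {
    cat(sprintf("Fully-connected ReLU NTK (depth %d%s)\n", x$depth,
                if (isTRUE(x$offset)) ", with offset" else ""))
  }
  invisible(x)
}

#' Convert a kernel spec to / from a plain list
#'
#' Supports serialization of kernel specifications as a structured config
#' block \code{{family, bandwidth, depth, offset}}.
#'
#' @param x A \code{kernel_spec} (for \code{kernel_spec_to_list}) or a named
#'   list with a \code{family} entry (for \code{as_kernel_spec}).
#' @return A plain named list, or a \code{kernel_spec}.
#' @export
kernel_spec_to_list <- function(x) {
  stopifnot(inherits(x, "kernel_spec"))
  unclass(x)
}

#' @rdname kernel_spec_to_list
#' @export
as_kernel_spec <- function(x) {
  if (inherits(x, "kernel_spec")) return(x)
  if (identical(x, "linear") || identical(x, list(family = "linear"))) {
    stop("a linear head is requested with head_spec = \"linear\", not a kernel_spec",
         call. = FALSE)
  }
  if (!is.list(x) || is.null(x$family)) {
    stop("cannot interpret `x` as a kernel spec", call. = FALSE)
  }
  switch(x$family,
         laplace = laplace_kernel(x$bandwidth %||% 10),
         ntk_fc = ntk_kernel(x$depth %||% 5, isTRUE(x$offset)),
         stop(sprintf("unknown kernel family '%s'", x$family), call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_sample_matrix <- function(X, name = "X") {
  if (is.vector(X) && is.numeric(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop(sprintf("`%s` must be a numeric matrix (rows are samples)", name),
         call. = FALSE)
  }
  if (any(!is.finite(X))) {
    stop(sprintf("`%s` contains non-finite entries", name), call. = FALSE)
  }
  X
}

#' Evaluate a kernel on a pair of feature vectors
#'
#' @param spec A \code{kernel_spec}.
#' @param x,z Numeric vectors of equal length.
#' @return The scalar kernel value \eqn{K(x, z)}.
#' @examples
#' kernel_value(laplace_kernel(10), c(0, 0, 0), c(6, 8, 0))  # exp(-1)
#' @export
kernel_value <- function(spec, x, z) {
  if (length(x) != length(z)) {
    stop("`x` and `z` must have the same dimension", call. = FALSE)
  }
  if (length(x) < 1L) stop("inputs must have dimension >= 1", call. = FALSE)
  G <- gram_matrix(spec, matrix(as.numeric(x), nrow = 1L),
                   matrix(as.numeric(z), nrow = 1L))
  G[1L, 1L]
}

#' Gram matrix between two sample sets
#'
#' Computes the matrix with entry \eqn{(i, j)} equal to the kernel evaluated
#' on row \eqn{i} of \code{X} and row \eqn{j} of \code{Z}. Rows are samples.
#' \code{gram_matrix(spec, X, X)} is symmetric and positive semidefinite up
#' to numerical tolerance.
#'
#' @param spec A \code{kernel_spec}.
#' @param X,Z Numeric matrices with the same number of columns (features).
#'   \code{Z} defaults to \code{X}.
#' @return An \code{nrow(X)} by \code{nrow(Z)} numeric matrix.
#' @export
gram_matrix <- function(spec, X, Z = X) {
  spec <- as_kernel_spec(spec)
  X <- check_sample_matrix(X, "X")
  Z <- check_sample_matrix(Z, "Z")
  if (ncol(X) != ncol(Z)) {
    stop(sprintf("feature dimension mismatch: X has %d columns, Z has %d",
                 ncol(X), ncol(Z)), call. = FALSE)
  }
  switch(spec$family,
         laplace = laplace_gram(X, Z, spec$bandwidth),
         ntk_fc = ntk_gram(X, Z, spec$depth, spec$offset))
}

laplace_gram <- function(X, Z, bandwidth) {
  # squared distances via the inner-product expansion; clamp the tiny
  # negatives that cancellation can produce before the square root
  sq <- outer(rowSums(X^2), rowSums(Z^2), "+") - 2 * tcrossprod(X, Z)
  sq[sq < 0] <- 0
  G <- exp(-sqrt(sq) / bandwidth)
  if (identical(dim(X), dim(Z)) && isTRUE(all.equal(X, Z, tolerance = 0))) {
    G <- (G + t(G)) / 2
  }
  G
}

# ReLU arc-cosine maps used by the NTK recursion.
kappa0 <- function(u) (pi - acos(u)) / pi
kappa1 <- function(u) (u * (pi - acos(u)) + sqrt(pmax(1 - u^2, 0))) / pi

ntk_gram <- function(X, Z, depth, offset) {
  if (isTRUE(offset)) {
    X <- cbind(X, 1)
    Z <- cbind(Z, 1)
  }
  sxz <- tcrossprod(X, Z)           # Sigma^0(x, z)
  sxx <- rowSums(X^2)               # Sigma^l(x, x); invariant across layers
  szz <- rowSums(Z^2)
  norms <- outer(sqrt(sxx), sqrt(szz))
  theta <- sxz
  for (l in seq_len(depth)) {
    lam <- ifelse(norms > 0, sxz / pmax(norms, .Machine$double.xmin), 0)
    lam <- pmin(pmax(lam, -1), 1)   # absorb floating-point drift for acos
    sxz <- norms * kappa1(lam)
    theta <- theta * kappa0(lam) + sxz
  }
  same <- nrow(X) == nrow(Z) && isTRUE(all.equal(X, Z, tolerance = 0))
  if (same) theta <- (theta + t(theta)) / 2
  theta
}
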