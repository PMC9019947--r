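`%||%` <- function(a, b) if (is.null(a)) b else a

#' Squared Euclidean distances between two sets of row vectors
#'
#' @param A numeric matrix (n x v).
#' @param B numeric matrix (m x v).
#' @return n x m matrix of squared distances; small negative values from
#'   floating-point cancellation are clamped to zero.
#' @keywords internal
#' @noRd
sqdist <- function(A, B) {
  D <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  D[D < 0] <- 0
  D
}

as_matrix_input <- function(X) {
  if (inherits(X, "feature_matrix")) X <- X$values
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("expected a numeric matrix or a 'feature_matrix'", call. = FALSE)
  }
  X
}

check_labels <- function(labels, n, K = NULL) {
  if (length(labels) != n) {
    stop(sprintf("expected %d labels, got %d", n, length(labels)), call. = FALSE)
  }
  labels <- as.integer(labels)
  if (anyNA(labels) || any(labels < 1L)) stop("labels must be integers >= 1", call. = FALSE)
  if (!is.null(K) && any(labels > K)) {
    stop(sprintf("labels exceed K = %d", K), call. = FALSE)
  }
  labels
}
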