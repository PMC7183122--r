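#' Gaussian kernel between weighted feature vectors
#'
#' `k(u, v) = exp(-||u - v||^2 / (2 sigma^2))`, so `k` lies in (0, 1] and
#' `k(u, u) = 1`.
#'
#' @param u,v numeric vectors of equal length.
#' @param sigma kernel bandwidth, > 0.
#' @return scalar kernel value.
#' @export
gaussian_kernel <- function(u, v, sigma) {
  check_sigma(sigma)
  if (length(u) != length(v)) stopf("u and v must have the same length")
  exp(-sum((u - v)^2) / (2 * sigma^2))
}

check_sigma <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) || sigma <= 0)
    stopf("kernel bandwidth sigma must be a single finite positive number")
  invisible(sigma)
}

# k(x, X[rows, ]) as a vector; x a single feature row
kernel_row <- function(x, X, rows, sigma) {
  check_sigma(sigma)
  if (length(rows) == 0L) return(numeric(0))
  if (any(rows < 1L | rows > nrow(X))) stopf("stale index in kernel_row")
  D2 <- colSums((t(X[rows, , drop = FALSE]) - x)^2)
  exp(-D2 / (2 * sigma^2))
}

# dense Gram matrix on the given rows
gram_matrix <- function(X, sigma, rows = seq_len(nrow(X))) {
  check_sigma(sigma)
  D <- as.matrix(stats::dist(X[rows, , drop = FALSE]))
  exp(-D^2 / (2 * sigma^2))
}

# cross-kernel matrix K[i, j] = k(A[i, ], B[j, ])
cross_kernel <- function(A, B, sigma) {
  check_sigma(sigma)
  aa <- rowSums(A^2); bb <- rowSums(B^2)
  D2 <- outer(aa, bb, "+") - 2 * tcrossprod(A, B)
  D2[D2 < 0] <- 0
  exp(-D2 / (2 * sigma^2))
}
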