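#' Hinge and ramp losses
#'
#' `hinge(t) = max(0, 1 - t)`. The ramp loss truncates the hinge at a plateau
#' of height `1 - s`: `ramp(t, s) = min(1 - s, max(0, 1 - t))`, equivalently
#' `hinge(t) - max(0, s - t)`. The plateau is what bounds the influence of
#' mislabeled (incorrect) target PSMs on the fit.
#'
#' @param t margin value(s) `y * f(x)`.
#' @param s ramp truncation parameter, `s < 1`.
#' @return numeric loss value(s).
#' @export
hinge <- function(t) pmax(0, 1 - t)

#' @rdname hinge
#' @export
ramp <- function(t, s) {
  if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s >= 1)
    stopf("ramp parameter s must be a single number < 1")
  pmin(1 - s, pmax(0, 1 - t))
}

#' Model parameters for the cost-sensitive kernel ranker
#'
#' `C1` weighs decoy (hinge) losses and `C2` target (ramp) losses; a decoy
#' scored as a target is a certain error, so `C1 >= C2` is enforced. The
#' selection-pressure parameter of the underlying weighted model is
#' `lambda = C2 * (1 - s)`; it is parameterized here through the ramp
#' truncation `s`, restricted to (-1, 1) so the ramp plateau stays below two
#' hinge units.
#'
#' @param C1 decoy loss weight, > 0.
#' @param C2 target loss weight, 0 < C2 <= C1.
#' @param s ramp truncation, in (-1, 1).
#' @param sigma Gaussian kernel bandwidth, > 0.
#' @param weights 9 per-attribute feature weights.
#' @param M maximum active-set size for the online solver.
#' @param m_frac fraction of the active set removed by a CLEAN pass.
#' @return object of class `cs_params`.
#' @export
cs_params <- function(C1 = 2, C2 = 1, s = 0, sigma = 3,
                      weights = default_feature_weights(),
                      M = 1000L, m_frac = 0.35) {
  if (!is.numeric(C2) || C2 <= 0) stopf("C2 must be > 0")
  if (!is.numeric(C1) || C1 < C2) stopf("C1 >= C2 > 0 is required (decoy losses weigh at least as much)")
  if (!is.numeric(s) || s <= -1 || s >= 1) stopf("s must lie in (-1, 1)")
  check_sigma(sigma)
  if (!is.numeric(M) || M < 1) stopf("M must be >= 1")
  if (!is.numeric(m_frac) || m_frac <= 0 || m_frac >= 1) stopf("m_frac must be in (0, 1)")
  structure(list(C1 = C1, C2 = C2, s = s, lambda = C2 * (1 - s), sigma = sigma,
                 weights = weights, M = as.integer(M), m_frac = m_frac),
            class = "cs_params")
}

#' @export
print.cs_params <- function(x, ...) {
  cat(sprintf("cost-sensitive ranker parameters: C1 = %g, C2 = %g, s = %g (lambda = %g), sigma = %g, M = %d, m_frac = %g\n",
              x$C1, x$C2, x$s, x$lambda, x$sigma, x$M, x$m_frac))
  invisible(x)
}

# Dual box bounds per index.
#   decoy  (y = -1):            [-C1, 0]
#   target (y = +1), eta = 0:   [0, C2]
#   target (y = +1), eta = 1:   [-C2, 0]
# General form: A = min(0, C y) - C eta y, B = max(0, C y) - C eta y
# (eta fixed at 0 for decoys).
bounds_for <- function(label, C1, C2, eta = NULL) {
  label <- as.integer(label)
  n <- length(label)
  if (is.null(eta)) eta <- numeric(n)
  if (length(eta) != n || anyNA(eta[label == 1L]))
    stopf("eta must be supplied (0/1) for every target index")
  eta <- ifelse(label == 1L, eta, 0)
  C <- ifelse(label == 1L, C2, C1)
  A <- pmin(0, C * label) - C * eta * label
  B <- pmax(0, C * label) - C * eta * label
  cbind(A = A, B = B)
}

# eta_i = 1 iff y_i f(x_i) < s (strict), defined for target indices
eta_rule <- function(f, s, label = 1L) as.numeric(label * f < s)

#' Discriminant value of a kernel expansion
#'
#' `f(x) = sum_j alpha_j k(x_j, x)` over the active set; there is no
#' intercept term.
#'
#' @param Xnew matrix of query feature rows (weighted, normalized scale).
#' @param Xactive matrix of active-set feature rows.
#' @param alpha dual coefficients aligned with `Xactive` rows.
#' @param sigma kernel bandwidth.
#' @return numeric vector of discriminant values.
#' @export
discriminant <- function(Xnew, Xactive, alpha, sigma) {
  Xnew <- rbind(Xnew)
  if (length(alpha) == 0L) return(numeric(nrow(Xnew)))
  as.vector(cross_kernel(Xnew, rbind(Xactive), sigma) %*% alpha)
}

# G(alpha) = -1/2 a'Ka + <a, y> + C2 * sum(eta over targets)
dual_objective <- function(alpha, K, y, eta, C2, label = NULL) {
  eta_sum <- if (is.null(label)) sum(eta) else sum(eta[label == 1L])
  -0.5 * drop(crossprod(alpha, K %*% alpha)) + sum(alpha * y) + C2 * eta_sum
}

# J(w) = 1/2||w||^2 + C1 sum_decoys hinge(y f) + C2 sum_targets ramp(y f, s)
# with ||w||^2 = a'Ka over the expansion indices; f over all rows.
primal_objective <- function(alpha, K, f, y, params) {
  wnorm2 <- drop(crossprod(alpha, K %*% alpha))
  dec <- y == -1L
  0.5 * wnorm2 + params$C1 * sum(hinge(y[dec] * f[dec])) +
    params$C2 * sum(ramp(y[!dec] * f[!dec], params$s))
}

# KKT violation per coordinate for the box-constrained dual:
# v_i = g_i if alpha_i < B_i and g_i > 0; -g_i if alpha_i > A_i and g_i < 0; else 0
kkt_violation <- function(alpha, g, A, B, slack = 1e-10) {
  up <- (alpha < B - slack) & (g > 0)
  dn <- (alpha > A + slack) & (g < 0)
  v <- numeric(length(alpha))
  v[up] <- g[up]
  v[dn] <- -g[dn]
  v
}
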