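# Full-batch reference solver: CCCP outer loop over the ramp-loss objective,
# exact box-constrained coordinate ascent on the Lagrange dual inside.
# Correctness baseline for the online active-set solver; quadratic memory in n.

# Maximize G(a) = -1/2 a'Ka + <a,y> subject to A <= a <= B by cyclic exact
# coordinate ascent. With no equality constraint, the single-coordinate
# maximizer is exact: a_i <- clip(a_i + g_i / K_ii, A_i, B_i).
solve_inner <- function(K, y, A, B, alpha = NULL, tol = 1e-5, max_sweeps = 10000L) {
  n <- length(y)
  if (is.null(alpha)) alpha <- numeric(n)
  alpha <- clip(alpha, A, B)
  g <- y - drop(K %*% alpha)
  kd <- diag(K)
  converged <- FALSE
  sweeps <- 0L
  while (sweeps < max_sweeps) {
    sweeps <- sweeps + 1L
    # shrinking: bound-locked coordinates with satisfied KKT conditions are
    # settled; sweep only over violators and interior coordinates
    v <- kkt_violation(alpha, g, A, B)
    if (max(v) < tol) { converged <- TRUE; break }
    act <- which(v > 0 | (alpha > A + 1e-12 & alpha < B - 1e-12))
    for (i in act) {
      if (kd[i] <= 0) next
      di <- clip(alpha[i] + g[i] / kd[i], A[i], B[i]) - alpha[i]
      if (di != 0) {
        alpha[i] <- alpha[i] + di
        g <- g - di * K[, i]
      }
    }
  }
  if (!converged && max(kkt_violation(alpha, g, A, B)) < tol) converged <- TRUE
  if (!converged)
    warnf("inner dual solver: KKT tolerance %g not reached in %d sweeps", tol, max_sweeps)
  list(alpha = alpha, g = g, converged = converged, sweeps = sweeps)
}

#' Batch CCCP training of the cost-sensitive ranker
#'
#' Reference solver. Alternates (i) fixing the concave-part linearization --
#' the 0/1 flags `eta_i = 1{y_i f(x_i) < s}` over target PSMs -- and (ii)
#' exactly solving the resulting convex box-constrained dual by coordinate
#' ascent, warm-started from the previous iterate. Stops when the `eta`
#' vector is unchanged between outer iterations. The primal objective is
#' non-increasing across outer iterations.
#'
#' Memory is quadratic in `n`; intended for moderate datasets and as the
#' correctness oracle for [cs_ranker()]'s online solver.
#'
#' @param X weighted, normalized feature matrix.
#' @param y labels, +1 target / -1 decoy.
#' @param params a [cs_params()] object.
#' @param tol KKT tolerance of the inner solver.
#' @param max_outer outer iteration cap.
#' @return list with `alpha`, `f` (fitted discriminant values), `eta`,
#'   `trace` (per-outer-iteration data frame with `G`, `J`, inner sweeps),
#'   and `converged`.
#' @export
cccp_train <- function(X, y, params, tol = 1e-5, max_outer = 50L) {
  stopifnot(inherits(params, "cs_params"))
  n <- length(y)
  if (n == 0L) stopf("empty dataset")
  K <- gram_matrix(X, params$sigma)
  alpha <- numeric(n)
  tgt <- y == 1L
  # hinge start: all eta = 0 at w^0 = 0, so the first inner solve treats every
  # target as reliable; eta flips come from the informed fit only (starting
  # from eta_rule at f == 0 would lock s > 0 fits in the all-negative optimum)
  eta <- numeric(n)
  trace <- list()
  converged <- FALSE
  for (it in seq_len(max_outer)) {
    bb <- bounds_for(y, params$C1, params$C2, eta)
    alpha <- clip(alpha, bb[, 1L], bb[, 2L])
    fit <- solve_inner(K, y, bb[, 1L], bb[, 2L], alpha, tol = tol)
    alpha <- fit$alpha
    f <- y - fit$g
    G <- dual_objective(alpha, K, y, eta, params$C2, label = y)
    J <- primal_objective(alpha, K, f, y, params)
    trace[[it]] <- data.frame(iter = it, G = G, J = J, sweeps = fit$sweeps,
                              n_eta = sum(eta[tgt]))
    eta_new <- eta
    eta_new[tgt] <- eta_rule(f[tgt], params$s)
    if (identical(eta_new, eta)) { converged <- TRUE; break }
    eta <- eta_new
  }
  list(alpha = alpha, f = y - fit$g, eta = eta, trace = do.call(rbind, trace),
       converged = converged)
}
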