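# Online active-set solver: one PSM per round, PROCESS / REPROCESS / CLEAN
# over a bounded active set S. Memory is O(|S|^2) (the active-set Gram block),
# never O(n^2).

#' Control settings for the online solver
#'
#' @param tol KKT tolerance driving REPROCESS within a round.
#' @param reprocess_cap maximum REPROCESS steps per round.
#' @param epochs passes over the data (each a fresh seeded permutation).
#' @param finish run REPROCESS to tolerance after the last round.
#' @param clean_rank ordering used by CLEAN among removable points:
#'   largest absolute gradient (default) or largest signed gradient.
#' @param max_finish step cap for the finishing pass.
#' @return list of class `online_control`.
#' @export
online_control <- function(tol = 1e-3, reprocess_cap = 100L, epochs = 1L,
                           finish = TRUE, clean_rank = c("abs_grad", "signed_grad"),
                           max_finish = 20000L) {
  stopifnot(tol > 0, reprocess_cap >= 1, epochs >= 1)
  structure(list(tol = tol, reprocess_cap = as.integer(reprocess_cap),
                 epochs = as.integer(epochs), finish = isTRUE(finish),
                 clean_rank = match.arg(clean_rank),
                 max_finish = as.integer(max_finish)),
            class = "online_control")
}

# ---- active-set state (environment; K block preallocated and grown) --------

st_new <- function(X, y, params, cap = 256L) {
  st <- new.env(parent = emptyenv())
  st$X <- X; st$y <- y
  st$C1 <- params$C1; st$C2 <- params$C2; st$s <- params$s; st$sigma <- params$sigma
  cap <- max(cap, 16L)
  st$K <- matrix(NA_real_, cap, cap)
  st$idx <- integer(0)      # data row indices in S, in insertion order
  st$alpha <- numeric(0)
  st$g <- numeric(0)        # maintained gradient y_i - sum_j a_j k(x_i, x_j)
  st$eta <- numeric(0)      # 0/1 for targets, 0 for decoys
  st$A <- numeric(0); st$B <- numeric(0)
  st$size <- 0L
  st$kernel_evals <- 0
  st
}

st_grow <- function(st, need) {
  cap <- nrow(st$K)
  if (need <= cap) return(invisible(st))
  newcap <- max(need, ceiling(cap * 1.5))
  Knew <- matrix(NA_real_, newcap, newcap)
  if (st$size > 0L) Knew[seq_len(st$size), seq_len(st$size)] <-
      st$K[seq_len(st$size), seq_len(st$size)]
  st$K <- Knew
  invisible(st)
}

st_pos <- function(st, i_data) match(i_data, st$idx[seq_len(st$size)])

# discriminant at active points is free: f_i = y_i - g_i
st_f_active <- function(st) st$y[st$idx[seq_len(st$size)]] - st$g[seq_len(st$size)]

# f at an arbitrary data row via the expansion
st_f_at <- function(st, i_data) {
  if (st$size == 0L) return(0)
  kr <- kernel_row(st$X[i_data, ], st$X, st$idx[seq_len(st$size)], st$sigma)
  st$kernel_evals <- st$kernel_evals + st$size
  sum(st$alpha[seq_len(st$size)] * kr)
}

# apply a coordinate change at active position p, keeping gradients exact
st_step <- function(st, p, delta) {
  if (delta == 0) return(invisible(st))
  sz <- st$size
  st$alpha[p] <- st$alpha[p] + delta
  st$g[seq_len(sz)] <- st$g[seq_len(sz)] - delta * st$K[seq_len(sz), p]
  invisible(st)
}

# Lines 4-7 of a round: recompute eta and bounds for targets in S from the
# current f, refresh decoy bounds, and clip any alpha its new box excludes.
st_refresh_bounds <- function(st) {
  sz <- st$size
  if (sz == 0L) return(invisible(st))
  sq <- seq_len(sz)
  yS <- st$y[st$idx[sq]]
  tgt <- yS == 1L
  f <- st$y[st$idx[sq]] - st$g[sq]
  eta <- numeric(sz)
  eta[tgt] <- eta_rule(f[tgt], st$s)
  st$eta <- eta
  bb <- bounds_for(yS, st$C1, st$C2, eta)
  st$A <- bb[, 1L]; st$B <- bb[, 2L]
  for (p in sq) {
    di <- clip(st$alpha[p], st$A[p], st$B[p]) - st$alpha[p]
    if (di != 0) st_step(st, p, di)
  }
  invisible(st)
}

# PROCESS: insert the incoming index with alpha = 0; re-arrival refreshes only.
# A target enters with eta = 0 (hinge treatment): its eta is re-evaluated at
# the next round's bound refresh, once the point's own mass is in the fit.
# Computing eta from f at arrival collapses the model to the all-negative
# optimum whenever the early discriminant is below s.
st_process <- function(st, i0) {
  if (!is.na(st_pos(st, i0))) return(invisible(st))
  f0 <- st_f_at(st, i0)
  st_grow(st, st$size + 1L)
  sz <- st$size + 1L
  sq <- seq_len(sz - 1L)
  kr <- if (sz > 1L) kernel_row(st$X[i0, ], st$X, st$idx[sq], st$sigma) else numeric(0)
  st$kernel_evals <- st$kernel_evals + length(kr)
  st$K[sq, sz] <- kr
  st$K[sz, sq] <- kr
  st$K[sz, sz] <- 1
  st$idx <- c(st$idx[sq], i0)
  st$alpha <- c(st$alpha[sq], 0)
  y0 <- st$y[i0]
  st$g <- c(st$g[sq], y0 - f0)
  eta0 <- 0
  bb <- bounds_for(y0, st$C1, st$C2, eta0)
  st$eta <- c(st$eta[sq], eta0)
  st$A <- c(st$A[sq], bb[1L]); st$B <- c(st$B[sq], bb[2L])
  st$size <- sz
  invisible(st)
}

# REPROCESS: one exact coordinate-ascent step on the worst KKT violator.
# Returns the violation before the step (0 means nothing to do).
st_reprocess <- function(st, tol) {
  sz <- st$size
  if (sz == 0L) return(0)
  sq <- seq_len(sz)
  v <- kkt_violation(st$alpha[sq], st$g[sq], st$A[sq], st$B[sq])
  i <- which.max(v)          # ties: lowest index (deterministic)
  if (v[i] < tol) return(v[i])
  di <- clip(st$alpha[i] + st$g[i] / st$K[i, i], st$A[i], st$B[i]) - st$alpha[i]
  st_step(st, i, di)
  v[i]
}

# CLEAN: drop up to m zero-alpha, KKT-satisfied points (largest gradients
# first). Removing only alpha = 0 points leaves f unchanged everywhere.
st_clean <- function(st, m, rank = "abs_grad") {
  if (m <= 0L || st$size == 0L) return(invisible(st))
  sq <- seq_len(st$size)
  v <- kkt_violation(st$alpha[sq], st$g[sq], st$A[sq], st$B[sq])
  V <- which(abs(st$alpha[sq]) < 1e-12 & v == 0)
  if (length(V) == 0L) return(invisible(st))
  key <- if (rank == "abs_grad") abs(st$g[V]) else st$g[V]
  drop_pos <- V[order(-key, V)][seq_len(min(m, length(V)))]
  keep <- setdiff(sq, drop_pos)
  nk <- length(keep)
  st$K[seq_len(nk), seq_len(nk)] <- st$K[keep, keep]
  st$idx <- st$idx[keep]; st$alpha <- st$alpha[keep]; st$g <- st$g[keep]
  st$eta <- st$eta[keep]; st$A <- st$A[keep]; st$B <- st$B[keep]
  st$size <- nk
  invisible(st)
}

# ---- driver -----------------------------------------------------------------

#' Online active-set training of the cost-sensitive ranker
#'
#' Visits a seeded random permutation of the data once per epoch. Each round:
#' refresh the target flags `eta` and the dual box bounds over the active
#' set, PROCESS the incoming PSM (insert with zero coefficient), run
#' REPROCESS (exact coordinate ascent on the worst box-KKT violator) until
#' the violation drops below `tol` or the per-round cap, and CLEAN the
#' active set back when it exceeds `M` by dropping zero-coefficient points.
#'
#' @param X weighted, normalized feature matrix.
#' @param y labels, +1 target / -1 decoy.
#' @param params a [cs_params()] object (supplies `M` and `m_frac`).
#' @param control an [online_control()] list.
#' @param seed integer seed for the visiting permutations.
#' @return list with `alpha` (named by active data row), `active` (data row
#'   indices of the active set), `eta`, `f_active`, `history` (per-round
#'   active-set size and REPROCESS counts), `kernel_evals`, `max_size`.
#' @export
train_online <- function(X, y, params, control = online_control(), seed = 1L) {
  stopifnot(inherits(params, "cs_params"))
  n <- length(y)
  if (n == 0L) stopf("empty dataset")
  st <- st_new(X, y, params, cap = min(params$M + 2L, n + 1L, 2048L))
  hist_size <- integer(0); hist_rp <- integer(0)
  max_size <- 0L
  with_seed(seed, {
    for (ep in seq_len(control$epochs)) {
      visit <- sample.int(n)
      for (i0 in visit) {
        st_refresh_bounds(st)
        st_process(st, i0)
        rp <- 0L
        while (rp < control$reprocess_cap) {
          v <- st_reprocess(st, control$tol)
          rp <- rp + 1L
          if (v < control$tol) break
        }
        max_size <- max(max_size, st$size)
        if (st$size > params$M)
          st_clean(st, floor(params$m_frac * st$size), control$clean_rank)
        hist_size <- c(hist_size, st$size); hist_rp <- c(hist_rp, rp)
      }
    }
  })
  if (control$finish) {
    st_refresh_bounds(st)
    for (k in seq_len(control$max_finish)) {
      if (st_reprocess(st, control$tol) < control$tol) break
    }
  }
  sq <- seq_len(st$size)
  alpha <- st$alpha[sq]
  names(alpha) <- as.character(st$idx[sq])
  list(alpha = alpha, active = st$idx[sq], eta = st$eta[sq],
       f_active = st_f_active(st),
       history = data.frame(round = seq_along(hist_size), size = hist_size,
                            reprocess = hist_rp),
       kernel_evals = st$kernel_evals, max_size = max(max_size, st$size))
}
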