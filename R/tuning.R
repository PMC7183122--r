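#' Candidate grid for cross-validated tuning
#'
#' Builds the Cartesian grid over `(C1, C2, sigma, s)`; `C1` is specified
#' through the cost ratio `C1/C2` so every grid point respects the model
#' constraint `C1 >= C2`.
#'
#' @param C2 target loss weights.
#' @param ratio `C1/C2` ratios, each >= 1.
#' @param sigma kernel bandwidths (features are standardized, so order-1
#'   values are sensible).
#' @param s ramp truncations in (-1, 1).
#' @return data frame with columns `C1`, `C2`, `sigma`, `s`.
#' @export
cv_grid <- function(C2 = c(0.5, 1, 2), ratio = c(1, 2, 4),
                    sigma = c(1, 2, 3), s = c(0, 0.3)) {
  if (any(ratio < 1)) stopf("cost ratios C1/C2 must be >= 1")
  g <- expand.grid(C2 = C2, ratio = ratio, sigma = sigma, s = s,
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(C1 = g$C2 * g$ratio, C2 = g$C2, sigma = g$sigma, s = g$s)
}

#' Cross-validated parameter tuning
#'
#' 3-fold (by default) stratified cross-validation: for each grid point the
#' model is trained on the other folds and the held-out fold is scored; the
#' number of held-out target PSMs identified at the nominal FDR -- computed
#' within the fold's own decoys -- is summed over folds, and the grid point
#' maximizing that count wins (ties: smaller `C1`, then `C2`, then `sigma`,
#' then `s`).
#'
#' @param data a `psm_dataset` (features derived or derivable).
#' @param grid data frame from [cv_grid()] (columns `C1`, `C2`, `sigma`, `s`).
#' @param folds number of stratified folds, >= 2.
#' @param level nominal FDR defining the objective.
#' @param params_base [cs_params()] supplying `M`, `m_frac` and weights.
#' @param control [online_control()] for the online solver.
#' @param seed seed for the fold split and training permutations.
#' @return list with `best` (a [cs_params()]), `objective` (summed held-out
#'   identifications of the winner), and `table` (grid point x fold counts).
#' @export
cv_tune <- function(data, grid = cv_grid(), folds = 3L, level = 0.02,
                    params_base = cs_params(), control = online_control(),
                    seed = 1L) {
  stopifnot(inherits(data, "psm_dataset"), folds >= 2L)
  if (is.null(data$features)) data <- derive_features(data)
  bad <- which(grid$C1 < grid$C2)
  if (length(bad)) stopf("grid rows with C1 < C2 are not admissible: %s",
                         paste(utils::head(bad, 5L), collapse = ", "))
  y <- data$records$label
  n <- length(y)
  fold_id <- integer(n)
  with_seed(seed, {
    for (lab in c(1L, -1L)) {
      ii <- which(y == lab)
      if (length(ii) < folds)
        stopf("stratification error: fewer than %d PSMs with label %d", folds, lab)
      fold_id[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
  })

  rows <- list()
  for (gi in seq_len(nrow(grid))) {
    pars <- cs_params(C1 = grid$C1[gi], C2 = grid$C2[gi], s = grid$s[gi],
                      sigma = grid$sigma[gi], weights = params_base$weights,
                      M = params_base$M, m_frac = params_base$m_frac)
    for (k in seq_len(folds)) {
      tr <- which(fold_id != k); te <- which(fold_id == k)
      Ztr <- weight_and_normalize(data$features[tr, , drop = FALSE],
                                  weights = pars$weights)
      fit <- train_online(Ztr, y[tr], pars, control = control,
                          seed = seed + 1000L * k)
      Zte <- weight_and_normalize(data$features[te, , drop = FALSE],
                                  weights = pars$weights,
                                  center = attr(Ztr, "center"),
                                  scale = attr(Ztr, "scale"))
      f_te <- discriminant(Zte, Ztr[fit$active, , drop = FALSE],
                           unname(fit$alpha), pars$sigma)
      sel <- select_at_fdr(psm_score(f_te), y[te], level)
      rows[[length(rows) + 1L]] <-
        data.frame(grid_row = gi, C1 = pars$C1, C2 = pars$C2,
                   sigma = pars$sigma, s = pars$s, fold = k,
                   identified = sel$T_sel)
    }
  }
  tab <- do.call(rbind, rows)
  tot <- stats::aggregate(identified ~ grid_row, data = tab, FUN = sum)
  tot <- merge(tot, grid_with_row(grid), by = "grid_row")
  best_rows <- tot[tot$identified == max(tot$identified), , drop = FALSE]
  best_rows <- best_rows[order(best_rows$C1, best_rows$C2, best_rows$sigma,
                               best_rows$s), , drop = FALSE]
  b <- best_rows[1L, ]
  list(best = cs_params(C1 = b$C1, C2 = b$C2, s = b$s, sigma = b$sigma,
                        weights = params_base$weights, M = params_base$M,
                        m_frac = params_base$m_frac),
       objective = b$identified, table = tab, totals = tot)
}

grid_with_row <- function(grid) {
  g <- grid
  g$grid_row <- seq_len(nrow(g))
  g
}
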