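#' Fit the cost-sensitive kernel ranker to a PSM dataset
#'
#' Trains the ramp-loss, class-weighted Gaussian-kernel ranking model used to
#' rescore peptide-spectrum matches after a database search. Decoy PSMs carry
#' a hinge loss with weight `C1`; target PSMs carry a bounded ramp loss with
#' weight `C2 <= C1`, so incorrect target labels cannot dominate the fit.
#' The model is trained either by an online active-set solver (default;
#' memory quadratic in the active-set cap `M`, not in `n`) or by a full-batch
#' concave-convex procedure (CCCP), and every PSM is then scored by
#' `(2/pi) atan(f(x))` with target-decoy FDR selection at the requested
#' levels.
#'
#' @param data a `psm_dataset` (see [read_psm_table()], [as_psm_dataset()],
#'   [simulate_psms()]) or a data frame coercible to one.
#' @param params model parameters from [cs_params()].
#' @param solver `"online"` (default) or `"batch"`.
#' @param control [online_control()] settings for the online solver.
#' @param fdr_levels nominal FDR levels reported by `summary()`.
#' @param train_frac fraction of PSMs used for training (stratified by
#'   label); the rest are held out and scored by the fitted model only.
#' @param seed integer seed controlling the visiting order (and split).
#' @param keep_history keep the per-round solver history.
#' @return An object of class `cs_ranker` with components including `alpha`
#'   (dual coefficients of the active set), `f` and `score` per PSM, `q`
#'   (q-values), `selections` (one [select_at_fdr()] report per level),
#'   `train_idx`/`test_idx`, and the stored normalization so [predict()]
#'   can score new tables.
#' @examples
#' d <- simulate_psms(n_target = 150, n_decoy = 150, pi_correct = 0.5,
#'                    effect = 2, seed = 7)
#' fit <- cs_ranker(d, params = cs_params(C1 = 2, C2 = 1, sigma = 2, M = 400),
#'                  seed = 7)
#' summary(fit)
#' @export
cs_ranker <- function(data, params = cs_params(), solver = c("online", "batch"),
                      control = online_control(), fdr_levels = c(0.02, 0.04),
                      train_frac = 1, seed = 1L, keep_history = FALSE) {
  solver <- match.arg(solver)
  stopifnot(inherits(params, "cs_params"), train_frac > 0, train_frac <= 1)
  cl <- match.call()
  if (!inherits(data, "psm_dataset")) data <- as_psm_dataset(data)
  if (is.null(data$features)) data <- derive_features(data)

  Z <- weight_and_normalize(data, weights = params$weights)
  rejected <- attr(Z, "rejected")
  if (length(rejected)) data$records <- data$records[-rejected, , drop = FALSE]
  y <- data$records$label
  n <- length(y)

  train_idx <- seq_len(n)
  if (train_frac < 1) {
    train_idx <- with_seed(seed + 1L, {
      tt <- which(y == 1L); dd <- which(y == -1L)
      sort(c(sample(tt, max(1L, round(train_frac * length(tt)))),
             sample(dd, max(1L, round(train_frac * length(dd))))))
    })
  }
  test_idx <- setdiff(seq_len(n), train_idx)

  t0 <- proc.time()[["elapsed"]]
  if (solver == "online") {
    fit <- train_online(Z[train_idx, , drop = FALSE], y[train_idx], params,
                        control = control, seed = seed)
    active <- train_idx[fit$active]
    alpha <- unname(fit$alpha)
    converged <- TRUE
    history <- if (keep_history) fit$history else NULL
    extras <- list(kernel_evals = fit$kernel_evals, max_size = fit$max_size)
  } else {
    fit <- cccp_train(Z[train_idx, , drop = FALSE], y[train_idx], params)
    keep <- which(abs(fit$alpha) > 1e-12)
    active <- train_idx[keep]
    alpha <- fit$alpha[keep]
    converged <- fit$converged
    history <- fit$trace
    extras <- list()
  }
  elapsed <- proc.time()[["elapsed"]] - t0

  sv <- Z[active, , drop = FALSE]
  f <- discriminant(Z, sv, alpha, params$sigma)
  score <- psm_score(f)
  selections <- lapply(fdr_levels, function(lv) select_at_fdr(score, y, lv))
  names(selections) <- sprintf("fdr_%g", fdr_levels)
  q <- selections[[1L]]$q

  names(alpha) <- data$records$psm_id[active]
  structure(c(list(call = cl, params = params, solver = solver,
                   control = control, seed = seed, alpha = alpha,
                   active = active, sv_features = sv,
                   center = attr(Z, "center"), scale = attr(Z, "scale"),
                   weights = attr(Z, "weights"), records = data$records,
                   f = f, score = score, q = q, label = y,
                   selections = selections, fdr_levels = fdr_levels,
                   train_idx = train_idx, test_idx = test_idx,
                   converged = converged, history = history,
                   n = n, elapsed = elapsed),
              extras),
            class = "cs_ranker")
}

#' @export
print.cs_ranker <- function(x, ...) {
  cat("Cost-sensitive kernel PSM ranker\n")
  cat(sprintf("  %d PSMs (%d targets, %d decoys); solver: %s; %d support vectors\n",
              x$n, sum(x$label == 1L), sum(x$label == -1L), x$solver,
              sum(abs(x$alpha) > 1e-12)))
  print(x$params)
  for (s in x$selections) print(s)
  invisible(x)
}

#' Summarize a fitted PSM ranker
#'
#' @param object a `cs_ranker` fit.
#' @param ... unused.
#' @return list of class `summary.cs_ranker` with a per-level selection
#'   table, split ratios when a held-out set exists, and fit diagnostics.
#' @export
summary.cs_ranker <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$selections, function(s)
    data.frame(level = s$level, targets = s$T_sel, decoys = s$D_sel,
               achieved_fdr = s$achieved_fdr, ratio = s$ratio)))
  rownames(tab) <- NULL
  split <- NULL
  if (length(object$test_idx)) {
    sel <- object$selections[[1L]]
    id_test <- sum(sel$selected[object$test_idx] & object$label[object$test_idx] == 1L)
    id_total <- sel$T_sel
    split <- list(train_frac = length(object$train_idx) / object$n,
                  identified_test = id_test, identified_total = id_total,
                  test_total_ratio = if (id_total > 0) id_test / id_total else NA_real_,
                  expected_ratio = 1 - length(object$train_idx) / object$n)
  }
  structure(list(params = object$params, solver = object$solver,
                 n = object$n, n_target = sum(object$label == 1L),
                 n_decoy = sum(object$label == -1L),
                 n_sv = sum(abs(object$alpha) > 1e-12),
                 selection_table = tab, split = split,
                 converged = object$converged, elapsed = object$elapsed),
            class = "summary.cs_ranker")
}

#' @export
print.summary.cs_ranker <- function(x, ...) {
  cat(sprintf("Cost-sensitive kernel PSM ranker (%s solver)\n", x$solver))
  cat(sprintf("  %d PSMs: %d targets, %d decoys; %d support vectors; fit in %.1fs\n",
              x$n, x$n_target, x$n_decoy, x$n_sv, x$elapsed))
  print(x$params)
  cat("Target-decoy selection:\n")
  print(x$selection_table, row.names = FALSE, digits = 4)
  if (!is.null(x$split))
    cat(sprintf("Held-out split: train frac %.2f; identified_test/identified_total = %d/%d = %.3f (expected %.3f)\n",
                x$split$train_frac, x$split$identified_test,
                x$split$identified_total, x$split$test_total_ratio,
                x$split$expected_ratio))
  invisible(x)
}

#' @export
coef.cs_ranker <- function(object, ...) object$alpha

#' Score new PSMs with a fitted ranker
#'
#' Applies the training normalization and feature weights to `newdata` and
#' evaluates the kernel expansion.
#'
#' @param object a `cs_ranker` fit.
#' @param newdata a `psm_dataset` or data frame; omit to return fitted values.
#' @param type `"link"` for the discriminant `f`, `"score"` for
#'   `(2/pi) atan(f)`.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.cs_ranker <- function(object, newdata = NULL,
                              type = c("link", "score"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    f <- object$f
  } else {
    if (!inherits(newdata, "psm_dataset")) newdata <- as_psm_dataset(newdata)
    if (is.null(newdata$features)) newdata <- derive_features(newdata)
    Z <- weight_and_normalize(newdata, weights = object$weights,
                              center = object$center, scale = object$scale)
    f <- discriminant(Z, object$sv_features, unname(object$alpha),
                      object$params$sigma)
  }
  if (type == "score") psm_score(f) else f
}

#' Plot score distributions and the selection cutoff
#'
#' Overlaid score histograms for target and decoy PSMs with the selection
#' cutoffs at the fitted FDR levels.
#'
#' @param x a `cs_ranker` fit.
#' @param breaks histogram breaks.
#' @param ... passed to [graphics::hist()].
#' @export
plot.cs_ranker <- function(x, breaks = 40, ...) {
  tgt <- x$score[x$label == 1L]
  dec <- x$score[x$label == -1L]
  br <- seq(-1, 1, length.out = breaks + 1L)
  ht <- graphics::hist(tgt, breaks = br, plot = FALSE)
  hd <- graphics::hist(dec, breaks = br, plot = FALSE)
  ylim <- c(0, max(ht$counts, hd$counts))
  graphics::plot(ht, col = grDevices::adjustcolor("steelblue", 0.5),
                 border = NA, ylim = ylim, xlab = "PSM score",
                 main = "Target and decoy score distributions", ...)
  graphics::plot(hd, col = grDevices::adjustcolor("firebrick", 0.5),
                 border = NA, add = TRUE)
  for (s in x$selections)
    if (!is.na(s$cutoff))
      graphics::abline(v = s$cutoff, lty = 2)
  graphics::legend("topright", fill = grDevices::adjustcolor(
    c("steelblue", "firebrick"), 0.5), border = NA,
    legend = c("targets", "decoys"), bty = "n")
  invisible(x)
}
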