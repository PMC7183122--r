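#' PSM score from a discriminant value
#'
#' `score = (2/pi) * atan(f)`, a strictly increasing map of the discriminant
#' onto (-1, 1); larger scores mean a PSM is more likely correct. Ranking by
#' score equals ranking by `f`.
#'
#' @param f discriminant value(s).
#' @return score(s) in (-1, 1).
#' @export
psm_score <- function(f) (2 / pi) * atan(f)

#' Target-decoy FDR estimate
#'
#' `FDR = 2D / (D + T)` where `D` and `T` are the numbers of selected decoy
#' and target PSMs.
#'
#' @param D selected decoy count.
#' @param T_ selected target count.
#' @return estimated FDR.
#' @export
estimate_fdr <- function(D, T_) {
  if (D < 0 || T_ < 0) stopf("counts must be non-negative")
  if (D + T_ == 0) stopf("FDR undefined for an empty selection")
  2 * D / (D + T_)
}

#' Ratio of selected to total target PSMs
#'
#' @param T_sel selected target count.
#' @param T_total total target count in the dataset.
#' @return `T_sel / T_total`.
#' @export
target_ratio <- function(T_sel, T_total) {
  if (T_total <= 0) stopf("target_ratio undefined: no target PSMs")
  T_sel / T_total
}

#' Percent improvement of one identification count over another
#'
#' `100 * (new - ref) / ref`, the arithmetic used when comparing selected-PSM
#' or peptide counts between two methods at a common FDR level.
#'
#' @param new,ref identification counts (ref > 0).
#' @return percent difference.
#' @export
percent_improvement <- function(new, ref) {
  if (ref <= 0) stopf("reference count must be positive")
  100 * (new - ref) / ref
}

#' Entrapment false match rate
#'
#' `FMR = N_entrapment / N_target` over a selected set: the fraction of
#' selected target PSMs that hit entrapment (known-foreign) sequences.
#'
#' @param n_entrapment selected entrapment-hit count.
#' @param n_target selected target count.
#' @return the false match rate.
#' @export
fmr <- function(n_entrapment, n_target) {
  if (n_target <= 0) stopf("FMR undefined: no selected target PSMs")
  n_entrapment / n_target
}

# q-values: monotonized running target-decoy FDR along the score ranking.
# Ties are ordered decoys-first (conservative). Returns per-PSM q in the
# original order plus the ranking permutation.
td_qvalues <- function(score, label) {
  stopifnot(length(score) == length(label))
  ord <- order(-score, label)            # decoy (-1) precedes target at ties
  lab <- label[ord]
  D <- cumsum(lab == -1L)
  T_ <- cumsum(lab == 1L)
  raw <- 2 * D / (D + T_)
  q_sorted <- rev(cummin(rev(raw)))
  q <- numeric(length(score))
  q[ord] <- q_sorted
  list(q = q, ord = ord, raw = raw, D = D, T_ = T_)
}

#' Select PSMs at a nominal FDR level
#'
#' Ranks PSMs by score (ties: decoys first, conservative), computes the
#' running target-decoy FDR `2D/(D+T)` over ranking prefixes, monotonizes it
#' from below (q-values), and selects the largest prefix whose q-value does
#' not exceed `level`.
#'
#' @param score numeric PSM scores (any strictly rank-equivalent scale).
#' @param label +1 target / -1 decoy per PSM.
#' @param level nominal FDR level in (0, 1).
#' @return list of class `psm_selection`: `level`, `selected` (logical, in
#'   input order), `T_sel`, `D_sel`, `achieved_fdr` (monotonized, `NA` for an
#'   empty selection), `raw_fdr`, `cutoff` (lowest selected score), `ratio`
#'   (`T_sel` over total targets), `q` (per-PSM q-values).
#' @export
select_at_fdr <- function(score, label, level = 0.02) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stopf("level must lie in (0, 1)")
  if (length(score) == 0L) stopf("empty score vector")
  qv <- td_qvalues(score, label)
  k <- which(qv$q[qv$ord] <= level)
  k <- if (length(k)) max(k) else 0L
  selected <- rep(FALSE, length(score))
  if (k > 0L) selected[qv$ord[seq_len(k)]] <- TRUE
  T_sel <- if (k > 0L) qv$T_[k] else 0L
  D_sel <- if (k > 0L) qv$D[k] else 0L
  structure(list(level = level, selected = selected,
                 T_sel = as.integer(T_sel), D_sel = as.integer(D_sel),
                 achieved_fdr = if (k > 0L) qv$q[qv$ord[k]] else NA_real_,
                 raw_fdr = if (k > 0L) qv$raw[k] else NA_real_,
                 cutoff = if (k > 0L) score[qv$ord[k]] else NA_real_,
                 ratio = target_ratio(T_sel, max(sum(label == 1L), 1L)),
                 q = qv$q),
            class = "psm_selection")
}

#' @export
print.psm_selection <- function(x, ...) {
  if (is.na(x$achieved_fdr))
    cat(sprintf("selection at FDR %.3g: empty (no prefix qualifies)\n", x$level))
  else
    cat(sprintf("selection at FDR %.3g: %d targets, %d decoys (achieved FDR %.4f, ratio %.3f)\n",
                x$level, x$T_sel, x$D_sel, x$achieved_fdr, x$ratio))
  invisible(x)
}

#' Entrapment FMR across FDR levels
#'
#' For each nominal FDR level, selects PSMs and reports the false match rate
#' among selected targets, where entrapment membership is flagged by a
#' protein-identifier prefix.
#'
#' @param score,label as in [select_at_fdr()].
#' @param proteins character vector of ";"-separated protein identifiers per
#'   PSM (used with `entrapment_prefix`), or `NULL` if `entrapment` is given.
#' @param entrapment optional logical per-PSM entrapment flag, overriding
#'   prefix matching.
#' @param levels nominal FDR levels.
#' @param entrapment_prefix protein prefix marking entrapment sequences.
#' @return data frame with `level`, `T_sel`, `n_entrapment`, `fmr`.
#' @export
fmr_report <- function(score, label, proteins = NULL, entrapment = NULL,
                       levels = c(0.01, 0.02, 0.04),
                       entrapment_prefix = "entrapment_") {
  if (is.null(entrapment)) {
    if (is.null(proteins)) stopf("supply proteins or an entrapment flag vector")
    entrapment <- vapply(strsplit(proteins, ";", fixed = TRUE),
                         function(p) any(startsWith(p, entrapment_prefix)),
                         logical(1))
  }
  if (!any(entrapment & label == 1L))
    warnf("no entrapment-flagged target PSMs; FMR will be 0 at every level")
  rows <- lapply(levels, function(lv) {
    sel <- select_at_fdr(score, label, lv)
    tsel <- sel$selected & label == 1L
    ne <- sum(tsel & entrapment)
    data.frame(level = lv, T_sel = sel$T_sel, n_entrapment = ne,
               fmr = if (sel$T_sel > 0) fmr(ne, sel$T_sel) else NA_real_)
  })
  do.call(rbind, rows)
}

#' Margin-plane projection for visual diagnostics
#'
#' Given a linear classifier `<b, x> + b0 = 0` over `q` features, builds an
#' orthogonal matrix `P` (Householder reflection) mapping the direction of
#' `w = (1, 1, 0, ..., 0)` to the direction of `b`, and returns the first two
#' coordinates of `P' x` for each row. In that plane the classifier is the
#' line `x1 + x2 + b0 * ||w|| / ||b|| = 0`, and the projected affine value
#' equals `(<b, x> + b0) * ||w|| / ||b||` for every row.
#'
#' @param b feature coefficient vector (nonzero, length >= 2).
#' @param b0 intercept.
#' @param X feature matrix with `length(b)` columns.
#' @return list with `coords` (n x 2), `P`, `b0_prime`, and `margin`
#'   (projected affine values).
#' @export
margin_projection <- function(b, b0, X) {
  b <- as.numeric(b)
  q <- length(b)
  if (q < 2L) stopf("need at least 2 features")
  nb <- sqrt(sum(b^2))
  if (nb == 0) stopf("degenerate classifier: b = 0")
  w <- c(1, 1, numeric(q - 2L))
  nw <- sqrt(sum(w^2))
  u <- w / nw - b / nb
  P <- if (sqrt(sum(u^2)) < 1e-12) diag(q) else diag(q) - 2 * tcrossprod(u) / sum(u^2)
  # Householder: P (w/||w||) = b/||b||, P symmetric orthogonal
  X <- rbind(X)
  XP <- X %*% P                       # rows of P' x (P symmetric)
  b0p <- b0 * nw / nb
  list(coords = XP[, 1:2, drop = FALSE], P = P, b0_prime = b0p,
       margin = XP[, 1L] + XP[, 2L] + b0p)
}
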