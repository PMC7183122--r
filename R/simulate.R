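#' Simulate a PSM dataset with planted ground truth
#'
#' Emulates the two-population structure of post-search PSM tables: decoys
#' and incorrect targets are drawn from one shared null distribution over the
#' search attributes -- the exchangeability assumption that licenses the
#' target-decoy FDR estimate -- while correct targets are shifted upward on
#' the discriminative attributes (`xcorr`, `deltacn`), are more often fully
#' tryptic, and concentrate on fewer proteins (raising `numProt`).
#'
#' Null attributes: `xcorr ~ N(2, noise_sd)` (floored at 0.1), `deltacn ~
#' N(0.1, 0.05 noise_sd)` (floored at 0), `sprank = 1 + Poisson(3)`,
#' `ions ~ Beta(2, 6)`, `hit_mass ~ N(1500, 200)`. Correct targets add
#' `effect` null standard deviations to `xcorr` and `deltacn` and draw
#' `sprank = 1 + Poisson(0.3)`. Peptide strings and flanking residues are
#' generated consistently with the tryptic flags so the feature-derivation
#' path is exercised end to end.
#'
#' @param n_target,n_decoy PSM counts.
#' @param pi_correct fraction of targets that are correct matches
#'   (0.5 resembles a typical dataset; 0.1 a "hard" one).
#' @param effect upward mean shift of correct targets on `xcorr` and
#'   `deltacn`, in null-SD units.
#' @param noise_sd null standard deviation scale.
#' @param p_enz_correct,p_enz_incorrect Bernoulli rates of the tryptic
#'   `enzN`/`enzC` flags for correct and null PSMs.
#' @param psms_per_protein expected correct-target PSMs per protein (controls
#'   the `numProt` contrast).
#' @param seed RNG seed; the same seed reproduces the dataset exactly.
#' @return A `psm_dataset` whose records carry an extra logical `is_correct`
#'   truth column (`FALSE` for decoys; ignored by training).
#' @export
simulate_psms <- function(n_target = 1000L, n_decoy = 1000L, pi_correct = 0.5,
                          effect = 2, noise_sd = 1, p_enz_correct = 0.9,
                          p_enz_incorrect = 0.3, psms_per_protein = 20,
                          seed = 1L) {
  stopifnot(n_target >= 0, n_decoy >= 0, pi_correct >= 0, pi_correct <= 1,
            effect >= 0, noise_sd > 0)
  n <- n_target + n_decoy
  if (n == 0L) stopf("empty simulation request")
  with_seed(seed, {
    n_correct <- round(pi_correct * n_target)
    correct <- c(rep(TRUE, n_correct), rep(FALSE, n_target - n_correct),
                 rep(FALSE, n_decoy))
    label <- c(rep(1L, n_target), rep(-1L, n_decoy))

    xcorr <- pmax(stats::rnorm(n, 2, noise_sd), 0.1)
    deltacn <- pmax(stats::rnorm(n, 0.1, 0.05 * noise_sd), 0)
    xcorr[correct] <- pmax(stats::rnorm(n_correct, 2 + effect * noise_sd, noise_sd), 0.1)
    deltacn[correct] <- pmax(stats::rnorm(n_correct, 0.1 + effect * 0.05 * noise_sd,
                                          0.05 * noise_sd), 0)
    sprank <- 1 + stats::rpois(n, 3)
    sprank[correct] <- 1 + stats::rpois(n_correct, 0.3)
    ions <- stats::rbeta(n, 2, 6)
    hit_mass <- stats::rnorm(n, 1500, 200)

    p_enz <- ifelse(correct, p_enz_correct, p_enz_incorrect)
    enzN <- stats::rbinom(n, 1L, p_enz)
    enzC <- stats::rbinom(n, 1L, p_enz)

    aa <- strsplit("ACDEFGHILMNPQSTVWY", "")[[1]]   # no K/R inside the core
    peplen <- sample(7:12, n, replace = TRUE)
    core <- vapply(peplen, function(L)
      paste(sample(aa, L - 1L, replace = TRUE), collapse = ""), character(1))
    last <- ifelse(enzC == 1L, sample(c("K", "R"), n, replace = TRUE),
                   sample(aa, n, replace = TRUE))
    peptide <- paste0(core, last)
    flank_n <- ifelse(enzN == 1L, sample(c("K", "R"), n, replace = TRUE),
                      sample(setdiff(aa, "P"), n, replace = TRUE))
    flank_c <- sample(c(aa, "K", "R"), n, replace = TRUE)

    # correct targets concentrate on few proteins; null matches scatter
    n_prot_c <- max(1L, ceiling(n_correct / psms_per_protein))
    prot <- character(n)
    prot[correct] <- sprintf("prot_c%04d", sample.int(n_prot_c, n_correct, replace = TRUE))
    null_t <- !correct & label == 1L
    prot[null_t] <- sprintf("prot_n%06d", sample.int(max(2L * sum(null_t), 1L),
                                                     sum(null_t), replace = TRUE))
    dec <- label == -1L
    prot[dec] <- sprintf("decoy_prot%06d", sample.int(max(2L * sum(dec), 1L),
                                                      sum(dec), replace = TRUE))

    df <- data.frame(psm_id = sprintf("psm_%05d", seq_len(n)),
                     peptide = peptide, flank_n = flank_n, flank_c = flank_c,
                     proteins = prot, label = label, xcorr = xcorr,
                     deltacn = deltacn, sprank = as.numeric(sprank),
                     ions = ions, hit_mass = hit_mass, is_correct = correct,
                     stringsAsFactors = FALSE)
    derive_features(as_psm_dataset(df))
  })
}

#' Compare a selection against planted truth
#'
#' @param selected logical selection vector (e.g. from [select_at_fdr()]).
#' @param is_correct logical truth flags per PSM.
#' @param label +1 target / -1 decoy per PSM.
#' @return list with `true_fdr` (incorrect targets selected / targets
#'   selected), `tpr` (selected correct / total correct), `fpr` (selected
#'   incorrect targets / total incorrect targets), counts, and `applicable`
#'   (`FALSE` for an empty target selection).
#' @export
evaluate_against_truth <- function(selected, is_correct, label) {
  stopifnot(length(selected) == length(is_correct),
            length(selected) == length(label))
  tsel <- selected & label == 1L
  n_tsel <- sum(tsel)
  n_correct <- sum(is_correct & label == 1L)
  n_incorrect <- sum(!is_correct & label == 1L)
  if (n_tsel == 0L)
    return(list(applicable = FALSE, true_fdr = NA_real_, tpr = NA_real_,
                fpr = NA_real_, T_sel = 0L, n_false = 0L))
  n_false <- sum(tsel & !is_correct)
  list(applicable = TRUE,
       true_fdr = n_false / n_tsel,
       tpr = if (n_correct > 0L) sum(tsel & is_correct) / n_correct else NA_real_,
       fpr = if (n_incorrect > 0L) n_false / n_incorrect else NA_real_,
       T_sel = n_tsel, n_false = n_false)
}
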