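#' End-to-end PSM rescoring run
#'
#' Reads (or accepts) a PSM table, fits the cost-sensitive ranker, and --
#' when an output directory is given -- writes a per-PSM TSV
#' (`psm_id`, `label`, `f`, `score`, `q_value`, one `selected_at_*` column
#' per FDR level), a JSON summary with selection counts per level, and a
#' run manifest (resolved configuration, seed, input checksum).
#'
#' @param input path to a PSM table, or a `psm_dataset` / data frame.
#' @param output_dir directory for outputs, or `NULL` to skip writing.
#' @param dialect input table dialect, see [read_psm_table()].
#' @param decoy_prefix decoy protein prefix for label inference.
#' @param ... passed to [cs_ranker()] (`params`, `solver`, `fdr_levels`,
#'   `train_frac`, `seed`, ...).
#' @return the `cs_ranker` fit, invisibly.
#' @export
rank_psms <- function(input, output_dir = NULL, dialect = "tsv",
                      decoy_prefix = "decoy_", ...) {
  data <- if (is.character(input))
    read_psm_table(input, dialect = dialect, decoy_prefix = decoy_prefix)
  else if (inherits(input, "psm_dataset")) input
  else as_psm_dataset(input, decoy_prefix = decoy_prefix)
  fit <- cs_ranker(data, ...)

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    out <- data.frame(psm_id = fit$records$psm_id, label = fit$label,
                      f = fit$f, score = fit$score, q_value = fit$q)
    for (i in seq_along(fit$selections))
      out[[sprintf("selected_at_%g", fit$selections[[i]]$level)]] <-
        as.integer(fit$selections[[i]]$selected)
    utils::write.table(out, file.path(output_dir, "psm_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    smry <- lapply(fit$selections, function(s)
      list(level = s$level, targets = s$T_sel, decoys = s$D_sel,
           achieved_fdr = s$achieved_fdr, ratio = s$ratio))
    jsonlite::write_json(smry, file.path(output_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest <- list(
      package = "csranker",
      version = as.character(utils::packageVersion("csranker")),
      seed = fit$seed, solver = fit$solver,
      params = unclass(fit$params), control = unclass(fit$control),
      fdr_levels = fit$fdr_levels,
      input = if (is.character(input))
        list(path = input, md5 = unname(tools::md5sum(input))) else "in-memory",
      n = fit$n, timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(fit)
}

#' Write a simulated PSM table to TSV
#'
#' Convenience wrapper around [simulate_psms()] writing the standard PSM
#' table plus the `is_correct` truth column (ignored by training).
#'
#' @param path output TSV path.
#' @param ... passed to [simulate_psms()].
#' @return the simulated `psm_dataset`, invisibly.
#' @export
write_simulated_psms <- function(path, ...) {
  d <- simulate_psms(...)
  utils::write.table(d$records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(d)
}
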