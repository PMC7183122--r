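#' Attribute names of a PSM feature vector
#'
#' The nine search attributes used by the ranker, in canonical order:
#' the raw search-engine scores `xcorr`, `deltacn`, `sprank`, `ions`,
#' `hit_mass`, plus the four derived attributes `enzN` (tryptic N-terminus),
#' `enzC` (tryptic C-terminus), `numProt` (PSM count of the best-supported
#' matched protein) and `deltacnR` (`deltacn/xcorr`).
#'
#' @return Character vector of length 9.
#' @export
psm_attributes <- function() {
  c("xcorr", "deltacn", "sprank", "ions", "hit_mass",
    "enzN", "enzC", "numProt", "deltacnR")
}

#' Default per-attribute weights
#'
#' `xcorr` and `deltacn` are the most discriminative search attributes and
#' carry weight 1.0; all other attributes carry 0.5. Weights multiply the
#' standardized feature columns before kernel evaluation.
#'
#' @return Named numeric vector of length 9.
#' @export
default_feature_weights <- function() {
  w <- c(1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  names(w) <- psm_attributes()
  w
}

.psm_required_cols <- c("psm_id", "peptide", "flank_n", "flank_c", "proteins",
                        "label", "xcorr", "deltacn", "sprank", "ions", "hit_mass")

#' Build a PSM dataset from a data frame
#'
#' Validates one-row-per-PSM input and wraps it as a `psm_dataset`. Rows with
#' any missing required field (`NA` or empty string) are dropped and counted.
#' The decoy/target status may be given either as a `label` column coded
#' +1 (target) / -1 (decoy), or inferred from a decoy protein prefix.
#'
#' @param df data frame with columns `psm_id`, `peptide`, `flank_n`,
#'   `flank_c`, `proteins` (";"-separated identifiers), `xcorr`, `deltacn`,
#'   `sprank`, `ions`, `hit_mass`, and either `label` or decoy-prefixed
#'   proteins. Extra columns (e.g. a truth flag) are carried through.
#' @param decoy_prefix protein-identifier prefix marking decoys when no
#'   `label` column is present.
#' @return An object of class `psm_dataset`: a list with elements `records`
#'   (the cleaned data frame), `n_dropped`, and once [derive_features()] has
#'   run, a numeric `features` matrix with columns [psm_attributes()].
#' @export
as_psm_dataset <- function(df, decoy_prefix = "decoy_") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!("label" %in% names(df))) {
    if (!("proteins" %in% names(df)))
      stopf("need a 'label' column or a 'proteins' column for decoy inference")
    df$label <- ifelse(vapply(strsplit(as.character(df$proteins), ";", fixed = TRUE),
                              function(p) all(startsWith(p, decoy_prefix)),
                              logical(1)), -1L, 1L)
  }
  missing_cols <- setdiff(.psm_required_cols, names(df))
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))

  num_cols <- c("xcorr", "deltacn", "sprank", "ions", "hit_mass")
  for (cc in num_cols) df[[cc]] <- suppressWarnings(as.numeric(df[[cc]]))
  df$label <- as.integer(df$label)

  chr_cols <- c("psm_id", "peptide", "flank_n", "flank_c", "proteins")
  blank <- rep(FALSE, nrow(df))
  for (cc in chr_cols) {
    v <- as.character(df[[cc]])
    blank <- blank | is.na(v) | !nzchar(v)
    df[[cc]] <- v
  }
  for (cc in num_cols) blank <- blank | is.na(df[[cc]])
  blank <- blank | is.na(df$label)
  n_dropped <- sum(blank)
  df <- df[!blank, , drop = FALSE]
  if (nrow(df) == 0L) stopf("no usable PSM rows after removing blank records")
  if (!all(df$label %in% c(-1L, 1L)))
    stopf("label column must be coded +1 (target) / -1 (decoy)")
  rownames(df) <- NULL

  structure(list(records = df, features = NULL, n_dropped = n_dropped),
            class = "psm_dataset")
}

#' Read a PSM table from delimited text
#'
#' Reads one PSM per row from a TSV or CSV export of a database search, or
#' from a Percolator-style PIN table (tab-separated, `SpecId`, `Label` in
#' {1, -1}, peptide in `X.SEQUENCE.Z` form with flanking residues, and a
#' trailing tab-joined `Proteins` field).
#'
#' @param path path to the table.
#' @param dialect one of `"tsv"`, `"csv"`, `"pin"`.
#' @param decoy_prefix protein prefix marking decoys when no label column is
#'   present (TSV/CSV only).
#' @return A [as_psm_dataset()] object.
#' @export
read_psm_table <- function(path, dialect = c("tsv", "csv", "pin"),
                           decoy_prefix = "decoy_") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stopf("file not found: %s", path)
  if (dialect == "pin") return(read_pin_table(path))
  df <- if (dialect == "tsv")
    utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                      na.strings = c("NA", ""))
  else
    utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  as_psm_dataset(df, decoy_prefix = decoy_prefix)
}

# PIN dialect: header + tab-split rows; everything from the Proteins column to
# the end of the line is the protein list. Peptide carries flanks as A.SEQ.B.
read_pin_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stopf("no usable PSM rows after removing blank records")
  hdr <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  need <- c("SpecId", "Label", "Peptide", "Proteins")
  missing_cols <- setdiff(need, hdr)
  if (length(missing_cols))
    stopf("missing required column(s): %s", paste(missing_cols, collapse = ", "))
  prot_i <- match("Proteins", hdr)
  cells <- strsplit(lines[-1L], "\t", fixed = TRUE)
  getcol <- function(nm) vapply(cells, function(x) {
    i <- match(nm, hdr)
    if (length(x) >= i) x[[i]] else NA_character_
  }, character(1))
  proteins <- vapply(cells, function(x)
    if (length(x) >= prot_i) paste(x[prot_i:length(x)], collapse = ";")
    else NA_character_, character(1))
  pep <- getcol("Peptide")
  parts <- regmatches(pep, regexec("^(.)[.](.*)[.](.)$", pep))
  flank_n <- vapply(parts, function(p) if (length(p) == 4L) p[2L] else NA_character_, character(1))
  core    <- vapply(parts, function(p) if (length(p) == 4L) p[3L] else pep[1L], character(1))
  flank_c <- vapply(parts, function(p) if (length(p) == 4L) p[4L] else NA_character_, character(1))
  feat <- function(nm) {
    i <- match(tolower(nm), tolower(hdr))
    if (is.na(i)) stopf("missing required column(s): %s", nm)
    suppressWarnings(as.numeric(vapply(cells, function(x)
      if (length(x) >= i) x[[i]] else NA_character_, character(1))))
  }
  df <- data.frame(psm_id = getcol("SpecId"),
                   peptide = ifelse(is.na(flank_n), pep, core),
                   flank_n = ifelse(is.na(flank_n), "-", flank_n),
                   flank_c = ifelse(is.na(flank_c), "-", flank_c),
                   proteins = proteins,
                   label = suppressWarnings(as.integer(getcol("Label"))),
                   xcorr = feat("xcorr"), deltacn = feat("deltacn"),
                   sprank = feat("sprank"), ions = feat("ions"),
                   hit_mass = feat("hit_mass"),
                   stringsAsFactors = FALSE)
  as_psm_dataset(df)
}

#' Derive the engineered PSM attributes
#'
#' Completes the 9-attribute feature matrix: `enzN` is 1 iff the preceding
#' residue is K or R (or the peptide is protein N-terminal, flank `"-"`);
#' `enzC` is 1 iff the peptide's last residue is K or R or the peptide is
#' protein C-terminal; `numProt` is, for each PSM, the largest number of PSMs
#' in the dataset matching any of its proteins (the PSM itself included by
#' default); `deltacnR = deltacn / xcorr`.
#'
#' @param d a `psm_dataset`.
#' @param proline_rule if `TRUE`, cleavage before proline is not counted as
#'   tryptic for `enzN`. Off by default.
#' @param count_self if `FALSE`, `numProt` excludes the PSM itself.
#' @return `d` with the `features` matrix filled in.
#' @export
derive_features <- function(d, proline_rule = FALSE, count_self = TRUE) {
  stopifnot(inherits(d, "psm_dataset"))
  r <- d$records
  bad <- which(r$xcorr <= 0)
  if (length(bad))
    stopf("deltacnR undefined: xcorr <= 0 in row(s) %s",
          paste(utils::head(bad, 5L), collapse = ", "))

  enzN <- as.numeric(r$flank_n %in% c("K", "R") | r$flank_n == "-")
  if (proline_rule)
    enzN <- enzN * as.numeric(substr(r$peptide, 1L, 1L) != "P" | r$flank_n == "-")
  last_res <- substr(r$peptide, nchar(r$peptide), nchar(r$peptide))
  enzC <- as.numeric(last_res %in% c("K", "R") | r$flank_c == "-")

  prot_lists <- strsplit(r$proteins, ";", fixed = TRUE)
  tab <- table(unlist(prot_lists))
  numProt <- vapply(prot_lists, function(p) max(tab[p]), numeric(1))
  if (!count_self) numProt <- numProt - 1

  X <- cbind(xcorr = r$xcorr, deltacn = r$deltacn, sprank = r$sprank,
             ions = r$ions, hit_mass = r$hit_mass, enzN = enzN, enzC = enzC,
             numProt = as.numeric(numProt), deltacnR = r$deltacn / r$xcorr)
  d$features <- X
  d
}

#' Standardize and weight the feature matrix
#'
#' Each attribute column is z-scored over the dataset (constant columns map
#' to zero) and then multiplied by its weight. Rows containing non-finite
#' values are rejected and reported via the `"rejected"` attribute.
#'
#' @param d a `psm_dataset` with derived features, or a numeric matrix with
#'   columns [psm_attributes()].
#' @param weights numeric vector of 9 per-attribute weights.
#' @param center,scale optional pre-computed column centers/scales (used to
#'   project new data onto a training normalization).
#' @return Weighted, standardized numeric matrix with attributes `center`,
#'   `scale`, `weights` and `rejected` (integer row indices removed).
#' @export
weight_and_normalize <- function(d, weights = default_feature_weights(),
                                 center = NULL, scale = NULL) {
  X <- if (inherits(d, "psm_dataset")) {
    if (is.null(d$features)) stopf("features not derived; call derive_features() first")
    d$features
  } else as.matrix(d)
  if (ncol(X) != 9L) stopf("feature matrix must have exactly 9 columns")
  weights <- as.numeric(weights)
  if (length(weights) != 9L || any(!is.finite(weights)))
    stopf("weights must be 9 finite numbers")

  ok <- apply(X, 1L, function(z) all(is.finite(z)))
  rejected <- which(!ok)
  if (length(rejected)) {
    warnf("rejecting %d row(s) with non-finite features", length(rejected))
    X <- X[ok, , drop = FALSE]
  }
  if (is.null(center)) center <- colMeans(X)
  if (is.null(scale)) {
    scale <- apply(X, 2L, stats::sd)
    scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  }
  Z <- sweep(sweep(X, 2L, center, "-"), 2L, scale, "/")
  # constant columns: mean-centering already makes them exactly zero
  Z <- sweep(Z, 2L, weights, "*")
  attr(Z, "center") <- center
  attr(Z, "scale") <- scale
  attr(Z, "weights") <- weights
  attr(Z, "rejected") <- rejected
  Z
}

#' @export
print.psm_dataset <- function(x, ...) {
  lab <- x$records$label
  cat(sprintf("PSM dataset: %d PSMs (%d targets, %d decoys), %d blank row(s) dropped\n",
              nrow(x$records), sum(lab == 1L), sum(lab == -1L), x$n_dropped))
  cat(sprintf("features: %s\n",
              if (is.null(x$features)) "not derived" else "derived (9 attributes)"))
  invisible(x)
}

# index sets of targets / decoys
omega_pos <- function(d) which(d$records$label == 1L)
omega_neg <- function(d) which(d$records$label == -1L)
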