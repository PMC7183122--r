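# In-code fixtures shared across test files.

# minimal hand-written PSM table; n rows cycle through the template
toy_psm_df <- function() {
  data.frame(
    psm_id   = c("s1", "s2", "s3"),
    peptide  = c("ACDK", "LMNPQR", "GHISTV"),
    flank_n  = c("K", "G", "R"),
    flank_c  = c("L", "-", "A"),
    proteins = c("protA", "protA;protB", "decoy_protC"),
    label    = c(1L, 1L, -1L),
    xcorr    = c(2.5, 1.8, 1.1),
    deltacn  = c(0.30, 0.12, 0.05),
    sprank   = c(1, 2, 7),
    ions     = c(0.6, 0.4, 0.2),
    hit_mass = c(1502.3, 1320.8, 998.4),
    stringsAsFactors = FALSE
  )
}

write_psm_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

write_psm_csv <- function(df, path) {
  utils::write.csv(df, path, quote = FALSE, row.names = FALSE)
  path
}

# Percolator-style PIN rendering of the same logical table
write_psm_pin <- function(df, path) {
  lines <- c(paste(c("SpecId", "Label", "xcorr", "deltacn", "sprank", "ions",
                     "hit_mass", "Peptide", "Proteins"), collapse = "\t"))
  for (i in seq_len(nrow(df))) {
    prots <- strsplit(df$proteins[i], ";", fixed = TRUE)[[1]]
    lines <- c(lines, paste(c(
      df$psm_id[i], df$label[i], df$xcorr[i], df$deltacn[i], df$sprank[i],
      df$ions[i], df$hit_mass[i],
      sprintf("%s.%s.%s", df$flank_n[i], df$peptide[i], df$flank_c[i]),
      prots), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}

# small random weighted-feature matrix (already on the normalized scale)
random_features <- function(n, q = 9, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * q), n, q)
}

# random labels with both classes present
random_labels <- function(n, seed = 1) {
  set.seed(seed)
  y <- sample(c(-1L, 1L), n, replace = TRUE)
  y[1] <- 1L; y[2] <- -1L
  y
}

# random feasible dual state for a given eta configuration
random_feasible_alpha <- function(y, C1, C2, eta, seed = 1) {
  set.seed(seed)
  bb <- csranker:::bounds_for(y, C1, C2, eta)
  bb[, 1] + runif(length(y)) * (bb[, 2] - bb[, 1])
}

# box-QP reference via kernlab::ipop: maximize -1/2 a'Ka + y'a on [A, B].
# ipop requires a linear constraint; a sum constraint spanning the whole box
# is never binding, so the boxed problem is unchanged.
ipop_qp <- function(K, y, A, B) {
  n <- length(y)
  fit <- kernlab::ipop(c = -y, H = K, A = matrix(1, 1, n), b = sum(A),
                       r = sum(B) - sum(A), l = A, u = B,
                       sigf = 9, maxiter = 400)
  kernlab::primal(fit)
}
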