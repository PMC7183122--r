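test_that("delimited PSM tables parse with correct target/decoy partition", {
  df <- toy_psm_df()
  d <- read_psm_table(write_psm_tsv(df, tempfile(fileext = ".tsv")), "tsv")
  expect_s3_class(d, "psm_dataset")
  expect_equal(nrow(d$records), 3L)
  expect_equal(length(csranker:::omega_neg(d)), 1L)
  expect_equal(length(csranker:::omega_pos(d)), 2L)
  expect_equal(d$n_dropped, 0L)
})

test_that("rows with blank required fields are dropped and counted", {
  df <- toy_psm_df()
  df$xcorr[2] <- NA
  d <- read_psm_table(write_psm_tsv(df, tempfile(fileext = ".tsv")), "tsv")
  expect_equal(nrow(d$records), 2L)
  expect_equal(d$n_dropped, 1L)
})

test_that("parsing is dialect-invariant across tsv, csv and pin", {
  df <- toy_psm_df()
  d_tsv <- read_psm_table(write_psm_tsv(df, tempfile(fileext = ".tsv")), "tsv")
  d_csv <- read_psm_table(write_psm_csv(df, tempfile(fileext = ".csv")), "csv")
  d_pin <- read_psm_table(write_psm_pin(df, tempfile(fileext = ".pin")), "pin")
  expect_equal(d_csv$records, d_tsv$records)
  for (cc in names(d_tsv$records))
    expect_equal(d_pin$records[[cc]], d_tsv$records[[cc]], info = cc)
})

test_that("schema violations are reported by column name", {
  df <- toy_psm_df()
  df$xcorr <- NULL
  expect_error(read_psm_table(write_psm_tsv(df, tempfile(fileext = ".tsv")), "tsv"),
               "xcorr")
  blank <- toy_psm_df()
  blank$deltacn <- NA
  expect_error(read_psm_table(write_psm_tsv(blank, tempfile(fileext = ".tsv")), "tsv"),
               "no usable PSM rows")
})

test_that("decoy labels can be inferred from the protein prefix", {
  df <- toy_psm_df()
  df$label <- NULL
  d <- as_psm_dataset(df)
  expect_equal(d$records$label, c(1L, 1L, -1L))
})

test_that("tryptic flags and deltacnR follow their definitions", {
  d <- derive_features(as_psm_dataset(toy_psm_df()))
  X <- d$features
  # row 1: flank_n = K, last residue K, flank_c = L
  expect_equal(unname(X[1, "enzN"]), 1)
  expect_equal(unname(X[1, "enzC"]), 1)
  # row 2: flank_n = G (not tryptic), last residue R
  expect_equal(unname(X[2, "enzN"]), 0)
  expect_equal(unname(X[2, "enzC"]), 1)
  # row 3: last residue V, but flank_c = A and flank_n = R
  expect_equal(unname(X[3, "enzN"]), 1)
  expect_equal(unname(X[3, "enzC"]), 0)
  # protein C-terminus counts as tryptic
  expect_equal(unname(X[2, "enzC"]), 1)
  expect_equal(X[, "deltacnR"], X[, "deltacn"] / X[, "xcorr"],
               ignore_attr = TRUE)
  expect_error(derive_features(as_psm_dataset(within(toy_psm_df(), xcorr[1] <- 0))),
               "deltacnR")
})

test_that("numProt counts PSMs of the best-supported matched protein", {
  df <- toy_psm_df()[c(1, 1, 2, 3, 1), ]
  df$psm_id <- paste0("s", 1:5)
  # protein P matching rows {1,2,5}: brute-force count = 3
  df$proteins <- c("P", "P", "P;Q", "decoy_X", "P")
  d <- derive_features(as_psm_dataset(df))
  expect_equal(unname(d$features[c(1, 2, 5), "numProt"]), c(4, 4, 4))
  # row 3 matches P (4 PSMs incl. itself) and Q (1): max rule
  expect_equal(unname(d$features[3, "numProt"]), 4)
  expect_equal(unname(d$features[4, "numProt"]), 1)
  d2 <- derive_features(as_psm_dataset(df), count_self = FALSE)
  expect_equal(unname(d2$features[4, "numProt"]), 0)
})

test_that("feature derivation is idempotent and permutation-invariant", {
  df <- toy_psm_df()
  d1 <- derive_features(as_psm_dataset(df))
  d2 <- derive_features(derive_features(as_psm_dataset(df)))
  expect_equal(d1$features, d2$features)
  perm <- c(3, 1, 2)
  dp <- derive_features(as_psm_dataset(df[perm, ]))
  expect_equal(dp$features, d1$features[perm, ], ignore_attr = TRUE)
})

test_that("normalization standardizes, weights, and zeroes constant columns", {
  df <- toy_psm_df()
  d <- derive_features(as_psm_dataset(df))
  expect_identical(unname(default_feature_weights()),
                   c(1, 1, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5))
  Z <- weight_and_normalize(d)
  expect_equal(unname(colMeans(Z)), rep(0, 9), tolerance = 1e-12)
  # enzC is constant (all 1s would be, here check a constructed constant col)
  X <- d$features
  X[, "ions"] <- 0.5
  Zc <- weight_and_normalize(X)
  expect_true(all(Zc[, "ions"] == 0))
  # identical rows map to identical vectors
  X2 <- rbind(X, X[1, ])
  Z2 <- weight_and_normalize(X2)
  expect_equal(Z2[1, ], Z2[4, ])
  # commutes with row permutation
  perm <- c(2, 3, 1)
  Zp <- weight_and_normalize(d$features[perm, ])
  expect_equal(Zp, Z[perm, ], ignore_attr = TRUE)
})

test_that("non-finite feature rows are rejected with a report", {
  X <- derive_features(as_psm_dataset(toy_psm_df()))$features
  X[2, "ions"] <- Inf
  expect_warning(Z <- weight_and_normalize(X), "non-finite")
  expect_equal(attr(Z, "rejected"), 2L)
  expect_equal(nrow(Z), 2L)
})
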