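# Shared fixtures and independent oracles, all built in code.

# A small pool of frozen valid / invalid SMILES used by the metric fuzz
# tests.  Canonical forms of the valid pool were frozen from the toolkit
# (non-isomeric, de-salted) and are asserted once in test-chem_io.R.
valid_pool <- c(
  "CCO", "CCN", "c1ccccc1", "CC(=O)O", "C1CC1", "CCCC", "c1ccncc1",
  "CC(C)O", "CCOC", "CC(=O)Nc1ccccc1", "Cc1ccccc1", "OCCO",
  "NCCN", "CC(C)(C)O", "C1CCCCC1", "CC=O", "CSC", "FC(F)F",
  "Clc1ccccc1", "CC#N"
)
invalid_pool <- c("not(", "C(C)(C)(C)(C)C", "xyz", "C1CC", "[Qq]", ")(")

# Tiny labelled record table built by hand (no chemistry needed): stages and
# regions only require aligned columns.
toy_labelled <- function() {
  df <- data.frame(
    id = paste0("m", 1:8),
    smiles_raw = c("CCO", "CCN", "CCCC", "CC(C)O", "c1ccccc1",
                   "Cc1ccccc1", "CC(=O)O", "CCOC"),
    smiles_canonical = c("CCO", "CCN", "CCCC", "CC(C)O", "c1ccccc1",
                         "Cc1ccccc1", "CC(=O)O", "CCOC"),
    pxc50 = c(5, 6.5, 7.5, 5.5, 8.5, 6.8, 5.2, 9.1),
    date = 0:7,
    source_row = 0:7,
    stringsAsFactors = FALSE
  )
  df$activity_class <- assign_activity_class(df$pxc50)
  df$stage <- factor(rep(c("early", "middle", "late"), c(4, 2, 2)),
                     levels = c("early", "middle", "late"))
  df$region <- assign_regions(df$stage, df$activity_class)
  df
}

# Independent PCA oracle: covariance eigendecomposition, no prcomp.
oracle_pca_scores <- function(x, k, standardize_scores = FALSE) {
  xc <- sweep(as.matrix(x), 2, colMeans(x))
  ev <- eigen(stats::cov(xc), symmetric = TRUE)
  s <- xc %*% ev$vectors[, seq_len(k), drop = FALSE]
  if (standardize_scores) s <- sweep(s, 2, apply(s, 2, stats::sd), "/")
  s
}

# Independent pseudo-time oracle: stage-1 PCA (standardized) on features,
# stage-2 PCA on [scores, pxc50], Euclidean distance to the least-potent
# compound.
oracle_pseudo_time <- function(features, pxc50, source_row = seq_along(pxc50) - 1L) {
  s1 <- oracle_pca_scores(features, 3, standardize_scores = TRUE)
  s2 <- oracle_pca_scores(cbind(s1, pxc50), 3)
  anchor <- order(pxc50, source_row)[1]
  d <- sqrt(rowSums(sweep(s2, 2, s2[anchor, ])^2))
  list(distances = d, order = order(d, source_row), anchor = anchor)
}

# Seeded project fixture, small enough for test budgets.
small_project <- function(regime = "public_like", seed = 7, n = 120) {
  simulate_project(synthetic_project_spec(n, regime, seed = seed))
}

label_fixture <- function(rec, regime = "public_like") {
  if (regime == "public_like") {
    label_dataset(rec)
  } else {
    n <- nrow(rec)
    label_dataset(rec, mode = "dated",
                  cutpoints = c(floor(0.5 * n), floor(0.75 * n)))
  }
}
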