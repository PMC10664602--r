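# pseudotime: PCA wrapper and the pseudo-time ordering.

test_that("pca_scores rejects degenerate input", {
  expect_error(pca_scores(matrix(1, 5, 4)), "rank deficiency")
  expect_error(pca_scores(matrix(1:4, 1, 4)), "at least 2 rows")
  # 4 exact collinear points in 10-D: rank 1, so 3 components must error
  line <- outer(c(0, 1, 2, 3), runif(10))
  expect_error(pca_scores(line, 3), "rank deficiency")
})

test_that("pca_scores concentrates variance on a near-linear cloud", {
  set.seed(11)
  direction <- rnorm(10)
  x <- outer(seq(0, 3, length.out = 12), direction) +
    matrix(rnorm(120, sd = 1e-4), 12, 10)
  s <- pca_scores(x, 3)
  v <- apply(s, 2, var)
  expect_gt(v[1] / sum(v), 0.999)
  expect_lt(max(abs(s[, 2:3])), 1e-2)
})

test_that("pairwise distances among scores are rotation invariant", {
  set.seed(12)
  x <- matrix(rnorm(80), 10, 8)
  rot <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  d1 <- dist(pca_scores(x, 3))
  d2 <- dist(pca_scores(x %*% rot, 3))
  expect_equal(as.numeric(d1), as.numeric(d2), tolerance = 1e-8)
})

test_that("pca_scores agrees with the eigendecomposition oracle", {
  set.seed(13)
  x <- matrix(rnorm(60), 12, 5)
  s <- pca_scores(x, 3)
  o <- oracle_pca_scores(x, 3)
  # same subspace up to per-column sign
  for (j in 1:3) expect_equal(abs(s[, j]), abs(o[, j]), tolerance = 1e-8)
})

test_that("pseudo_time_order matches the independent oracle on a toy set", {
  # 6 compounds, hand-built 4-bit fingerprints, pXC50 4..9
  fp <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0),
              c(0, 1, 1, 0), c(0, 1, 1, 1), c(0, 0, 1, 1))
  rec <- data.frame(pxc50 = 4:9, source_row = 0:5)
  pt <- pseudo_time_order(rec, fingerprints = fp)
  o <- oracle_pseudo_time(fp, rec$pxc50, rec$source_row)
  expect_equal(pt$distances, o$distances, tolerance = 1e-8)
  expect_equal(pt$order, o$order)
  expect_equal(pt$anchor_index, o$anchor)
})

test_that("anchor properties and invariances hold", {
  fp <- rbind(c(1, 0, 0, 0), c(1, 1, 0, 0), c(1, 1, 1, 0),
              c(0, 1, 1, 0), c(0, 1, 1, 1), c(0, 0, 1, 1))
  rec <- data.frame(pxc50 = c(7, 4, 8, 6, 9, 5), source_row = 0:5)
  pt <- pseudo_time_order(rec, fingerprints = fp)
  expect_equal(pt$anchor_index, 2L)           # lowest pXC50
  expect_equal(pt$distances[pt$anchor_index], 0)
  expect_equal(pt$order[1], pt$anchor_index)  # anchor comes first
  expect_setequal(pt$order, 1:6)              # a permutation
  expect_true(all(diff(pt$distances[pt$order]) >= -1e-12))

  # sign-flip invariance: negating a stage-2 component leaves distances
  # unchanged (distances only use differences within each column)
  s2 <- pt$pc_scores_stage2
  flipped <- s2 %*% diag(c(-1, 1, -1))
  d_flip <- sqrt(rowSums(sweep(flipped, 2, flipped[pt$anchor_index, ])^2))
  expect_equal(d_flip, pt$distances, tolerance = 1e-10)

  # permutation equivariance
  perm <- c(3, 1, 6, 2, 5, 4)
  rec_p <- data.frame(pxc50 = rec$pxc50[perm], source_row = 0:5)
  pt_p <- pseudo_time_order(rec_p, fingerprints = fp[perm, ])
  expect_equal(pt_p$distances, pt$distances[perm], tolerance = 1e-8)
})

test_that("degenerate and undersized inputs error", {
  rec <- data.frame(pxc50 = rep(5, 4), source_row = 0:3)
  expect_error(pseudo_time_order(rec, fingerprints = matrix(1, 4, 8)),
               "rank deficiency")
  expect_error(pseudo_time_order(data.frame(pxc50 = 1:3, source_row = 0:2),
                                 fingerprints = matrix(0, 3, 4)),
               "at least 4")
})

test_that("tie for lowest pXC50 breaks by smallest source_row", {
  set.seed(3)
  fp <- matrix(rbinom(40, 1, 0.5), 10, 4)
  rec <- data.frame(pxc50 = c(4, 4, 5:12), source_row = 0:9)
  pt <- pseudo_time_order(rec, fingerprints = fp)
  expect_equal(pt$anchor_index, 1L)
})
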