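# stratify: activity classes, stages, regions, focus set.

test_that("activity classes use half-open bins", {
  th <- activity_thresholds()
  expect_equal(as.character(assign_activity_class(c(5.5, 8.2, 6.0, 6.99, 7.0, 8.0), th)),
               c("low", "ultra_high", "middle", "middle", "high", "ultra_high"))
  th2 <- activity_thresholds(7, 8, 9)
  expect_equal(as.character(assign_activity_class(7.5, th2)), "middle")
  expect_error(assign_activity_class(NaN, th), "non-finite")
  expect_error(activity_thresholds(7, 7, 8), "strictly increasing")
})

test_that("raising thresholds never raises a class (monotonicity)", {
  set.seed(21)
  px <- runif(200, 3, 11)
  lo <- assign_activity_class(px, activity_thresholds(6, 7, 8))
  hi <- assign_activity_class(px, activity_thresholds(6.5, 7.5, 8.5))
  expect_true(all(as.integer(hi) <= as.integer(lo)))
})

test_that("pseudo-time stages follow the floor-based 50/25/25 cut", {
  mk <- function(n) {
    rec <- data.frame(pxc50 = seq(4, 9, length.out = n), source_row = 0:(n - 1))
    pt <- structure(list(distances = seq_len(n) / n, order = seq_len(n),
                         anchor_index = 1L), class = "pseudo_time_map")
    table(assign_stages(rec, pseudo_time = pt))
  }
  expect_equal(as.integer(mk(100)), c(50L, 25L, 25L))
  expect_equal(as.integer(mk(7)), c(3L, 2L, 2L))
})

test_that("dated stages split at the given compound-count cutpoints", {
  n <- 1500
  rec <- data.frame(pxc50 = rep(5, n), source_row = 0:(n - 1), date = 1:n)
  st <- assign_stages(rec, cutpoints = c(500, 1000), mode = "dated")
  expect_equal(as.integer(table(st)), c(500L, 500L, 500L))
  expect_error(assign_stages(rec, cutpoints = c(500, 2000), mode = "dated"),
               "outside data range")
  rec$date[3] <- NA
  expect_error(assign_stages(rec, cutpoints = c(500, 1000), mode = "dated"),
               "missing dates")
})

test_that("regions follow the alpha/beta/gamma rules", {
  st <- factor(c("early", "early", "late", "middle", "late", "early"),
               levels = c("early", "middle", "late"))
  cl <- factor(c("high", "low", "middle", "low", "ultra_high", "middle"),
               levels = c("low", "middle", "high", "ultra_high"))
  reg <- assign_regions(st, cl)
  expect_equal(as.character(reg),
               c("alpha", "none", "beta", "beta", "gamma", "alpha"))
})

test_that("region labels partition stages for random inputs", {
  set.seed(22)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    st <- factor(sample(c("early", "middle", "late"), n, replace = TRUE),
                 levels = c("early", "middle", "late"))
    cl <- factor(sample(c("low", "middle", "high", "ultra_high"), n, TRUE),
                 levels = c("low", "middle", "high", "ultra_high"))
    reg <- assign_regions(st, cl)
    early <- st == "early"
    expect_true(all(reg[early] %in% c("alpha", "none")))
    expect_true(all(reg[!early] %in% c("beta", "gamma")))
    expect_true(all((reg == "none") == (early & cl == "low")))
    expect_equal(sum(table(st)), n)  # stages partition the dataset
  }
})

test_that("focus set rules select the documented subsets", {
  lab <- toy_labelled()
  # early stage: pxc50 {5, 6.5, 7.5, 5.5}, mean 6.125 -> {6.5, 7.5}
  fs <- focus_set(lab, "above_mean_early")
  expect_setequal(fs$pxc50, c(6.5, 7.5))
  fa <- focus_set(lab, "region_alpha")
  expect_setequal(fa$pxc50, c(6.5, 7.5))   # alpha = early with >= middle
  lab_low <- lab
  lab_low$pxc50[lab_low$stage == "early"] <- 4
  lab_low$activity_class <- assign_activity_class(lab_low$pxc50)
  lab_low$region <- assign_regions(lab_low$stage, lab_low$activity_class)
  expect_error(focus_set(lab_low, "region_alpha"), "empty")
})

test_that("region_asnn is 1 for identical regions and errors when empty", {
  lab <- toy_labelled()
  lab$region <- factor(rep(c("alpha", "gamma"), each = 4),
                       levels = c("alpha", "beta", "gamma", "none"))
  lab$smiles_canonical[5:8] <- lab$smiles_canonical[1:4]
  expect_equal(region_asnn(lab, "alpha", "gamma"), 1.0)
  expect_error(region_asnn(lab, "alpha", "beta"), "empty region")
})
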