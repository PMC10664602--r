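# metrics: funnel metrics, aSNN, top-k.

test_that("validity parses and sanitizes", {
  v <- validity(c("CCO", "C1CC1", "not(", "C(C)(C)(C)(C)C"))
  expect_equal(v$n_val, 2)       # the 5-valent carbon fails sanitization
  expect_equal(v$pct, 50)
  expect_equal(validity(valid_pool)$pct, 100)
  allbad <- validity(c("not(", ")("))
  expect_equal(allbad$n_val, 0)
  expect_length(allbad$valid_canonical, 0)
  expect_error(validity(character(0)), "empty")
})

test_that("uniqueness de-duplicates canonical forms, first kept", {
  u <- uniqueness(c("CCO", "CCO", "C"))
  expect_equal(u$n_uni, 2)
  expect_equal(u$pct, 100 * 2 / 3, tolerance = 1e-12)
  expect_equal(u$unique_canonical, c("CCO", "C"))
  # different raw spellings collapse after canonicalization upstream
  expect_equal(uniqueness(standardize_smiles(c("OCC", "CCO")))$n_uni, 1)
})

test_that("novelty counts structures absent from the reference", {
  expect_equal(novelty(c("CCO", "C"), "CCO")$pct, 50)
  expect_equal(novelty(c("CCO", "C"), c("CCO", "C", "CC"))$pct, 0)
  expect_equal(novelty(c("CCO", "C"), "CCCC")$pct, 100)
})

test_that("rediscovery matches canonical structures against the reference", {
  r <- rediscovery(c("CCO", "CCN", "CCC", "CCCC", "c1ccccc1"), "CCO")
  expect_equal(r$n_redis, 1)
  expect_equal(r$pct, 20)
  expect_equal(rediscovery(c("CCO", "CC"), "CCCC")$pct, 0)
  ref4 <- c("CCO", "CCN", "CCC", "CCCC")
  expect_equal(rediscovery(ref4, ref4)$pct, 100)
  # duplicates in the generated list count once; denominator is the list size
  r2 <- rediscovery(c("CCO", "OCC", "CC"), c("CCO"))
  expect_equal(r2$n_redis, 1)
  expect_equal(r2$pct, 100 / 3, tolerance = 1e-12)
  expect_warning(r3 <- rediscovery("CCO", character(0)), "empty")
  expect_equal(r3$pct, 0)
})

test_that("asnn_from_bits equals explicit set arithmetic", {
  a <- list(c(0L, 1L, 2L))
  b <- list(c(1L, 2L, 3L, 4L))
  expect_equal(asnn_from_bits(a, b, 8), 2 / 5)  # |intersect|=2, |union|=5
  expect_equal(asnn_from_bits(a, a, 8), 1)
  # mean over queries of the max against the reference
  q <- list(c(0L, 1L), c(4L, 5L))
  r <- list(c(0L, 1L), c(6L, 7L))
  expect_equal(asnn_from_bits(q, r, 8), mean(c(1, 0)))
  # growing the reference never decreases aSNN
  r2 <- c(r, list(c(4L, 5L)))
  expect_gte(asnn_from_bits(q, r2, 8), asnn_from_bits(q, r, 8))
})

test_that("asnn on SMILES is 1 on itself and directional in general", {
  expect_equal(asnn(valid_pool[1:5], valid_pool[1:5]), 1)
  a <- c("CCO", "CCN")
  b <- c("CCO", "c1ccccc1", "CC(=O)O")
  expect_false(isTRUE(all.equal(asnn(a, b), asnn(b, a))))
  expect_error(asnn(character(0), "CCO"), "empty")
})

test_that("stratified aSNN matches per-subset recomputation", {
  lab <- label_fixture(small_project(seed = 5))
  gen <- valid_pool[1:6]
  tab <- stratified_asnn(gen, lab)
  expect_true(all(tab$asnn >= 0 & tab$asnn <= 1))
  for (i in seq_len(nrow(tab))) {
    ref <- lab$smiles_canonical[lab$stage == tab$stage[i] &
                                  lab$activity_class == tab$activity_class[i]]
    expect_equal(tab$asnn[i], asnn(gen, ref), tolerance = 1e-12)
    expect_equal(tab$n_reference[i], length(ref))
  }
  # populated cells only
  combos <- table(lab$stage, lab$activity_class)
  n_pop <- sum(combos[c("middle", "late"), ] > 0)
  expect_equal(nrow(tab), n_pop)
})

test_that("stratified aSNN is 1 for a generated set equal to one cell", {
  lab <- label_fixture(small_project(seed = 5))
  sel <- lab$stage == "late" & lab$activity_class == "ultra_high"
  gen <- unique(lab$smiles_canonical[sel])
  tab <- stratified_asnn(gen, lab)
  cell <- tab[tab$stage == "late" & tab$activity_class == "ultra_high", ]
  expect_equal(cell$asnn, 1)
})

test_that("top_k_by_score is stable under ties", {
  x <- c("a", "b", "c")
  expect_equal(as.character(top_k_by_score(x, c(0.9, 0.1, 0.8), 2)),
               c("a", "c"))
  expect_equal(as.character(top_k_by_score(x, c(0.5, 0.5, 0.5), 2)),
               c("a", "b"))
  expect_equal(as.character(top_k_by_score(x, c(1, 2, 3), 3)), x)
  expect_error(top_k_by_score(x, 1:3, 4), "exceeds")
  # NA scores rank last
  expect_equal(as.character(top_k_by_score(x, c(NA, 0.2, 0.1), 2)),
               c("b", "c"))
})

test_that("generation_report satisfies the funnel chain", {
  gen <- c("CCO", "OCC", "CCN", "not(", "CC(=O)O")
  rep <- generation_report(gen, novelty_reference = "CCO",
                           rediscovery_reference = c("CCN", "CCCC"))
  expect_equal(rep$n_gen, 5)
  expect_equal(rep$n_val, 4)
  expect_equal(rep$n_uni, 3)   # CCO == OCC
  expect_equal(rep$n_unk, 2)   # CCN, CC(=O)O
  expect_equal(rep$n_redis, 1) # CCN
  expect_true(rep$n_unk <= rep$n_uni && rep$n_uni <= rep$n_val &&
                rep$n_val <= rep$n_gen)
  expect_equal(rep$validity_pct, 100 * rep$n_val / rep$n_gen)
  expect_equal(rep$uniqueness_pct, 100 * rep$n_uni / rep$n_val)
  expect_equal(rep$novelty_pct, 100 * rep$n_unk / rep$n_uni)
  expect_equal(rep$rediscovery_pct, 100 * rep$n_redis / rep$n_gen)
})
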