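# baseline_generator: tokenizer, Markov fit/focus/sample/NLL.

test_that("tokenizer keeps multi-character units atomic and round-trips", {
  expect_equal(smiles_tokenize("CCl"), c("C", "Cl"))
  expect_equal(smiles_tokenize("C[nH]1cccc1"),
               c("C", "[nH]", "1", "c", "c", "c", "c", "1"))
  expect_equal(smiles_tokenize("BrCC%12"), c("Br", "C", "C", "%12"))
  expect_error(smiles_tokenize("C[nH"), "dangling")
  for (s in c(valid_pool, "O=C(Nc1ccc(F)cc1)c1ccc(OC)cc1")) {
    expect_equal(paste(smiles_tokenize(s), collapse = ""), s)
  }
})

test_that("two-string toy model reproduces hand-derived probabilities", {
  m <- markov_fit(c("CC", "CC"), order = 1, smoothing = 0)
  # from C: two C->C and two C->end events; p(C|^)=1, p(C|C)=p($|C)=0.5
  expect_equal(markov_nll(m, "CC"), 2 * log(2), tolerance = 1e-12)
  expect_equal(markov_nll(m, "C"), log(2), tolerance = 1e-12)
  # deterministic single-path model: training-string NLL is 0
  m1 <- markov_fit("CCO", order = 3, smoothing = 0)
  expect_equal(markov_nll(m1, "CCO"), 0)
  expect_equal(unique(markov_sample(m1, 20, seed = 4)), "CCO")
})

test_that("per-context probabilities normalize to 1", {
  m <- markov_fit(valid_pool, order = 2, smoothing = 0.01)
  ctxs <- names(m$counts)
  for (ctx in ctxs[seq(1, length(ctxs), by = 7)]) {
    p <- retromol:::.context_prob(m, ctx)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p > 0))
  }
  m0 <- markov_fit(valid_pool, order = 2, smoothing = 0)
  p0 <- retromol:::.context_prob(m0, ctxs[1])
  expect_equal(sum(p0), 1, tolerance = 1e-12)
})

test_that("focusing interpolates toward the focus corpus", {
  prior <- markov_fit(valid_pool, order = 2, smoothing = 0.01)
  target <- "CC(=O)Nc1ccccc1"
  # lambda = 0 leaves the model unchanged
  f0 <- markov_focus(prior, target, lambda = 0)
  expect_equal(markov_nll(f0, valid_pool), markov_nll(prior, valid_pool))
  # mean focus-compound NLL is non-increasing in lambda
  nlls <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(l) {
    markov_nll(markov_focus(prior, target, lambda = l), target)
  }, numeric(1))
  expect_true(all(diff(nlls) <= 1e-9))
  expect_lt(nlls[5], nlls[1])  # strict improvement at lambda = 1
  # lambda = 1 with a single-molecule focus concentrates sampling on it
  # (a target whose order-3 contexts are unambiguous is fully deterministic)
  det_target <- "CC(=O)NC"
  f1 <- markov_focus(markov_fit(det_target, order = 3, smoothing = 0),
                     det_target, lambda = 1)
  expect_equal(unique(markov_sample(f1, 10, seed = 2)), det_target)
})

test_that("sampling is seed-reproducible and better than random tokens", {
  lib <- enumerate_library()
  m <- markov_fit(lib$smiles_canonical[1:200], order = 3)
  s1 <- markov_sample(m, 100, seed = 10)
  expect_identical(s1, markov_sample(m, 100, seed = 10))
  v_model <- validity(s1)$pct
  # uniform-random token baseline at matching length distribution
  toks <- unique(unlist(lapply(lib$smiles_canonical[1:50], smiles_tokenize)))
  lens <- nchar(s1)
  set.seed(10)
  rand <- vapply(lens, function(l) {
    paste(sample(toks, max(l %/% 2, 1), replace = TRUE), collapse = "")
  }, character(1))
  v_rand <- validity(rand)$pct
  expect_gt(v_model, v_rand)
})

test_that("model JSON persistence round-trips NLL and sampling", {
  m <- markov_fit(valid_pool, order = 2, smoothing = 0.01)
  f <- withr::local_tempfile(fileext = ".json")
  markov_save(m, f)
  m2 <- markov_load(f)
  expect_equal(markov_nll(m2, valid_pool), markov_nll(m, valid_pool))
  expect_identical(markov_sample(m2, 10, seed = 3),
                   markov_sample(m, 10, seed = 3))
})

test_that("region NLL summary: focused model gains on its focus region", {
  lab <- label_fixture(small_project(seed = 5))
  prior <- markov_fit(lab$smiles_canonical, order = 2, smoothing = 0.01)
  alpha <- lab$smiles_canonical[lab$region == "alpha"]
  agent <- markov_focus(prior, alpha, lambda = 0.7)
  tab <- region_nll_summary(list(prior = prior, focused = agent), lab)
  expect_setequal(unique(tab$model), c("prior", "focused"))
  a_prior <- tab$mean_nll[tab$model == "prior" & tab$region == "alpha"]
  a_focus <- tab$mean_nll[tab$model == "focused" & tab$region == "alpha"]
  expect_lt(a_focus, a_prior)
  # three populated regions -> 3 cells per model
  expect_equal(sum(tab$model == "prior"),
               sum(table(lab$region)[c("alpha", "beta", "gamma")] > 0))
})
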