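# synthetic_data: library enumeration and project simulation.

test_that("library enumeration counts, parses and de-duplicates", {
  t1 <- list(T = list(template = "c1ccc(<R1>)cc1",
                      sites = list(R1 = c("F", "Cl", "C"))))
  lib1 <- enumerate_library(t1)
  expect_equal(nrow(lib1), 3)
  t2 <- list(T = list(template = "c1cc(<R1>)ccc1<R2>",
                      sites = list(R1 = c("[H]", "F", "Cl", "C"),
                                   R2 = c("[H]", "F", "Cl", "C"))))
  lib2 <- enumerate_library(t2)
  expect_lte(nrow(lib2), 16)              # symmetric pairs collapse
  expect_true(all(!is.na(standardize_smiles(lib2$smiles_canonical))))
  t_bad <- list(T = list(template = "C(<R1>",
                         sites = list(R1 = c("F"))))
  expect_error(enumerate_library(t_bad), "unparseable")
})

test_that("default library is valid and two-chemotype", {
  lib <- enumerate_library()
  expect_setequal(unique(lib$template_id), c("A", "B"))
  expect_true(all(!duplicated(lib$smiles_canonical)))
  expect_true(all(lib$effect >= 0))
})

test_that("simulation is seed-reproducible and covers all classes", {
  spec <- synthetic_project_spec(120, "public_like", seed = 5)
  r1 <- simulate_project(spec)
  r2 <- simulate_project(spec)
  expect_identical(r1, r2)
  expect_true(all(table(assign_activity_class(r1$pxc50)) >= 5))
  expect_equal(r1$date, 0:119)  # one compound per day, series order
})

test_that("zero drift and zero noise reduce to the substituent effects", {
  # thresholds lowered so the effect range alone can span all four classes
  spec <- synthetic_project_spec(60, "public_like", drift = 0, noise_sd = 0,
                                 thresholds = activity_thresholds(5.5, 6.2, 7),
                                 seed = 9)
  rec <- simulate_project(spec)
  eff <- spec$library$effect[match(rec$smiles_canonical,
                                   spec$library$smiles_canonical)]
  expect_equal(rec$pxc50, round(spec$base + eff, 3), tolerance = 1e-9)
})

test_that("early stage is pure chemotype A; regimes place late actives", {
  pub <- simulate_project(synthetic_project_spec(120, "public_like", seed = 3))
  inh <- simulate_project(synthetic_project_spec(120, "inhouse_like", seed = 3))
  expect_true(all(pub$chemotype[pub$date < 60] == "A"))
  late_active <- function(r) r$chemotype[r$date >= 60 & r$pxc50 >= 7]
  expect_gt(mean(late_active(pub) == "A"), 0.8)
  expect_gt(mean(late_active(inh) == "B"), 0.8)
})

test_that("fixture suite is complete, loadable and byte-identical", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  f1 <- make_fixture_suite(d1, seed = 21, n_compounds = 60, n_generated = 40)
  f2 <- make_fixture_suite(d2, seed = 21, n_compounds = 60, n_generated = 40)
  expect_setequal(names(f1), c("public", "inhouse", "corpus", "generated"))
  for (nm in names(f1)) {
    expect_identical(readLines(f1[[nm]]), readLines(f2[[nm]]))
  }
  rec <- load_project_table(f1[["public"]])
  expect_equal(attr(rec, "load_report")$n_dropped_smiles, 0)
  expect_equal(attr(rec, "load_report")$n_dropped_pxc50, 0)
  expect_equal(nrow(rec), 60)
  gen <- load_generated_set(f1[["generated"]])
  expect_length(gen$smiles, 40)
})

test_that("infeasible specs error after bounded retries", {
  # zero slope and zero effects cannot reach the upper classes
  t0 <- list(T = list(template = "c1ccc(<R1>)cc1",
                      sites = list(R1 = c("F", "Cl", "C", "N", "O", "CC")),
                      effects = list(R1 = c(F = 0, Cl = 0, C = 0, N = 0,
                                            O = 0, CC = 0))))
  spec <- synthetic_project_spec(40, "public_like", templates = t0,
                                 target_slope = 0, drift = 0, seed = 2)
  expect_error(simulate_project(spec), "infeasible")
})
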