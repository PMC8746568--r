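test_that("simulation is deterministic under a fixed seed", {
  cl <- cached_closure()
  cfg <- simulation_config(seed = 42)
  t1 <- simulate_metabolome(cfg, cl)
  t2 <- simulate_metabolome(cfg, cl)
  expect_identical(t1, t2)
  s1 <- simulate_features(t1, cfg)
  s2 <- simulate_features(t2, cfg)
  expect_identical(s1, s2)
  # and written artifacts are byte-identical
  p1 <- tempfile(fileext = ".mgf"); p2 <- tempfile(fileext = ".mgf")
  write_mgf(s1$spectra, p1); write_mgf(s2$spectra, p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("sample size one yields the parent alone", {
  cfg <- simulation_config(seed = 1, n_true = 1)
  truth <- simulate_metabolome(cfg, cached_closure())
  expect_equal(truth$formula, "C34H42O19")
  expect_equal(truth$depth, 0L)
})

test_that("every simulated truth lies in the configured closure", {
  cl <- cached_closure()
  cfg <- simulation_config(seed = 9)
  truth <- simulate_metabolome(cfg, cl)
  expect_true(all(truth$formula %in% cl$formula))
  expect_true("C34H42O19" %in% truth$formula)
  expect_false(anyDuplicated(truth$formula) > 0)
})

test_that("requesting more truths than the closure holds errors", {
  small <- rule_closure("C34H42O19", default_rules(), max_depth = 0)
  cfg <- simulation_config(seed = 1, n_true = 5)
  expect_error(simulate_metabolome(cfg, small), "closure")
})

test_that("zero noise produces exactly theoretical adduct m/z", {
  cl <- cached_closure()
  cfg <- simulation_config(seed = 4, noise_ppm_sd = 0, n_decoys = 0)
  truth <- simulate_metabolome(cfg, cl)
  sim <- simulate_features(truth, cfg)
  for (i in seq_len(nrow(sim$features))) {
    row <- sim$features[i, ]
    theo <- adduct_mz(monoisotopic_mass(
      truth$formula[truth$truth_id == row$truth_id]), row$adduct)
    expect_equal(row$mz, theo, tolerance = 1e-12)
  }
  # the parent's sodiated ion, when emitted, sits at its exact value
  pos <- sim$features[sim$features$adduct == "[M+Na]+" &
                        sim$features$truth_id == "T01", ]
  if (nrow(pos)) expect_equal(pos$mz, 777.22125, tolerance = 1e-5)
})

test_that("the noiseless decoy-free pipeline recovers everything", {
  cfg <- simulation_config(seed = 8, noise_ppm_sd = 0, n_decoys = 0)
  res <- recovery_experiment(cfg, closure = cached_closure())
  expect_equal(res$recall, 1.0)
  expect_equal(res$precision, 1.0)
})

test_that("recall degrades monotonically as mass noise grows", {
  cl <- cached_closure()
  sds <- c(0, 1, 3, 10)
  mean_recall <- vapply(sds, function(sd) {
    mean(vapply(1:10, function(s) {
      cfg <- simulation_config(seed = 100 + s, noise_ppm_sd = sd)
      recovery_experiment(cfg, closure = cl)$recall
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_recall) <= 1e-9))
  expect_gte(mean_recall[2], 0.95)  # 1 ppm noise against a 5 ppm gate
})

test_that("an implausibly tight gate identifies almost nothing", {
  cfg <- simulation_config(seed = 21, noise_ppm_sd = 1)
  res <- recovery_experiment(cfg, tol_ppm = 0.01, closure = cached_closure())
  expect_lt(res$recall, 0.3)
})
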