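test_that("matrix codes map bijectively to the six biological matrices", {
  nm <- matrix_codes()
  expect_length(nm, 6)
  expect_equal(unname(nm["6"]), "brain")
  expect_equal(unname(nm["1"]), "plasma")
  expect_false(anyDuplicated(nm) > 0)
})

test_that("set differences separate sham-only from model-only matrices", {
  rec <- data.frame(metabolite = c("A", "B", "C"), stringsAsFactors = FALSE)
  rec$sham <- list(c(1L, 2L, 3L, 4L, 5L), c(1L, 2L), c(2L, 3L, 6L))
  rec$model <- list(c(1L, 2L, 3L, 4L, 5L, 6L), c(1L, 2L), c(2L, 6L))
  dr <- differential_report(rec)
  expect_equal(dr$model_only[[1]], 6L)
  expect_equal(dr$model_only_names[1], "brain")
  expect_true(dr$concordant[2])
  expect_equal(dr$sham_only[[3]], 3L)
  expect_equal(dr$sham_only_names[3], "feces")
})

test_that("unknown matrix codes are rejected by name", {
  feats <- data.frame(metabolite = "A", sham = "1,9", model = "1",
                      stringsAsFactors = FALSE)
  expect_error(distribution_records(feats), "9")
})

test_that("fixture distribution differences match the narrative claims", {
  fx <- cached_fixture()
  dr <- differential_report(fx$distribution)
  noncon <- sort(dr$metabolite[!dr$concordant])
  expect_setequal(noncon, c("M0", "M1", "M4", "M6", "M7", "M9",
                            "M13", "M14", "M18", "M19"))
  get <- function(m, col) dr[dr$metabolite == m, ][[col]][[1]]
  expect_true(6L %in% get("M4", "model_only"))     # brain, model only
  expect_true(6L %in% get("M19", "model_only"))
  expect_true(6L %in% get("M9", "sham_only"))      # brain, sham only
  expect_true(all(c(2L, 3L) %in% get("M9", "model_only")))  # urine+feces
  expect_true(5L %in% get("M13", "sham_only"))     # kidney, sham only
  expect_true(all(c(2L, 4L, 5L) %in% get("M6", "model_only")))
  expect_true(all(c(4L, 5L) %in% get("M7", "model_only")))  # liver+kidney
  for (m in c("M0", "M1", "M14")) {
    expect_true(3L %in% get(m, "sham_only"), label = paste(m, "feces"))
  }
})

test_that("blood-brain-barrier penetrance lists derive from code 6 alone", {
  fx <- cached_fixture()
  bbb <- bbb_penetrance(fx$distribution)
  expect_setequal(bbb$brain_model_only, c("M4", "M19"))
  expect_setequal(bbb$brain_sham_only, "M9")

  rec <- data.frame(metabolite = "A", stringsAsFactors = FALSE)
  rec$sham <- list(c(1L, 6L)); rec$model <- list(c(1L, 6L))
  bbb0 <- bbb_penetrance(rec)
  expect_length(bbb0$brain_model_only, 0)
  expect_length(bbb0$brain_sham_only, 0)
})

test_that("the recognition index is the novel-time share of total time", {
  expect_equal(recognition_index(5, 5), 0.5)
  expect_equal(recognition_index(0, 10), 0)
  expect_equal(recognition_index(6.545, 3.455), 0.6545)
  expect_error(recognition_index(0, 0), "undefined")
  # scale invariance
  set.seed(5)
  for (i in 1:10) {
    a <- runif(1, 0.1, 60); b <- runif(1, 0.1, 60); k <- runif(1, 0.1, 10)
    expect_equal(recognition_index(k * a, k * b), recognition_index(a, b))
  }
})

test_that("the pooled t-test reproduces the published group comparison", {
  sham <- group_summary(0.6545, 0.1148, 10)
  model <- group_summary(0.5131, 0.1046, 12)
  res <- pooled_t_test(sham, model)
  expect_equal(res$df, 20)
  expect_equal(res$t, 3.02, tolerance = 0.005)
  expect_equal(round(res$p, 3), 0.007)
  # swapping groups negates t, p unchanged
  swapped <- pooled_t_test(model, sham)
  expect_equal(swapped$t, -res$t)
  expect_equal(swapped$p, res$p)
  # identical summaries
  same <- pooled_t_test(sham, sham)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("p-values agree with a numerically integrated t distribution", {
  set.seed(7)
  for (i in 1:20) {
    a <- group_summary(runif(1, -1, 1), runif(1, 0.05, 0.5), sample(3:30, 1))
    b <- group_summary(runif(1, -1, 1), runif(1, 0.05, 0.5), sample(3:30, 1))
    res <- pooled_t_test(a, b)
    expect_equal(res$p, numeric_t_p2(res$t, res$df), tolerance = 1e-6)
  }
})

test_that("the Welch variant widens df under variance imbalance", {
  a <- group_summary(1, 0.5, 10)
  b <- group_summary(0.5, 0.1, 12)
  w <- pooled_t_test(a, b, welch = TRUE)
  p <- pooled_t_test(a, b)
  expect_lt(w$df, p$df)
  expect_equal(w$df,
               (0.5^2 / 10 + 0.1^2 / 12)^2 /
                 ((0.5^2 / 10)^2 / 9 + (0.1^2 / 12)^2 / 11))
})

test_that("Bonferroni multiplies and caps at one", {
  expect_equal(bonferroni(0.007, 1), 0.007)
  expect_equal(bonferroni(c(0.02, 0.4), 2), c(0.04, 0.8))
  expect_equal(bonferroni(0.9, 2), 1)
  expect_error(bonferroni(c(0.1, 0.2), 1))
})
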