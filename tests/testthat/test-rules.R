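test_that("the packaged rule catalog loads with parsed signed deltas", {
  rules <- default_rules()
  expect_true(all(c("name", "delta", "class", "direction") %in% names(rules)))
  i <- match("demethylation", rules$name)
  expect_equal(rules$delta_counts[[i]], c(C = -1, H = -2))
  expect_equal(rules$direction[i], "loss")
  i <- match("reduction", rules$name)
  expect_equal(rules$delta_counts[[i]], c(H = 2))
  expect_equal(rules$direction[i], "gain")
})

test_that("depth-zero closure is the parent alone", {
  cl <- rule_closure("C34H42O19", default_rules(), max_depth = 0)
  expect_equal(cl$formula, "C34H42O19")
  expect_equal(cl$depth, 0L)
  expect_equal(cl$path, "")
})

test_that("sinapoyl ester cleavage reaches the mono-ester at depth one", {
  rules <- as_rules(data.frame(name = "sinapoyl ester cleavage",
                               delta = "-C11H10O4", class = "cleavage",
                               stringsAsFactors = FALSE))
  cl <- rule_closure("C34H42O19", rules, max_depth = 1)
  expect_true("C23H32O15" %in% cl$formula)
  expect_equal(cl$path[cl$formula == "C23H32O15"], "sinapoyl ester cleavage")
})

test_that("the depth-8 closure contains all 20 fixture metabolite formulas", {
  cl <- cached_closure()
  fx <- cached_fixture()
  expect_true(all(unique(fx$features$formula) %in% cl$formula))
})

test_that("closures are monotone in depth and always contain the parent", {
  prev <- character()
  for (d in 0:4) {
    cl <- rule_closure("C11H12O5", default_rules(), max_depth = d)
    expect_true("C11H12O5" %in% cl$formula)
    expect_true(all(prev %in% cl$formula),
                label = paste("depth", d, "lost members"))
    prev <- cl$formula
  }
})

test_that("replaying every closure path reproduces its formula", {
  cl <- rule_closure("C11H12O5", default_rules(), max_depth = 4)
  for (i in seq_len(nrow(cl))) {
    expect_equal(format_formula(replay_path("C11H12O5", cl$path[i])),
                 cl$formula[i])
  }
  # and depth equals path length
  lens <- vapply(strsplit(cl$path, ";", fixed = TRUE),
                 function(p) sum(nzchar(p)), integer(1))
  expect_equal(lens, cl$depth)
})

test_that("an empty catalog with positive depth warns and returns the parent", {
  empty <- as_rules(data.frame(name = character(), delta = character(),
                               class = character(), stringsAsFactors = FALSE))
  expect_warning(cl <- rule_closure("C34H42O19", empty, max_depth = 3),
                 "empty")
  expect_equal(cl$formula, "C34H42O19")
})

test_that("reactions are labelled by shortest rule path", {
  lr <- label_reaction("C34H42O19", "C31H36O19")
  expect_equal(lr$status, "explained")
  expect_equal(lr$path, rep("demethylation", 3))

  lr0 <- label_reaction("C34H42O19", "C34H42O19")
  expect_equal(lr0$depth, 0L)
  expect_length(lr0$path, 0)

  lr19 <- label_reaction("C34H42O19", "C27H36O19")
  expect_equal(lr19$path, "C7H6 loss")

  none <- label_reaction("C34H42O19", "C2H5N", max_depth = 2)
  expect_equal(none$status, "unexplained")
})
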