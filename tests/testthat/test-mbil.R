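test_that("enumerate_candidates counts and order", {
  p4 <- paste0("V", 1:4)
  expect_length(enumerate_candidates(p4, 2), 10)       # 4 + 6
  expect_length(enumerate_candidates(p4, 1), 4)
  expect_length(enumerate_candidates(paste0("V", 1:31), 3), 4991)
  expect_identical(enumerate_candidates(p4, 2)[[1]], "V1")
  expect_identical(enumerate_candidates(p4, 2)[[5]], c("V1", "V2"))
  expect_error(enumerate_candidates(p4, 4), "max_size")
  expect_error(enumerate_candidates(p4, 0), "max_size")
})

test_that("a predictor equal to the outcome is ranked first", {
  set.seed(8)
  y <- rbinom(120, 1, 0.5)
  df <- bin_df(copy = y, other = rbinom(120, 1, 0.5), y = y)
  ints <- detect_interactions(df, "y", alpha = 1, max_size = 2)
  expect_identical(ints$variables[[1]], "copy")
  expect_identical(ints$classification[1], "single")
})

test_that("detect_interactions validates inputs", {
  df3 <- data.frame(a = factor(c(1, 2, 3)), y = bf(c(0, 1, 1)))
  expect_error(detect_interactions(df3, "a"), "binary")
  expect_error(detect_interactions(df3[0, ], "y"), "empty")
})

test_that("XOR pair is detected as interactive while its singles are not", {
  spec <- build_figure1_spec()
  d <- simulate_cohort(spec, 2000, seed = 31)
  ints <- detect_interactions(d, "T", alpha = 1, max_size = 2,
                              predictors = c("X13", "X14", "X16"))
  keys <- vapply(ints$variables, paste, character(1), collapse = "+")
  expect_true("X13+X14" %in% keys)
  i <- match("X13+X14", keys)
  expect_identical(ints$classification[i], "interactive")
  expect_gt(ints$gain_over_best_subset[i], 0)
  expect_false("X13" %in% keys)     # zero marginal: singleton gain <= 0
  expect_false("X14" %in% keys)
})

test_that("results are ranked by score with deterministic tie-breaks", {
  set.seed(13)
  d <- simulate_cohort(build_figure1_spec(), 800, seed = 13)
  ints <- detect_interactions(d, "T", alpha = 1, max_size = 3)
  expect_false(is.unsorted(-ints$log_score))
  again <- detect_interactions(d, "T", alpha = 1, max_size = 3)
  expect_identical(ints, again)
})

test_that("greedy trace increases the family score monotonically", {
  d <- simulate_cohort(build_figure1_spec(), 3000, seed = 17)
  bl <- learn_markov_blanket(d, "T", alpha = 1, max_size = 2)
  scores <- vapply(bl$trace, `[[`, numeric(1), "log_score")
  adds <- vapply(bl$trace, `[[`, character(1), "step") == "add"
  expect_true(all(diff(scores) > 0) || length(scores) <= 1)
  expect_true(any(adds))
  # self-consistency: selected interactive sets satisfy the detect criterion
  det_keys <- vapply(detect_interactions(d, "T", 1, 2)$variables,
                     paste, character(1), collapse = "+")
  sel_keys <- vapply(bl$direct_sets$variables, paste, character(1),
                     collapse = "+")
  expect_true(all(sel_keys %in% det_keys))
  # direct sets and other interactions are disjoint
  oth_keys <- vapply(bl$other_interactions$variables, paste, character(1),
                     collapse = "+")
  expect_length(intersect(sel_keys, oth_keys), 0)
  # the union of direct sets equals the reported parent union
  expect_setequal(unique(unlist(bl$direct_sets$variables)), bl$parent_union)
})

test_that("greedy blanket matches exhaustive search on tiny problems", {
  hits <- 0
  n_cases <- 200
  all_subsets <- unlist(lapply(0:4, function(k)
    utils::combn(paste0("V", 1:6), k, simplify = FALSE)), recursive = FALSE)
  for (case in seq_len(n_cases)) {
    set.seed(7000 + case)
    n <- 60
    df <- as.data.frame(lapply(1:6, function(i) bf(rbinom(n, 1, 0.5))),
                        col.names = paste0("V", 1:6), check.names = FALSE)
    names(df) <- paste0("V", 1:6)
    pa <- sample(paste0("V", 1:6), 2)
    logit <- -0.5 + 1.5 * (df[[pa[1]]] == "1") - 1.5 * (df[[pa[2]]] == "1")
    df$y <- bf(rbinom(n, 1, plogis(logit)))
    cache <- score_cache()
    bl <- learn_markov_blanket(df, "y", alpha = 1, max_size = 2,
                               predictors = paste0("V", 1:6), cache = cache)
    best <- max(vapply(all_subsets, function(s)
      family_score(df, "y", s, 1, cache = cache)$log_score, numeric(1)))
    hits <- hits + (abs(bl$log_score - best) < 1e-9)
  }
  expect_gte(hits, 0.95 * n_cases)
})

test_that("run_mbil produces one result per horizon x alpha", {
  spec <- build_lsm_like_spec(seed = 5)
  d <- simulate_cohort(spec, 600, seed = 5, schema = lsm_schema())
  res <- run_mbil(d, max_size = 1)
  expect_length(res, 9)
  expect_named(res, c("h5_a1", "h5_a120", "h5_a480",
                      "h10_a1", "h10_a120", "h10_a480",
                      "h15_a1", "h15_a120", "h15_a480"))
  expect_equal(res$h10_a120$horizon, 10)
  expect_equal(res$h10_a120$alpha, 120)
  # missing outcome column errors
  d2 <- d[, setdiff(names(d), "Metastasis_15yr")]
  attr(d2, "schema") <- lsm_schema()
  expect_error(run_mbil(d2, max_size = 1), "Metastasis_15yr")
})
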