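test_that("figure-1 spec matches its stated roles", {
  spec <- build_figure1_spec()
  expect_setequal(spec$parents$T, paste0("X", 11:15))
  ints <- spec$effects$T$interactive_sets
  expect_true(any(vapply(ints, setequal, logical(1), c("X13", "X14"))))
  expect_true(any(vapply(ints, setequal, logical(1), c("X8", "X9"))))
  expect_true(all(c("X8", "X9", "X16", "X17") %in% spec$noise_variables))
  # every CPT row sums to 1 within 1e-12
  for (v in names(spec$cpts))
    expect_true(all(abs(rowSums(spec$cpts[[v]]) - 1) <= 1e-12), label = v)
  # XOR construction: P(T=1 | X13) identical for both X13 values when X14
  # is marginalized uniformly (X14 is marginally uniform by design)
  cpt <- spec$cpts$T
  pt1 <- function(x13) {
    idx <- expand.grid(x15 = 0:1, x14 = 0:1, x12 = 0:1, x11 = 0:1)
    j <- ((idx$x11 * 2 + idx$x12) * 2 + x13) * 4 + idx$x14 * 2 + idx$x15
    mean(cpt[j + 1, 2])
  }
  expect_equal(pt1(0), pt1(1), tolerance = 1e-12)
})

test_that("ground_truth_spec validates structure", {
  vars <- list(A = c("0", "1"), T = c("0", "1"))
  cp <- list(A = matrix(c(0.5, 0.5), 1),
             T = matrix(c(0.3, 0.7, 0.8, 0.2), 2, byrow = TRUE))
  ok <- ground_truth_spec(vars, list(T = "A"), cp, "T",
                          list(T = list(direct_singles = "A",
                                        interactive_sets = list())))
  expect_s3_class(ok, "mbil_truth")
  # cycle
  expect_error(ground_truth_spec(vars, list(A = "T", T = "A"),
                                 cp, "T",
                                 list(T = list(direct_singles = "A",
                                               interactive_sets = list()))),
               "cyclic")
  # CPT row sums
  bad <- cp; bad$T[1, ] <- c(0.3, 0.6)
  expect_error(ground_truth_spec(vars, list(T = "A"), bad, "T",
                                 list(T = list(direct_singles = "A",
                                               interactive_sets = list()))),
               "sum to 1")
  # effects must cover the parent set
  expect_error(ground_truth_spec(vars, list(T = "A"), cp, "T",
                                 list(T = list(direct_singles = character(),
                                               interactive_sets = list()))),
               "cover")
})

test_that("simulate_cohort is deterministic and honors n", {
  spec <- build_figure1_spec()
  a <- simulate_cohort(spec, 200, seed = 3)
  b <- simulate_cohort(spec, 200, seed = 3)
  expect_identical(a, b)
  c <- simulate_cohort(spec, 200, seed = 4)
  expect_false(identical(a, c))
  e <- simulate_cohort(spec, 0, seed = 3)
  expect_equal(nrow(e), 0)
  expect_equal(ncol(e), 18)
  # simulation does not touch the caller's RNG stream
  set.seed(42); u1 <- runif(1)
  set.seed(42); invisible(simulate_cohort(spec, 10, seed = 9)); u2 <- runif(1)
  expect_identical(u1, u2)
})

test_that("root marginals match their CPTs within binomial error", {
  spec <- build_figure1_spec()
  d <- simulate_cohort(spec, 50000, seed = 12)
  for (v in c("X1", "X5", "X8")) {
    f <- mean(d[[v]] == "1")
    expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / 50000))
  }
  # X13/X14 are marginally uniform by construction
  expect_lt(abs(mean(d$X13 == "1") - 0.5), 3 * sqrt(0.25 / 50000))
})

test_that("noise variables are conditionally independent of T given parents", {
  spec <- build_figure1_spec()
  d <- simulate_cohort(spec, 50000, seed = 21)
  cond_mi <- function(v) {
    pa <- paste0("X", 11:15)
    dc <- list(vapply(c(v, "T", pa), function(x) as.integer(d[[x]]),
                      integer(nrow(d))))[[1]]
    j <- as.vector(dc[, pa] %*% 2^(0:4))
    mi <- 0
    for (g in unique(j)) {
      sub <- dc[j == g, c(v, "T"), drop = FALSE]
      tab <- table(sub[, 1], sub[, 2])
      if (sum(tab) < 2) next
      e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      nz <- tab > 0
      mi <- mi + sum(tab[nz] * log(tab[nz] / e[nz]))
    }
    mi / nrow(d)
  }
  # estimation bias alone is ~ df/(2n) = 32/1e5; 1e-3 is a generous ceiling
  expect_lt(cond_mi("X1"), 1e-3)
  expect_lt(cond_mi("X16"), 1e-3)
})

test_that("LSM-like spec covers the schema and plants the stated effects", {
  spec <- build_lsm_like_spec(seed = 2)
  sch <- lsm_schema()
  expect_setequal(setdiff(names(spec$variables), spec$targets),
                  predictor_names(sch))
  expect_setequal(spec$targets, outcome_names(sch))
  for (v in predictor_names(sch))
    expect_identical(spec$variables[[v]], sch$variables[[v]]$categories)
  ints10 <- spec$effects$Metastasis_10yr$interactive_sets
  expect_true(any(vapply(ints10, setequal, logical(1),
                         c("ER", "n_tnm_stage", "Surgical_margins"))))
  expect_true("Stage" %in% spec$effects$Metastasis_5yr$direct_singles)
  expect_identical(build_lsm_like_spec(seed = 2)$cpts, spec$cpts)
  expect_false(identical(build_lsm_like_spec(seed = 3)$cpts, spec$cpts))
})

test_that("recovery_metrics computes set precision/recall", {
  truth <- build_figure1_spec()
  exact <- recovery_metrics(list(direct = paste0("X", 11:15)), truth)
  expect_equal(exact$direct$precision, 1)
  expect_equal(exact$direct$recall, 1)
  none <- recovery_metrics(list(direct = character()), truth)
  expect_equal(none$direct$recall, 0)
  expect_true(is.na(none$direct$precision))
  extra <- recovery_metrics(list(direct = c(paste0("X", 11:15), "X16")), truth)
  expect_equal(extra$direct$precision, 5 / 6)
  expect_equal(extra$direct$recall, 1)
  ints <- recovery_metrics(list(direct = character(),
                                interactive = list(c("X14", "X13"),
                                                   c("X1", "X2"))), truth)
  expect_equal(ints$interactive$precision, 1 / 2)
  expect_equal(ints$interactive$recall, 1 / 2)
  expect_error(recovery_metrics(list(direct = "nope"), truth), "unknown")
})
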