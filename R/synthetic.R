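#' Ground-truth specifications for synthetic cohorts
#'
#' A ground-truth spec is a discrete Bayesian network — a DAG over named
#' categorical variables with one conditional probability table (CPT) per
#' variable — annotated with which variables are planted direct (single)
#' risk factors of each outcome, which variable sets carry a nonadditive
#' interactive effect, and which variables influence the outcome only
#' through the direct risk factors ("noise" variables).  Cohorts sampled
#' from a spec give the learner a known answer key.
#'
#' CPTs are `q x r` matrices: one row per parent configuration (mixed-radix
#' order over the listed parents, first parent most significant — the same
#' convention as [sufficient_counts()]), one column per category.  Rows
#' must sum to 1 within 1e-12.
#'
#' @param variables named list: variable name -> character vector of
#'   category labels.
#' @param parents named list: variable name -> character vector of parents
#'   (empty for roots; absent names are treated as roots).
#' @param cpts named list: variable name -> CPT matrix.
#' @param targets character vector of outcome variable names.
#' @param effects named list keyed by target: each a list with
#'   `direct_singles` (character vector) and `interactive_sets` (list of
#'   character vectors).
#' @param noise_variables character vector of variables influencing targets
#'   only indirectly.
#' @param horizons integer vector, one follow-up horizon (years) per target.
#' @return an object of class `mbil_truth`.
#' @export
ground_truth_spec <- function(variables, parents, cpts, targets, effects,
                              noise_variables = character(),
                              horizons = NULL) {
  nms <- names(variables)
  parents <- stats::setNames(
    lapply(nms, function(v) as.character(parents[[v]] %||% character())), nms)
  ord <- topo_order(nms, parents)          # errors on cycles
  for (v in nms) {
    r <- length(variables[[v]])
    q <- if (length(parents[[v]]))
      prod(vapply(parents[[v]], function(p) length(variables[[p]]), numeric(1)))
    else 1
    cpt <- cpts[[v]]
    if (is.null(cpt) || !all(dim(cpt) == c(q, r)))
      stop("CPT of '", v, "' must be ", q, " x ", r)
    if (any(abs(rowSums(cpt) - 1) > 1e-12))
      stop("CPT rows of '", v, "' must sum to 1 within 1e-12")
    if (any(cpt < 0)) stop("negative probability in CPT of '", v, "'")
  }
  for (tg in targets) {
    ef <- effects[[tg]]
    pa <- parents[[tg]]
    members <- unique(unlist(ef$interactive_sets))
    covered <- union(ef$direct_singles, intersect(members, pa))
    if (!setequal(covered, pa))
      stop("effects of '", tg, "' do not cover its parent set")
    if (length(intersect(noise_variables, pa)))
      stop("noise variables cannot be parents of '", tg, "'")
  }
  structure(list(variables = variables, parents = parents, cpts = cpts,
                 targets = targets, effects = effects,
                 noise_variables = noise_variables,
                 horizons = horizons %||% seq(5, by = 5,
                                              length.out = length(targets)),
                 order = ord),
            class = "mbil_truth")
}

topo_order <- function(nms, parents) {
  remaining <- sort(nms)
  done <- character()
  ord <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(v)
      all(parents[[v]] %in% done), logical(1))]
    if (!length(ready)) stop("cyclic dependency among: ",
                             paste(remaining, collapse = ", "))
    v <- ready[1]                          # ties broken alphabetically
    ord <- c(ord, v); done <- c(done, v)
    remaining <- setdiff(remaining, v)
  }
  ord
}

#' @export
print.mbil_truth <- function(x, ...) {
  cat(sprintf("<mbil_truth: %d variables, targets %s>\n",
              length(x$variables), paste(x$targets, collapse = ", ")))
  invisible(x)
}

# CPT built from a function of the (0-based) parent category indices,
# returning P(category) over the variable's categories.
cpt_from_fun <- function(parent_cards, r, f) {
  q <- if (length(parent_cards)) prod(parent_cards) else 1
  m <- matrix(0, q, r)
  for (j in seq_len(q) - 1L) {
    idx <- integer(length(parent_cards))
    rem <- j
    for (i in rev(seq_along(parent_cards))) {  # first parent most significant
      idx[i] <- rem %% parent_cards[i]
      rem <- rem %/% parent_cards[i]
    }
    m[j + 1L, ] <- f(idx)
  }
  m
}

bern <- function(p) c(1 - p, p)   # categories ("0","1"): index 2 is "1"

#' The 17-variable illustrative network with a known Markov blanket
#'
#' Builds the canonical validation network over binary variables X1--X17
#' and a leaf outcome T:
#' \itemize{
#'   \item parents(T) = X11..X15, so the Markov blanket of the leaf T is
#'     exactly these five direct risk factors;
#'   \item X13 and X14 act on T through a pure XOR (exclusive-or) effect:
#'     each alone has exactly zero marginal association with T, only the
#'     pair carries signal;
#'   \item X8 and X9 drive the parent X15 through an XOR, forming an
#'     interactive pair that influences T only indirectly — an interactive
#'     risk factor outside the Markov blanket;
#'   \item X1--X10 are ancestors of the parents only, and X16, X17 are
#'     children of parents: all are "noise" variables a blanket-blind
#'     learner would flag.
#' }
#' All roots are Bernoulli(1/2) and intermediate CPTs are balanced so that
#' every variable, and in particular the XOR partners, is marginally
#' uniform — which is what makes the XOR marginals vanish exactly.
#'
#' @return an `mbil_truth` over 18 binary variables with target `"T"`.
#' @export
build_figure1_spec <- function() {
  xs <- paste0("X", 1:17)
  vars <- stats::setNames(rep(list(c("0", "1")), 18), c(xs, "T"))
  parents <- list(
    X11 = c("X1", "X2"),
    X12 = c("X3", "X4", "X10"),
    X13 = "X5",
    X14 = "X6",
    X15 = c("X7", "X8", "X9"),
    X16 = "X11",
    X17 = "X15",
    T   = c("X11", "X12", "X13", "X14", "X15"))
  cpts <- list()
  for (v in paste0("X", c(1:10))) cpts[[v]] <- matrix(c(0.5, 0.5), 1)
  cpts$X11 <- cpt_from_fun(c(2, 2), 2, function(i)
    bern(0.15 + 0.35 * i[1] + 0.35 * i[2]))
  cpts$X12 <- cpt_from_fun(c(2, 2, 2), 2, function(i)
    bern(0.1 + 0.15 * i[1] + 0.15 * i[2] + 0.1 * i[3]))
  cpts$X13 <- cpt_from_fun(2, 2, function(i) bern(0.2 + 0.6 * i[1]))
  cpts$X14 <- cpt_from_fun(2, 2, function(i) bern(0.2 + 0.6 * i[1]))
  cpts$X15 <- cpt_from_fun(c(2, 2, 2), 2, function(i)
    bern(0.15 + 0.2 * i[1] + 0.5 * xor(i[2] == 1, i[3] == 1)))
  cpts$X16 <- cpt_from_fun(2, 2, function(i) bern(0.2 + 0.6 * i[1]))
  cpts$X17 <- cpt_from_fun(2, 2, function(i) bern(0.2 + 0.6 * i[1]))
  cpts$T <- cpt_from_fun(rep(2, 5), 2, function(i)
    bern(0.04 + 0.2 * i[1] + 0.2 * i[2] + 0.22 * i[5] +
           0.26 * xor(i[3] == 1, i[4] == 1)))
  ground_truth_spec(
    variables = vars, parents = parents, cpts = cpts,
    targets = "T",
    effects = list(T = list(
      direct_singles = c("X11", "X12", "X15"),
      interactive_sets = list(c("X13", "X14"), c("X8", "X9")))),
    noise_variables = c(paste0("X", 1:10), "X16", "X17"),
    horizons = 5L)
}

#' A clinically shaped synthetic cohort spec on the LSM schema
#'
#' Builds a ground-truth network over the 31 packaged LSM predictors (exact
#' category sets) plus the three binary metastasis outcomes, with planted
#' effects mirroring the shapes the learner is meant to find:
#' \itemize{
#'   \item 5-year outcome: a graded direct single effect of `Stage` plus a
#'     2-way nonadditive (XOR-shaped) interaction of `Lymph_node_status`
#'     with `HER2`;
#'   \item 10-year outcome: a 3-way "jackpot" interaction of `ER`,
#'     `n_tnm_stage` and `Surgical_margins` — the risk jumps only when ER
#'     is negative, nodal stage is high and margins carry residual tumour;
#'   \item 15-year outcome: a direct single effect of `TNEG`.
#' }
#' Predictors not involved in a planted effect are independent roots whose
#' marginals are drawn (reproducibly from `seed`) from a flat Dirichlet, so
#' the cohort has realistic category imbalance without any further hidden
#' structure.
#'
#' @param seed integer; fixes the drawn marginals (same seed, same CPTs).
#' @param effect_config list of planted effect sizes:
#'   `stage_base` (per-stage 5-year risk), `pair` (XOR jump, 5-year),
#'   `jackpot_base`/`jackpot` (10-year base and jump),
#'   `tneg_base`/`tneg` (15-year base and jump).
#' @return an `mbil_truth` over 34 variables.
#' @export
build_lsm_like_spec <- function(seed = 1L,
                                effect_config = list()) {
  ec <- utils::modifyList(list(
    stage_base = c(0.04, 0.10, 0.18, 0.28), pair = 0.22,
    jackpot_base = 0.07, jackpot = 0.55,
    tneg_base = 0.06, tneg = 0.18), effect_config)
  schema <- lsm_schema()
  pn <- predictor_names(schema)
  vars <- c(lapply(schema$variables, `[[`, "categories"),
            lapply(schema$outcomes, `[[`, "categories"))
  names(vars) <- c(pn, outcome_names(schema))
  fixed <- list(
    Stage = c(0.25, 0.35, 0.25, 0.15),
    Lymph_node_status = c(0.60, 0.40),
    HER2 = c(0.75, 0.25),
    ER = c(0.35, 0.55, 0.10),
    n_tnm_stage = c(0.45, 0.15, 0.12, 0.10, 0.08, 0.10),
    Surgical_margins = c(0.25, 0.70, 0.05),
    TNEG = c(0.15, 0.85))
  rng <- make_rng(seed)
  cpts <- list()
  for (v in pn) {
    p <- fixed[[v]]
    if (is.null(p)) {
      g <- rng$rgamma(length(vars[[v]]), shape = 5)
      p <- g / sum(g)
    }
    cpts[[v]] <- matrix(p, 1)
  }
  card <- function(v) length(vars[[v]])
  parents <- list(
    Metastasis_5yr  = c("Stage", "Lymph_node_status", "HER2"),
    Metastasis_10yr = c("ER", "n_tnm_stage", "Surgical_margins"),
    Metastasis_15yr = "TNEG")
  cpts$Metastasis_5yr <- cpt_from_fun(
    vapply(parents$Metastasis_5yr, card, numeric(1)), 2, function(i)
      bern(ec$stage_base[i[1] + 1] + ec$pair * xor(i[2] == 1, i[3] == 1)))
  cpts$Metastasis_10yr <- cpt_from_fun(
    vapply(parents$Metastasis_10yr, card, numeric(1)), 2, function(i)
      bern(ec$jackpot_base +
             ec$jackpot * (i[1] == 0 && i[2] >= 2 && i[3] == 0)))
  cpts$Metastasis_15yr <- cpt_from_fun(card("TNEG"), 2, function(i)
    bern(ec$tneg_base + ec$tneg * (i[1] == 0)))
  ground_truth_spec(
    variables = vars, parents = parents, cpts = cpts,
    targets = outcome_names(schema),
    effects = list(
      Metastasis_5yr = list(
        direct_singles = "Stage",
        interactive_sets = list(c("Lymph_node_status", "HER2"))),
      Metastasis_10yr = list(
        direct_singles = character(),
        interactive_sets = list(c("ER", "n_tnm_stage", "Surgical_margins"))),
      Metastasis_15yr = list(
        direct_singles = "TNEG",
        interactive_sets = list())),
    noise_variables = setdiff(pn, c("Stage", "Lymph_node_status", "HER2",
                                    "ER", "n_tnm_stage", "Surgical_margins",
                                    "TNEG")),
    horizons = schema_horizons(schema))
}

# Local RNG so simulation never disturbs (or depends on) the global stream.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  local_do <- function(f, ...) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    if (!is.null(env$state)) assign(".Random.seed", env$state, globalenv())
    else set.seed(env$seed)
    on.exit({
      env$state <- get(".Random.seed", globalenv())
      if (!is.null(old)) assign(".Random.seed", old, globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
    f(...)
  }
  env$seed <- as.integer(seed)
  list(runif = function(n) local_do(stats::runif, n),
       rgamma = function(n, shape) local_do(stats::rgamma, n, shape))
}

#' Sample a cohort from a ground-truth spec
#'
#' Ancestral (forward) sampling: variables are visited in topological
#' order, ties broken alphabetically, and each record draws every variable
#' from its CPT row given the already-sampled parent values.  A single
#' generator seeded once per call makes output identical for identical
#' `(spec, n, seed)`.
#'
#' @param spec an `mbil_truth`.
#' @param n number of records (>= 0).
#' @param seed integer seed.
#' @param schema optional `mbil_schema` to attach (e.g. [lsm_schema()] for
#'   [build_lsm_like_spec()] cohorts); by default a minimal schema is
#'   derived from the spec.
#' @return an `mbil_dataset` with columns in spec declaration order.
#' @export
simulate_cohort <- function(spec, n, seed = 1L, schema = NULL) {
  stopifnot(inherits(spec, "mbil_truth"), n >= 0)
  rng <- make_rng(seed)
  cols <- list()
  for (v in spec$order) {
    r <- length(spec$variables[[v]])
    pa <- spec$parents[[v]]
    j <- numeric(n)
    for (p in pa) j <- j * length(spec$variables[[p]]) + (cols[[p]] - 1)
    cum <- t(apply(spec$cpts[[v]], 1, cumsum))
    u <- rng$runif(n)
    cols[[v]] <- rowSums(u > cum[j + 1, , drop = FALSE]) + 1L
  }
  nms <- names(spec$variables)
  df <- as.data.frame(lapply(nms, function(v)
    factor(spec$variables[[v]][cols[[v]]], levels = spec$variables[[v]])),
    col.names = nms, check.names = FALSE, optional = TRUE)
  names(df) <- nms
  if (n == 0)
    df <- as.data.frame(lapply(nms, function(v)
      factor(character(), levels = spec$variables[[v]])),
      col.names = nms, check.names = FALSE, optional = TRUE)
  names(df) <- nms
  structure(df, schema = schema %||% schema_from_spec(spec),
            class = c("mbil_dataset", "data.frame"))
}

schema_from_spec <- function(spec) {
  pred <- setdiff(names(spec$variables), spec$targets)
  mbil_schema(
    variables = lapply(pred, function(v)
      list(name = v, categories = spec$variables[[v]],
           kind = "raw-categorical")),
    outcomes = lapply(seq_along(spec$targets), function(i)
      list(name = spec$targets[i], horizon = as.integer(spec$horizons[i]),
           categories = spec$variables[[spec$targets[i]]])),
    name = "synthetic")
}

#' Score learned risk factors against a ground truth
#'
#' Direct risk factors are compared at the variable level: the union of the
#' learned sets against the true parent set of the target.  Interactive
#' sets are compared as exact sets (a learned pair matching a true triple
#' counts as neither precision nor recall credit).
#'
#' @param learned list with `direct` (character vector of variable names,
#'   or list of sets whose union is taken) and optionally `interactive`
#'   (list of character vectors).
#' @param truth an `mbil_truth`.
#' @param target which outcome to score against (default: first).
#' @return list with components `direct` and `interactive`, each holding
#'   `precision` and `recall` in \[0, 1\] (`NA` when undefined, i.e. 0/0).
#' @export
recovery_metrics <- function(learned, truth, target = truth$targets[1]) {
  known <- names(truth$variables)
  lv <- unique(unlist(c(learned$direct, learned$interactive)))
  bad <- setdiff(lv, known)
  if (length(bad)) stop("unknown variable names: ", paste(bad, collapse = ", "))
  true_direct <- truth$parents[[target]]
  got_direct <- unique(unlist(learned$direct))
  pr <- function(hits, got, want)
    list(precision = if (length(got)) hits / length(got) else NA_real_,
         recall = if (length(want)) hits / length(want) else NA_real_)
  direct <- pr(length(intersect(got_direct, true_direct)),
               got_direct, true_direct)
  true_int <- truth$effects[[target]]$interactive_sets
  got_int <- learned$interactive %||% list()
  hits <- sum(vapply(got_int, function(s)
    any(vapply(true_int, setequal, logical(1), s)), logical(1)))
  interactive <- pr(hits, got_int, true_int)
  list(direct = direct, interactive = interactive)
}
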