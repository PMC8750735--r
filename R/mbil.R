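#' Enumerate candidate predictor sets
#'
#' All subsets of the predictors of size 1..`max_size`, in deterministic
#' order: by size, then lexicographically by the predictor order given.
#'
#' @param predictors character vector of predictor names (or an
#'   `mbil_schema`, whose predictors are used).
#' @param max_size maximal subset size, 1, 2 or 3.
#' @return list of character vectors.
#' @export
enumerate_candidates <- function(predictors, max_size = 3) {
  if (inherits(predictors, "mbil_schema"))
    predictors <- predictor_names(predictors)
  if (!max_size %in% 1:3) stop("max_size must be 1, 2 or 3")
  out <- list()
  for (k in seq_len(max_size)) {
    if (length(predictors) < k) break
    cmb <- utils::combn(predictors, k, simplify = FALSE)
    out <- c(out, cmb)
  }
  out
}

#' Detect single and interactive risk factors of an outcome
#'
#' Scores every candidate set S of 1..`max_size` predictors with the BDeu
#' family score of the outcome given S.  A set of two or more variables is
#' reported as *interactive* exactly when its score beats the score of
#' every proper subset (including the empty set): the joint effect is
#' nonadditive — no sub-combination explains the data as well.  Singletons
#' are reported when they beat the empty parent set.  The reported gain is
#' the score margin over the best proper subset; results are ranked by
#' score, ties broken by smaller set then lexicographic names.
#'
#' @param data an `mbil_dataset`.
#' @param outcome name of a binary outcome column.
#' @param alpha prior equivalent sample size for the BDeu score.
#' @param max_size largest set size considered (default 3).
#' @param predictors candidate predictors (default: every non-outcome
#'   column of `data`).
#' @param cache optional [score_cache()] shared across calls.
#' @return data frame of class `mbil_interactions`: columns `variables`
#'   (list of character vectors), `size`, `log_score`,
#'   `gain_over_best_subset`, `classification` (`"single"`/`"interactive"`),
#'   `alpha`.
#' @export
detect_interactions <- function(data, outcome, alpha = 1, max_size = 3,
                                predictors = NULL, cache = NULL) {
  if (nrow(data) == 0) stop("empty dataset")
  if (nlevels(data[[outcome]]) != 2)
    stop("outcome '", outcome, "' must be binary")
  schema <- attr(data, "schema")
  if (is.null(predictors))
    predictors <- setdiff(names(data),
                          if (!is.null(schema)) outcome_names(schema)
                          else outcome)
  dc <- dataset_codes(data)
  sets <- enumerate_candidates(predictors, max_size)
  keyof <- function(s) if (!length(s)) "()" else paste(sort(s), collapse = "|")
  score <- numeric(length(sets) + 1)
  names(score) <- c("()", vapply(sets, keyof, character(1)))
  score[1] <- family_score(data, outcome, character(), alpha,
                           cache = cache, dc = dc)$log_score
  for (i in seq_along(sets))
    score[i + 1] <- family_score(data, outcome, sets[[i]], alpha,
                                 cache = cache, dc = dc)$log_score
  best_subset <- function(s) {
    subs <- c(list(character()),
              unlist(lapply(seq_len(length(s) - 1),
                            function(k) utils::combn(s, k, simplify = FALSE)),
                     recursive = FALSE))
    max(score[vapply(subs, keyof, character(1))])
  }
  gain <- vapply(seq_along(sets), function(i)
    unname(score[i + 1] - best_subset(sets[[i]])), numeric(1))
  keep <- gain > 0
  res <- data.frame(
    size = vapply(sets, length, integer(1))[keep],
    log_score = unname(score[-1])[keep],
    gain_over_best_subset = gain[keep],
    alpha = rep_len(alpha, sum(keep)))
  res$variables <- lapply(sets[keep], sort)
  res$classification <- ifelse(res$size >= 2, "interactive", "single")
  if (!nrow(res)) res$classification <- character()
  # rank: score desc, then smaller set, then lexicographic member names
  lex <- vapply(res$variables, paste, character(1), collapse = "|")
  res <- res[order(-res$log_score, res$size, lex), ,
             drop = FALSE]
  rownames(res) <- NULL
  res <- res[, c("variables", "size", "log_score", "gain_over_best_subset",
                 "classification", "alpha")]
  class(res) <- c("mbil_interactions", "data.frame")
  res
}

#' Learn the Markov blanket (direct risk factors) of an outcome
#'
#' Greedy score-based search over the candidate sets reported by
#' [detect_interactions()] (singles with positive gain and interactive
#' sets).  Forward phase: repeatedly add the candidate set whose variables,
#' joined to the current parent union, most increase the BDeu family score
#' of the outcome; stop when no addition improves it.  Backward phase:
#' remove any selected set whose removal improves the score, until none
#' does.  The result is a local score optimum; for the leaf outcomes
#' handled here the learned parent set is the Markov blanket.
#'
#' @inheritParams detect_interactions
#' @param interactions optionally, a precomputed [detect_interactions()]
#'   result for the same data/alpha.
#' @return object of class `mbil_blanket`: list with `direct_sets` (the
#'   selected rows, singles and interactive sets whose union is the learned
#'   parent set), `other_interactions` (reported interactive sets not
#'   selected), `parent_union`, `log_score`, `trace` (accepted search
#'   steps), `alpha`, `outcome`.
#' @export
learn_markov_blanket <- function(data, outcome, alpha = 1, max_size = 3,
                                 predictors = NULL, cache = NULL,
                                 interactions = NULL) {
  if (nrow(data) == 0) stop("empty dataset")
  if (is.null(cache)) cache <- score_cache()
  if (is.null(interactions))
    interactions <- detect_interactions(data, outcome, alpha, max_size,
                                        predictors, cache)
  dc <- dataset_codes(data)
  fam <- function(par) family_score(data, outcome, par, alpha,
                                    cache = cache, dc = dc)$log_score
  cand <- interactions$variables
  selected <- integer()
  union_vars <- character()
  cur <- fam(character())
  trace <- list()
  repeat {                                      # forward
    best_i <- 0L; best_s <- cur
    for (i in setdiff(seq_along(cand), selected)) {
      add <- cand[[i]]
      if (all(add %in% union_vars)) next
      s <- fam(sort(union(union_vars, add)))
      if (s > best_s + 1e-9) { best_s <- s; best_i <- i }
    }
    if (!best_i) break
    selected <- c(selected, best_i)
    union_vars <- sort(union(union_vars, cand[[best_i]]))
    trace[[length(trace) + 1]] <-
      list(step = "add", set = cand[[best_i]], log_score = best_s)
    cur <- best_s
  }
  repeat {                                      # backward pruning
    best_i <- 0L; best_s <- cur
    for (i in selected) {
      rest <- selected[selected != i]
      vars <- sort(unique(unlist(cand[rest])))
      s <- fam(vars)
      if (s > best_s + 1e-9) { best_s <- s; best_i <- i }
    }
    if (!best_i) break
    trace[[length(trace) + 1]] <-
      list(step = "drop", set = cand[[best_i]], log_score = best_s)
    selected <- selected[selected != best_i]
    union_vars <- sort(unique(unlist(cand[selected])))
    cur <- best_s
  }
  is_int <- interactions$classification == "interactive"
  structure(list(
    direct_sets = interactions[selected, , drop = FALSE],
    other_interactions = interactions[setdiff(which(is_int), selected), ,
                                      drop = FALSE],
    parent_union = union_vars,
    log_score = cur,
    trace = trace,
    alpha = alpha,
    outcome = outcome),
    class = "mbil_blanket")
}

#' @export
print.mbil_blanket <- function(x, ...) {
  cat(sprintf("<mbil_blanket of %s (alpha=%g): %d direct set(s), union {%s}>\n",
              x$outcome, x$alpha, nrow(x$direct_sets),
              paste(x$parent_union, collapse = ", ")))
  invisible(x)
}

#' Run the full learner over all horizons and alpha values
#'
#' One [learn_markov_blanket()] per (horizon, alpha) pair — by default the
#' 3 x 3 grid of 5/10/15-year outcomes and alpha 1/120/480 — giving nine
#' results.  Learning is deterministic given the data.
#'
#' @param data an `mbil_dataset` containing one outcome column per horizon.
#' @param schema schema declaring the outcomes (default: the dataset's).
#' @param horizons integer vector of horizons (years).
#' @param alphas numeric vector of PESS values.
#' @param max_size largest interactive set size.
#' @return object of class `mbil_run`: named list (keys `"h<years>_a<alpha>"`)
#'   of `mbil_blanket` results, with `horizon` and `alpha` attached to each.
#' @export
run_mbil <- function(data, schema = attr(data, "schema"),
                     horizons = c(5, 10, 15), alphas = c(1, 120, 480),
                     max_size = 3) {
  if (is.null(schema)) stop("no schema available")
  miss <- setdiff(vapply(horizons, function(h)
    outcome_for_horizon(schema, h), character(1)), names(data))
  if (length(miss))
    stop("outcome columns absent from data: ", paste(miss, collapse = ", "))
  preds <- intersect(predictor_names(schema), names(data))
  out <- list()
  for (h in horizons) {
    oc <- outcome_for_horizon(schema, h)
    for (a in alphas) {
      cache <- score_cache()
      bl <- learn_markov_blanket(data, oc, alpha = a, max_size = max_size,
                                 predictors = preds, cache = cache)
      bl$horizon <- h
      out[[sprintf("h%d_a%g", h, a)]] <- bl
    }
  }
  structure(out, class = "mbil_run")
}
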