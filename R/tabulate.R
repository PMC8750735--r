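#' Merge jointly-quantified variable names
#'
#' For quantitation, race and ethnicity are counted as one variable, as
#' are smoking and alcohol usage, and the two lymph-node columns (count of
#' positive nodes / positivity status).  Maps a variable name — a schema
#' name or one of the printed display aliases used in the partner tables —
#' to its merged label; every other known name is returned unchanged.
#'
#' @param name character vector of variable names.
#' @return character vector of merged names.
#' @export
merge_variables <- function(name) {
  groups <- list(
    "Race/ethnicity" = c("Race", "race", "Ethnicity", "Race/ethnicity"),
    "Smoking/alcohol" = c("Smoking", "Alcohol", "Alcohol usage",
                          "Smoking/alcohol", "Alcohol/smoking"),
    "LN positive/status" = c("Lymph_nodes_positive", "Lymph_node_status",
                             "LN positive", "LN status",
                             "LN positive/status"))
  aliases <- c("n-TNM", "t-TNM", "Age at DG", "Surgical margins",
               "Invasive tumor location", "Re-excision")
  sch <- lsm_schema()
  known <- c(unlist(groups, use.names = FALSE), aliases,
             predictor_names(sch), outcome_names(sch))
  vapply(name, function(nm) {
    if (!nm %in% known && !grepl("^X\\d+$|^T$", nm))
      stop("unknown variable name: '", nm, "'")
    for (lab in names(groups))
      if (nm %in% groups[[lab]]) return(lab)
    nm
  }, character(1), USE.NAMES = FALSE)
}

# round half away from zero, the convention of the printed percentages
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Interaction records
#'
#' An interaction record is one learned interactive risk-factor set tagged
#' with the horizon (years to metastasis) and the alpha of the run that
#' produced it.  Records are the input of the frequency tabulations.
#'
#' @param variables list of character vectors (each of >= 2 names).
#' @param horizon integer vector (recycled), each in the schema's horizons.
#' @param alpha numeric vector (recycled).
#' @return data frame of class `mbil_records` with list-column `vars`.
#' @export
interaction_records <- function(variables, horizon, alpha) {
  stopifnot(all(vapply(variables, length, integer(1)) >= 2))
  df <- data.frame(horizon = as.integer(horizon), alpha = as.numeric(alpha))
  df <- df[rep_len(seq_len(nrow(df)), length(variables)), , drop = FALSE]
  df$vars <- variables
  rownames(df) <- NULL
  class(df) <- c("mbil_records", "data.frame")
  df
}

#' Read a transcribed partner-frequency table
#'
#' Reads a fixture CSV with the printed columns `variable`, `interacts_with`,
#' `n_times`, `years`, `total`, `percent` (one row per focus/partner pair).
#'
#' @param path CSV path; the three packaged transcriptions are available
#'   via `system.file("extdata", ..., package = "mbil")`.
#' @return data frame with those columns.
#' @export
read_interaction_table <- function(path) {
  utils::read.csv(path, check.names = FALSE, colClasses = c(
    variable = "character", interacts_with = "character",
    n_times = "integer", years = "character",
    total = "integer", percent = "numeric"))
}

#' Expand a transcribed table into pairwise interaction records
#'
#' Each table row (focus, partner, n_times, years) becomes `n_times`
#' records of the pair, with horizons taken from the printed year tokens
#' recycled to length `n_times`.  (A couple of printed rows have more or
#' fewer year tokens than `n_times`; recycling/truncation keeps the record
#' count equal to the printed counts, which is what the totals are based
#' on.)
#'
#' @param rows data frame from [read_interaction_table()].
#' @param alpha the alpha value of the table.
#' @return an `mbil_records` data frame.
#' @export
records_from_table <- function(rows, alpha) {
  vars <- list(); hs <- integer()
  for (i in seq_len(nrow(rows))) {
    toks <- as.integer(trimws(strsplit(rows$years[i], ",")[[1]]))
    h <- rep_len(toks, rows$n_times[i])
    for (y in h) {
      vars[[length(vars) + 1]] <- c(rows$variable[i], rows$interacts_with[i])
      hs <- c(hs, y)
    }
  }
  interaction_records(vars, hs, alpha)
}

#' Re-tabulate a transcribed table focus by focus
#'
#' The printed partner tables are per-focus views and are not mutually
#' symmetric (the same pair can be credited a different number of times
#' from its two ends), so they cannot be pooled into a single record set
#' without double counting.  This reproduces each focus's sub-table from
#' that focus's own rows: expand to records, tabulate, and stack.
#'
#' @param rows data frame from [read_interaction_table()].
#' @param alpha the alpha value of the table.
#' @return data frame of [tabulate_partner_frequencies()] rows for every
#'   focus, in the table's focus order.
#' @export
retabulate_interaction_table <- function(rows, alpha) {
  focus_of <- merge_variables(rows$variable)
  out <- lapply(unique(focus_of), function(f) {
    rec <- records_from_table(rows[focus_of == f, , drop = FALSE], alpha)
    tabulate_partner_frequencies(rec, f, alpha)
  })
  do.call(rbind, out)
}

#' Partner-frequency table for one focus variable
#'
#' For every record containing the focus (after name merging), each other
#' merged member contributes one partner occurrence tagged with the
#' record's horizon.  Occurrences are aggregated by partner in order of
#' first appearance; the focus total is its number of partner occurrences,
#' and each partner's percentage is its share of that total, rounded half
#' away from zero to two decimals.
#'
#' @param records an `mbil_records` data frame.
#' @param focus merged focus name (e.g. `"ER"`, `"Race/ethnicity"`).
#' @param alpha if given, only records at this alpha are used.
#' @return data frame with columns `focus`, `partner`, `n_times`, `years`
#'   (comma-joined sorted horizon tokens, duplicates preserved), `total`,
#'   `percent`; empty when the focus never occurs.
#' @export
tabulate_partner_frequencies <- function(records, focus, alpha = NULL) {
  if (!is.null(alpha)) records <- records[records$alpha == alpha, , drop = FALSE]
  partner <- character(); horizon <- integer()
  for (i in seq_len(nrow(records))) {
    mem <- merge_variables(records$vars[[i]])
    if (!focus %in% mem) next
    others <- mem[mem != focus]
    partner <- c(partner, others)
    horizon <- c(horizon, rep(records$horizon[i], length(others)))
  }
  if (!length(partner))
    return(data.frame(focus = character(), partner = character(),
                      n_times = integer(), years = character(),
                      total = integer(), percent = numeric()))
  total <- length(partner)
  uniq <- unique(partner)                      # first-appearance order
  data.frame(
    focus = focus,
    partner = uniq,
    n_times = vapply(uniq, function(p) sum(partner == p), integer(1)),
    years = vapply(uniq, function(p)
      paste(sort(horizon[partner == p]), collapse = ", "), character(1)),
    total = total,
    percent = vapply(uniq, function(p)
      round_half_up(100 * sum(partner == p) / total), numeric(1)),
    row.names = NULL)
}

#' Count how often a focus variable is an interactive risk factor
#'
#' Number of interaction records at a given (alpha, horizon) containing the
#' focus after name merging — the quantity behind the per-alpha/horizon
#' variable-count summaries.
#'
#' @inheritParams tabulate_partner_frequencies
#' @param horizon horizon in years.
#' @return integer count.
#' @export
count_focus_frequency <- function(records, focus, alpha, horizon) {
  records <- records[records$alpha == alpha &
                       records$horizon == horizon, , drop = FALSE]
  sum(vapply(records$vars, function(v)
    focus %in% merge_variables(v), logical(1)))
}

#' Render learned causal sets as a report
#'
#' One section per (horizon, alpha) listing the direct causal sets — the
#' singles and interactive sets selected into the outcome's Markov blanket
#' — followed by the other reported interactive risk factors, both ranked
#' by score.  Multi-variable sets are rendered with an " x " separator.
#'
#' @param results an `mbil_run` (or any named list of `mbil_blanket`s with
#'   `horizon`/`alpha` fields).
#' @return list with `text` (character vector of report lines) and `csv`
#'   (a data frame: horizon, alpha, role, variables, size, log_score,
#'   gain_over_best_subset, classification).
#' @export
render_causal_set_report <- function(results) {
  lines <- character()
  rows <- list()
  fmt_set <- function(v) paste(v, collapse = " \u00d7 ")
  for (res in results) {
    lines <- c(lines, sprintf("== horizon %d years, alpha = %g ==",
                              res$horizon, res$alpha))
    sect <- function(df, role, label) {
      lines <<- c(lines, paste0(label, ":"))
      if (!nrow(df)) { lines <<- c(lines, "  (none)"); return(invisible()) }
      df <- df[order(-df$log_score), , drop = FALSE]
      for (i in seq_len(nrow(df))) {
        lines <<- c(lines, sprintf("  %s  (score %.6f)",
                                   fmt_set(df$variables[[i]]),
                                   df$log_score[i]))
        rows[[length(rows) + 1]] <<- data.frame(
          horizon = res$horizon, alpha = res$alpha, role = role,
          variables = fmt_set(df$variables[[i]]), size = df$size[i],
          log_score = round(df$log_score[i], 6),
          gain_over_best_subset = round(df$gain_over_best_subset[i], 6),
          classification = df$classification[i])
      }
    }
    sect(res$direct_sets, "direct", "direct causal sets")
    sect(res$other_interactions, "other", "other interactive risk factors")
    lines <- c(lines, "")
  }
  csv <- if (length(rows)) do.call(rbind, rows) else
    data.frame(horizon = integer(), alpha = numeric(), role = character(),
               variables = character(), size = integer(),
               log_score = numeric(), gain_over_best_subset = numeric(),
               classification = character())
  list(text = lines, csv = csv)
}

#' Write pipeline results to disk
#'
#' Writes the machine-readable causal-set CSV to `path` and the
#' human-readable summary next to it (same name, `.txt` extension).
#' Output is byte-identical across runs for identical results.
#'
#' @param results an `mbil_run`.
#' @param path output CSV path.
#' @return invisibly, the paths written.
#' @export
write_report <- function(results, path) {
  rep <- render_causal_set_report(results)
  utils::write.csv(rep$csv, path, row.names = FALSE, quote = TRUE)
  txt <- paste0(sub("\\.[^.]*$", "", path), ".txt")
  writeLines(rep$text, txt)
  invisible(c(path, txt))
}

#' @rdname write_report
#' @param ... passed to [utils::read.csv()].
#' @export
read_report <- function(path, ...)
  utils::read.csv(path, check.names = FALSE,
                  colClasses = c(variables = "character",
                                 role = "character",
                                 classification = "character"), ...)
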