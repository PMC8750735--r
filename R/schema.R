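#' Variable schemas for discrete clinical tables
#'
#' A schema declares, for every predictor, its name, its ordered category
#' set and (for variables recorded as numbers, e.g. age or tumour size) the
#' bin edges used to discretize them, plus one binary outcome column per
#' follow-up horizon.  Category order is meaningful: index 1 is the first
#' declared token, and all downstream encodings are indices against this
#' order.
#'
#' Binned variables follow a lower-inclusive / upper-exclusive convention;
#' the final bin is unbounded above.  A designated missing token (default
#' `"NA"`) is mapped on load to an explicit extra category appended after
#' the declared ones, so sparse clinical tables keep their full n.
#'
#' @param variables list of variable descriptors; each a list with elements
#'   `name`, `categories` (character, length >= 2), `kind`
#'   (`"raw-categorical"` or `"binned-numeric"`) and, for binned variables,
#'   strictly increasing `bin_edges` (one lower edge per bin).
#' @param outcomes list of outcome descriptors: `name`, integer `horizon`
#'   (years) and binary `categories`.
#' @param missing_token token in input files standing for a missing value.
#' @param missing_category category label the missing token is mapped to.
#' @param name schema label used in reports.
#' @return an object of class `mbil_schema`.
#' @export
mbil_schema <- function(variables, outcomes, missing_token = "NA",
                        missing_category = "(missing)", name = "schema") {
  stopifnot(is.list(variables), length(variables) >= 1, is.list(outcomes))
  vnames <- vapply(variables, function(v) v$name, character(1))
  if (anyDuplicated(vnames))
    stop("duplicate variable names in schema: ",
         paste(unique(vnames[duplicated(vnames)]), collapse = ", "))
  for (v in variables) {
    if (length(v$categories) < 2)
      stop("variable '", v$name, "' must have at least 2 categories")
    if (identical(v$kind, "binned-numeric")) {
      if (is.null(v$bin_edges) || is.unsorted(v$bin_edges, strictly = TRUE))
        stop("variable '", v$name, "' needs strictly increasing bin_edges")
      if (length(v$bin_edges) != length(v$categories))
        stop("variable '", v$name, "': one lower bin edge per category required")
    } else if (!identical(v$kind, "raw-categorical")) {
      stop("variable '", v$name, "': unknown kind '", v$kind, "'")
    }
  }
  for (o in outcomes) {
    if (length(o$categories) != 2)
      stop("outcome '", o$name, "' must be binary")
  }
  structure(
    list(variables = stats::setNames(variables, vnames),
         outcomes = stats::setNames(outcomes,
                                    vapply(outcomes, `[[`, character(1), "name")),
         missing_token = missing_token,
         missing_category = missing_category,
         name = name),
    class = "mbil_schema")
}

#' The packaged LSM breast-cancer metastasis schema
#'
#' Loads the 31-predictor schema of the LSM ("LSDS for Metastasis")
#' breast-cancer tables: demographic, exposure, receptor, staging and
#' surgical variables, plus one binary metastasis outcome for each of the
#' 5-, 10- and 15-year horizons.  The category sets are shipped as a JSON
#' document under `inst/extdata/lsm_schema.json`.
#'
#' @return an `mbil_schema` with 31 predictors and 3 outcomes.
#' @export
lsm_schema <- function() {
  if (is.null(.mbil_env$lsm_schema)) {
    path <- system.file("extdata", "lsm_schema.json", package = "mbil",
                        mustWork = TRUE)
    .mbil_env$lsm_schema <- read_schema(path)
  }
  .mbil_env$lsm_schema
}

.mbil_env <- new.env(parent = emptyenv())

#' Read a schema from a JSON document
#'
#' @param path path to a JSON schema file (same layout as the packaged
#'   `lsm_schema.json`).
#' @return an `mbil_schema`.
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  vars <- lapply(doc$variables, function(v)
    list(name = v$name,
         categories = vapply(v$categories, identity, character(1)),
         kind = v$kind,
         bin_edges = if (!is.null(v$bin_edges))
           vapply(v$bin_edges, as.numeric, numeric(1))))
  outs <- lapply(doc$outcomes, function(o)
    list(name = o$name, horizon = as.integer(o$horizon),
         categories = vapply(o$categories, identity, character(1))))
  mbil_schema(vars, outs,
              missing_token = doc$missing_token %||% "NA",
              missing_category = doc$missing_category %||% "(missing)",
              name = doc$name %||% "schema")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mbil_schema <- function(x, ...) {
  cat(sprintf("<mbil_schema '%s': %d predictors, %d outcomes (horizons %s)>\n",
              x$name, length(x$variables), length(x$outcomes),
              paste(schema_horizons(x), collapse = "/")))
  invisible(x)
}

#' Schema accessors
#'
#' `predictor_names()` and `outcome_names()` list the column names a
#' conforming table must provide; `schema_horizons()` gives the follow-up
#' horizons (years); `outcome_for_horizon()` maps a horizon to its outcome
#' column.
#'
#' @param schema an `mbil_schema`.
#' @param horizon integer horizon in years.
#' @return character vector (names) or integer vector (horizons).
#' @export
predictor_names <- function(schema) names(schema$variables)

#' @rdname predictor_names
#' @export
outcome_names <- function(schema) names(schema$outcomes)

#' @rdname predictor_names
#' @export
schema_horizons <- function(schema)
  vapply(schema$outcomes, `[[`, integer(1), "horizon")

#' @rdname predictor_names
#' @export
outcome_for_horizon <- function(schema, horizon) {
  hs <- schema_horizons(schema)
  i <- match(as.integer(horizon), hs)
  if (is.na(i)) stop("no outcome declared for horizon ", horizon)
  names(schema$outcomes)[i]
}

# Ordered factor levels for a column, missing category appended when asked.
column_levels <- function(schema, name, with_missing = FALSE) {
  ent <- schema$variables[[name]]
  if (is.null(ent)) ent <- schema$outcomes[[name]]
  if (is.null(ent)) stop("column '", name, "' not in schema")
  lv <- ent$categories
  if (with_missing) c(lv, schema$missing_category) else lv
}

#' Map a raw numeric value to its discretization bin
#'
#' Bins are lower-inclusive and upper-exclusive; the final bin is unbounded
#' above.  The mapping is monotone in the raw value.
#'
#' @param raw_value numeric value as recorded (e.g. age in years, size in mm).
#' @param variable a schema variable entry of kind `"binned-numeric"`
#'   (an element of `schema$variables`).
#' @return integer bin index, 1-based against the variable's categories.
#' @examples
#' sch <- lsm_schema()
#' discretize_numeric(49, sch$variables$Age_at_diagnosis)  # -> 1
#' discretize_numeric(32, sch$variables$Size)              # -> 2
#' @export
discretize_numeric <- function(raw_value, variable) {
  if (!identical(variable$kind, "binned-numeric"))
    stop("variable '", variable$name, "' is not binned-numeric")
  edges <- variable$bin_edges
  out <- findInterval(raw_value, edges)   # 0 below first edge
  if (any(out == 0, na.rm = TRUE))
    stop("value below the domain of '", variable$name,
         "' (first bin starts at ", edges[1], ")")
  as.integer(out)
}

#' Construct a discrete dataset from encoded columns
#'
#' A dataset is a data frame of factors whose levels are exactly the
#' schema's category sets (plus, for loaded files containing the missing
#' token, the explicit missing category), carrying its schema as an
#' attribute.  Scoring and learning functions operate on the integer codes.
#'
#' @param df data frame of factor (or character) columns.
#' @param schema an `mbil_schema`; every column of `df` must be declared.
#' @param with_missing logical, whether to append the missing category to
#'   every predictor column's level set.  Outcome columns stay strictly
#'   binary: a missing outcome value is a validation error.
#' @return an object of class `mbil_dataset` (a data frame).
#' @export
as_mbil_dataset <- function(df, schema, with_missing = FALSE) {
  for (nm in names(df)) {
    lv <- column_levels(schema, nm, with_missing = with_missing &&
                          nm %in% names(schema$variables))
    col <- as.character(df[[nm]])
    bad <- !is.na(col) & !(col %in% lv)
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("row %d, column '%s': value '%s' not in category set {%s}",
                   i, nm, col[i], paste(lv, collapse = ", ")))
    }
    df[[nm]] <- factor(col, levels = lv)
  }
  structure(df, schema = schema, class = c("mbil_dataset", "data.frame"))
}

#' Read a patient table against a schema
#'
#' Reads an RFC 4180 CSV with a header row, checks that every schema
#' predictor and at least the requested outcome columns are present, maps
#' the designated missing token to the explicit missing category, encodes
#' every cell against the schema's category order, discretizes
#' binned-numeric columns when they arrive as raw numbers, and normalizes
#' column order to schema order.
#'
#' @param path CSV file path.
#' @param schema an `mbil_schema`.
#' @param require_outcomes character vector of outcome columns that must be
#'   present (default: all declared outcomes that appear in the file).
#' @return an `mbil_dataset`.
#' @export
load_dataset <- function(path, schema, require_outcomes = NULL) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        na.strings = NULL)
  missing_pred <- setdiff(predictor_names(schema), names(df))
  if (length(missing_pred))
    stop("schema columns absent from '", path, "': ",
         paste(missing_pred, collapse = ", "))
  if (!is.null(require_outcomes)) {
    miss <- setdiff(require_outcomes, names(df))
    if (length(miss))
      stop("required outcome columns absent: ", paste(miss, collapse = ", "))
  }
  keep <- c(predictor_names(schema),
            intersect(outcome_names(schema), names(df)))
  df <- df[, keep, drop = FALSE]
  for (nm in names(df)) {
    ent <- schema$variables[[nm]] %||% schema$outcomes[[nm]]
    col <- df[[nm]]
    is_missing <- col == schema$missing_token
    # numeric cells in binned columns are discretized; label cells kept as-is
    if (identical(ent$kind, "binned-numeric")) {
      num <- suppressWarnings(as.numeric(col))
      conv <- !is.na(num) & !(col %in% ent$categories)
      if (any(conv & !is_missing))
        col[conv & !is_missing] <-
          ent$categories[discretize_numeric(num[conv & !is_missing], ent)]
    }
    if (nm %in% names(schema$variables))
      col[is_missing] <- schema$missing_category
    df[[nm]] <- col
  }
  as_mbil_dataset(df, schema, with_missing = TRUE)
}

#' Write a dataset back to CSV
#'
#' Inverse of [load_dataset()]: factor levels are written as their category
#' tokens, the explicit missing category as the schema's missing token.
#' Byte-identical across runs for identical input.
#'
#' @param data an `mbil_dataset`.
#' @param path output CSV path.
#' @export
write_dataset <- function(data, path) {
  schema <- attr(data, "schema")
  out <- as.data.frame(lapply(data, as.character),
                       check.names = FALSE, optional = TRUE)
  names(out) <- names(data)
  out[is.na(out)] <- schema$missing_token
  for (nm in names(out))
    out[[nm]][out[[nm]] == schema$missing_category] <- schema$missing_token
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

# Integer code matrix (1-based) plus per-column cardinalities; the working
# representation for all counting.
dataset_codes <- function(data) {
  m <- vapply(data, as.integer, integer(nrow(data)))
  if (is.null(dim(m))) m <- matrix(m, nrow = nrow(data))
  colnames(m) <- names(data)
  card <- vapply(data, nlevels, integer(1))
  list(codes = m, card = card, n = nrow(data))
}
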