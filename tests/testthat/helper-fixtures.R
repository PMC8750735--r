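# Shared fixtures, all built in code.

# binary factor column helper
bf <- function(x) factor(x, levels = c("0", "1"))

# a plain data frame of binary factors from 0/1 vectors
bin_df <- function(...) {
  cols <- list(...)
  as.data.frame(lapply(cols, function(v) bf(as.character(v))),
                col.names = names(cols), check.names = FALSE)
}

# random tiny categorical dataset for oracle cross-checks
random_tiny <- function(seed, n_max = 12, p_max = 3, card_max = 3) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  p <- sample(1:(p_max + 1), 1)      # predictors + target
  cards <- sample(2:card_max, p, replace = TRUE)
  df <- as.data.frame(lapply(seq_len(p), function(i)
    factor(sample(seq_len(cards[i]), n, replace = TRUE),
           levels = seq_len(cards[i]))),
    col.names = paste0("V", seq_len(p)), check.names = FALSE)
  names(df) <- paste0("V", seq_len(p))
  df
}

# all-noise spec: the Figure-1 predictors with the outcome disconnected
build_null_spec <- function() {
  fig <- build_figure1_spec()
  parents <- fig$parents
  cpts <- fig$cpts
  parents$T <- character()
  cpts$T <- matrix(c(0.6, 0.4), 1)
  ground_truth_spec(
    fig$variables, parents, cpts, targets = "T",
    effects = list(T = list(direct_singles = character(),
                            interactive_sets = list())),
    noise_variables = paste0("X", 1:17), horizons = 5L)
}

fixture_table <- function(which) {
  f <- c(`1` = "table2_alpha1.csv", `120` = "table3_alpha120.csv",
         `480` = "table4_alpha480.csv")[[as.character(which)]]
  read_interaction_table(system.file("extdata", f, package = "mbil"))
}

# tiny LSM-shaped CSV written to a temp file; returns the path
write_tiny_lsm_csv <- function(n = 5, seed = 99, missing_at = NULL) {
  spec <- build_lsm_like_spec(seed = seed)
  d <- simulate_cohort(spec, n, seed = seed, schema = lsm_schema())
  path <- tempfile(fileext = ".csv")
  write_dataset(d, path)
  if (!is.null(missing_at)) {             # poke an NA token into a cell
    df <- utils::read.csv(path, check.names = FALSE,
                          colClasses = "character")
    df[missing_at$row, missing_at$col] <- "NA"
    utils::write.csv(df, path, row.names = FALSE)
  }
  path
}
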