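#' Construct a validated person-by-item response matrix
#'
#' Container for polytomous questionnaire responses: an `n x J` matrix of
#' ordered integer categories coded `1..n_categories`, an optional two-level
#' grouping label per person, and optional additional categorical covariates
#' (e.g. gender, education, age group). Out-of-range or non-integer cells are
#' rejected with their row/column location; nothing is silently clamped.
#'
#' @param responses integer matrix or data frame, categories `1..n_categories`
#'   (`NA` allowed for missing responses).
#' @param group optional per-person categorical label; a DIF run requires
#'   exactly two observed levels.
#' @param item_ids item labels; defaults to column names or `item01..`.
#' @param covariates optional data frame of additional per-person categorical
#'   columns.
#' @param n_categories number of ordered response levels (5 for the DAI-36).
#' @return An object of class `response_matrix` with elements `responses`,
#'   `item_ids`, `group`, `covariates`, `n_categories`.
#' @examples
#' m <- matrix(sample(1:5, 40, TRUE), 10, 4)
#' rm <- response_matrix(m, group = rep(c("a", "b"), 5))
#' dim(rm)
#' @export
response_matrix <- function(responses, group = NULL, item_ids = NULL,
                            covariates = NULL, n_categories = 5L) {
  if (is.data.frame(responses)) responses <- as.matrix(responses)
  if (!is.matrix(responses)) responses <- matrix(responses, ncol = 1L)
  n <- nrow(responses); J <- ncol(responses)
  if (n < 1L || J < 1L) stop_validation("need at least 1 person and 1 item (got n=%d, J=%d)", n, J)
  m <- as.integer(n_categories)
  if (m < 2L) stop_validation("n_categories must be >= 2")

  if (is.null(item_ids)) {
    item_ids <- colnames(responses)
    if (is.null(item_ids)) item_ids <- sprintf("item%02d", seq_len(J))
  }
  if (length(item_ids) != J) stop_validation("item_ids length (%d) != number of items (%d)", length(item_ids), J)
  if (anyDuplicated(item_ids)) stop_validation("item_ids must be unique")

  num <- suppressWarnings(array(as.numeric(responses), dim = dim(responses)))
  bad_parse <- which(!is.na(responses) & is.na(num), arr.ind = TRUE)
  bad_int <- which(!is.na(num) & (num != round(num)), arr.ind = TRUE)
  bad_rng <- which(!is.na(num) & num == round(num) & (num < 1 | num > m), arr.ind = TRUE)
  bad <- rbind(bad_parse, bad_int, bad_rng)
  if (nrow(bad) > 0L) {
    bad <- bad[order(bad[, 1L], bad[, 2L]), , drop = FALSE]
    cells <- apply(head(bad, 10L), 1L, function(rc)
      sprintf("row %d, item '%s' = %s", rc[1L], item_ids[rc[2L]], as.character(responses[rc[1L], rc[2L]])))
    stop_validation("responses must be integers in [1, %d]; offending cells: %s%s",
                    m, paste(cells, collapse = "; "),
                    if (nrow(bad) > 10L) sprintf(" (and %d more)", nrow(bad) - 10L) else "")
  }
  storage.mode(num) <- "integer"
  colnames(num) <- item_ids
  rownames(num) <- NULL

  if (!is.null(group)) {
    if (length(group) != n) stop_validation("group length (%d) != number of persons (%d)", length(group), n)
    group <- factor(group)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
    if (nrow(covariates) != n) stop_validation("covariates must have one row per person")
  }
  structure(list(responses = num, item_ids = item_ids, group = group,
                 covariates = covariates, n_categories = m),
            class = "response_matrix")
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("response_matrix: %d persons x %d items, categories 1..%d\n",
              nrow(x$responses), ncol(x$responses), x$n_categories))
  if (!is.null(x$group)) {
    tb <- table(x$group)
    cat("  group:", paste(sprintf("%s (n=%d)", names(tb), tb), collapse = ", "), "\n")
  }
  if (!is.null(x$covariates))
    cat("  covariates:", paste(names(x$covariates), collapse = ", "), "\n")
  nmiss <- sum(is.na(x$responses))
  if (nmiss > 0L) cat(sprintf("  missing cells: %d\n", nmiss))
  invisible(x)
}

#' @export
as.data.frame.response_matrix <- function(x, ...) {
  out <- as.data.frame(x$responses)
  if (!is.null(x$group)) out$group <- x$group
  if (!is.null(x$covariates)) out <- cbind(out, x$covariates)
  out
}

## exactly-two-level group factor coded reference = first level (0),
## focal = second (1); alphabetical unless the factor carries its own order
dif_group_coding <- function(group) {
  if (is.null(group)) stop_validation("a DIF analysis requires a grouping variable")
  g <- factor(group)
  g <- droplevels(g)
  if (nlevels(g) != 2L)
    stop_validation("grouping variable must have exactly 2 observed levels (got %d: %s)",
                    nlevels(g), paste(levels(g), collapse = ", "))
  list(code = as.integer(g) - 1L, reference = levels(g)[1L], focal = levels(g)[2L])
}

## apply the configured missing-data policy; listwise drops any person with
## a missing item, pairwise_item defers per-item deletion to analyze_item
apply_missing_policy <- function(data, policy = c("listwise", "pairwise_item")) {
  policy <- match.arg(policy)
  if (policy == "listwise") {
    keep <- stats::complete.cases(data$responses)
    if (!all(keep)) {
      data$responses <- data$responses[keep, , drop = FALSE]
      if (!is.null(data$group)) data$group <- data$group[keep]
      if (!is.null(data$covariates)) data$covariates <- data$covariates[keep, , drop = FALSE]
    }
  }
  data
}

#' Read a wide-format response table from CSV
#'
#' Reads one row per person. Item columns must parse to integers in
#' `1..n_categories` or the missing token; violations raise a validation
#' error naming the offending cells.
#'
#' @param path CSV file path (UTF-8, header row required).
#' @param item_columns character vector of item column names; `NULL` means
#'   every column not named as group/covariate.
#' @param group_column optional name of the grouping column.
#' @param covariate_columns optional further categorical columns to carry.
#' @param n_categories number of ordered response levels.
#' @param na_strings tokens treated as missing.
#' @return A [response_matrix].
#' @export
read_responses <- function(path, item_columns = NULL, group_column = NULL,
                           covariate_columns = NULL, n_categories = 5L,
                           na_strings = c("NA", "")) {
  if (!file.exists(path)) stop_io("file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = na_strings,
                        check.names = FALSE, fileEncoding = "UTF-8")
  named <- c(item_columns, group_column, covariate_columns)
  missing_cols <- setdiff(named, names(df))
  if (length(missing_cols) > 0L)
    stop_config("column(s) not present in %s: %s", path, paste(missing_cols, collapse = ", "))
  if (is.null(item_columns))
    item_columns <- setdiff(names(df), c(group_column, covariate_columns))
  response_matrix(df[item_columns],
                  group = if (!is.null(group_column)) df[[group_column]],
                  item_ids = item_columns,
                  covariates = if (!is.null(covariate_columns)) df[covariate_columns],
                  n_categories = n_categories)
}
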