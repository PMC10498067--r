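#' Per-person questionnaire scores
#'
#' The total score is the per-person mean item response on the 1..m item
#' scale (optionally after excluding items, e.g. uniform-DIF items), so
#' corrected and uncorrected scores stay directly comparable.
#'
#' @param data a [response_matrix].
#' @param exclude_items item ids or indices to drop before scoring.
#' @return numeric vector of person scores in `[1, m]`.
#' @export
person_scores <- function(data, exclude_items = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  Y <- data$responses
  if (!is.null(exclude_items) && length(exclude_items)) {
    idx <- if (is.character(exclude_items)) match(exclude_items, data$item_ids)
           else as.integer(exclude_items)
    if (anyNA(idx)) stop_validation("unknown item(s) in exclude_items")
    keep <- setdiff(seq_len(ncol(Y)), idx)
    if (length(keep) == 0L) stop_validation("cannot exclude every item")
    Y <- Y[, keep, drop = FALSE]
  }
  rowMeans(Y, na.rm = TRUE)
}

#' Pooled-variance independent-samples t-test
#'
#' Two-sided pooled (equal-variance) t statistic and p-value, via
#' [stats::t.test] with `var.equal = TRUE`.
#'
#' @param x,y numeric samples (each n >= 2 with positive pooled variance).
#' @return list with `statistic`, `p_value`, `df`.
#' @export
t_test_pooled <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L)
    stop_validation("each sample needs n >= 2")
  sp <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp <= 0) stop_validation("zero pooled variance")
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter))
}

## null distribution of the doubled rank-sum of the first sample over all
## equally likely subsets: dynamic programme over the pooled doubled
## midranks (exact, tie-safe)
rank_sum_distribution <- function(ranks2, nx) {
  smax <- sum(sort(ranks2, decreasing = TRUE)[seq_len(nx)])
  # counts[k + 1, s + 1] = number of size-k subsets with doubled rank sum s
  counts <- matrix(0, nx + 1L, smax + 1L)
  counts[1L, 1L] <- 1
  for (r in ranks2) {
    for (k in nx:1L) {                     # size k - 1 gains this element
      nz <- which(counts[k, ] > 0)
      if (length(nz))
        counts[k + 1L, nz + r] <- counts[k + 1L, nz + r] + counts[k, nz]
    }
  }
  counts[nx + 1L, ]
}

#' Mann-Whitney U test
#'
#' The U statistic counts pairs where an `x` observation exceeds a `y`
#' observation (ties count one half), i.e. `U = W - nx(nx+1)/2` with `W` the
#' rank sum of `x`; `x` entirely below `y` therefore gives `U = 0`. The
#' two-sided p-value comes from exact enumeration of the tie-aware rank-sum
#' permutation distribution (dynamic programme over doubled midranks) when
#' `nx * ny <= 400`, and otherwise from the normal approximation with tie
#' and continuity corrections.
#'
#' @param x,y numeric samples (non-empty).
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return list with `U`, `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, method = c("auto", "exact", "normal")) {
  method <- match.arg(method)
  if (!length(x) || !length(y)) stop_validation("both samples must be non-empty")
  nx <- length(x); ny <- length(y); n <- nx + ny
  pooled <- c(x, y)
  rk <- rank(pooled)
  W <- sum(rk[seq_len(nx)])
  U <- W - nx * (nx + 1) / 2
  if (method == "auto") method <- if (nx * ny <= 400) "exact" else "normal"
  if (method == "exact") {
    r2 <- as.integer(round(2 * rk))
    dist <- rank_sum_distribution(r2, nx)
    total <- sum(dist)
    s <- seq_along(dist) - 1L            # doubled rank sums with any count
    mu2 <- nx * (n + 1)                  # doubled mean rank sum
    dev_obs <- abs(2 * W - mu2)
    p <- sum(dist[abs(s - mu2) >= dev_obs - 1e-9]) / total
  } else {
    mu <- nx * ny / 2
    ties <- table(pooled)
    tie_adj <- sum(ties^3 - ties) / (n * (n - 1))
    v <- nx * ny / 12 * ((n + 1) - tie_adj)
    if (v <= 0) return(list(U = U, p_value = 1, method = "normal"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(v)
    if (abs(U - mu) <= 0.5) z <- 0
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  list(U = U, p_value = p, method = method)
}

#' Compare group scores with and without uniform-DIF items
#'
#' For the grouping variable of a DIF run, compares the person-level total
#' scores between the two groups twice: uncorrected (all items) and
#' corrected (items with significant uniform DIF removed). Both the
#' pooled-variance t-test and the Mann-Whitney U-test are computed and
#' reported for each comparison.
#'
#' @param data a [response_matrix] (defaults to the data stored in `report`).
#' @param report a [dif_olr] fit for the grouping of interest.
#' @param config a [dif_config] (defaults to the report's).
#' @return data frame, one row per group level per correction status, with
#'   columns `correction`, `level`, `n`, `mean`, `sd`, `p_t_test`,
#'   `p_mann_whitney`, `excluded_items`.
#' @export
compare_with_without_dif <- function(report, data = report$data,
                                     config = report$config) {
  stopifnot(inherits(report, "dif_olr"))
  res <- report$results
  uniform_items <- res$item_id[res$flag_uniform_sig & res$usable]
  coding <- dif_group_coding(data$group)
  g <- coding$code
  one <- function(excl, label) {
    sc <- person_scores(data, exclude_items = if (length(excl)) excl else NULL)
    x <- sc[g == 0L]; y <- sc[g == 1L]
    tt <- t_test_pooled(x, y)
    mw <- mann_whitney_u(x, y)
    data.frame(correction = label,
               level = c(coding$reference, coding$focal),
               n = c(length(x), length(y)),
               mean = c(mean(x), mean(y)),
               sd = c(sd(x), sd(y)),
               p_t_test = tt$p_value,
               p_mann_whitney = mw$p_value,
               excluded_items = paste(excl, collapse = ";"),
               stringsAsFactors = FALSE)
  }
  rbind(one(character(0), "uncorrected"),
        one(uniform_items, "corrected"))
}
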