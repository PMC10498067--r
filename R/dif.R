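#' Three-model DIF statistics for one item
#'
#' Fits the nested cumulative-logit models M1 (trait), M2 (+ group) and M3
#' (+ trait-by-group interaction) on the persons with an observed response,
#' and returns the uniform (M1 vs M2) and nonuniform (M2 vs M3)
#' likelihood-ratio chi-squares (df 1 each), the overall M1 vs M3 chi-square
#' (df 2, reported but not used for flagging), the pseudo-R-squared
#' differences and the beta-change criterion.
#'
#' @param y item responses (`1..m`, `NA` allowed).
#' @param theta trait scores aligned with `y`.
#' @param group 0/1 group aligned with `y`.
#' @param config a [dif_config] (controls the pseudo-R-squared formula).
#' @param item_id label carried into the result row.
#' @return One-row data frame of statistics (class `dif_stats`); when a fit
#'   fails the row is marked `usable = FALSE` and carries `NA` statistics.
#' @export
analyze_item <- function(y, theta, group, config = dif_config(), item_id = "item") {
  stopifnot(length(y) == length(theta), length(y) == length(group))
  keep <- !is.na(y)
  y <- y[keep]; theta <- theta[keep]; group <- group[keep]
  row <- data.frame(item_id = item_id, n_used = length(y),
                    chi2_uniform = NA_real_, p_uniform = NA_real_,
                    chi2_nonuniform = NA_real_, p_nonuniform = NA_real_,
                    chi2_total = NA_real_, p_total = NA_real_,
                    delta_r1 = NA_real_, delta_r2 = NA_real_,
                    delta_beta1 = NA_real_, converged = FALSE, usable = FALSE,
                    stringsAsFactors = FALSE)
  res <- tryCatch({
    m1 <- fit_cumulative_logit(y, theta, group, "M1")
    m2 <- fit_cumulative_logit(y, theta, group, "M2")
    m3 <- fit_cumulative_logit(y, theta, group, "M3")
    null_fit <- if (config$delta_r_formula == "mcfadden_difference")
      fit_cumulative_logit(y, model = "M0") else NULL
    uni <- lr_chi2(m1, m2, df = 1L)
    nonuni <- lr_chi2(m2, m3, df = 1L)
    tot <- lr_chi2(m1, m3, df = 2L)
    row$chi2_uniform <- uni$chi2; row$p_uniform <- uni$p
    row$chi2_nonuniform <- nonuni$chi2; row$p_nonuniform <- nonuni$p
    row$chi2_total <- tot$chi2; row$p_total <- tot$p
    row$delta_r1 <- delta_r(m1, m2, config$delta_r_formula, null_fit)
    row$delta_r2 <- delta_r(m2, m3, config$delta_r_formula, null_fit)
    row$delta_beta1 <- cvbl_delta_beta(m1, m2)
    row$converged <- m1$converged && m2$converged && m3$converged
    row$usable <- TRUE
    row
  }, error = function(e) {
    warning(sprintf("item '%s' could not be analysed (%s); excluded from anchors and flag counts",
                    item_id, conditionMessage(e)))
    row
  })
  class(res) <- c("dif_stats", class(res))
  res
}

#' Apply the flagging criteria to DIF statistics
#'
#' Pure function of the statistics and the criteria: significance flags from
#' the chi-square p-values at `alpha` (optionally Bonferroni-adjusted across
#' `n_items`), a large-effect flag when the larger pseudo-R-squared
#' difference exceeds `r2_threshold`, a large-effect flag when the
#' beta-change criterion exceeds `cvbl_threshold`, and the combined flag that
#' drives purification (per `purification_criterion`).
#'
#' @param stats data frame with columns `p_uniform`, `p_nonuniform`,
#'   `delta_r1`, `delta_r2`, `delta_beta1` (and optionally `usable`).
#' @param config a [dif_config].
#' @param n_items divisor for the Bonferroni option; default `nrow(stats)`.
#' @return `stats` with logical columns `flag_uniform_sig`,
#'   `flag_nonuniform_sig`, `flag_large_r2`, `flag_large_cvbl`, `flag_dif`.
#' @export
classify_item <- function(stats, config = dif_config(), n_items = nrow(stats)) {
  stats <- as.data.frame(stats)
  alpha <- if (config$bonferroni) config$alpha / max(n_items, 1L) else config$alpha
  usable <- if ("usable" %in% names(stats)) stats$usable else rep(TRUE, nrow(stats))
  stats$flag_uniform_sig <- usable & !is.na(stats$p_uniform) & stats$p_uniform < alpha
  stats$flag_nonuniform_sig <- usable & !is.na(stats$p_nonuniform) & stats$p_nonuniform < alpha
  max_r <- pmax(stats$delta_r1, stats$delta_r2, na.rm = TRUE)
  stats$flag_large_r2 <- usable & is.finite(max_r) & max_r > config$r2_threshold
  stats$flag_large_cvbl <- usable & !is.na(stats$delta_beta1) &
    stats$delta_beta1 > config$cvbl_threshold
  sig <- stats$flag_uniform_sig | stats$flag_nonuniform_sig
  large <- stats$flag_large_r2 | stats$flag_large_cvbl
  stats$flag_dif <- switch(config$purification_criterion,
                           chisq = sig,
                           effect_size = large,
                           both = sig & large)
  stats
}

#' Iterative hybrid OLR/IRT differential item functioning analysis
#'
#' The central fitting function. Iteration 0 estimates the graded trait
#' model on all items, scores every person by EAP, runs the three-model
#' comparison for every item and flags items by the chi-square criteria.
#' Each subsequent iteration re-scores the trait using only the current
#' anchor (unflagged) items — re-estimating their parameters unless
#' `refit_anchors` is off — re-analyses every item against the purified
#' trait, and re-flags. The loop stops when the flagged set repeats any
#' earlier flagged set (a fixed point or a detected cycle) or at
#' `max_purification_iters`; the termination reason is recorded. If every
#' item becomes flagged the run stops with the last non-empty anchor set and
#' a prominent warning.
#'
#' @param data a [response_matrix]; the grouping variable must have exactly
#'   two observed levels (taken from `data$group`, or from the covariate
#'   named by `config$grouping_variable`).
#' @param config a [dif_config].
#' @return An object of class `dif_olr`: `results` (per-item statistics and
#'   flags), `flagged`, `anchors`, `trace` (flagged set per iteration),
#'   `iterations`, `termination`, `theta` (final trait scores), `grm` (final
#'   trait-model fit), `group` (coding record), `config`, `data`, `call`.
#' @seealso [summary.dif_olr], [plot.dif_olr], [export_dif_curves],
#'   [compare_with_without_dif]
#' @examples
#' sim <- simulate_responses(synthetic_spec(n_per_group = c(150, 150),
#'                                          n_items = 6, seed = 42))
#' fit <- dif_olr(sim$data, dif_config(max_purification_iters = 3))
#' print(fit)
#' @export
dif_olr <- function(data, config = dif_config()) {
  cl <- match.call()
  stopifnot(inherits(data, "response_matrix"), inherits(config, "dif_config"))
  grp <- data$group
  if (!is.null(config$grouping_variable)) {
    if (is.null(data$covariates) || !config$grouping_variable %in% names(data$covariates))
      stop_config("grouping variable '%s' not found among covariates", config$grouping_variable)
    grp <- data$covariates[[config$grouping_variable]]
  }
  coding <- dif_group_coding(grp)
  data$group <- factor(ifelse(coding$code == 0L, coding$reference, coding$focal),
                       levels = c(coding$reference, coding$focal))
  data <- apply_missing_policy(data, config$missing_policy)
  coding <- dif_group_coding(data$group)
  g <- coding$code
  Y <- data$responses
  J <- ncol(Y)
  ids <- data$item_ids

  grm0 <- fit_grm(data, variant = config$model_variant,
                  quadrature_points = config$quadrature_points)
  usable_ids <- grm0$item_ids
  anchors <- usable_ids
  trace <- list()
  termination <- "max_iterations"
  iter <- 0L
  results <- NULL; theta_est <- NULL; grm_cur <- grm0

  repeat {
    theta_est <- eap_theta(grm_cur, data, anchor_items = anchors)
    stats <- do.call(rbind, lapply(seq_len(J), function(j)
      analyze_item(Y[, j], theta_est$theta, g, config, item_id = ids[j])))
    results <- classify_item(stats, config, n_items = sum(stats$usable))
    flagged <- results$item_id[results$flag_dif & results$usable]
    trace[[iter + 1L]] <- flagged
    new_anchors <- setdiff(usable_ids, flagged)

    if (length(new_anchors) == 0L) {
      warning("all items flagged as DIF: purification stopped; ",
              "results use the last non-empty anchor set (", length(anchors),
              " items)", call. = FALSE)
      termination <- "all_items_flagged"
      break
    }
    if (setequal(new_anchors, anchors)) { termination <- "converged"; break }
    if (iter >= 1L &&
        any(vapply(trace[seq_len(iter)], function(f) setequal(f, flagged), logical(1)))) {
      termination <- "cycle_detected"
      break
    }
    if (iter + 1L >= config$max_purification_iters) { termination <- "max_iterations"; break }

    anchors <- new_anchors
    iter <- iter + 1L
    if (config$refit_anchors) {
      grm_cur <- fit_grm(data, variant = config$model_variant,
                         quadrature_points = config$quadrature_points,
                         items = anchors)
    }
  }

  flagged_final <- results$item_id[results$flag_dif & results$usable]
  anchors_final <- setdiff(usable_ids, flagged_final)
  if (length(anchors_final) == 0L) anchors_final <- anchors
  structure(list(results = results, flagged = flagged_final,
                 anchors = anchors_final, trace = trace,
                 iterations = length(trace), termination = termination,
                 theta = theta_est, grm = grm_cur, group = coding,
                 config = config, data = data, call = cl),
            class = "dif_olr")
}

#' @export
print.dif_olr <- function(x, ...) {
  cat("Iterative hybrid OLR/IRT DIF analysis\n")
  cat(sprintf("  groups: %s (reference) vs %s (focal), n = %d\n",
              x$group$reference, x$group$focal, nrow(x$data$responses)))
  cat(sprintf("  items analysed: %d; purification iterations: %d (%s)\n",
              nrow(x$results), x$iterations, x$termination))
  cat(sprintf("  flagged (chi-square, alpha = %g): uniform %d, nonuniform %d, either %d\n",
              x$config$alpha, sum(x$results$flag_uniform_sig),
              sum(x$results$flag_nonuniform_sig), length(x$flagged)))
  if (length(x$flagged))
    cat("  flagged items:", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Summarise a DIF analysis
#'
#' @param object a [dif_olr] fit.
#' @param digits rounding for display.
#' @param ... unused.
#' @return The per-item results table, invisibly, after printing it together
#'   with the purification trace.
#' @export
summary.dif_olr <- function(object, digits = 4L, ...) {
  print(object)
  cat("\nPer-item statistics:\n")
  show <- object$results
  num <- vapply(show, is.numeric, logical(1))
  show[num] <- lapply(show[num], round, digits = digits)
  print(show, row.names = FALSE)
  cat("\nPurification trace (flagged sets):\n")
  for (i in seq_along(object$trace))
    cat(sprintf("  iteration %d: %s\n", i - 1L,
                if (length(object$trace[[i]])) paste(object$trace[[i]], collapse = ", ")
                else "(none)"))
  invisible(object$results)
}

#' @export
coef.dif_olr <- function(object, ...) {
  out <- object$results
  rownames(out) <- out$item_id
  as.matrix(out[, c("chi2_uniform", "p_uniform", "chi2_nonuniform",
                    "p_nonuniform", "delta_r1", "delta_r2", "delta_beta1")])
}

#' Group-specific test characteristic curves of flagged items
#'
#' Re-estimates group-specific graded item parameters for the flagged
#' items (anchor items keep their common parameters) by fixed-trait maximum
#' likelihood against the final purified trait scores, then sums expected
#' item scores per group over the trait grid.
#'
#' @param object a [dif_olr] fit.
#' @param which `"uniform"` (default, items with significant uniform DIF),
#'   `"nonuniform"`, or `"any"`.
#' @param theta_grid trait grid.
#' @return data frame `theta` x one column per group (attribute
#'   `items` lists the curve's items); zero-row with a `note` attribute when
#'   nothing is flagged.
#' @export
export_dif_curves <- function(object, which = c("uniform", "nonuniform", "any"),
                              theta_grid = seq(-4, 4, length.out = 101)) {
  stopifnot(inherits(object, "dif_olr"))
  which <- match.arg(which)
  res <- object$results
  sel <- switch(which,
                uniform = res$flag_uniform_sig,
                nonuniform = res$flag_nonuniform_sig,
                any = res$flag_uniform_sig | res$flag_nonuniform_sig)
  items <- res$item_id[sel & res$usable]
  if (length(items) == 0L) {
    message("no flagged items; returning empty curve set")
    out <- data.frame(theta = numeric(0))
    attr(out, "note") <- "no flagged items"
    attr(out, "items") <- character(0)
    return(out)
  }
  Y <- object$data$responses
  m <- object$data$n_categories
  g <- dif_group_coding(object$data$group)$code
  theta <- object$theta$theta
  groups <- c(object$group$reference, object$group$focal)
  params <- lapply(0:1, function(gv) {
    rows <- which(g == gv)
    fits <- lapply(items, function(it)
      fit_item_fixed_theta(Y[rows, it], theta[rows], m = m))
    list(a = vapply(fits, `[[`, numeric(1), "a"),
         b = lapply(fits, `[[`, "b"))
  })
  names(params) <- groups
  out <- test_characteristic_curve(params, items = seq_along(items),
                                   theta_grid = theta_grid)
  attr(out, "items") <- items
  out
}

#' Plot group test characteristic curves of flagged items
#'
#' @param x a [dif_olr] fit.
#' @param which passed to [export_dif_curves].
#' @param ... further arguments to [graphics::matplot].
#' @return The curve data frame, invisibly.
#' @export
plot.dif_olr <- function(x, which = "uniform", ...) {
  curves <- export_dif_curves(x, which = which)
  if (nrow(curves) == 0L) return(invisible(curves))
  graphics::matplot(curves$theta, as.matrix(curves[, -1L, drop = FALSE]),
                    type = "l", lty = 1:2, col = c("black", "grey40"),
                    xlab = expression(theta),
                    ylab = "expected summed score",
                    main = sprintf("Test characteristic curves (%s DIF items)", which),
                    ...)
  graphics::legend("topleft", legend = colnames(curves)[-1L],
                   lty = 1:2, col = c("black", "grey40"), bty = "n")
  invisible(curves)
}
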