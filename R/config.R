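#' DIF run configuration
#'
#' Collects every analysis option: the grouping variable, the significance
#' level for the likelihood-ratio chi-square tests, the large-DIF effect-size
#' cutoffs (pseudo-R-squared difference > 0.070, Crane-van Belle-Larson
#' beta-change > 0.01), the purification cap, the trait-model variant and the
#' missing-data policy.
#'
#' @param grouping_variable name of the covariate used as the DIF grouping
#'   variable (`NULL` when the data carry their own `group`).
#' @param alpha significance level for the chi-square DIF tests.
#' @param r2_threshold large-DIF cutoff for the pseudo-R-squared differences.
#' @param cvbl_threshold large-DIF cutoff for the beta-change criterion.
#' @param max_purification_iters cap on purification iterations (>= 1).
#' @param model_variant trait model: `"graded"` (per-item discrimination) or
#'   `"equal_discrimination"` (one common slope).
#' @param missing_policy `"listwise"` (drop persons with any missing item) or
#'   `"pairwise_item"` (drop a person only from items they skipped; trait
#'   scores use observed items).
#' @param delta_r_formula `"ratio"` for the log-likelihood ratio form
#'   `1 - lnL(full)/lnL(sub)`, or `"mcfadden_difference"` for the difference
#'   of McFadden pseudo-R-squared values against an intercept-only model.
#' @param purification_criterion which flags drive anchor selection:
#'   `"chisq"` (either DIF chi-square significant; default), `"effect_size"`
#'   (either large-effect flag), or `"both"` (significant and large).
#' @param refit_anchors re-estimate item parameters on the anchor set each
#'   purification iteration (`TRUE`, the full hybrid) or freeze the
#'   iteration-0 parameters and only re-score (`FALSE`, faster).
#' @param quadrature_points number of trait quadrature points.
#' @param bonferroni apply a Bonferroni correction to `alpha` across items.
#' @param seed optional integer seed recorded with the run.
#' @return An object of class `dif_config` (a validated named list).
#' @export
dif_config <- function(grouping_variable = NULL,
                       alpha = 0.05,
                       r2_threshold = 0.070,
                       cvbl_threshold = 0.01,
                       max_purification_iters = 10L,
                       model_variant = c("graded", "equal_discrimination"),
                       missing_policy = c("listwise", "pairwise_item"),
                       delta_r_formula = c("ratio", "mcfadden_difference"),
                       purification_criterion = c("chisq", "effect_size", "both"),
                       refit_anchors = TRUE,
                       quadrature_points = 49L,
                       bonferroni = FALSE,
                       seed = NULL) {
  model_variant <- match.arg(model_variant)
  missing_policy <- match.arg(missing_policy)
  delta_r_formula <- match.arg(delta_r_formula)
  purification_criterion <- match.arg(purification_criterion)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop_config("alpha must be in (0, 1)")
  if (!is.numeric(r2_threshold) || r2_threshold <= 0)
    stop_config("r2_threshold must be > 0")
  if (!is.numeric(cvbl_threshold) || cvbl_threshold <= 0)
    stop_config("cvbl_threshold must be > 0")
  max_purification_iters <- as.integer(max_purification_iters)
  if (is.na(max_purification_iters) || max_purification_iters < 1L)
    stop_config("max_purification_iters must be >= 1")
  quadrature_points <- as.integer(quadrature_points)
  if (quadrature_points < 5L) stop_config("quadrature_points must be >= 5")
  structure(list(grouping_variable = grouping_variable,
                 alpha = alpha,
                 r2_threshold = r2_threshold,
                 cvbl_threshold = cvbl_threshold,
                 max_purification_iters = max_purification_iters,
                 model_variant = model_variant,
                 missing_policy = missing_policy,
                 delta_r_formula = delta_r_formula,
                 purification_criterion = purification_criterion,
                 refit_anchors = isTRUE(refit_anchors),
                 quadrature_points = quadrature_points,
                 bonferroni = isTRUE(bonferroni),
                 seed = if (!is.null(seed)) as.integer(seed)),
            class = "dif_config")
}

#' @export
print.dif_config <- function(x, ...) {
  cat("dif_config:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, if (is.null(v)) "<null>" else paste(v, collapse = ", ")))
  }
  invisible(x)
}

#' Read or write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_config` returns a [dif_config]; `write_config` returns the
#'   path invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_io("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(dif_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown) > 0L)
    stop_config("unknown config key(s): %s", paste(unknown, collapse = ", "))
  do.call(dif_config, vals)
}

#' @rdname read_config
#' @param config a [dif_config].
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "dif_config"))
  vals <- unclass(config)
  vals <- vals[!vapply(vals, is.null, logical(1))]
  yaml::write_yaml(vals, path)
  invisible(path)
}
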