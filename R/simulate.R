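#' Default graded-response item parameters
#'
#' A deterministic bank of realistic item parameters: discriminations cycling
#' through 0.9, 1.2, 1.5, 1.8 and threshold sets of common spread centred on
#' an equally spaced grid across the trait scale.
#'
#' @param n_items number of items.
#' @param n_categories number of ordered categories (thresholds are
#'   `n_categories - 1` per item).
#' @return list with vector `a` (length `n_items`) and matrix `b`
#'   (`n_items x (n_categories - 1)`, strictly ascending rows).
#' @export
default_item_params <- function(n_items, n_categories = 5L) {
  J <- as.integer(n_items); m <- as.integer(n_categories)
  a <- rep(c(0.9, 1.2, 1.5, 1.8), length.out = J)
  centre <- if (J == 1L) 0 else seq(-1, 1, length.out = J)
  gaps <- seq(-(m - 2) / 2, (m - 2) / 2, length.out = m - 1L)
  b <- outer(centre, rep(1, m - 1L)) + outer(rep(1, J), gaps)
  list(a = a, b = b)
}

#' Specify a synthetic two-group graded-response dataset
#'
#' Defines the generating conditions for simulated questionnaire data: a
#' unit-variance (by default) normal latent trait per group with optional
#' mean difference (impact), graded-response items, and injected DIF.
#' Uniform DIF of magnitude `delta` shifts every focal-group threshold of an
#' item by `+delta` (the focal group's expected score is lower at every trait
#' level); nonuniform DIF of magnitude `rho` multiplies the focal group's
#' discrimination by `rho` (the group response curves cross).
#'
#' @param n_per_group integer pair: persons in the reference and focal group.
#' @param n_items number of items.
#' @param n_categories ordered categories per item.
#' @param a,b base item parameters (defaults from [default_item_params]).
#' @param impact focal-minus-reference trait mean difference in SD units
#'   (trait means are `c(0, impact)`).
#' @param trait_sd common within-group trait SD.
#' @param dif_items `NULL` or a data frame with columns `item` (index),
#'   `type` (`"uniform"` or `"nonuniform"`) and `magnitude`.
#' @param group_labels labels for the two groups.
#' @param seed integer seed; identical specs generate identical data.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_group = c(500L, 500L), n_items = 20L,
                           n_categories = 5L, a = NULL, b = NULL,
                           impact = 0, trait_sd = 1, dif_items = NULL,
                           group_labels = c("reference", "focal"), seed = 1L) {
  J <- as.integer(n_items); m <- as.integer(n_categories)
  base <- default_item_params(J, m)
  if (is.null(a)) a <- base$a
  if (is.null(b)) b <- base$b
  a <- rep_len(as.numeric(a), J)
  b <- matrix(as.numeric(b), nrow = J, ncol = m - 1L)
  if (any(a <= 0)) stop_validation("discriminations must be > 0")
  if (any(apply(b, 1L, function(r) any(diff(r) <= 0))))
    stop_validation("thresholds must be strictly ascending per item")
  if (!is.null(dif_items)) {
    dif_items <- as.data.frame(dif_items)
    stopifnot(all(c("item", "type", "magnitude") %in% names(dif_items)))
    if (!all(dif_items$type %in% c("uniform", "nonuniform")))
      stop_validation("dif type must be 'uniform' or 'nonuniform'")
    if (!all(dif_items$item %in% seq_len(J)))
      stop_validation("dif item index out of range")
    if (any(dif_items$type == "nonuniform" & dif_items$magnitude <= 0))
      stop_validation("nonuniform magnitude (discrimination ratio) must be > 0")
  }
  if (length(n_per_group) != 2L || any(n_per_group < 1L))
    stop_validation("n_per_group must be two positive integers")
  if (trait_sd < 0) stop_validation("trait_sd must be >= 0")
  structure(list(n_per_group = as.integer(n_per_group), n_items = J,
                 n_categories = m, a = a, b = b,
                 impact = as.numeric(impact), trait_sd = as.numeric(trait_sd),
                 dif_items = dif_items, group_labels = group_labels,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' The shipped desk-scale DIF scenario
#'
#' Twenty 5-category items, 500 persons per group, no impact, two
#' uniform-DIF items (threshold shift 0.5) and two nonuniform-DIF items
#' (discrimination ratio 2) — magnitudes chosen for test power at this
#' sample size.
#'
#' @param seed integer seed.
#' @return A [synthetic_spec].
#' @export
default_scenario <- function(seed = 1L) {
  synthetic_spec(n_per_group = c(500L, 500L), n_items = 20L, n_categories = 5L,
                 dif_items = data.frame(item = c(3L, 7L, 12L, 17L),
                                        type = c("uniform", "uniform",
                                                 "nonuniform", "nonuniform"),
                                        magnitude = c(0.5, 0.5, 2, 2)),
                 seed = seed)
}

## per-group parameter sets after DIF injection
spec_params_by_group <- function(spec) {
  ref <- list(a = spec$a, b = spec$b)
  foc <- list(a = spec$a, b = spec$b)
  if (!is.null(spec$dif_items)) {
    for (i in seq_len(nrow(spec$dif_items))) {
      j <- spec$dif_items$item[i]
      if (spec$dif_items$type[i] == "uniform") {
        foc$b[j, ] <- foc$b[j, ] + spec$dif_items$magnitude[i]
      } else {
        foc$a[j] <- foc$a[j] * spec$dif_items$magnitude[i]
      }
    }
  }
  for (p in list(ref, foc))
    if (any(apply(p$b, 1L, function(r) any(diff(r) <= 0))))
      stop_validation("thresholds not strictly ascending after DIF injection")
  list(reference = ref, focal = foc)
}

## graded-model category probabilities for one item over a theta vector:
## P(Y >= k+1 | theta) = plogis(a (theta - b_k)); returns length(theta) x m
grm_category_probs <- function(theta, a, b) {
  m <- length(b) + 1L
  cum <- plogis(a * outer(theta, b, "-"))          # P(Y >= k+1), decreasing in k
  cbind(1, cum) - cbind(cum, 0)
}

## expected item score E[Y | theta] on the 1..m scale
grm_expected_score <- function(theta, a, b) {
  p <- grm_category_probs(theta, a, b)
  drop(p %*% seq_len(ncol(p)))
}

#' Generate synthetic graded responses with known truth
#'
#' Draws per-group latent traits and category responses from the graded
#' response model defined by a [synthetic_spec], and returns the generating
#' truth (trait values, per-group parameters, per-item DIF labels) alongside
#' the data for recovery testing.
#'
#' @param spec a [synthetic_spec].
#' @return list with `data` (a [response_matrix]) and `truth` (class
#'   `synthetic_truth`: `theta`, `params_by_group`, `dif_labels`).
#' @examples
#' out <- simulate_responses(synthetic_spec(n_per_group = c(50, 50),
#'                                          n_items = 5, seed = 7))
#' table(out$truth$dif_labels)
#' @export
simulate_responses <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  params <- spec_params_by_group(spec)
  n0 <- spec$n_per_group[1L]; n1 <- spec$n_per_group[2L]
  J <- spec$n_items
  set.seed(spec$seed)
  theta <- c(rnorm(n0, 0, spec$trait_sd), rnorm(n1, spec$impact, spec$trait_sd))
  gidx <- rep(1:2, c(n0, n1))
  Y <- matrix(0L, n0 + n1, J)
  for (j in seq_len(J)) {
    u <- runif(n0 + n1)
    for (g in 1:2) {
      rows <- which(gidx == g)
      p <- params[[g]]
      cum <- plogis(p$a[j] * outer(theta[rows], p$b[j, ], "-"))  # P(Y >= k+1)
      Y[rows, j] <- 1L + as.integer(rowSums(u[rows] < cum))
    }
  }
  labels <- rep("none", J)
  if (!is.null(spec$dif_items)) labels[spec$dif_items$item] <- spec$dif_items$type
  data <- response_matrix(Y, group = factor(spec$group_labels[gidx], levels = spec$group_labels),
                          n_categories = spec$n_categories)
  truth <- structure(list(theta = theta, params_by_group = params,
                          dif_labels = labels, spec = spec),
                     class = "synthetic_truth")
  list(data = data, truth = truth)
}

#' Marginal category probabilities of a graded item
#'
#' Integrates the graded-model category probabilities over a normal trait
#' distribution by fixed-point quadrature (closed form at `trait_sd = 0`).
#'
#' @param a item discrimination (> 0).
#' @param b strictly ascending thresholds.
#' @param trait_mean,trait_sd trait distribution parameters.
#' @param n_quad quadrature points.
#' @return probability vector of length `length(b) + 1`, summing to 1.
#' @export
marginal_category_probs <- function(a, b, trait_mean = 0, trait_sd = 1,
                                    n_quad = 181L) {
  if (a <= 0) stop_validation("a must be > 0")
  if (any(diff(b) <= 0)) stop_validation("thresholds must be strictly ascending")
  if (trait_sd < 0) stop_validation("trait_sd must be >= 0")
  if (trait_sd == 0)
    return(drop(grm_category_probs(trait_mean, a, b)))
  q <- seq(trait_mean - 8 * trait_sd, trait_mean + 8 * trait_sd, length.out = n_quad)
  w <- dnorm(q, trait_mean, trait_sd); w <- w / sum(w)
  drop(w %*% grm_category_probs(q, a, b))
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("synthetic_spec: J=%d items, m=%d categories, n=%d+%d, impact=%.2f, sd=%.2f, seed=%d\n",
              x$n_items, x$n_categories, x$n_per_group[1L], x$n_per_group[2L],
              x$impact, x$trait_sd, x$seed))
  if (!is.null(x$dif_items)) {
    cat("  DIF items:\n")
    for (i in seq_len(nrow(x$dif_items)))
      cat(sprintf("    item %d: %s, magnitude %.3g\n", x$dif_items$item[i],
                  x$dif_items$type[i], x$dif_items$magnitude[i]))
  }
  invisible(x)
}
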