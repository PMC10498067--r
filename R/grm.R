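## Graded response model by marginal maximum likelihood EM over a fixed
## normal quadrature grid, EAP trait scoring on anchor subsets, and test
## characteristic curves.

grm_quadrature <- function(n_points) {
  q <- seq(-4, 4, length.out = n_points)
  w <- dnorm(q); w <- w / sum(w)
  list(points = q, weights = w)
}

## collapse unobserved categories of one item into the adjacent lower
## category so every cumulative logit stays estimable; returns recoded
## vector (consecutive 1..K) and the category map
collapse_categories <- function(y, m) {
  obs <- sort(unique(y[!is.na(y)]))
  map <- integer(m)
  k <- 0L
  for (c in seq_len(m)) {
    if (c %in% obs) k <- k + 1L
    map[c] <- max(k, 1L)  # categories below the first observed fold upward
  }
  list(y = map[y], n_collapsed = max(map), map = map)
}

## Q x K log category-probability table for one item at quadrature points
grm_log_probs <- function(q, a, b) {
  p <- grm_category_probs(q, a, b)
  log(pmax(p, 1e-300))
}

z_from_ab <- function(a, b) c(log(a), b[1L], log(pmax(diff(b), 1e-6)))
ab_from_z <- function(z) list(a = exp(z[1L]),
                              b = cumsum(c(z[2L], exp(z[-(1:2)]))))

## negative expected complete-data log-likelihood for one item and its
## analytic gradient, parameterised z = (log a, b1, log diffs); a closure
## with a one-slot cache so nlminb's separate objective/gradient calls share
## one evaluation
grm_item_objective <- function(r, q, free_a = TRUE, a_fixed = NULL) {
  last_z <- NULL; last <- NULL
  eval_at <- function(z) {
    if (!is.null(last_z) && identical(z, last_z)) return(last)
    if (free_a) {
      a <- exp(z[1L]); zb <- z[-1L]
    } else {
      a <- a_fixed; zb <- z
    }
    d <- exp(zb[-1L])
    b <- cumsum(c(zb[1L], d))
    Km1 <- length(b)
    Pstar <- 1 / (1 + exp(-a * outer(q, b, "-")))   # Q x (K-1), P(Y >= k+1)
    P <- cbind(1, Pstar) - cbind(Pstar, 0)
    P <- pmax(P, 1e-300)
    nll <- -sum(r * log(P))
    R <- r / P
    gstar <- R[, -1L, drop = FALSE] - R[, -(Km1 + 1L), drop = FALSE]  # dQ/dPstar_t
    f <- Pstar * (1 - Pstar)
    gf <- gstar * f
    db <- -a * colSums(gf)                           # dQ/db_t
    gb1 <- sum(db)
    gd <- if (Km1 > 1L) d * rev(cumsum(rev(db)))[-1L] else numeric(0)
    grad <- -c(gb1, gd)
    if (free_a) {
      ga <- sum(gf * outer(q, b, "-")) * a           # dQ/d(log a)
      grad <- c(-ga, grad)
    }
    last_z <<- z; last <<- list(nll = nll, grad = grad)
    last
  }
  list(fn = function(z) eval_at(z)$nll,
       gr = function(z) eval_at(z)$grad)
}

#' Fit the graded response model by marginal maximum likelihood
#'
#' Estimates per-item discriminations and ascending thresholds with an
#' expectation-maximisation algorithm over a fixed, renormalised normal
#' quadrature grid on \[-4, 4\]. The `equal_discrimination` variant constrains
#' one common slope (a one-parameter-logistic analogue for ordered
#' categories). Items with a single observed category are excluded with a
#' warning; unobserved categories of retained items are merged into the
#' adjacent lower category and the recode map is kept.
#'
#' @param data a [response_matrix] or integer matrix (`NA` = missing).
#' @param variant `"graded"` or `"equal_discrimination"`.
#' @param quadrature_points number of quadrature points.
#' @param items optional subset of item ids or indices to fit.
#' @param control list: `max_em_iter` (default 500), `par_tol` (EM stops when
#'   the largest absolute parameter change is below it, default 1e-4).
#' @return An object of class `grm_fit`: `a`, `b` (list of threshold vectors
#'   on the original category scale positions), `item_ids`, `loglik`,
#'   `ll_trace`, `iterations`, `converged`, `collapse_maps`, `quadrature`,
#'   `variant`, `n`.
#' @export
fit_grm <- function(data, variant = c("graded", "equal_discrimination"),
                    quadrature_points = 49L, items = NULL, control = list()) {
  variant <- match.arg(variant)
  ctl <- modifyList(list(max_em_iter = 500L, par_tol = 1e-4), control)
  if (inherits(data, "response_matrix")) {
    Y <- data$responses; m <- data$n_categories; ids <- data$item_ids
  } else {
    Y <- as.matrix(data); m <- max(Y, na.rm = TRUE)
    ids <- colnames(Y); if (is.null(ids)) ids <- sprintf("item%02d", seq_len(ncol(Y)))
  }
  if (!is.null(items)) {
    idx <- if (is.character(items)) match(items, ids) else as.integer(items)
    if (anyNA(idx)) stop_validation("unknown item(s) requested")
    Y <- Y[, idx, drop = FALSE]; ids <- ids[idx]
  }
  n <- nrow(Y); J <- ncol(Y)
  if (n < 2L) stop_validation("need at least 2 persons to fit a trait model")

  collapse_maps <- vector("list", J)
  K <- integer(J)
  dropped <- logical(J)
  for (j in seq_len(J)) {
    cj <- collapse_categories(Y[, j], m)
    if (cj$n_collapsed < 2L) {
      dropped[j] <- TRUE
      next
    }
    Y[, j] <- cj$y
    K[j] <- cj$n_collapsed
    collapse_maps[[j]] <- cj$map
  }
  if (any(dropped)) {
    warning(sprintf("item(s) with a single observed category excluded: %s",
                    paste(ids[dropped], collapse = ", ")))
    Y <- Y[, !dropped, drop = FALSE]
    ids <- ids[!dropped]; K <- K[!dropped]
    collapse_maps <- collapse_maps[!dropped]
    J <- ncol(Y)
  }
  if (J < 1L) stop_validation("no estimable items")

  quad <- grm_quadrature(quadrature_points)
  q <- quad$points; w <- quad$weights; Q <- length(q)

  # start values: unit slopes, thresholds from marginal cumulative log-odds
  a <- rep(1, J)
  b <- vector("list", J)
  for (j in seq_len(J)) {
    yj <- Y[!is.na(Y[, j]), j]
    cp <- cumsum(tabulate(yj, K[j]))[seq_len(K[j] - 1L)] / length(yj)
    b[[j]] <- qlogis(pmin(pmax(cp, 1e-3), 1 - 1e-3))
    if (any(diff(b[[j]]) <= 0)) b[[j]] <- sort(b[[j]]) + seq_len(K[j] - 1L) * 1e-6
  }

  ll_trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    # E-step: person-wise posteriors over the grid
    logP <- lapply(seq_len(J), function(j) grm_log_probs(q, a[j], b[[j]]))
    LP <- matrix(log(w), Q, n)
    for (j in seq_len(J)) {
      obs <- which(!is.na(Y[, j]))
      LP[, obs] <- LP[, obs] + logP[[j]][, Y[obs, j], drop = FALSE]
    }
    mx <- apply(LP, 2L, max)
    E <- exp(sweep(LP, 2L, mx))
    cs <- colSums(E)
    post <- sweep(E, 2L, cs, "/")
    ll <- sum(log(cs) + mx)
    ll_trace <- c(ll_trace, ll)

    # expected category counts per item over the grid
    r <- vector("list", J)
    for (j in seq_len(J)) {
      obs <- which(!is.na(Y[, j]))
      ind <- matrix(0, length(obs), K[j])
      ind[cbind(seq_along(obs), Y[obs, j])] <- 1
      r[[j]] <- post[, obs, drop = FALSE] %*% ind
    }

    a_old <- a; b_old <- b
    if (variant == "graded") {
      for (j in seq_len(J)) {
        o <- grm_item_objective(r[[j]], q)
        fit <- nlminb(z_from_ab(a[j], b[[j]]), o$fn, o$gr,
                      lower = c(log(0.05), -10, rep(log(1e-5), K[j] - 2L)),
                      upper = c(log(25), 10, rep(log(20), K[j] - 2L)))
        ab <- ab_from_z(fit$par)
        a[j] <- ab$a; b[[j]] <- ab$b
      }
    } else {
      # coordinate ascent: thresholds given the common slope, then the slope
      for (j in seq_len(J)) {
        o <- grm_item_objective(r[[j]], q, free_a = FALSE, a_fixed = a[1L])
        zb <- c(b[[j]][1L], log(pmax(diff(b[[j]]), 1e-6)))
        fit <- nlminb(zb, o$fn, o$gr,
                      lower = c(-10, rep(log(1e-5), K[j] - 2L)),
                      upper = c(10, rep(log(20), K[j] - 2L)))
        b[[j]] <- cumsum(c(fit$par[1L], exp(fit$par[-1L])))
      }
      obj_a <- function(la) {
        av <- exp(la)
        sum(vapply(seq_len(J), function(j)
          -sum(r[[j]] * grm_log_probs(q, av, b[[j]])), numeric(1)))
      }
      a[] <- exp(optimize(obj_a, c(log(0.05), log(25)))$minimum)
    }

    delta <- max(abs(a - a_old),
                 max(vapply(seq_len(J), function(j) max(abs(b[[j]] - b_old[[j]])), numeric(1))))
    if (delta < ctl$par_tol) { converged <- TRUE; break }
    if (iter >= ctl$max_em_iter) break
  }
  if (!converged)
    warning(sprintf("EM reached %d cycles without parameter change < %g; best iterate returned",
                    iter, ctl$par_tol))
  structure(list(a = a, b = b, item_ids = ids, n_categories_fitted = K,
                 loglik = ll_trace[length(ll_trace)], ll_trace = ll_trace,
                 iterations = iter, converged = converged,
                 collapse_maps = collapse_maps, quadrature = quad,
                 variant = variant, n = n),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("grm_fit (%s): %d items, n=%d, logLik=%.2f, %d EM cycles%s\n",
              x$variant, length(x$a), x$n, x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' @export
coef.grm_fit <- function(object, ...) {
  mb <- max(vapply(object$b, length, integer(1)))
  bmat <- t(vapply(object$b, function(bi) c(bi, rep(NA_real_, mb - length(bi))),
                   numeric(mb)))
  colnames(bmat) <- paste0("b", seq_len(mb))
  cbind(a = object$a, bmat)
}

#' @export
logLik.grm_fit <- function(object, ...) {
  structure(object$loglik, df = NA_integer_, nobs = object$n, class = "logLik")
}

## recode a response vector with an item's collapse map (original 1..m codes
## to the fitted consecutive codes); NA passes through
apply_collapse <- function(y, map) if (is.null(map)) y else map[y]

#' Expected a posteriori (EAP) trait scores
#'
#' Posterior mean and SD of the latent trait per person, computed on the
#' fitted quadrature grid using only the designated anchor items, then
#' linearly standardised to sample mean 0 and SD 1 (higher raw responses map
#' to higher scores via the model's threshold orientation).
#'
#' @param fit a [grm_fit].
#' @param data the [response_matrix] (or integer matrix) to score; categories
#'   on the original 1..m scale.
#' @param anchor_items item ids or indices used for scoring; default all
#'   fitted items. An empty anchor set is an error (purification must stop
#'   when every item is flagged).
#' @param standardize standardise scores over the sample (default `TRUE`).
#' @return An object of class `theta_estimate`: `theta` (standardised),
#'   `raw_theta`, `se` (posterior SDs, on the raw scale), `anchor_items`,
#'   `center`, `scale`.
#' @export
eap_theta <- function(fit, data, anchor_items = NULL, standardize = TRUE) {
  stopifnot(inherits(fit, "grm_fit"))
  Y <- if (inherits(data, "response_matrix")) data$responses else as.matrix(data)
  if (is.null(anchor_items)) anchor_items <- fit$item_ids
  idx <- if (is.character(anchor_items)) match(anchor_items, fit$item_ids) else as.integer(anchor_items)
  if (length(idx) == 0L)
    stop_validation("anchor set is empty: all items are flagged, stop purification")
  if (anyNA(idx)) stop_validation("anchor item(s) not present in the fitted model")
  col <- match(fit$item_ids[idx], colnames(Y))
  if (anyNA(col)) stop_validation("anchor item(s) not present in the data")
  q <- fit$quadrature$points; w <- fit$quadrature$weights
  Q <- length(q); n <- nrow(Y)
  LP <- matrix(log(w), Q, n)
  for (k in seq_along(idx)) {
    j <- idx[k]
    yj <- apply_collapse(Y[, col[k]], fit$collapse_maps[[j]])
    obs <- which(!is.na(yj))
    lp <- grm_log_probs(q, fit$a[j], fit$b[[j]])
    LP[, obs] <- LP[, obs] + lp[, yj[obs], drop = FALSE]
  }
  mx <- apply(LP, 2L, max)
  E <- exp(sweep(LP, 2L, mx))
  post <- sweep(E, 2L, colSums(E), "/")
  raw <- drop(crossprod(post, q))
  pvar <- drop(crossprod(post, q^2)) - raw^2
  se <- sqrt(pmax(pvar, 0))
  if (standardize) {
    ctr <- mean(raw); scl <- sd(raw)
    if (!is.finite(scl) || scl <= 0)
      stop_validation("cannot standardise: trait scores are constant")
    theta <- (raw - ctr) / scl
  } else {
    ctr <- 0; scl <- 1; theta <- raw
  }
  structure(list(theta = theta, raw_theta = raw, se = se,
                 anchor_items = fit$item_ids[idx], center = ctr, scale = scl),
            class = "theta_estimate")
}

#' @export
print.theta_estimate <- function(x, ...) {
  cat(sprintf("theta_estimate: %d persons, %d anchor items, mean=%.3g, sd=%.3g\n",
              length(x$theta), length(x$anchor_items), mean(x$theta), sd(x$theta)))
  invisible(x)
}

## maximum-likelihood graded item parameters treating theta as known
## (used to re-estimate group-specific parameters of flagged items)
fit_item_fixed_theta <- function(y, theta, m = max(y, na.rm = TRUE)) {
  keep <- !is.na(y) & is.finite(theta)
  y <- y[keep]; theta <- theta[keep]
  cj <- collapse_categories(y, m)
  y <- cj$y; K <- cj$n_collapsed
  if (K < 2L) stop_validation("item has a single observed category")
  cp <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / length(y)
  b0 <- qlogis(pmin(pmax(cp, 1e-3), 1 - 1e-3))
  if (any(diff(b0) <= 0)) b0 <- sort(b0) + seq_len(K - 1L) * 1e-6
  nll <- function(z) {
    ab <- ab_from_z(z)
    p <- grm_category_probs(theta, ab$a, ab$b)
    -sum(log(pmax(p[cbind(seq_along(y), y)], 1e-300)))
  }
  fit <- nlminb(z_from_ab(1, b0), nll,
                lower = c(log(0.05), -10, rep(log(1e-5), K - 2L)),
                upper = c(log(25), 10, rep(log(20), K - 2L)))
  ab <- ab_from_z(fit$par)
  list(a = ab$a, b = ab$b, map = cj$map, loglik = -fit$objective)
}

#' Test characteristic curves by group
#'
#' Sum of expected item scores over a set of items as a function of the
#' latent trait, one curve per group, using each group's item parameters.
#' Each item's conditional expectation lies in `[1, m]`, so the curve is
#' bounded by `[#items, m * #items]` and is non-decreasing in the trait.
#'
#' @param params_by_group named list (one element per group) of parameter
#'   sets, each a list with vector `a` and a matrix or list `b` of ascending
#'   thresholds per item.
#' @param items indices of the items to sum; default all.
#' @param theta_grid trait grid.
#' @return data frame with columns `theta` and one expected-score column per
#'   group.
#' @export
test_characteristic_curve <- function(params_by_group, items = NULL,
                                      theta_grid = seq(-4, 4, length.out = 101)) {
  stopifnot(is.list(params_by_group), length(params_by_group) >= 1L)
  if (is.null(names(params_by_group)))
    names(params_by_group) <- paste0("group", seq_along(params_by_group))
  if (!all(is.finite(theta_grid))) stop_validation("theta grid must be finite")
  get_b <- function(p, j) if (is.list(p$b)) p$b[[j]] else p$b[j, ]
  J_all <- length(params_by_group[[1L]]$a)
  if (is.null(items)) items <- seq_len(J_all)
  if (length(items) == 0L) stop_validation("items must be non-empty")
  out <- data.frame(theta = theta_grid)
  for (g in names(params_by_group)) {
    p <- params_by_group[[g]]
    percurve <- vapply(items, function(j)
      grm_expected_score(theta_grid, p$a[j], get_b(p, j)),
      numeric(length(theta_grid)))
    curve <- rowSums(matrix(percurve, nrow = length(theta_grid)))
    out[[g]] <- curve
  }
  out
}
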