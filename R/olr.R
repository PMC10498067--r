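## Cumulative-logit (proportional-odds) maximum likelihood by Newton
## iterations with step-halving, and the nested-model DIF statistics built
## on it. The three models per item are, with k indexing cumulative logits
## of P(Y <= k), theta the matching trait and g the 0/1 group:
##   M1: logit P(Y <= k) = b0k + b1 theta
##   M2: M1 + b2 g
##   M3: M2 + b3 theta*g
## (M0, intercepts only, supports the McFadden pseudo-R-squared option.)

olr_design <- function(theta, group, model) {
  switch(model,
         M0 = NULL,
         M1 = cbind(theta = theta),
         M2 = cbind(theta = theta, group = group),
         M3 = cbind(theta = theta, group = group, `theta:group` = theta * group))
}

## log-likelihood, score and Hessian of the proportional-odds model.
## Parameters: alpha (K-1 ascending cutpoints), beta (slopes on X).
olr_llik_parts <- function(alpha, beta, y, X, K, want_deriv = TRUE) {
  n <- length(y)
  p <- if (is.null(X)) 0L else ncol(X)
  eta <- if (p) drop(X %*% beta) else numeric(n)
  G <- plogis(outer(eta, alpha, "+"))            # n x (K-1): P(Y <= k)
  lo <- y > 1L; hi <- y < K
  F2 <- rep(1, n); F2[hi] <- G[cbind(which(hi), y[hi])]
  F1 <- rep(0, n); F1[lo] <- G[cbind(which(lo), y[lo] - 1L)]
  pi <- pmax(F2 - F1, 1e-300)
  ll <- sum(log(pi))
  if (!want_deriv) return(list(ll = ll))
  f2 <- ifelse(hi, F2 * (1 - F2), 0)
  f1 <- ifelse(lo, F1 * (1 - F1), 0)
  fp2 <- ifelse(hi, f2 * (1 - 2 * F2), 0)
  fp1 <- ifelse(lo, f1 * (1 - 2 * F1), 0)
  d <- (K - 1L) + p
  U2 <- matrix(0, n, d); U1 <- matrix(0, n, d)
  w2 <- which(hi); w1 <- which(lo)
  U2[cbind(w2, y[w2])] <- 1
  U1[cbind(w1, y[w1] - 1L)] <- 1
  if (p) { U2[, K - 1L + seq_len(p)] <- X; U1[, K - 1L + seq_len(p)] <- X }
  S <- U2 * (f2 / pi) - U1 * (f1 / pi)
  g <- colSums(S)
  H <- crossprod(U2, U2 * (fp2 / pi)) - crossprod(U1, U1 * (fp1 / pi)) - crossprod(S)
  list(ll = ll, grad = g, hess = H)
}

#' Fit one cumulative-logit DIF model
#'
#' Maximum-likelihood proportional-odds fit of one of the nested DIF models
#' (`M1`: trait only; `M2`: + group; `M3`: + trait-by-group interaction;
#' `M0`: intercepts only) by Newton iterations with step-halving. Cutpoints
#' are kept strictly ascending, so fitted cumulative probabilities are
#' strictly increasing in the category index for every person. Design
#' columns with zero variance (e.g. a constant trait) are held at
#' coefficient 0 rather than making the Hessian singular.
#'
#' @param y ordered integer responses; recoded internally to consecutive
#'   categories `1..K` (K >= 2 required).
#' @param theta trait scores (finite).
#' @param group binary group, coded 0 (reference) / 1 (focal).
#' @param model `"M1"`, `"M2"`, `"M3"` or `"M0"`.
#' @param tol convergence: gradient max-norm below `tol`.
#' @param max_iter,max_halvings Newton iteration and step-halving caps.
#' @return An object of class `olr_fit`: `alpha` (cutpoints), `beta` (named
#'   slopes), `logLik`, `n_used`, `K`, `converged`, `iterations`,
#'   `grad_norm`, `model`, `diverged`, `fixed_terms`.
#' @export
fit_cumulative_logit <- function(y, theta = NULL, group = NULL,
                                 model = c("M1", "M2", "M3", "M0"),
                                 tol = 1e-8, max_iter = 100L, max_halvings = 20L) {
  model <- match.arg(model)
  y <- as.integer(y)
  n <- length(y)
  if (model != "M0") {
    if (is.null(theta) || length(theta) != n || any(!is.finite(theta)))
      stop_validation("theta must be finite and aligned with y")
  }
  if (model %in% c("M2", "M3")) {
    if (is.null(group) || length(group) != n || !all(group %in% c(0L, 1L)))
      stop_validation("group must be 0/1 and aligned with y")
  }
  lev <- sort(unique(y))
  K <- length(lev)
  if (K < 2L) stop_validation("y has a single observed category")
  y <- match(y, lev)

  X <- olr_design(theta, group, model)
  fixed <- character(0)
  if (!is.null(X)) {
    sds <- apply(X, 2L, function(v) max(v) - min(v))
    fixed <- colnames(X)[sds == 0]
    Xf <- X[, sds > 0, drop = FALSE]
    if (ncol(Xf) == 0L) Xf <- NULL
  } else Xf <- NULL
  p <- if (is.null(Xf)) 0L else ncol(Xf)

  cp <- cumsum(tabulate(y, K))[seq_len(K - 1L)] / n
  alpha <- qlogis(pmin(pmax(cp, 1e-6), 1 - 1e-6))
  beta <- rep(0, p)

  parts <- olr_llik_parts(alpha, beta, y, Xf, K)
  ll <- parts$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    g <- parts$grad; H <- parts$hess
    if (max(abs(g)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(H, g), error = function(e) {
      ridge <- diag(1e-6 * max(1, abs(diag(H))), nrow(H))
      solve(H - ridge, g)
    })
    accepted <- FALSE
    fac <- 1
    for (h in 0:max_halvings) {
      a_new <- alpha - fac * step[seq_len(K - 1L)]
      b_new <- if (p) beta - fac * step[K - 1L + seq_len(p)] else beta
      if (K == 2L || all(diff(a_new) > 0)) {
        parts_new <- olr_llik_parts(a_new, b_new, y, Xf, K)
        if (is.finite(parts_new$ll) && parts_new$ll >= ll - 1e-12) {
          alpha <- a_new; beta <- b_new
          ll <- parts_new$ll; parts <- parts_new
          accepted <- TRUE
          break
        }
      }
      fac <- fac / 2
    }
    if (!accepted) break
  }
  grad_norm <- max(abs(parts$grad))
  converged <- converged || grad_norm < tol
  # coefficients this large on a standardised trait mean the likelihood is
  # drifting to a boundary (complete separation): report non-convergence
  diverged <- max(abs(beta), 0) > 30 || max(abs(alpha)) > 30
  if (diverged) converged <- FALSE

  beta_full <- numeric(0)
  if (!is.null(X)) {
    beta_full <- setNames(rep(0, ncol(X)), colnames(X))
    if (p) beta_full[colnames(Xf)] <- beta
  }
  structure(list(alpha = setNames(alpha, paste0("alpha", seq_len(K - 1L))),
                 beta = beta_full, logLik = ll, n_used = n, K = K,
                 y_levels = lev, converged = converged, iterations = iter,
                 grad_norm = grad_norm, model = model, diverged = diverged,
                 fixed_terms = fixed),
            class = "olr_fit")
}

#' @export
print.olr_fit <- function(x, ...) {
  cat(sprintf("olr_fit %s: logLik=%.4f, n=%d, K=%d, %s (%d Newton iterations)\n",
              x$model, x$logLik, x$n_used, x$K,
              if (x$converged) "converged" else if (x$diverged)
                "NOT converged (diverging coefficients, possible separation)"
              else "NOT converged", x$iterations))
  print(c(x$alpha, x$beta))
  invisible(x)
}

#' @export
coef.olr_fit <- function(object, ...) c(object$alpha, object$beta)

#' @export
logLik.olr_fit <- function(object, ...) {
  structure(object$logLik, df = length(object$alpha) + length(object$beta),
            nobs = object$n_used, class = "logLik")
}

#' @export
predict.olr_fit <- function(object, theta = NULL, group = NULL, ...) {
  n <- max(length(theta), length(group), 1L)
  if (is.null(theta)) theta <- numeric(n)
  if (is.null(group)) group <- integer(n)
  X <- olr_design(theta, group, object$model)
  eta <- if (is.null(X) || length(object$beta) == 0L) numeric(n)
         else drop(X %*% object$beta[colnames(X)])
  G <- plogis(outer(eta, object$alpha, "+"))
  probs <- cbind(G, 1) - cbind(0, G)
  colnames(probs) <- object$y_levels
  probs
}

#' Likelihood-ratio chi-square between nested cumulative-logit fits
#'
#' The difference in -2 log-likelihood of the full and the sub-model,
#' clipped at 0 for numerical noise, referred to a chi-square distribution
#' (df 1 for each single added term).
#'
#' @param sub,full nested [fit_cumulative_logit] fits on identical persons.
#' @param df degrees of freedom; default is the parameter-count difference.
#' @return list with `chi2`, `p`, `df`.
#' @export
lr_chi2 <- function(sub, full, df = NULL) {
  stopifnot(inherits(sub, "olr_fit"), inherits(full, "olr_fit"))
  if (sub$n_used != full$n_used)
    stop_validation("nesting violated: fits use different persons (n=%d vs %d)",
                    sub$n_used, full$n_used)
  if (is.null(df))
    df <- (length(full$alpha) + length(full$beta)) -
          (length(sub$alpha) + length(sub$beta))
  chi2 <- max(0, 2 * (full$logLik - sub$logLik))
  list(chi2 = chi2, p = pchisq(chi2, df = df, lower.tail = FALSE), df = df)
}

#' Pseudo-R-squared difference between nested fits
#'
#' The default `"ratio"` form is `1 - lnL(full) / lnL(sub)` (the form used
#' with the 0.070 large-DIF cutoff). `"mcfadden_difference"` is the textbook
#' McFadden difference `R2(full) - R2(sub)` with
#' `R2 = 1 - lnL(model)/lnL(intercept-only)` and requires `null_fit`.
#'
#' @param sub,full nested [fit_cumulative_logit] fits.
#' @param formula `"ratio"` or `"mcfadden_difference"`.
#' @param null_fit the intercept-only (`M0`) fit, for the McFadden form.
#' @return numeric effect size (0 when the fits coincide).
#' @export
delta_r <- function(sub, full, formula = c("ratio", "mcfadden_difference"),
                    null_fit = NULL) {
  formula <- match.arg(formula)
  if (sub$n_used != full$n_used) stop_validation("nesting violated: different persons")
  if (sub$logLik >= 0 || full$logLik >= 0)
    stop_validation("degenerate fit: log-likelihood must be negative")
  if (formula == "ratio") return(1 - full$logLik / sub$logLik)
  if (is.null(null_fit)) stop_config("mcfadden_difference requires null_fit (M0)")
  if (null_fit$logLik >= 0) stop_validation("degenerate intercept-only fit")
  (1 - full$logLik / null_fit$logLik) - (1 - sub$logLik / null_fit$logLik)
}

#' Crane-van Belle-Larson beta-change criterion
#'
#' Absolute proportional change in the trait slope when the group term is
#' added: `|(b1(without G) - b1(with G)) / b1(without G)|`. Invariant to the
#' group coding by construction (absolute value).
#'
#' @param fit_without_g,fit_with_g the M1 and M2 fits.
#' @return non-negative numeric.
#' @export
cvbl_delta_beta <- function(fit_without_g, fit_with_g) {
  b0 <- unname(fit_without_g$beta["theta"])
  b1 <- unname(fit_with_g$beta["theta"])
  if (anyNA(c(b0, b1)) || !length(b0) || !length(b1))
    stop_validation("both fits must contain a trait slope")
  if (b0 == 0) stop_validation("trait slope of the without-group model is 0; criterion undefined")
  abs((b0 - b1) / b0)
}
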