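#' Cronbach's alpha
#'
#' `alpha = J/(J-1) * (1 - sum(var(item)) / var(total))`, with sample
#' variances (denominator n-1). Invariant to adding constants to items and
#' to a common positive rescaling.
#'
#' @param x numeric matrix or data frame, persons in rows, items in columns
#'   (at least 2 items with positive variance).
#' @return numeric scalar (<= 1).
#' @export
cronbach_alpha <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  J <- ncol(x)
  if (J < 2L) stop_validation("Cronbach's alpha needs at least 2 items")
  iv <- apply(x, 2L, var)
  if (any(iv <= 0)) stop_validation("every item needs positive variance")
  tv <- var(rowSums(x))
  if (tv <= 0) stop_validation("total score has zero variance")
  (J / (J - 1)) * (1 - sum(iv) / tv)
}

#' Guttman's lambda-6 reliability
#'
#' `lambda6 = 1 - sum_j e2_j / var(total)` on the covariance scale, where
#' `e2_j = var_j (1 - R2_j)` is item j's residual variance when regressed on
#' all other items, i.e. `1 / (C^-1)_jj` for covariance matrix `C`.
#'
#' @param x numeric matrix or data frame of item responses.
#' @return numeric scalar (<= 1).
#' @export
guttman_lambda6 <- function(x) {
  x <- as.matrix(x)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  C <- cov(x)
  Cinv <- tryCatch(solve(C), error = function(e)
    stop_validation("covariance matrix is singular (exactly collinear items); drop duplicated items or add a ridge to the covariance before calling"))
  if (kappa(C) > 1e12)
    stop_validation("covariance matrix is numerically singular; drop collinear items or add a ridge")
  e2 <- 1 / diag(Cinv)
  1 - sum(e2) / sum(C)
}

## normal-theory ML discrepancy of a one-factor model:
## F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - J, Sigma = lambda lambda' + diag(psi)
cfa_discrepancy <- function(lambda, psi, S, logdetS) {
  Sigma <- tcrossprod(lambda) + diag(psi, length(psi))
  ch <- tryCatch(chol(Sigma), error = function(e) NULL)
  if (is.null(ch)) return(Inf)
  logdet <- 2 * sum(log(diag(ch)))
  logdet + sum(diag(chol2inv(ch) %*% S)) - logdetS - length(psi)
}

#' One-factor confirmatory factor analysis with fit indices
#'
#' Fits the single-factor model `Sigma = lambda lambda' + diag(psi)` to the
#' Pearson covariance matrix by minimising the normal-theory ML discrepancy
#' `F = ln|Sigma| + tr(S Sigma^-1) - ln|S| - J` (L-BFGS-B with analytic
#' gradient; uniquenesses floored at a small positive bound, and fits at
#' that bound are reported as Heywood cases). Indices: `model_chi2 =
#' (n-1) F`, `df = J(J+1)/2 - 2J`, `rmsea = sqrt(max(0, (chi2 - df) /
#' (df (n-1))))`, CFI/TLI against the independence baseline (reported
#' unclipped, with clipped-to-\[0,1\] companions), SRMR as the root mean
#' square of the standardised residual covariances (diagonal included), and
#' McDonald's omega `(sum lambda)^2 / ((sum lambda)^2 + sum psi)` from the
#' fitted loadings. Items are treated as continuous.
#'
#' @param x numeric matrix or data frame (persons x items, J >= 3), or a
#'   covariance matrix if `n` is given.
#' @param n sample size when `x` is a covariance matrix.
#' @return An object of class `cfa_fit`: `loadings`, `uniqueness`,
#'   `discrepancy`, `converged`, `heywood`, and an `indices` list
#'   (`model_chi2`, `model_df`, `baseline_chi2`, `baseline_df`, `rmsea`,
#'   `srmr`, `cfi`, `tli`, `cfi_clipped`, `tli_clipped`, `omega`, `n_used`,
#'   `saturated`).
#' @export
fit_one_factor_cfa <- function(x, n = NULL) {
  if (is.null(n)) {
    x <- as.matrix(x)
    x <- x[stats::complete.cases(x), , drop = FALSE]
    n <- nrow(x)
    S <- cov(x)
  } else {
    S <- as.matrix(x)
  }
  J <- ncol(S)
  if (J < 3L) stop_validation("one-factor CFA needs at least 3 items")
  eS <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(eS) <= 0) stop_validation("sample covariance matrix must be positive definite")
  logdetS <- sum(log(eS))

  # start: first principal component scaled to covariance metric
  e <- eigen(S, symmetric = TRUE)
  lambda0 <- e$vectors[, 1L] * sqrt(max(e$values[1L], 1e-6))
  if (sum(lambda0) < 0) lambda0 <- -lambda0
  psi0 <- pmax(diag(S) - lambda0^2, 0.05 * diag(S))
  floor_psi <- 1e-4 * diag(S)

  obj <- function(par) {
    cfa_discrepancy(par[seq_len(J)], par[J + seq_len(J)], S, logdetS)
  }
  grad <- function(par) {
    lambda <- par[seq_len(J)]; psi <- par[J + seq_len(J)]
    Sigma <- tcrossprod(lambda) + diag(psi, J)
    Sinv <- tryCatch(chol2inv(chol(Sigma)), error = function(e) NULL)
    if (is.null(Sinv)) return(rep(0, 2L * J))
    G <- Sinv %*% (Sigma - S) %*% Sinv
    c(2 * drop(G %*% lambda), diag(G))
  }
  fit <- optim(c(lambda0, psi0), obj, grad, method = "L-BFGS-B",
               lower = c(rep(-Inf, J), floor_psi),
               control = list(maxit = 1000L, factr = 1e4))
  converged <- fit$convergence == 0L
  if (!converged)
    warning(sprintf("CFA optimiser did not converge (code %d); last iterate returned",
                    fit$convergence))
  lambda <- fit$par[seq_len(J)]
  if (sum(lambda) < 0) lambda <- -lambda
  psi <- fit$par[J + seq_len(J)]
  heywood <- which(psi <= floor_psi * (1 + 1e-8))
  if (length(heywood))
    warning(sprintf("Heywood case(s): uniqueness at the positive floor for item(s) %s",
                    paste(heywood, collapse = ", ")))
  Fhat <- fit$value
  df <- J * (J + 1) / 2 - 2 * J
  chi2 <- (n - 1) * Fhat
  # independence baseline: diagonal covariance
  F_base <- sum(log(diag(S))) - logdetS
  chi2_b <- (n - 1) * F_base
  df_b <- J * (J - 1) / 2
  saturated <- df == 0
  rmsea <- if (saturated) 0 else sqrt(max(0, (chi2 - df) / (df * (n - 1))))
  cfi <- 1 - (chi2 - df) / (chi2_b - df_b)
  tli <- ((chi2_b / df_b) - (chi2 / max(df, 1))) / ((chi2_b / df_b) - 1)
  if (saturated) { cfi <- 1; tli <- 1 }
  Sigma <- tcrossprod(lambda) + diag(psi, J)
  Dn <- sqrt(diag(S))
  resid_std <- (S - Sigma) / tcrossprod(Dn)
  srmr <- sqrt(mean(resid_std[lower.tri(resid_std, diag = TRUE)]^2))
  omega <- sum(lambda)^2 / (sum(lambda)^2 + sum(psi))
  structure(list(loadings = lambda, uniqueness = psi, discrepancy = Fhat,
                 converged = converged, heywood = heywood,
                 indices = list(model_chi2 = chi2, model_df = df,
                                baseline_chi2 = chi2_b, baseline_df = df_b,
                                rmsea = rmsea, srmr = srmr,
                                cfi = cfi, tli = tli,
                                cfi_clipped = min(max(cfi, 0), 1),
                                tli_clipped = min(max(tli, 0), 1),
                                omega = omega, n_used = n,
                                saturated = saturated)),
            class = "cfa_fit")
}

#' @export
print.cfa_fit <- function(x, ...) {
  i <- x$indices
  cat(sprintf("one-factor CFA: n=%d, chi2=%.3f (df=%d), RMSEA=%.3f, SRMR=%.3f, CFI=%.3f, TLI=%.3f, omega=%.3f\n",
              i$n_used, i$model_chi2, i$model_df, i$rmsea, i$srmr, i$cfi, i$tli, i$omega))
  if (i$saturated) cat("  (just-identified model: discrepancy ~ 0 by construction)\n")
  invisible(x)
}

#' Reliability and fit-index table per subgroup
#'
#' Computes Cronbach's alpha, McDonald's omega, Guttman's lambda-6, RMSEA,
#' SRMR, CFI and TLI for the full sample and for each level of each
#' requested categorical covariate (one row per subgroup plus a `Total`
#' row). Omega and lambda-6 are reported side by side.
#'
#' @param data a [response_matrix].
#' @param by covariate names (defaults to all covariates, plus the group).
#' @return data frame, one row per subgroup.
#' @export
psychometric_table <- function(data, by = NULL) {
  stopifnot(inherits(data, "response_matrix"))
  Y <- data$responses
  fac <- list()
  if (!is.null(data$group)) fac$group <- data$group
  if (!is.null(data$covariates)) fac <- c(fac, as.list(data$covariates))
  if (!is.null(by)) fac <- fac[intersect(by, names(fac))]
  one <- function(rows, factor_name, level) {
    sub <- Y[rows, , drop = FALSE]
    sub <- sub[stats::complete.cases(sub), , drop = FALSE]
    cfa <- fit_one_factor_cfa(sub)
    data.frame(factor = factor_name, level = level, n = nrow(sub),
               alpha = cronbach_alpha(sub), omega = cfa$indices$omega,
               lambda6 = guttman_lambda6(sub),
               rmsea = cfa$indices$rmsea, srmr = cfa$indices$srmr,
               cfi = cfa$indices$cfi, tli = cfa$indices$tli,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (nm in names(fac)) {
    f <- factor(fac[[nm]])
    for (lv in levels(f))
      rows[[length(rows) + 1L]] <- one(which(f == lv), nm, lv)
  }
  rows[[length(rows) + 1L]] <- one(seq_len(nrow(Y)), "Total", "Total")
  do.call(rbind, rows)
}
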