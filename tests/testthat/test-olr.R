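test_that("the degenerate two-by-two fit recovers the table log odds ratio", {
  # g=0: 10 low / 10 high; g=1: 5 low / 15 high; trait held constant
  y <- c(rep(1L, 10), rep(2L, 10), rep(1L, 5), rep(2L, 15))
  g <- rep(0:1, each = 20)
  fit <- fit_cumulative_logit(y, theta = rep(0, 40), group = g, model = "M2")
  expect_true(fit$converged)
  expect_identical(fit$fixed_terms, "theta")   # constant column held at 0
  expect_equal(abs(unname(fit$beta["group"])), log(3), tolerance = 1e-6)
  # modelling P(Y <= k), the focal group has lower odds of a low response
  expect_lt(unname(fit$beta["group"]), 0)
  expect_equal(unname(fit$alpha[1]), 0, tolerance = 1e-6)  # logit(1/2)
})

test_that("nested models never lose log-likelihood and chi-squares are non-negative", {
  sim <- small_sim(n = 300, J = 4, seed = 41)
  g <- as.integer(sim$data$group) - 1L
  th <- sim$truth$theta
  for (j in 1:3) {
    y <- sim$data$responses[, j]
    m1 <- fit_cumulative_logit(y, th, g, "M1")
    m2 <- fit_cumulative_logit(y, th, g, "M2")
    m3 <- fit_cumulative_logit(y, th, g, "M3")
    expect_lte(m1$logLik, m2$logLik + 1e-10)
    expect_lte(m2$logLik, m3$logLik + 1e-10)
    expect_gte(lr_chi2(m1, m2)$chi2, 0)
    expect_identical(lr_chi2(m1, m2)$df, 1L)
    expect_identical(lr_chi2(m1, m3)$df, 2L)
  }
})

test_that("the Newton maximiser matches a derivative-free global search on a small problem", {
  set.seed(42)
  n <- 60
  theta <- rnorm(n); g <- rep(0:1, n / 2)
  y <- 1L + rowSums(runif(n) < plogis(1.1 * outer(theta + 0.4 * g, c(-0.5, 0.8), "-")))
  fit <- fit_cumulative_logit(y, theta, g, "M3")
  # independent parameterisation: (alpha1, log gap, slopes), Nelder-Mead
  nll <- function(p) {
    al <- c(p[1], p[1] + exp(p[2]))
    eta <- drop(cbind(theta, g, theta * g) %*% p[3:5])
    G <- plogis(outer(eta, al, "+"))
    pr <- cbind(G[, 1], G[, 2] - G[, 1], 1 - G[, 2])
    -sum(log(pmax(pr[cbind(seq_len(n), y)], 1e-300)))
  }
  o <- optim(c(-0.5, 0, 0, 0, 0), nll, method = "Nelder-Mead",
             control = list(maxit = 1e5, reltol = 1e-15))
  o <- optim(o$par, nll, method = "Nelder-Mead",
             control = list(maxit = 1e5, reltol = 1e-15))
  expect_equal(fit$logLik, -o$value, tolerance = 1e-5)
})

test_that("the fit agrees with an established proportional-odds implementation", {
  skip_if_not_installed("MASS")
  set.seed(43)
  n <- 500
  theta <- rnorm(n); g <- rep(0:1, n / 2)
  y <- 1L + rowSums(runif(n) < plogis(1.3 * outer(theta + 0.3 * g, c(-1, 0, 1, 1.8), "-")))
  fit <- fit_cumulative_logit(y, theta, g, "M2")
  pf <- MASS::polr(factor(y) ~ theta + g, method = "logistic")
  expect_equal(fit$logLik, as.numeric(logLik(pf)), tolerance = 1e-6)
  # polr models logit P(Y<=k) = zeta_k - eta, so slopes flip sign
  expect_equal(unname(fit$beta[c("theta", "group")]),
               unname(-coef(pf)), tolerance = 1e-4)
})

test_that("likelihood-ratio p-values reproduce published chi-square tail areas", {
  base <- fake_olr(-1000)
  expect_equal(lr_chi2(base, fake_olr(-1000, n_beta = 2))$chi2, 0)
  expect_equal(lr_chi2(base, fake_olr(-1000, n_beta = 2))$p, 1)
  # chi2 = 8.239 and 0.351 on 1 df: printed p .0041 and .5534
  expect_equal(lr_chi2(base, fake_olr(-1000 + 8.239 / 2, n_beta = 2))$p,
               0.0041, tolerance = 5e-5)
  expect_equal(lr_chi2(base, fake_olr(-1000 + 0.351 / 2, n_beta = 2))$p,
               0.5534, tolerance = 5e-4)
  expect_error(lr_chi2(base, fake_olr(-999, n = 99L)),
               class = "difolr_validation_error")
})

test_that("pseudo-R-squared differences follow the stated arithmetic", {
  s <- fake_olr(-100); f <- fake_olr(-99, n_beta = 2)
  expect_equal(delta_r(s, f), 1 - 99 / 100)
  same <- fake_olr(-100, n_beta = 2)
  expect_equal(delta_r(s, same), 0)
  null0 <- fake_olr(-120, n_beta = 0)
  expect_equal(delta_r(s, same, "mcfadden_difference", null0), 0)
  expect_equal(delta_r(s, f, "mcfadden_difference", null0),
               (1 - 99 / 120) - (1 - 100 / 120))
  expect_error(delta_r(fake_olr(1), f), class = "difolr_validation_error")
})

test_that("the beta-change criterion is the absolute proportional slope change", {
  expect_equal(cvbl_delta_beta(fake_olr(-10, 2.0), fake_olr(-9, 1.9)), 0.05)
  expect_equal(cvbl_delta_beta(fake_olr(-10, 1.5), fake_olr(-9, 1.5)), 0)
  expect_equal(cvbl_delta_beta(fake_olr(-10, -2.0), fake_olr(-9, -1.9)), 0.05)
  expect_error(cvbl_delta_beta(fake_olr(-10, 0), fake_olr(-9, 1)),
               class = "difolr_validation_error")
})

test_that("category probabilities are proper and the likelihood is scale-invariant", {
  sim <- small_sim(n = 250, J = 3, seed = 44)
  g <- as.integer(sim$data$group) - 1L
  th <- sim$truth$theta
  y <- sim$data$responses[, 2]
  fit <- fit_cumulative_logit(y, th, g, "M3")
  pr <- predict(fit, theta = c(-2, 0, 2), group = c(0L, 1L, 0L))
  expect_true(all(pr >= 0))
  expect_equal(rowSums(pr), rep(1, 3), tolerance = 1e-10)
  # linear rescaling of the trait reparameterises without changing ln L
  fit2 <- fit_cumulative_logit(y, 2.5 * th + 1, g, "M3")
  expect_equal(fit$logLik, fit2$logLik, tolerance = 1e-8)
  expect_equal(unname(fit$beta["theta"]), 2.5 * unname(fit2$beta["theta"]),
               tolerance = 1e-5)
})

test_that("degenerate responses and separation are reported, not papered over", {
  expect_error(fit_cumulative_logit(rep(2L, 50), rnorm(50), model = "M1"),
               class = "difolr_validation_error")
  # y determined by g: the group coefficient runs to the boundary
  y <- rep(1:2, each = 20); g <- rep(0:1, each = 20)
  fit <- fit_cumulative_logit(y, rnorm(40), g, "M2")
  expect_false(fit$converged)
  expect_true(fit$diverged)
})
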