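# shared fixture builders; all data generated in code at test time

small_sim <- function(n = 200, J = 6, seed = 101, ...) {
  simulate_responses(synthetic_spec(n_per_group = c(n / 2, n / 2),
                                    n_items = J, seed = seed, ...))
}

# a grm_fit shell with known parameters, for scoring against oracles
manual_grm <- function(a, b, item_ids = sprintf("i%d", seq_along(a)),
                       n_quad = 49L) {
  q <- seq(-4, 4, length.out = n_quad)
  w <- dnorm(q); w <- w / sum(w)
  structure(list(a = a, b = b, item_ids = item_ids,
                 collapse_maps = vector("list", length(a)),
                 quadrature = list(points = q, weights = w)),
            class = "grm_fit")
}

# olr_fit shell carrying just the fields the statistic functions read
fake_olr <- function(logLik, beta_theta = NULL, n = 100L, K = 3L,
                     n_beta = 1L) {
  beta <- if (is.null(beta_theta)) setNames(numeric(n_beta), rep("x", n_beta))
          else c(theta = beta_theta)
  structure(list(alpha = setNames(numeric(K - 1L), paste0("alpha", seq_len(K - 1L))),
                 beta = beta, logLik = logLik, n_used = n, K = K,
                 converged = TRUE, model = "fake"),
            class = "olr_fit")
}

# published per-item statistics arranged as a report-shaped data frame
published_report <- function(grouping = NULL) {
  df <- dai36_published_dif_stats()
  if (!is.null(grouping)) df <- df[df$grouping == grouping, ]
  df$item_id <- sprintf("item%02d", df$item)
  df
}

expect_monotone_nondecreasing <- function(x, tol = 1e-9) {
  expect_true(all(diff(x) >= -tol))
}
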