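test_that("person scores are mean item responses with exclusions honoured", {
  rm3 <- response_matrix(matrix(3L, 5, 4))
  expect_equal(person_scores(rm3), rep(3, 5))
  expect_equal(person_scores(rm3, exclude_items = c(1, 4)), rep(3, 5))

  rm2 <- response_matrix(matrix(c(1L, 5L), 1, 2), item_ids = c("a", "b"))
  expect_equal(person_scores(rm2), 3)
  expect_equal(person_scores(rm2, exclude_items = "b"), 1)
  expect_error(person_scores(rm2, exclude_items = c("a", "b")),
               class = "difolr_validation_error")

  set.seed(71)
  rmx <- response_matrix(matrix(sample(1:5, 200, TRUE), 20, 10))
  sc <- person_scores(rmx)
  for (i in 1:20) {
    j <- which.max(rmx$responses[i, ])  # above-mean response (or tied max)
    if (rmx$responses[i, j] > sc[i])
      expect_lt(person_scores(rmx, exclude_items = j)[i], sc[i])
  }
  expect_true(all(sc >= 1 & sc <= 5))
})

test_that("the pooled t-test matches the textbook formula", {
  same <- c(1, 2, 3)
  r <- t_test_pooled(same, same)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  sp2 <- (3 * var(x) + 3 * var(y)) / 6
  t_hand <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / 4 + 1 / 4))
  r2 <- t_test_pooled(x, y)
  expect_equal(r2$statistic, t_hand, tolerance = 1e-12)
  expect_equal(r2$df, 6)
  expect_error(t_test_pooled(rep(1, 5), rep(1, 4)), class = "difolr_validation_error")
})

test_that("Mann-Whitney U follows the documented convention and enumeration", {
  below <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6, 7))
  expect_equal(below$U, 0)  # x entirely below y

  expect_gte(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p_value, 0.99)

  x <- c(1.2, 3.4, 2.2, 5.0); y <- c(2.0, 1.1, 4.4, 6.1, 3.3)
  mw <- mann_whitney_u(x, y)
  expect_identical(mw$method, "exact")
  # exhaustive oracle over all C(9, 4) labelings
  rk <- rank(c(x, y))
  us <- apply(combn(9, 4), 2, function(ix) sum(rk[ix]) - 10)
  p_enum <- mean(abs(us - 10) >= abs(mw$U - 10) - 1e-9)
  expect_equal(mw$p_value, p_enum, tolerance = 1e-12)

  # tied data: the exact DP still matches enumeration
  xt <- c(1, 2, 2, 3); yt <- c(2, 3, 3, 4, 4)
  mt <- mann_whitney_u(xt, yt)
  rkt <- rank(c(xt, yt))
  ut <- apply(combn(9, 4), 2, function(ix) sum(rkt[ix]) - 10)
  expect_equal(mt$p_value, mean(abs(ut - 10) >= abs(mt$U - 10) - 1e-9),
               tolerance = 1e-12)
})

test_that("the normal approximation agrees with the reference implementation", {
  set.seed(72)
  x <- sample(1:5, 60, TRUE); y <- sample(1:5, 75, TRUE)
  mine <- mann_whitney_u(x, y, method = "normal")
  ref <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = TRUE))
  expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the exact p-value is invariant under strictly monotone transforms", {
  set.seed(73)
  x <- rnorm(6); y <- rnorm(7, 0.5)
  p1 <- mann_whitney_u(x, y)$p_value
  expect_equal(mann_whitney_u(exp(x), exp(y))$p_value, p1, tolerance = 1e-12)
  expect_equal(mann_whitney_u(x^3, y^3)$p_value, p1, tolerance = 1e-12)
})

test_that("without uniform flags the corrected comparison equals the uncorrected", {
  sim <- small_sim(n = 300, J = 5, seed = 74)
  fit <- dif_olr(sim$data, dif_config(alpha = 1e-9))
  cmp <- compare_with_without_dif(fit)
  expect_identical(nrow(cmp), 4L)
  un <- cmp[cmp$correction == "uncorrected", ]
  co <- cmp[cmp$correction == "corrected", ]
  expect_equal(un$mean, co$mean)
  expect_equal(un$p_t_test, co$p_t_test)
  expect_true(all(cmp$sd >= 0) && all(cmp$mean >= 1 & cmp$mean <= 5))
})

test_that("a pure trait-impact difference stays significant after correction", {
  spec <- synthetic_spec(n_per_group = c(400, 400), n_items = 8,
                         impact = 0.6, seed = 75)
  sim <- simulate_responses(spec)
  # report shell with two arbitrary non-DIF items flagged uniform
  res <- data.frame(item_id = sim$data$item_ids,
                    flag_uniform_sig = c(TRUE, TRUE, rep(FALSE, 6)),
                    usable = TRUE)
  rep_obj <- structure(list(results = res, data = sim$data,
                            config = dif_config()), class = "dif_olr")
  cmp <- compare_with_without_dif(rep_obj)
  expect_lt(max(cmp$p_mann_whitney), 0.05)
  dir_un <- diff(cmp$mean[cmp$correction == "uncorrected"])
  dir_co <- diff(cmp$mean[cmp$correction == "corrected"])
  expect_identical(sign(dir_un), sign(dir_co))
})

test_that("removing uniform-DIF items shrinks a spurious group gap", {
  gaps <- vapply(1:30, function(r) {
    spec <- synthetic_spec(n_per_group = c(250, 250), n_items = 8, impact = 0,
                           dif_items = data.frame(item = c(1, 2),
                                                  type = "uniform",
                                                  magnitude = c(0.8, 0.8)),
                           seed = 7500 + r)
    sim <- simulate_responses(spec)
    res <- data.frame(item_id = sim$data$item_ids,
                      flag_uniform_sig = sim$truth$dif_labels == "uniform",
                      usable = TRUE)
    rep_obj <- structure(list(results = res, data = sim$data,
                              config = dif_config()), class = "dif_olr")
    cmp <- compare_with_without_dif(rep_obj)
    c(abs(diff(cmp$mean[cmp$correction == "uncorrected"])),
      abs(diff(cmp$mean[cmp$correction == "corrected"])))
  }, numeric(2))
  expect_lt(median(gaps[2, ]), median(gaps[1, ]))
})
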