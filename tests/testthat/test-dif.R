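test_that("published per-item statistics classify exactly as printed", {
  cfg <- dif_config()
  g1 <- classify_item(published_report("gender"), cfg)
  r1 <- g1[g1$item == 1, ]   # uniform chi2 8.239 (p .0041), dR1 .0029, dB1 .0137
  expect_true(r1$flag_uniform_sig)
  expect_false(r1$flag_nonuniform_sig)
  expect_false(r1$flag_large_r2)
  expect_true(r1$flag_large_cvbl)
  r36 <- g1[g1$item == 36, ]  # nonuniform chi2 15.138 (p .0001), dR2 .0054
  expect_true(r36$flag_nonuniform_sig)
  expect_false(r36$flag_large_r2)

  nothing <- data.frame(p_uniform = 1, p_nonuniform = 1, delta_r1 = 0,
                        delta_r2 = 0, delta_beta1 = 0)
  flags <- classify_item(nothing, cfg)
  expect_false(any(unlist(flags[c("flag_uniform_sig", "flag_nonuniform_sig",
                                  "flag_large_r2", "flag_large_cvbl", "flag_dif")])))
})

test_that("flags respond to each criterion independently", {
  cfg <- dif_config(alpha = 0.01, r2_threshold = 0.05, cvbl_threshold = 0.02)
  s <- data.frame(p_uniform = c(0.005, 0.02), p_nonuniform = c(0.5, 0.005),
                  delta_r1 = c(0.06, 0.01), delta_r2 = c(0.01, 0.06),
                  delta_beta1 = c(0.03, 0.01))
  f <- classify_item(s, cfg)
  expect_identical(f$flag_uniform_sig, c(TRUE, FALSE))
  expect_identical(f$flag_nonuniform_sig, c(FALSE, TRUE))
  expect_identical(f$flag_large_r2, c(TRUE, TRUE))   # max(dR1, dR2) > 0.05
  expect_identical(f$flag_large_cvbl, c(TRUE, FALSE))
  # effect-size-driven purification flag
  f2 <- classify_item(s, dif_config(alpha = 0.01, r2_threshold = 0.05,
                                    cvbl_threshold = 0.02,
                                    purification_criterion = "effect_size"))
  expect_identical(f2$flag_dif, f2$flag_large_r2 | f2$flag_large_cvbl)
})

test_that("a trait-only response process yields null group statistics", {
  set.seed(51)
  theta <- rnorm(600)
  y <- 1L + findInterval(theta, c(-1, 0, 1))   # deterministic in theta
  g <- rep(0:1, 300)
  st <- suppressWarnings(analyze_item(y, theta, g))
  expect_true(st$usable)
  expect_lt(st$chi2_uniform, 1e-3)
  expect_lt(st$chi2_nonuniform, 1e-3)
  expect_gt(st$p_uniform, 0.97)
  expect_gt(st$p_nonuniform, 0.97)
})

test_that("an unanalysable item is reported unusable with a warning", {
  y <- rep(3L, 100); y[1] <- NA
  expect_warning(st <- analyze_item(y, rnorm(100), rep(0:1, 50)),
                 "could not be analysed")
  expect_false(st$usable)
  expect_true(is.na(st$chi2_uniform))
})

test_that("when iteration 0 flags nothing the run is a single-pass fixed point", {
  sim <- small_sim(n = 400, J = 6, seed = 52)
  cfg <- dif_config(alpha = 1e-6)   # no-DIF data: nothing can clear this bar
  fit <- dif_olr(sim$data, cfg)
  expect_identical(fit$iterations, 1L)
  expect_identical(fit$termination, "converged")
  expect_identical(fit$trace, list(character(0)))
  # identical to one manual pass with the same trait scores
  grm <- fit_grm(sim$data, quadrature_points = cfg$quadrature_points)
  th <- eap_theta(grm, sim$data)
  g <- as.integer(sim$data$group) - 1L
  manual <- classify_item(do.call(rbind, lapply(1:6, function(j)
    analyze_item(sim$data$responses[, j], th$theta, g, cfg,
                 item_id = sim$data$item_ids[j]))), cfg)
  expect_equal(fit$results, manual)
})

test_that("purification is deterministic and its trace converges on the shipped scenario", {
  sim <- simulate_responses(default_scenario(seed = 1))
  cfg <- dif_config(refit_anchors = FALSE)
  f1 <- suppressWarnings(dif_olr(sim$data, cfg))
  f2 <- suppressWarnings(dif_olr(sim$data, cfg))
  expect_identical(serialize(f1$results, NULL), serialize(f2$results, NULL))
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$flagged, f2$flagged)

  expect_lte(f1$iterations, 10L)
  expect_identical(f1$termination, "converged")
  n_tr <- length(f1$trace)
  expect_gte(n_tr, 2L)
  expect_setequal(f1$trace[[n_tr]], f1$trace[[n_tr - 1L]])
})

test_that("the full-refit hybrid runs and records anchors disjoint from flags", {
  sim <- simulate_responses(synthetic_spec(
    n_per_group = c(250, 250), n_items = 8,
    dif_items = data.frame(item = 2, type = "uniform", magnitude = 1), seed = 53))
  fit <- suppressWarnings(dif_olr(sim$data, dif_config(max_purification_iters = 4)))
  expect_true("item02" %in% fit$flagged)
  expect_length(intersect(fit$anchors, fit$flagged), 0)
  expect_setequal(union(fit$anchors, fit$flagged), fit$results$item_id)
  expect_lte(length(fit$trace), 4L)
})

test_that("raising the uniform shift never weakens the median uniform chi-square", {
  deltas <- c(0, 0.25, 0.5, 1.0)
  med <- vapply(deltas, function(d) {
    chi <- vapply(1:40, function(r) {
      dif <- if (d > 0) data.frame(item = 1, type = "uniform", magnitude = d)
      sim <- simulate_responses(synthetic_spec(n_per_group = c(250, 250),
                                               n_items = 4, dif_items = dif,
                                               seed = 6000 + r))
      g <- as.integer(sim$data$group) - 1L
      analyze_item(sim$data$responses[, 1], sim$truth$theta, g)$chi2_uniform
    }, numeric(1))
    median(chi)
  }, numeric(1))
  expect_monotone_nondecreasing(med)
  expect_gt(med[4], med[1])
})

test_that("flagging everything stops with a warning and keeps the last anchors", {
  sim <- small_sim(n = 200, J = 4, seed = 54)
  cfg <- dif_config(alpha = 0.999999)
  expect_warning(fit <- dif_olr(sim$data, cfg), "all items flagged")
  expect_identical(fit$termination, "all_items_flagged")
  expect_gt(length(fit$anchors), 0)
})

test_that("opposite uniform shifts produce crossing group curves (cancel-out pattern)", {
  spec <- synthetic_spec(
    n_per_group = c(500, 500), n_items = 8,
    dif_items = data.frame(item = c(2, 5), type = "uniform",
                           magnitude = c(1.0, -1.0)), seed = 55)
  sim <- simulate_responses(spec)
  fit <- suppressWarnings(dif_olr(sim$data, dif_config(refit_anchors = FALSE)))
  expect_true(all(c("item02", "item05") %in%
                  fit$results$item_id[fit$results$flag_uniform_sig]))
  curves <- export_dif_curves(fit, which = "uniform")
  k <- length(attr(curves, "items"))
  gap <- curves[[fit$group$focal]] - curves[[fit$group$reference]]
  expect_true(min(gap) < 0 && max(gap) > 0)
  expect_true(all(curves[[2]] >= k & curves[[2]] <= 5 * k))
  expect_true(all(curves[[3]] >= k & curves[[3]] <= 5 * k))
})

test_that("with nothing flagged the curve export is empty with a note", {
  sim <- small_sim(n = 300, J = 5, seed = 56)
  fit <- dif_olr(sim$data, dif_config(alpha = 1e-9))
  expect_message(curves <- export_dif_curves(fit), "no flagged items")
  expect_identical(nrow(curves), 0L)
  expect_identical(attr(curves, "note"), "no flagged items")
})
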