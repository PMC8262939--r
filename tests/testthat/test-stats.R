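test_that("genus aggregation averages isolates and keeps singletons", {
  iso <- data.frame(assembly_id = paste0("a", 1:3),
                    genus = c("g1", "g1", "g2"),
                    genome_size = c(2e6, 4e6, 5e6),
                    rm_total = c(3, 5, 7))
  gt <- aggregate_genus(iso)
  expect_equal(gt$mean_rmpg[gt$genus == "g1"], 4)
  expect_equal(gt$n_isolates, c(2, 1))
  expect_equal(gt$mean_genome_size[gt$genus == "g1"], 3e6)
  expect_error(aggregate_genus(iso[0, ]), "empty")
  # invariant to isolate row order
  expect_equal(aggregate_genus(iso[3:1, ]), gt)
})

test_that("distribution summaries filter by isolate count and use
           order-statistic interpolation", {
  gt <- data.frame(genus = letters[1:5], n_isolates = c(1, 2, 5, 7, 10),
                   mean_rmpg = 0:4, mean_genome_size = 1:5 * 1e6)
  s <- summarize_rmpg(gt, 1)
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  expect_equal(s$q05, 0.2)   # (n-1)*p + 1 = 1.2 -> 0 + 0.2*(1-0)
  expect_equal(s$q95, 3.8)
  s5 <- summarize_rmpg(gt, 5)
  expect_equal(s5$n_genera, 3)
  expect_equal(s5$median, 3)
  # filtered genera are a subset of the unfiltered ones
  expect_true(s5$n_genera <= s$n_genera)
  expect_error(summarize_rmpg(gt, 99), "no genera")
})

test_that("recovery of synthetic genus structure is exact", {
  st <- gen_stats_tables(n_genera = 20, isolates_per_genus = c(2, 6),
                         seed = 8)
  manual <- tapply(st$isolates$rm_total, st$isolates$genus, mean)
  expect_equal(as.numeric(manual[st$genus$genus]), st$genus$mean_rmpg)
  # removing putative IIG counts never increases a genus mean
  gt2 <- aggregate_genus(st$isolates, response = "rm_total_no_iig")
  expect_true(all(gt2$mean_rmpg <= st$genus$mean_rmpg))
})

test_that("the linear fit recovers exact and simulated slopes", {
  gt <- data.frame(genus = letters[1:6], n_isolates = 5,
                   mean_rmpg = 0.5 * (2:7), mean_genome_size = (2:7) * 1e6)
  fit <- suppressWarnings(rmpg_fit(gt, "linear"))  # exact fit warns in summary()
  expect_equal(unname(coef(fit)["slope"]), 0.5)
  expect_equal(fit$r_squared, 1)
  expect_equal(predict(fit, 10), unname(coef(fit)["intercept"]) + 5)
  expect_equal(residuals(fit), rep(0, 6), tolerance = 1e-12)
  expect_error(rmpg_fit(gt[1:2, ], "linear"), "at least 3")
  gt$mean_genome_size <- 2e6
  expect_error(rmpg_fit(gt, "linear"), "degenerate")

  # 95% CI covers the generating slope at nominal rate
  hits <- 0
  for (r in 1:200) {
    st <- gen_stats_tables(n_genera = 500, isolates_per_genus = 1,
                           model = "linear", intercept = 1, slope = 0.4,
                           noise_sd = 1, seed = 1000 + r)
    f <- rmpg_fit(st$genus, "linear")
    se <- sqrt(diag(stats::vcov(f$lm)))[2]
    ci <- unname(coef(f)["slope"]) + c(-1.96, 1.96) * se
    if (ci[1] <= 0.4 && 0.4 <= ci[2]) hits <- hits + 1
  }
  expect_gte(hits / 200, 0.93)
})

test_that("the negative-binomial fit recovers simulated parameters and
           agrees with an independent integer-response fit", {
  st <- gen_stats_tables(n_genera = 1000, isolates_per_genus = 1,
                         model = "negbin", intercept = 0.5, slope = 0.1,
                         theta = 2, seed = 77)
  fit <- rmpg_fit(st$genus, "negbin")
  expect_lt(abs(unname(coef(fit)["slope"]) - 0.1), 0.02)
  expect_gt(fit$dispersion, 0)
  expect_true(fit$pseudo_r_squared >= 0 && fit$pseudo_r_squared <= 1)
  # single-isolate genera have integer counts: MASS::glm.nb is an
  # independent route to the same estimate
  nb <- MASS::glm.nb(mean_rmpg ~ I(mean_genome_size / 1e6), data = st$genus)
  expect_lt(abs(unname(coef(fit)["slope"]) - unname(coef(nb)[2])), 1e-4)
  rounded <- rmpg_fit(st$genus, "negbin", nb_response = "round")
  expect_lt(abs(unname(coef(rounded)["slope"]) -
                  unname(coef(fit)["slope"])), 1e-4)

  # a zero-slope world shows essentially no explained deviance
  st0 <- gen_stats_tables(n_genera = 800, isolates_per_genus = 1,
                          model = "negbin", intercept = 0.7, slope = 0,
                          theta = 2, seed = 5)
  fit0 <- rmpg_fit(st0$genus, "negbin")
  expect_lt(fit0$pseudo_r_squared, 0.01)
})

test_that("genome expansion needed to gain one RM follows the fitted link", {
  expect_equal(round(delta_size_for_one_rm(0.145), 2), 6.90)
  expect_equal(delta_size_for_one_rm(0.5), 2)
  # linear: reciprocal identity holds exactly
  expect_equal(delta_size_for_one_rm(0.37) * 0.37, 1)
  expect_error(delta_size_for_one_rm(-0.1), "non-positive")
  # NB: solves exp(a + b (x + d)) = exp(a + b x) + 1
  st <- gen_stats_tables(n_genera = 400, isolates_per_genus = 1,
                         model = "negbin", intercept = 0.5, slope = 0.1,
                         theta = 2, seed = 12)
  fit <- rmpg_fit(st$genus, "negbin")
  d <- delta_size_for_one_rm(fit, baseline_size = 2)
  a <- unname(coef(fit)["intercept"]); b <- unname(coef(fit)["slope"])
  expect_equal(exp(a + b * (2 + d)), exp(a + b * 2) + 1, tolerance = 1e-8)
})

test_that("the rank-sum test enumerates exactly for small samples and
           matches the tie-corrected normal approximation for large ones", {
  # identical tied groups: exact p = 1
  expect_equal(rank_sum_test(rep(2, 5), rep(2, 5))$p_value, 1)
  # fully separated groups of 4: exact p = 2/70
  expect_equal(rank_sum_test(1:4, 5:8)$p_value, 2 / 70)
  # small untied samples agree with the exact reference implementation
  set.seed(2)
  for (r in 1:20) {
    a <- rnorm(6); b <- rnorm(7)
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # large samples agree with the continuity-corrected normal reference
  for (r in 1:10) {
    a <- rnorm(25); b <- rnorm(30, 0.3)
    ours <- rank_sum_test(a, b)
    ref <- stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-12)
  }
  # null calibration: type-I error within 1.5% of the nominal 5%
  set.seed(99)
  rej <- 0
  for (r in 1:2000) {
    if (rank_sum_test(rnorm(30), rnorm(30))$p_value < 0.05) rej <- rej + 1
  }
  expect_lt(abs(rej / 2000 - 0.05), 0.015)
})

test_that("fit objects print and summarize without error", {
  gt <- data.frame(genus = letters[1:6], n_isolates = 5,
                   mean_rmpg = c(1, 2, 2, 3, 4, 5),
                   mean_genome_size = (2:7) * 1e6)
  fit <- rmpg_fit(gt, "linear")
  expect_output(print(fit), "linear")
  expect_output(summary(fit), "Mbp")
  expect_s3_class(logLik(fit), "logLik")
})
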