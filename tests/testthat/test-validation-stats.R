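test_that("paired t matches the closed form and the one-sample oracle", {
  res <- paired_t(c(1, 2, 3), c(0, 0, 0))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-9)
  expect_equal(res$statistic, 3.4641, tolerance = 1e-4)
  expect_equal(res$df, 2L)
  expect_equal(res$p, 0.07418, tolerance = 1e-4)

  withr::local_seed(99)
  for (i in 1:25) {
    n <- sample(3:15, 1L)
    x <- rnorm(n, 120, 2)
    y <- rnorm(n, 120, 2)
    mine <- paired_t(x, y)
    oracle <- t.test(x, y, paired = TRUE)
    expect_equal(mine$statistic, unname(oracle$statistic),
                 tolerance = 1e-10)
    expect_equal(mine$p, oracle$p.value, tolerance = 1e-10)
    # antisymmetry
    rev <- paired_t(y, x)
    expect_equal(rev$statistic, -mine$statistic, tolerance = 1e-12)
    expect_equal(rev$p, mine$p, tolerance = 1e-12)
  }
})

test_that("paired t handles degenerate pairings as documented", {
  x <- c(1, 3, 5)
  expect_error(paired_t(x, x), "degenerate pairing")
  res <- paired_t(x + 2, x)
  expect_true(is.infinite(res$statistic) && res$statistic > 0)
  expect_equal(res$p, 0)
  expect_error(paired_t(1:3, 1:4), "equal length")
})

test_that("Bonferroni adjustment reproduces the printed p/p.adj pairs", {
  expect_equal(adjust_p(0.5, m = 40L), 1.0)
  expect_equal(adjust_p(0.002, m = 40L), 0.08, tolerance = 1e-12)
  expect_equal(adjust_p(0.018, m = 40L), 0.72, tolerance = 1e-12)
  expect_equal(adjust_p(0.005, m = 40L), 0.20, tolerance = 1e-12)
  expect_equal(adjust_p(c(0.001, 0.5), m = 2L), c(0.002, 1.0))
  expect_error(adjust_p(1.2, m = 2L), "invalid probability")
  expect_error(adjust_p(c(0.1, 0.2), m = 1L), "m must be")
})

test_that("significance labels follow the threshold chain", {
  expect_equal(significance_label(c(0.72, 0.05, 0.051, 0.01, 0.001,
                                    0.00003)),
               c("ns", "*", "ns", "**", "***", "****"))
})

test_that("prediction interval matches closed form, oracle and printed shape", {
  pi <- prediction_interval(c(0, 2), confidence = 0.99)
  expect_equal(pi$mean_mm, 1)
  expect_equal(pi$sd_mm, sqrt(2))
  expect_equal(pi$lower_mm, -109.2567, tolerance = 1e-4)
  expect_equal(pi$upper_mm, 111.2567, tolerance = 1e-4)

  # oracle: single-future-observation interval from an intercept-only fit
  withr::local_seed(7)
  for (i in 1:10) {
    y <- rnorm(10, 123, 0.4)
    pi <- prediction_interval(y, 0.99)
    fit <- lm(y ~ 1)
    pr <- predict(fit, newdata = data.frame(x = 1),
                  interval = "prediction", level = 0.99)
    expect_equal(pi$lower_mm, unname(pr[1L, "lwr"]), tolerance = 1e-9)
    expect_equal(pi$upper_mm, unname(pr[1L, "upr"]), tolerance = 1e-9)
    expect_true(pi$lower_mm <= pi$mean_mm && pi$mean_mm <= pi$upper_mm)
    # width strictly increases with confidence
    wider <- prediction_interval(y, 0.995)
    expect_gt(wider$upper_mm - wider$lower_mm,
              pi$upper_mm - pi$lower_mm)
  }

  expect_warning(pc <- prediction_interval(rep(5, 4)), "degenerate")
  expect_equal(c(pc$lower_mm, pc$upper_mm), c(5, 5))
  expect_true(pc$degenerate)
  expect_error(prediction_interval(3), "insufficient sample")
})

test_that("a 99% prediction interval covers a future draw ~99% of the time", {
  withr::local_seed(20260101)
  n <- 10L
  n_sim <- 10000L
  x <- matrix(rnorm(n_sim * n, 125, 1.5), nrow = n_sim)
  future <- rnorm(n_sim, 125, 1.5)
  mu <- rowMeans(x)
  s <- sqrt(rowSums((x - mu)^2) / (n - 1L))
  half <- qt(0.995, n - 1L) * s * sqrt(1 + 1 / n)
  covered <- mean(future >= mu - half & future <= mu + half)
  expect_gt(covered, 0.98)
  expect_lt(covered, 1.0)
  expect_equal(covered, 0.99, tolerance = 0.011)
})

test_that("inclusion audit uses closed limits and signed exceedance", {
  iv <- list(lower_mm = 121.94, upper_mm = 122.96)
  inside <- inclusion_audit(122.82, iv)
  expect_true(inside$included)
  expect_equal(inside$signed_exceedance_mm, 0)

  boundary <- inclusion_audit(121.94, iv)
  expect_true(boundary$included)

  above <- inclusion_audit(147.20, list(lower_mm = 143.50,
                                        upper_mm = 146.34))
  expect_false(above$included)
  expect_equal(above$signed_exceedance_mm, 0.86, tolerance = 1e-9)

  below <- inclusion_audit(118.92, list(lower_mm = 120.89,
                                        upper_mm = 122.73))
  expect_false(below$included)
  expect_equal(below$signed_exceedance_mm, -1.97, tolerance = 1e-9)

  # widening an interval around the same center never drops an inclusion
  expect_true(inclusion_audit(122.82, list(lower_mm = 121, upper_mm = 124)
                              )$included)
})

test_that("run_validation produces the full table layout on synthetic data", {
  spec <- synthetic_measurement_spec(seed = 5L)
  tab <- make_measurement_table(spec)
  run <- run_validation(tab, m = 40L)

  # 10 G1 comparisons + 3 per specimen in G2/G3 = 10 + 15 + 15 = 40
  expect_equal(nrow(run$comparisons), 40L)
  expect_true(all(run$comparisons$df == 9L))
  expect_true(all(run$comparisons$n1 == 10L))
  # one interval per specimen x repeated modality: 10*2 + 10*3
  expect_equal(nrow(run$intervals), 50L)
  expect_equal(nrow(run$inclusions), 50L)

  g3 <- run$comparisons[run$comparisons$group == "G3", ]
  wrong <- g3[g3$modality_1 == "CT_0.58" & g3$modality_2 == "CT_0.60", ]
  expect_true(all(wrong$significance == "****"))
  expect_true(all(wrong$statistic < 0))
  true_vs_orig <- g3[g3$modality_1 == "CT_0.58" &
                       g3$modality_2 == "Original", ]
  expect_true(all(true_vs_orig$significance == "ns"))
  wrong_vs_orig <- g3[g3$modality_1 == "CT_0.60" &
                        g3$modality_2 == "Original", ]
  expect_true(all(wrong_vs_orig$p_adj <= 0.05))
})

test_that("misassigned modalities are flagged across generator seeds", {
  for (seed in c(2L, 17L, 304L)) {
    tab <- make_measurement_table(synthetic_measurement_spec(seed = seed))
    run <- run_validation(tab, m = 40L)
    cmp <- run$comparisons
    mis <- cmp[(cmp$group == "G3" & cmp$modality_1 == "CT_0.60" &
                  cmp$modality_2 == "Original") |
               (cmp$group == "G2" & cmp$modality_1 == "CT_0.58" &
                  cmp$modality_2 == "Original"), ]
    expect_equal(nrow(mis), 10L)
    expect_true(all(mis$p_adj <= 0.05))
  }
})

test_that("degenerate pairings and missing probes do not abort a run", {
  tab <- data.frame(
    specimen_id = "S1", group = "G1",
    modality = rep(c("CT_0.75", "Original"), each = 3L),
    replicate = rep(1:3, 2L),
    distance_mm = rep(c(120, 121, 122), 2L))
  expect_warning(expect_warning(run <- run_validation(tab),
                                "degenerate pairing"),
                 "no Microscribe")
  expect_true(is.na(run$comparisons$statistic))
  expect_equal(run$summary$n_inclusions_total, 0L)
})

test_that("measurement table schema violations are rejected", {
  tab <- make_measurement_table(synthetic_measurement_spec(seed = 3L))
  expect_silent(validate_measurement_table(tab))
  bad <- tab
  bad$modality[1L] <- "MRI"
  expect_error(validate_measurement_table(bad), "unknown modality")
  dup <- rbind(tab, tab[1L, ])
  expect_error(validate_measurement_table(dup), "duplicate")
  neg <- tab
  neg$distance_mm[2L] <- -1
  expect_error(validate_measurement_table(neg), "positive")
  expect_error(validate_measurement_table(tab[0L, ]), "empty")

  f <- withr::local_tempfile(fileext = ".csv")
  write_measurement_table(tab, f)
  back <- read_measurement_table(f)
  expect_equal(nrow(back), nrow(tab))
  expect_equal(back$distance_mm, tab$distance_mm, tolerance = 1e-9)
})

test_that("printed-interval fixture audit reproduces every published verdict", {
  fx <- audit_printed_intervals()
  expect_equal(nrow(fx), 50L)
  expect_equal(fx$included, fx$included_printed)
  orig <- fx[fx$modality == "Original", ]
  expect_equal(sum(orig$included), 17L)
  expect_equal(nrow(orig), 20L)
})
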