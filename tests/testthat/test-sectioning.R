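test_that("equal-SD groups section at the midpoint of the means", {
  f <- group_summary(10, 20, 1, 17, 23)
  m <- group_summary(10, 22, 1, 19, 25)
  res <- fit_cutoff(f, m)
  expect_equal(res$cutoff, 21)
  expect_equal(res$method, "density_intersection")
})

test_that("published unburnt sectioning points are recovered from the summaries", {
  t3 <- load_fixture("table3_unburnt")
  maxt <- fit_cutoff(t3$maxt$female, t3$maxt$male, "maxt")
  expect_equal(round(maxt$cutoff, 2), 19.41)
  maxw <- fit_cutoff(t3$maxw$female, t3$maxw$male, "maxw")
  expect_equal(round(maxw$cutoff, 2), 41.28)
})

test_that("unequal-SD intersection matches the fine-grid density scan", {
  f <- group_summary(10, 10, 1, 7, 13)   # standard pair shifted into range
  m <- group_summary(10, 13, 2, 10, 16)
  res <- fit_cutoff(f, m)
  expect_equal(res$cutoff, 10 + 1.418345, tolerance = 1e-5)
})

test_that("fit_cutoff agrees with the density-scan oracle on random pairs", {
  set.seed(61)
  for (i in 1:200) {
    p <- random_summary_pair()
    fitted <- fit_cutoff(p$female, p$male)
    oracle <- scan_cutoff(p$female, p$male)
    if (fitted$method == "density_intersection" && !is.na(oracle)) {
      expect_lt(abs(fitted$cutoff - oracle), 1e-4)
    }
    if (fitted$method == "density_intersection") {
      # the densities really are equal at the claimed crossing
      expect_lt(abs(dnorm(fitted$cutoff, p$female$mean, p$female$sd) -
                      dnorm(fitted$cutoff, p$male$mean, p$male$sd)), 1e-8)
    }
    # either way the cut-off maximises the D-value over the interval
    grid <- seq(p$female$mean, p$male$mean, length.out = 500)
    expect_gte(fitted$d_value + 1e-6,
               max(d_value(grid, p$female, p$male)))
  }
})

test_that("fallback to D-value maximization engages when no crossing lies between means", {
  t2 <- load_fixture("table2_burnt")
  f <- group_summary(t2$maxt$female$n, t2$maxt$female$mean, t2$maxt$female$sd,
                     t2$maxt$female$min, t2$maxt$female$max)
  m <- group_summary(t2$maxt$male$n, t2$maxt$male$mean, t2$maxt$male$sd,
                     t2$maxt$male$min, t2$maxt$male$max)
  res <- fit_cutoff(f, m, "maxt")
  expect_equal(res$method, "dvalue_maximization")
  expect_gte(res$cutoff, f$mean)
  expect_lte(res$cutoff, m$mean)
})

test_that("degenerate summary pairs are rejected; reversed polarity is flagged", {
  f <- group_summary(5, 20, 1, 17, 23)
  m_same <- group_summary(5, 20, 1.5, 17, 23)
  expect_error(fit_cutoff(f, m_same), "equal")
  zero_sd <- group_summary(5, 25, 1, 22, 28)
  zero_sd$sd <- 0
  expect_error(fit_cutoff(f, zero_sd), "sd")

  rev <- fit_cutoff(group_summary(5, 25, 1, 22, 28), f)
  expect_true(rev$reversed)
  expect_gt(rev$d_value, 0)
})

test_that("D-value reproduces the published burnt values at the published cut-offs", {
  t2 <- load_fixture("table2_burnt")
  sec <- load_fixture("table2_cutoffs")
  for (i in seq_len(nrow(sec))) {
    m <- sec$measurement[i]
    expect_lt(abs(d_value(sec$cutoff[i], t2[[m]]$female, t2[[m]]$male) -
                    sec$d_value[i]), 1e-3)
  }
})

test_that("D-value basics: identical groups give 0; symmetric pair gives Phi(1)-Phi(-1)", {
  g <- group_summary(5, 20, 2, 16, 24)
  expect_equal(d_value(21.7, g, g), 0)
  f <- group_summary(5, 9, 1, 6, 12)
  m <- group_summary(5, 11, 1, 8, 14)
  expect_equal(d_value(10, f, m), pnorm(1) - pnorm(-1), tolerance = 1e-10)
})

test_that("equal-variance closed form: D at the midpoint is 2 Phi(delta / 2s) - 1", {
  set.seed(71)
  for (i in 1:50) {
    mu <- runif(1, 10, 40)
    delta <- runif(1, 0.2, 8)
    s <- runif(1, 0.5, 4)
    f <- group_summary(8, mu, s, mu - 5, mu + 5)
    m <- group_summary(8, mu + delta, s, mu + delta - 5, mu + delta + 5)
    res <- fit_cutoff(f, m)
    expect_equal(res$d_value, 2 * pnorm(delta / (2 * s)) - 1,
                 tolerance = 1e-10)
  }
})

test_that("D-value is invariant under common affine rescaling", {
  set.seed(81)
  for (i in 1:25) {
    p <- random_summary_pair()
    x0 <- runif(1, p$female$mean, p$male$mean)
    a <- runif(1, 0.5, 3); b <- runif(1, -5, 5)
    f2 <- group_summary(p$female$n, a * p$female$mean + b, a * p$female$sd)
    m2 <- group_summary(p$male$n, a * p$male$mean + b, a * p$male$sd)
    expect_equal(d_value(a * x0 + b, f2, m2),
                 d_value(x0, p$female, p$male), tolerance = 1e-12)
  }
})

test_that("cut-off classification rule and tie-break", {
  expect_equal(classify_by_cutoff(30.00, 35.87), "female")
  expect_equal(classify_by_cutoff(42.93, 35.87), "male")
  expect_equal(classify_by_cutoff(35.87, 35.87), "male")  # boundary -> male
  expect_error(classify_by_cutoff(NA, 35.87), "finite")
})

test_that("evaluate_cutoff tallies per-sex and pooled accuracy", {
  d <- study_dataset(data.frame(
    individual_id = c("a", "b", "c", "d"),
    sex = c("F", "F", "M", "M"), side = "left", burn_state = "unburnt",
    maxh = c(30, 36, 40, 34)))
  rep <- evaluate_cutoff(d, "maxh", 35)
  expect_equal(rep$percent_correct_female, 50)
  expect_equal(rep$percent_correct_male, 50)
  expect_equal(rep$percent_correct_total, 50)

  rep_low <- evaluate_cutoff(d, "maxh", 1.5)
  expect_equal(rep_low$percent_correct_female, 0)
  expect_equal(rep_low$percent_correct_male, 100)

  only_f <- study_dataset(data.frame(
    individual_id = c("a", "b"), sex = "female", side = "left",
    burn_state = "unburnt", maxh = c(30, 31)))
  expect_error(evaluate_cutoff(only_f, "maxh", 35), "male")
})

test_that("evaluate_cutoff percentages are exact rational multiples of 100", {
  set.seed(91)
  d <- simulate_study(synthetic_config(seed = 91, missing_prob_burnt = 0.3))
  rep <- evaluate_cutoff(subset_ds(d, "burnt"), "maxw", 41)
  expect_equal((rep$percent_correct_female / 100) * rep$n_female,
               round((rep$percent_correct_female / 100) * rep$n_female))
  expect_equal((rep$percent_correct_total / 100) * (rep$n_female + rep$n_male),
               round((rep$percent_correct_total / 100) *
                       (rep$n_female + rep$n_male)))
})

test_that("calcined filter keeps only hot white burnt records", {
  d <- study_dataset(data.frame(
    individual_id = c("a", "b", "c", "d"),
    sex = c("F", "F", "M", "M"), side = "right", burn_state = "burnt",
    burn_temperature = c(1100, 700, 900, 900),
    burn_colour = c("white", "white", "black", "white"),
    maxh = c(30, 31, 40, 41)))
  kept <- filter_calcined(d)
  expect_equal(kept$individual_id, c("a", "d"))
  cold <- study_dataset(data.frame(
    individual_id = "x", sex = "F", side = "right", burn_state = "burnt",
    burn_temperature = 500, burn_colour = "black", maxh = 30))
  expect_warning(empty <- filter_calcined(cold), "no calcined")
  expect_equal(nrow(empty), 0)
})
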