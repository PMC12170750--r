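test_that("1-D toy model matches the hand computation", {
  d <- toy_1d_dataset()  # female {10, 12}, male {14, 16}: pooled var 2
  model <- fit_lda(d, "maxh")
  expect_equal(unname(model$coefficients), 1 / sqrt(2), tolerance = 1e-10)
  expect_equal(model$centroid_female, -sqrt(2), tolerance = 1e-10)
  expect_equal(model$centroid_male, sqrt(2), tolerance = 1e-10)
  expect_equal(model$threshold, 0, tolerance = 1e-10)
  # constant centres the case-weighted grand mean at score zero
  expect_equal(model$constant, -13 / sqrt(2), tolerance = 1e-10)
})

test_that("n-weighted centroid sum is zero and pooled score variance is one", {
  set.seed(101)
  for (i in 1:10) {
    d <- simulate_study(synthetic_config(seed = 200 + i,
                                         missing_prob_burnt = 0))
    model <- fit_lda(d, burn_state = "unburnt")
    nf <- model$group_sizes["female"]; nm <- model$group_sizes["male"]
    expect_lt(abs(nf * model$centroid_female + nm * model$centroid_male),
              1e-8)
    # recompute pooled within-group variance of the training scores
    df <- as.data.frame(d)[d$burn_state == "unburnt", ]
    y <- as.matrix(df[, names(model$coefficients)]) %*% model$coefficients +
      model$constant
    yf <- y[df$sex == "female"]; ym <- y[df$sex == "male"]
    pooled <- (sum((yf - mean(yf))^2) + sum((ym - mean(ym))^2)) /
      (length(yf) + length(ym) - 2)
    expect_equal(pooled, 1, tolerance = 1e-8)
    expect_gt(model$centroid_male, model$centroid_female)
  }
})

test_that("scoring the published combined coefficients reproduces the group-mean scores", {
  published <- list(coef = c(maxh = 0.159, maxt = -0.302, maxw = 0.193),
                    constant = -7.448)
  score_at <- function(v) sum(published$coef * v) + published$constant
  f_mean <- c(maxh = 33.33, maxt = 17.01, maxw = 34.90)
  m_mean <- c(maxh = 38.22, maxt = 18.26, maxw = 39.58)
  expect_equal(round(score_at(f_mean), 3), -0.550)
  expect_equal(round(score_at(m_mean), 3), 0.753)
})

test_that("score_lda is linear and errors on missing components", {
  d <- toy_1d_dataset()
  model <- fit_lda(d, "maxh")
  expect_equal(score_lda(model, c(maxh = 0)), model$constant)
  expect_error(score_lda(model, c(maxw = 3)), "missing component")
})

test_that("classification side and tie-break at the threshold", {
  d <- toy_1d_dataset()
  model <- fit_lda(d, "maxh")
  expect_equal(classify_lda(model, c(maxh = 15)), "male")
  expect_equal(classify_lda(model, c(maxh = 11)), "female")
  at_threshold <- c(maxh = 13)  # grand mean scores exactly 0 = threshold
  expect_equal(score_lda(model, at_threshold), model$threshold)
  expect_equal(classify_lda(model, at_threshold), "female")
})

test_that("resubstitution classification is invariant under affine rescaling", {
  d <- simulate_study(synthetic_config(seed = 303, missing_prob_burnt = 0))
  base <- resubstitution_lda(d, burn_state = "unburnt")
  df <- as.data.frame(d)
  df$maxh <- df$maxh / 2 + 3    # rescale plus shift, staying in-range
  df$maxt <- df$maxt * 2
  d2 <- study_dataset(df, provenance = "rescaled")
  rescaled <- resubstitution_lda(d2, burn_state = "unburnt")
  expect_equal(rescaled$percent_correct_total, base$percent_correct_total)
  expect_equal(rescaled$percent_correct_female, base$percent_correct_female)
})

test_that("model agrees with an independent reference implementation", {
  d <- simulate_study(synthetic_config(seed = 404, missing_prob_burnt = 0))
  df <- as.data.frame(d)[d$burn_state == "unburnt", ]
  model <- fit_lda(d, burn_state = "unburnt")
  ref <- MASS::lda(sex ~ maxh + maxt + maxw, data = df)
  # scalings agree up to sign/normalisation: directions must be collinear
  ang <- angle_deg(model$coefficients, ref$scaling[, 1])
  expect_lt(min(ang, 180 - ang), 0.01)
  # and the hard classifications agree case by case (equal priors)
  ref_pred <- as.character(predict(ref, df, prior = c(0.5, 0.5))$class)
  own_pred <- vapply(seq_len(nrow(df)), function(i) {
    classify_lda(model, unlist(df[i, c("maxh", "maxt", "maxw")]))
  }, character(1))
  expect_equal(own_pred, ref_pred)
})

test_that("LOOCV is perfect on the well-separated toy and matches resubstitution", {
  d <- toy_1d_dataset(female = c(10, 11, 12), male = c(20, 21, 22))
  cv <- loocv_lda(d, "maxh")
  expect_equal(cv$percent_correct_total, 100)
  expect_equal(resubstitution_lda(d, "maxh")$percent_correct_total, 100)
})

test_that("LOOCV is stable under duplication at large separation", {
  d <- toy_1d_dataset(female = c(10, 11, 12), male = c(20, 21, 22))
  df <- as.data.frame(d)
  df2 <- rbind(df, transform(df, individual_id = paste0(individual_id, "b")))
  dup <- study_dataset(df2, provenance = "dup")
  expect_equal(loocv_lda(dup, "maxh")$percent_correct_total,
               loocv_lda(d, "maxh")$percent_correct_total)
})

test_that("fitted direction converges to the population Fisher direction", {
  cfg <- burnt_params_config(seed = 555, n_female = 5000L, n_male = 5000L)
  d <- simulate_study(cfg)
  model <- fit_lda(d, burn_state = "unburnt")
  pop <- population_direction(cfg)
  expect_lt(angle_deg(model$coefficients, pop), 5)
})

test_that("degenerate fits are rejected informatively", {
  d <- toy_1d_dataset(female = c(10, 12), male = c(14, 16))
  df <- as.data.frame(d)
  df$maxt <- df$maxh        # perfectly collinear pair
  d2 <- study_dataset(df, provenance = "collinear")
  expect_error(fit_lda(d2, c("maxh", "maxt")), "singular")
  tiny <- toy_1d_dataset(female = c(10, 12), male = c(14, 16))
  expect_error(loocv_lda(tiny, "maxh"), "at least 3")
})
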