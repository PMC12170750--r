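# shared fixtures built in code

# a minimal hand-written dataset: 2 females, 2 males, one side each
toy_dataset <- function() {
  study_dataset(data.frame(
    individual_id = c("F1", "F2", "M1", "M2"),
    sex = c("F", "f", "male", "M"),
    age_at_death = c(70, 80, 75, 85),
    side = "left",
    burn_state = "unburnt",
    maxh = c(30, 36, 40, 34),
    maxt = c(16, 17, 19, 20),
    maxw = c(33, 35, 41, 39)),
    provenance = "toy")
}

# 1-D toy for discriminant hand-checks: the classic well-separated pairs
# {10, 12} vs {14, 16} (pooled within-group variance exactly 2); shift
# invariance makes the coefficient and centroids identical to the
# {0, 2}/{4, 6} textbook case while keeping measurements positive
toy_1d_dataset <- function(female = c(10, 12), male = c(14, 16)) {
  study_dataset(data.frame(
    individual_id = sprintf("I%d", seq_len(length(female) + length(male))),
    sex = rep(c("female", "male"), c(length(female), length(male))),
    side = "left", burn_state = "unburnt",
    maxh = c(female, male)), provenance = "toy-1d")
}

# burn-state subset that stays a study_dataset
subset_ds <- function(d, state) {
  study_dataset(as.data.frame(d)[d$burn_state == state, , drop = FALSE],
                provenance = state)
}

# random group_summary pairs for property tests (means ordered female < male)
random_summary_pair <- function() {
  mf <- runif(1, 10, 40)
  mm <- mf + runif(1, 0.5, 8)
  group_f <- group_summary(sample(5:40, 1), mf, runif(1, 0.5, 5),
                           mf - 5, mf + 5)
  group_m <- group_summary(sample(5:40, 1), mm, runif(1, 0.5, 5),
                           mm - 5, mm + 5)
  list(female = group_f, male = group_m)
}

# independent sectioning oracle: scan |log densityF - log densityM| over the
# closed interval between the means, refining the grid to a 1e-6 step; NA
# when the densities do not cross inside the interval
scan_cutoff <- function(female, male, final_step = 1e-6) {
  g <- function(x) {
    dnorm(x, female$mean, female$sd, log = TRUE) -
      dnorm(x, male$mean, male$sd, log = TRUE)
  }
  lo <- female$mean
  hi <- male$mean
  if (g(lo) * g(hi) > 0) return(NA_real_)
  step <- (hi - lo) / 2000
  repeat {
    grid <- seq(lo, hi, by = step)
    best <- grid[which.min(abs(g(grid)))]
    if (step <= final_step) return(best)
    lo <- best - 2 * step
    hi <- best + 2 * step
    step <- max(final_step, step / 1000)
  }
}

# population Fisher direction from generator parameters (pooled covariance)
population_direction <- function(config) {
  cov_of <- function(sds) diag(sds) %*% config$correlation %*% diag(sds)
  Sp <- (cov_of(config$sd_female) + cov_of(config$sd_male)) / 2
  solve(Sp, config$mean_male - config$mean_female)
}

angle_deg <- function(a, b) {
  cosang <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(min(max(cosang, -1), 1)) * 180 / pi
}

# synthetic_config matching the burnt-sample summary statistics, with the
# burning pathway disabled so the drawn values follow those distributions
burnt_params_config <- function(seed, n_female = 18L, n_male = 14L) {
  synthetic_config(
    n_female = n_female, n_male = n_male,
    mean_female = c(maxh = 33.33, maxt = 17.01, maxw = 34.90),
    mean_male = c(maxh = 38.22, maxt = 18.26, maxw = 39.58),
    sd_female = c(maxh = 4.53, maxt = 1.96, maxw = 4.43),
    sd_male = c(maxh = 4.23, maxt = 2.49, maxw = 3.35),
    correlation = 0.6,
    shrinkage_mean = c(female = 0, male = 0),
    shrinkage_sd = 0,
    missing_prob_burnt = 0,
    seed = seed)
}
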