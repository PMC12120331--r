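test_that("covariate generation spans the deployment conditions", {
  cfg <- deployment_config(seed = 11)
  cov <- generate_covariates(cfg)
  expect_equal(nrow(cov), 80)
  # trend endpoints within noise of the configured 27.5 -> 19.0 decline
  expect_lt(abs(cov$TPm_true[1] - 27.5), 4 * cfg$temp_daily_noise_sd)
  expect_lt(abs(cov$TPm_true[80] - 19.0), 4 * cfg$temp_daily_noise_sd)
  expect_true(all(cov$TPiq_true > 0))
  expect_true(all(cov$ACm_true > 0))
  expect_true(all(cov$TF >= 0 & cov$TF <= cfg$feed_max_tons))
  expect_true(any(cov$TF == 0))   # fasting spells occur
})

test_that("degenerate and invalid deployment spans are handled", {
  cov0 <- generate_covariates(deployment_config(n_days = 0))
  expect_equal(nrow(cov0), 0)
  expect_error(deployment_config(n_days = -1), "n_days")
  expect_error(deployment_config(qi_bad_prob = 1.5), "probabilities")
  expect_error(deployment_config(hr_bounds = c(120, 8)), "hr_bounds")
})

test_that("generators are deterministic given config and seed", {
  cfg <- deployment_config(seed = 99)
  a <- simulate_deployment(cfg)
  b <- simulate_deployment(cfg)
  expect_identical(a$covariates, b$covariates)
  expect_identical(a$hr_true, b$hr_true)
  expect_identical(a$records, b$records)
  c <- simulate_deployment(deployment_config(seed = 100))
  expect_false(identical(a$records$hr_bpm, c$records$hr_bpm))
})

test_that("daily heart rates are Poisson draws around the model mean", {
  # constant covariates over many replicate days: sample mean ~ mu
  n <- 400
  cov <- data.frame(date = as.Date("2021-08-01") + seq_len(n) - 1,
                    TPm_true = 23, TPiq_true = 1, ACm_true = 30, TF = 5)
  hr <- generate_hr_series(cov, best_model_params(), seed = 21)
  mu <- 50.188  # centered covariates vanish when constant
  expect_lt(abs(mean(hr) - mu), 3 * sqrt(mu / n))
  expect_true(all(hr == round(hr)))
})

test_that("feeding raises heart rate by beta_minus per ton below threshold", {
  # paired days identical except TF = 0 vs 10 t, all below the threshold:
  # expected HRm difference is 10 * beta_minus
  n_pairs <- 3000
  cov <- data.frame(date = as.Date("2021-08-01") + seq_len(2 * n_pairs) - 1,
                    TPm_true = 22, TPiq_true = 1, ACm_true = 30,
                    TF = rep(c(0, 10), n_pairs))
  hr <- generate_hr_series(cov, best_model_params(), seed = 31)
  d <- hr[seq(2, 2 * n_pairs, 2)] - hr[seq(1, 2 * n_pairs, 2)]
  expected <- 10 * 1.831
  mc_sd <- sqrt(2 * 50 / n_pairs)   # var(HR2 - HR1) ~ mu1 + mu2 ~ 100
  expect_lt(abs(mean(d) - expected), 3 * mc_sd)
})

test_that("above the threshold the feeding slope is the small beta_plus", {
  n <- 4000
  set.seed(41)
  cov <- data.frame(date = as.Date("2021-08-01") + seq_len(n) - 1,
                    TPm_true = 26.5, TPiq_true = 0.5, ACm_true = 30,
                    TF = runif(n, 0, 15))
  hr <- generate_hr_series(cov, best_model_params(), seed = 42)
  sl <- summary(lm(hr ~ cov$TF))$coefficients[2, ]
  # recovered slope matches beta_plus = 0.313, whose reported 95% CI spans 0
  expect_lt(abs(sl["Estimate"] - 0.313), 3 * sl["Std. Error"])
})

test_that("infeasible generating parameters raise a generation error", {
  cov <- data.frame(date = as.Date("2021-08-01") + 0:4,
                    TPm_true = 22, TPiq_true = 1, ACm_true = 30, TF = 0:4)
  bad <- model_params(best_model_spec(), alpha = 0.1, betas = c(TPm = 2),
                      beta_plus = 0.3, beta_minus = 1.8, thresh = 25)
  expect_error(generate_hr_series(cov, bad, seed = 1), "non-positive")
})

test_that("logger record stream has the configured shape and corruption", {
  cfg <- deployment_config(seed = 5)
  sim <- simulate_deployment(cfg)
  expect_equal(nrow(sim$records), 80 * 144)
  expect_true(all(sim$records$qi %in% 0:3))
  # clean stream: everything passes QC
  clean <- deployment_config(seed = 6, qi_bad_prob = 0, oob_bad_frac = 0)
  simc <- simulate_deployment(clean)
  qc <- filter_records(simc$records)
  expect_equal(qc$report$pass_fraction, 1)
  # default corruption: pass fraction ~ 0.85 (pair-level binomial error)
  qc2 <- filter_records(sim$records)
  tol <- 4 * sqrt(0.85 * 0.15 / (80 * 144 / 2))
  expect_lt(abs(qc2$report$pass_fraction - 0.85), tol + 0.005)
  expect_error(generate_logger_records(sim$covariates, sim$hr_true[-1], cfg),
               "spans differ")
})

test_that("QC pass fraction decomposes into QI and out-of-bounds corruption", {
  cfg <- deployment_config(seed = 8, qi_bad_prob = 0.2, hr_oob_prob = 0.1,
                           oob_bad_frac = 0)
  sim <- simulate_deployment(cfg)
  qc <- filter_records(sim$records)
  expected <- (1 - 0.2) * (1 - 0.1)
  tol <- 4 * sqrt(expected * (1 - expected) / (80 * 144 / 2))
  expect_lt(abs(qc$report$pass_fraction - expected), tol + 0.005)
})

test_that("deployment-level median of usable heart rates sits near 50 bpm", {
  for (s in c(1, 7, 123)) {
    sim <- simulate_deployment(deployment_config(seed = s))
    qc <- filter_records(sim$records)
    expect_lt(abs(median(qc$records$hr_bpm) - 50), 3)
  }
})

test_that("within-day construction preserves the daily median heart rate", {
  sim <- simulate_deployment(deployment_config(seed = 17))
  # on the raw clean stream the within-day median equals truth by symmetry
  clean <- simulate_deployment(deployment_config(seed = 18, qi_bad_prob = 0))
  day <- as.Date(clean$records$timestamp, tz = "UTC")
  med <- tapply(clean$records$hr_bpm, day, function(x) floor(median(x) + 0.5))
  expect_true(mean(med == clean$hr_true) >= 0.95)
  # and it survives quality control on the corrupted stream
  qc <- filter_records(sim$records)
  daily <- daily_summaries(qc$records, sim$feeding)
  truth <- sim$hr_true[match(daily$date, sim$covariates$date)]
  expect_true(mean(daily$HRm == truth) >= 0.95)
})

test_that("synthetic ECG bursts have the requested beat geometry", {
  tr <- synth_ecg(60, duration_s = 10, sample_rate = 200)
  expect_length(tr$amplitude, 2000)
  expect_length(tr$r_times, 10)
  expect_equal(diff(tr$r_times), rep(1, 9))
  tr43 <- synth_ecg(43, duration_s = 7.5, sample_rate = 200)
  expect_equal(unique(round(diff(tr43$r_times), 4)), round(60 / 43, 4))
  # noiseless traces are exactly periodic and reproducible
  expect_identical(synth_ecg(50)$amplitude, synth_ecg(50)$amplitude)
  expect_error(synth_ecg(-10), "argument error")
  expect_error(synth_ecg(60, duration_s = 0), "argument error")
})

test_that("synthetic acceleration bursts carry the target activity level", {
  b <- synth_accel_burst(target_ea_mg = 50, seed = 3)
  expect_length(b$ax, 25 * 60)
  ea <- external_acceleration(b)
  expect_lt(abs(ea$avg_ea - 50) / 50, 0.15)
})
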