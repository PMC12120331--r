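test_that("the linear predictor applies the switched slope on the identity scale", {
  # intercept-only: mu is alpha everywhere
  p0 <- model_params(model_spec(character(0)), alpha = 50)
  rows <- data.frame(TF = c(0, 10), TPm = c(20, 26), TPiq = c(1, 2),
                     ACm = c(30, 35))
  expect_equal(evaluate_mu(p0, rows), c(50, 50))

  # best-model structure at the reported posterior means, hand-computed with
  # mean-centered covariates and the uncentered temperature for the switch
  pb <- best_model_params()
  d <- data.frame(TF = c(5, 12, 0), TPm = c(20, 26.5, 24))
  ctf <- d$TF - mean(d$TF); ctp <- d$TPm - mean(d$TPm)
  slope <- ifelse(d$TPm > 25.462, 0.313, 1.831)
  by_hand <- 50.188 + 2.137 * ctp + slope * ctf
  expect_equal(evaluate_mu(pb, d), by_hand)

  # equality at the threshold falls in the below branch
  pe <- model_params(best_model_spec(), alpha = 50, betas = c(TPm = 0),
                     beta_plus = 10, beta_minus = 1, thresh = 25)
  de <- data.frame(TF = c(1, 1, 1), TPm = c(25, 25 + 1e-9, 24))
  mu <- evaluate_mu(pe, de, center = FALSE)
  expect_equal(mu, c(51, 60, 51))
})

test_that("a threshold model with equal switched slopes degenerates exactly", {
  set.seed(3)
  d <- data.frame(HRm = rpois(30, 50), TF = runif(30, 0, 20),
                  TPm = runif(30, 19, 28))
  pt <- model_params(best_model_spec(), alpha = 48, betas = c(TPm = 2),
                     beta_plus = 1.2, beta_minus = 1.2, thresh = 24)
  pl <- model_params(model_spec(c("TF", "TPm")), alpha = 48,
                     betas = c(TF = 1.2, TPm = 2))
  expect_identical(evaluate_mu(pt, d), evaluate_mu(pl, d))
  expect_identical(log_likelihood(pt, d), log_likelihood(pl, d))
})

test_that("the Poisson log-likelihood matches closed forms", {
  p <- function(a) model_params(model_spec(character(0)), alpha = a)
  d0 <- data.frame(HRm = 0L, TF = 1, TPm = 1, TPiq = 1, ACm = 1)
  expect_equal(log_likelihood(p(1), d0), -1)
  d2 <- data.frame(HRm = 2L, TF = 1, TPm = 1, TPiq = 1, ACm = 1)
  expect_equal(log_likelihood(p(2), d2), log(2) - 2)
  # non-positive mu yields the -Inf sentinel
  expect_identical(log_likelihood(p(0), d2), -Inf)
  expect_identical(log_likelihood(p(-3), d2), -Inf)
  d_bad <- data.frame(HRm = 2.5, TF = 1, TPm = 1, TPiq = 1, ACm = 1)
  expect_error(log_likelihood(p(2), d_bad), "integer")
})

test_that("the candidate set is the 21 nested structures", {
  ms <- enumerate_models()
  expect_length(ms, 21)
  labels <- vapply(ms, function(m) m$label, character(1))
  expect_identical(anyDuplicated(labels), 0L)
  # the best-supported structure: feeding slope switched by temperature
  best <- ms[[1]]
  expect_identical(best$label, "alpha + TF:thresh + TPm")
  expect_identical(best$covariates, c("TF", "TPm"))
  expect_identical(best$modulated, "TF")
  expect_identical(best$governing, "TPm")
  # the null structure
  expect_identical(labels[20], "alpha")
  expect_length(ms[[20]]$covariates, 0)
  # feeding-only threshold rows are still governed by temperature
  tf_alone <- ms[[15]]
  expect_identical(tf_alone$covariates, "TF")
  expect_identical(tf_alone$governing, "TPm")
  # temperature variables threshold on themselves
  expect_identical(ms[[21]]$governing, "TPiq")
  expect_identical(ms[[18]]$governing, "TPm")
  # at most one threshold anywhere
  expect_true(all(vapply(ms, function(m) length(m$modulated) <= 1,
                         logical(1))))
})

test_that("invalid model structures are rejected", {
  expect_error(model_spec("TF", modulated = "TPm"), "modulated")
  expect_error(model_spec(c("TF", "XX")), "unknown")
  expect_error(model_params(best_model_spec(), alpha = 50,
                            betas = c(TPm = 2)), "threshold model requires")
})

test_that("MCMC matches dense-grid integration on the intercept-only model", {
  set.seed(12)
  d <- data.frame(HRm = rpois(8, 47))
  oracle <- grid_posterior_alpha(d$HRm)
  dr <- sample_posterior(model_spec(character(0)), d,
                         mcmc = mcmc_config(n_chains = 3, n_burn = 2000,
                                            n_keep = 10000, seed = 7))
  po <- do.call(rbind, dr$chains)
  expect_lt(abs(mean(po[, "alpha"]) - oracle$mean), 0.02 * oracle$sd)
  expect_lt(abs(sd(po[, "alpha"]) - oracle$sd), 0.02 * oracle$sd)
})

test_that("MCMC matches dense-grid integration on a two-parameter model", {
  set.seed(13)
  x <- seq(-2, 2, length.out = 10)
  d <- data.frame(HRm = rpois(10, 50 + 3 * x), TF = x + 10)
  oracle <- grid_posterior_slope(d$HRm, d$TF - mean(d$TF))
  dr <- sample_posterior(model_spec("TF"), d,
                         mcmc = mcmc_config(n_chains = 3, n_burn = 2000,
                                            n_keep = 25000, seed = 8))
  po <- do.call(rbind, dr$chains)
  expect_lt(abs(mean(po[, "alpha"]) - oracle$alpha_mean),
            0.02 * oracle$alpha_sd)
  expect_lt(abs(mean(po[, "beta_TF"]) - oracle$beta_mean),
            0.02 * oracle$beta_sd)
  expect_lt(abs(sd(po[, "beta_TF"]) - oracle$beta_sd), 0.02 * oracle$beta_sd)
})

test_that("the sampler is reproducible and respects positivity", {
  d <- make_daily(seed = 300)
  mc <- mcmc_config(n_burn = 500, n_keep = 800, seed = 5)
  a <- sample_posterior(best_model_spec(), d, mcmc = mc)
  b <- sample_posterior(best_model_spec(), d, mcmc = mc)
  expect_identical(a$chains, b$chains)
  # every retained draw has finite likelihood (mu > 0 throughout)
  expect_true(all(is.finite(unlist(a$loglik))))
  # thresholds stay inside the admissible prior interval
  po <- do.call(rbind, a$chains)
  expect_true(all(po[, "thresh"] >= a$thresh_range[1] &
                    po[, "thresh"] <= a$thresh_range[2]))
})

test_that("null covariate effects are covered by the credible interval", {
  # data with no temperature effect: the TPm interval should cover 0 in
  # at least 90% of replicates
  hits <- 0L
  for (r in 1:20) {
    set.seed(400 + r)
    d <- data.frame(HRm = rpois(40, 50), TPm = seq(27, 19, length.out = 40))
    fit <- fit_model(model_spec("TPm"), d,
                     mcmc = mcmc_config(n_chains = 2, n_burn = 1000,
                                        n_keep = 2000, seed = 500 + r))
    ci <- fit$summary[fit$summary$parameter == "beta_TPm",
                      c("q2.5", "q97.5")]
    if (ci$q2.5 <= 0 && 0 <= ci$q97.5) hits <- hits + 1L
  }
  expect_gte(hits, 18L)
})

test_that("DIC decomposes into mean deviance and effective parameters", {
  # degenerate chains of one repeated draw: pD = 0, DIC = D(theta_hat)
  d <- data.frame(HRm = c(48L, 52L, 50L))
  spec0 <- model_spec(character(0))
  theta <- matrix(50, nrow = 200, ncol = 1,
                  dimnames = list(NULL, "alpha"))
  ll <- rep(sum(dpois(d$HRm, 50, log = TRUE)), 200)
  dg <- fake_draws(list(theta, theta), list(ll, ll), spec0, d)
  dic <- compute_dic(dg, d)
  expect_equal(dic$pD, 0)
  expect_equal(dic$DIC, -2 * sum(dpois(d$HRm, 50, log = TRUE)))
  expect_equal(dic$DIC, dic$Dbar + dic$pD)

  # two-draw chain, hand arithmetic on a 2-observation dataset
  d2 <- data.frame(HRm = c(45L, 55L))
  draws2 <- matrix(c(48, 52), ncol = 1, dimnames = list(NULL, "alpha"))
  ll2 <- c(sum(dpois(d2$HRm, 48, log = TRUE)),
           sum(dpois(d2$HRm, 52, log = TRUE)))
  dg2 <- fake_draws(list(draws2, draws2), list(ll2, ll2), spec0, d2)
  dic2 <- compute_dic(dg2, d2)
  D1 <- -2 * ll2[1]; D2 <- -2 * ll2[2]
  Dbar <- (D1 + D2) / 2
  Dhat <- -2 * sum(dpois(d2$HRm, 50, log = TRUE))   # mean draw is 50
  expect_equal(dic2$Dbar, Dbar)
  expect_equal(dic2$pD, Dbar - Dhat)
  expect_equal(dic2$DIC, Dbar + (Dbar - Dhat))
})

test_that("R-squared at posterior-mean predictions matches hand arithmetic", {
  spec <- model_spec("TF")
  d <- data.frame(HRm = c(10L, 20L), TF = c(0, 1))
  # posterior mean alpha = 15, beta = 6 -> mu = {12, 18} after centering
  th <- matrix(rep(c(15, 6), each = 50), ncol = 2,
               dimnames = list(NULL, c("alpha", "beta_TF")))
  dg <- fake_draws(list(th, th), list(rep(0, 50), rep(0, 50)), spec, d)
  expect_equal(compute_r2(dg, d), 1 - (4 + 4) / 50)   # 0.84
  # predicting the mean gives exactly zero
  th0 <- matrix(rep(c(15, 0), each = 50), ncol = 2,
                dimnames = list(NULL, c("alpha", "beta_TF")))
  dg0 <- fake_draws(list(th0, th0), list(rep(0, 50), rep(0, 50)), spec, d)
  expect_equal(compute_r2(dg0, d), 0)
  # perfect prediction gives exactly one
  th1 <- matrix(rep(c(15, 10), each = 50), ncol = 2,
                dimnames = list(NULL, c("alpha", "beta_TF")))
  dg1 <- fake_draws(list(th1, th1), list(rep(0, 50), rep(0, 50)), spec, d)
  expect_equal(compute_r2(dg1, d), 1)
  dc <- data.frame(HRm = c(12L, 12L), TF = c(0, 1))
  expect_error(compute_r2(dg, dc), "constant HRm")
})

test_that("Gelman-Rubin diagnostics separate mixed from stuck chains", {
  set.seed(31)
  n <- 2000
  base <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "alpha"))
  # duplicated chains: R-hat = 1 up to the (n-1)/n finite-sample factor
  expect_equal(unname(compute_rhat(list(base, base))), 1, tolerance = 1e-3)
  # chains centered 100 apart with unit spread: closed-form B/W blowup
  far <- base + 100
  rh <- compute_rhat(list(base, far))
  expect_gt(unname(rh), 10)
  expect_error(compute_rhat(list(base)), "2 chains")
})

test_that("model ranking orders by DIC and flags close competitors", {
  mk_fit <- function(spec, dic, pd = 3, r2 = 0.5)
    structure(list(spec = spec, DIC = dic, pD = pd, R2 = r2),
              class = "ctag_fit")
  specs <- enumerate_models()[c(20, 16, 6)]   # null, TF, TF+TPm
  fits <- list(mk_fit(specs[[3]], 101), mk_fit(specs[[2]], 120),
               mk_fit(specs[[1]], 100))
  rk <- select_best(fits)
  expect_equal(rk$dDIC[1], 0)
  expect_identical(rk$model[1], "alpha")
  expect_true(rk$within_5[rk$model == "alpha + TF + TPm"])
  expect_false(rk$within_5[rk$model == "alpha + TF"])
  # undefined DIC excluded with a warning
  fits2 <- c(fits, list(mk_fit(specs[[2]], NA_real_)))
  expect_warning(rk2 <- select_best(fits2), "undefined DIC")
  expect_equal(nrow(rk2), 3)
})

test_that("the generating structure is selected over rival structures", {
  # majority vote across seeded replicates, full 21-model scan per replicate
  wins <- 0L
  n_rep <- 10L
  for (r in seq_len(n_rep)) {
    d <- make_daily(seed = 600 + r)
    fits <- lapply(seq_len(21), function(i)
      suppressWarnings(
        fit_model(enumerate_models()[[i]], d,
                  mcmc = mcmc_config(n_burn = 800, n_keep = 1500,
                                     seed = 700 + 21L * r + i))))
    rk <- suppressWarnings(select_best(fits))
    if (rk$model[1] == "alpha + TF:thresh + TPm") wins <- wins + 1L
  }
  expect_gt(wins, n_rep / 2)
})
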