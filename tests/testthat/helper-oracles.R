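# Independent numerical oracles and small fixture builders used across tests.

# a daily covariate table drawn from the generator truth, under the model's
# column names
make_daily <- function(seed, n_days = 80, params = best_model_params()) {
  cfg <- deployment_config(n_days = n_days, seed = seed)
  cov <- generate_covariates(cfg)
  hr <- generate_hr_series(cov, params, seed = seed + 5000L)
  data.frame(date = cov$date, HRm = hr, TF = cov$TF, TPm = cov$TPm_true,
             TPiq = cov$TPiq_true, ACm = cov$ACm_true)
}

# dense-grid posterior mean/sd for the intercept-only Poisson model with a
# Normal(0, prior_sd) prior on alpha -- brute-force integration, no MCMC
grid_posterior_alpha <- function(y, prior_sd = 100, n_grid = 40001) {
  m <- mean(y)
  s <- sqrt(m / length(y))
  grid <- seq(max(1e-6, m - 10 * s), m + 10 * s, length.out = n_grid)
  lp <- vapply(grid, function(a)
    sum(dpois(y, a, log = TRUE)) + dnorm(a, 0, prior_sd, log = TRUE),
    numeric(1))
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  mu <- sum(w * grid)
  list(mean = mu, sd = sqrt(sum(w * (grid - mu)^2)))
}

# dense-grid posterior for a two-parameter model mu = alpha + beta * x
# (x already centered); returns marginal means/sds for alpha and beta
grid_posterior_slope <- function(y, x, prior_sd = 100, n_grid = 501) {
  fit <- lm(y ~ x)
  ctr <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  a_grid <- seq(ctr[1] - 9 * se[1], ctr[1] + 9 * se[1], length.out = n_grid)
  b_grid <- seq(ctr[2] - 9 * se[2], ctr[2] + 9 * se[2], length.out = n_grid)
  lp <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    mu_i <- a_grid[i] + outer(x, b_grid)   # n x n_grid
    bad <- mu_i <= 0
    ll <- dpois(y, pmax(mu_i, 1e-12), log = TRUE)
    ll[bad] <- -Inf
    lp[i, ] <- colSums(ll) + dnorm(a_grid[i], 0, prior_sd, log = TRUE) +
      dnorm(b_grid, 0, prior_sd, log = TRUE)
  }
  w <- exp(lp - max(lp))
  w <- w / sum(w)
  wa <- rowSums(w)
  wb <- colSums(w)
  am <- sum(wa * a_grid); bm <- sum(wb * b_grid)
  list(alpha_mean = am, alpha_sd = sqrt(sum(wa * (a_grid - am)^2)),
       beta_mean = bm, beta_sd = sqrt(sum(wb * (b_grid - bm)^2)))
}

# minimal hand-built posterior-draws object for testing the summary
# statistics on known chains
fake_draws <- function(chains, loglik, spec, data, center = TRUE) {
  centers <- if (center) {
    cv <- spec$covariates
    stats::setNames(vapply(cv, function(v) mean(data[[v]]), numeric(1)), cv)
  } else NULL
  structure(list(chains = chains, loglik = loglik, spec = spec,
                 centers = centers, center = center,
                 thresh_range = NULL,
                 acceptance = NULL,
                 mcmc = mcmc_config(n_chains = length(chains), n_burn = 0,
                                    n_keep = nrow(chains[[1]])),
                 priors = prior_config(), n_obs = nrow(data)),
            class = "ctag_draws")
}
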