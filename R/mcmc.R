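#' MCMC sampler settings
#'
#' Defaults follow the analysis protocol: three parallel chains, 10,000
#' retained draws per chain after a 10,000-draw burn-in, with componentwise
#' random-walk step sizes adapted during burn-in only.
#'
#' @param n_chains number of chains (>= 2 for convergence diagnostics).
#' @param n_burn burn-in draws per chain, discarded.
#' @param n_keep retained draws per chain.
#' @param adapt adapt proposal step sizes during burn-in (Robbins-Monro,
#'   target acceptance 0.44), frozen before retention.
#' @param seed integer seed for the sampler.
#' @export
mcmc_config <- function(n_chains = 3, n_burn = 10000, n_keep = 10000,
                        adapt = TRUE, seed = 1L) {
  stopifnot(n_chains >= 1, n_burn >= 0, n_keep >= 1)
  structure(list(n_chains = as.integer(n_chains), n_burn = as.integer(n_burn),
                 n_keep = as.integer(n_keep), adapt = isTRUE(adapt),
                 seed = as.integer(seed)),
            class = "ctag_mcmc")
}

#' Prior settings
#'
#' Proper but diffuse priors: Normal(0, sd \code{coef_sd}) on the intercept
#' and all slopes; the threshold is uniform over the central range of the
#' governing covariate (between its \code{q_lo} and \code{q_hi} quantiles),
#' further constrained so at least \code{min_side} observations fall on each
#' side, which keeps the switched slopes identifiable.
#'
#' @param coef_sd prior SD for intercept and slopes (bpm scale).
#' @param q_lo,q_hi quantile bounds of the uniform threshold prior.
#' @param min_side minimum observations required on each side of any
#'   admissible threshold.
#' @export
prior_config <- function(coef_sd = 100, q_lo = 0.10, q_hi = 0.90,
                         min_side = 3L) {
  stopifnot(coef_sd > 0, q_lo < q_hi, min_side >= 1)
  structure(list(coef_sd = coef_sd, q_lo = q_lo, q_hi = q_hi,
                 min_side = as.integer(min_side)),
            class = "ctag_prior")
}

# admissible threshold interval for a governing covariate
thresh_range <- function(g, priors) {
  gs <- sort(g)
  n <- length(gs)
  if (n < 2L * priors$min_side + 1L)
    stop("too few observations to identify a threshold")
  lo <- max(unname(quantile(g, priors$q_lo, type = 7)), gs[priors$min_side])
  hi <- min(unname(quantile(g, priors$q_hi, type = 7)), gs[n - priors$min_side])
  if (!(lo < hi))
    stop("governing covariate leaves no admissible threshold interval")
  c(lo, hi)
}

# design pieces shared by the sampler and posterior summaries
build_design <- function(spec, data, center = TRUE, centers = NULL) {
  lin <- setdiff(spec$covariates, spec$modulated)
  if (center && is.null(centers))
    centers <- covariate_centers(data, spec$covariates)
  ctr <- function(cv) {
    x <- data[[cv]]
    if (center) x - centers[[cv]] else x
  }
  X <- if (length(lin))
    do.call(cbind, lapply(lin, ctr))
  else
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  has_thr <- !is.null(spec$modulated)
  list(X = X, lin = lin,
       xm = if (has_thr) ctr(spec$modulated) else numeric(0),
       gov = if (has_thr) data[[spec$governing]] else numeric(0),
       has_thresh = has_thr, centers = centers)
}

# method-of-moments starting values: an OLS fit of HRm on the centered
# covariates (modulated covariate entered un-switched)
mom_start <- function(spec, data, des) {
  y <- data$HRm
  Xall <- des$X
  nm <- if (length(des$lin)) des$lin else character(0)
  if (des$has_thresh) {
    Xall <- cbind(Xall, des$xm)
    nm <- c(nm, spec$modulated)
  }
  if (ncol(Xall) == 0) {
    est <- mean(y)
    se <- sd(y) / sqrt(length(y))
    if (!is.finite(se) || se == 0) se <- max(1, abs(est) * 0.1)
    return(list(est = c(alpha = est), se = c(alpha = se)))
  }
  df <- data.frame(y = y, Xall)
  names(df) <- c("y", nm)
  fit <- lm(y ~ ., data = df)
  cf <- coef(fit)
  sm <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) abs(cf) * 0 + 1)
  sm[!is.finite(sm) | sm == 0] <- 1
  list(est = setNames(as.numeric(cf), c("alpha", nm)),
       se = setNames(as.numeric(sm), c("alpha", nm)))
}

#' Draw from the posterior of a threshold Poisson regression
#'
#' Componentwise Gaussian random-walk Metropolis (Metropolis-within-Gibbs)
#' over the model's parameters, with the positivity constraint
#' \eqn{\mu_t > 0} enforced by rejection and the threshold restricted to its
#' admissible prior interval. Chains are initialised by overdispersed draws
#' around ordinary-least-squares estimates; step sizes adapt during burn-in
#' only. Fully reproducible given \code{mcmc$seed}.
#'
#' @param spec a \code{\link{model_spec}}.
#' @param data daily summary data frame with integer \code{HRm} and the
#'   covariate columns.
#' @param mcmc a \code{\link{mcmc_config}}.
#' @param priors a \code{\link{prior_config}}.
#' @param center mean-center covariates (threshold always compared on the
#'   uncentered governing covariate).
#' @return an object of class \code{ctag_draws}: per-chain draw matrices
#'   (columns in \code{param_names} order), per-draw log-likelihoods,
#'   acceptance rates, the centering constants and threshold interval used.
#' @export
sample_posterior <- function(spec, data, mcmc = mcmc_config(),
                             priors = prior_config(), center = TRUE) {
  stopifnot(inherits(spec, "ctag_spec"), nrow(data) >= 1)
  y <- data$HRm
  if (is.null(y) || any(y < 0) || any(y != round(y)))
    stop("data$HRm must be non-negative integers")
  des <- build_design(spec, data, center = center)
  tr <- if (des$has_thresh) thresh_range(des$gov, priors) else c(0, 0)
  nm <- param_names(spec)
  p <- length(nm)
  start <- mom_start(spec, data, des)

  set.seed(mcmc$seed)
  chains <- vector("list", mcmc$n_chains)
  logliks <- vector("list", mcmc$n_chains)
  acc <- matrix(NA_real_, mcmc$n_chains, p, dimnames = list(NULL, nm))
  for (ch in seq_len(mcmc$n_chains)) {
    init <- chain_init(spec, start, tr, des, data, nm)
    # initial step sizes from the OLS standard errors; adaptation refines them
    base <- sub("^beta_(plus_|minus_)?", "", nm)
    base[nm == "alpha"] <- "alpha"
    scale0 <- unname(start$se[base])
    scale0[!is.finite(scale0) | scale0 <= 0] <- 0.5
    if (des$has_thresh) scale0[p] <- (tr[2] - tr[1]) / 10
    res <- cpp_rwm_chain(as.numeric(y), des$X, des$xm, des$gov,
                         des$has_thresh, tr[1], tr[2],
                         init, scale0, mcmc$n_burn, mcmc$n_keep,
                         mcmc$adapt, priors$coef_sd, 0.44)
    if (any(res$accepted == 0L))
      stop("sampler failure: zero post-burn-in acceptance for parameter(s) ",
           paste(nm[res$accepted == 0L], collapse = ", "),
           " (final step sizes: ",
           paste(signif(res$scale, 3), collapse = ", "), ")")
    colnames(res$draws) <- nm
    chains[[ch]] <- res$draws
    logliks[[ch]] <- res$loglik
    acc[ch, ] <- res$accepted / res$proposed
  }
  structure(list(chains = chains, loglik = logliks, spec = spec,
                 centers = des$centers, center = center,
                 thresh_range = if (des$has_thresh) tr else NULL,
                 acceptance = acc, mcmc = mcmc, priors = priors,
                 n_obs = nrow(data)),
            class = "ctag_draws")
}

# overdispersed feasible initial state for one chain
chain_init <- function(spec, start, tr, des, data, nm) {
  p <- length(nm)
  for (try in seq_len(200L)) {
    shrink <- 0.98^try
    init <- numeric(p)
    names(init) <- nm
    init["alpha"] <- start$est[["alpha"]] +
      rnorm(1, 0, 2 * start$se[["alpha"]] * shrink)
    for (cv in setdiff(spec$covariates, spec$modulated))
      init[paste0("beta_", cv)] <- start$est[[cv]] +
        rnorm(1, 0, 2 * start$se[[cv]] * shrink)
    if (!is.null(spec$modulated)) {
      b0 <- start$est[[spec$modulated]]
      s0 <- start$se[[spec$modulated]]
      init[paste0("beta_plus_", spec$modulated)] <- b0 + rnorm(1, 0, 2 * s0 * shrink)
      init[paste0("beta_minus_", spec$modulated)] <- b0 + rnorm(1, 0, 2 * s0 * shrink)
      init["thresh"] <- runif(1, tr[1], tr[2])
    }
    params <- params_from_vector(spec, init)
    mu <- evaluate_mu(params, data, center = !is.null(des$centers),
                      centers = des$centers)
    if (all(mu > 0)) return(unname(init))
  }
  stop("could not find a feasible (all mu > 0) initial state")
}

# pooled retained draws as one matrix
pool_draws <- function(draws) do.call(rbind, draws$chains)

# mu for every draw (rows) and every day (columns), fully vectorized
mu_draw_matrix <- function(draws, theta, data) {
  spec <- draws$spec
  des <- build_design(spec, data, center = draws$center,
                      centers = draws$centers)
  R <- nrow(theta)
  n <- nrow(data)
  mu <- matrix(theta[, "alpha"], R, n)
  for (cv in des$lin)
    mu <- mu + outer(theta[, paste0("beta_", cv)], des$X[, match(cv, des$lin)])
  if (des$has_thresh) {
    above <- outer(theta[, "thresh"], des$gov, FUN = function(th, g) g > th)
    slope <- ifelse(above, theta[, paste0("beta_plus_", spec$modulated)],
                    theta[, paste0("beta_minus_", spec$modulated)])
    mu <- mu + slope * matrix(des$xm, R, n, byrow = TRUE)
  }
  mu
}

#' Deviance information criterion
#'
#' \eqn{D(\theta) = -2 \log L(\theta)}; \code{Dbar} is the posterior mean
#' deviance over pooled retained draws, \code{pD = Dbar - D(\bar\theta)} at
#' the pooled posterior mean \eqn{\bar\theta}, and \code{DIC = Dbar + pD}.
#' \code{pD} can be negative in pathological fits and is reported as-is with
#' a warning.
#'
#' @param draws a \code{ctag_draws} object from \code{\link{sample_posterior}}.
#' @param data the data the draws were fit to.
#' @return list with \code{Dbar}, \code{pD}, \code{DIC}.
#' @export
compute_dic <- function(draws, data) {
  stopifnot(inherits(draws, "ctag_draws"))
  ll <- unlist(draws$loglik)
  if (!all(is.finite(ll)))
    stop("non-finite log-likelihood among retained draws")
  Dbar <- mean(-2 * ll)
  theta_bar <- colMeans(pool_draws(draws))
  params <- params_from_vector(draws$spec, theta_bar)
  ll_hat <- log_likelihood(params, data, center = draws$center,
                           centers = draws$centers)
  if (!is.finite(ll_hat))
    stop("posterior-mean state infeasible (mu <= 0); DIC undefined")
  pD <- Dbar - (-2 * ll_hat)
  if (pD < 0)
    warning("negative pD (", signif(pD, 3), "); reported as-is")
  list(Dbar = Dbar, pD = pD, DIC = Dbar + pD)
}

#' Classical R-squared at posterior-mean predictions
#'
#' \eqn{R^2 = 1 - \sum_t (HRm_t - \hat\mu_t)^2 / \sum_t (HRm_t -
#' \overline{HRm})^2}, with \eqn{\hat\mu_t} evaluated at the pooled posterior
#' means. Can be negative for models fitting worse than the mean.
#'
#' @inheritParams compute_dic
#' @export
compute_r2 <- function(draws, data) {
  stopifnot(inherits(draws, "ctag_draws"))
  y <- data$HRm
  sst <- sum((y - mean(y))^2)
  if (sst == 0) stop("constant HRm: R-squared undefined")
  params <- params_from_vector(draws$spec, colMeans(pool_draws(draws)))
  mu_hat <- evaluate_mu(params, data, center = draws$center,
                        centers = draws$centers)
  1 - sum((y - mu_hat)^2) / sst
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Classical (non-split) \eqn{\hat R} from between- and within-chain
#' variances, per parameter. Values near 1 indicate convergence; 1.1 is the
#' usual cutoff.
#'
#' @param draws a \code{ctag_draws} object, or a list of equal-size draw
#'   matrices (one per chain).
#' @export
compute_rhat <- function(draws) {
  chains <- if (inherits(draws, "ctag_draws")) draws$chains else draws
  m <- length(chains)
  if (m < 2L) stop("convergence diagnostics need at least 2 chains")
  n <- nrow(chains[[1]])
  if (!all(vapply(chains, nrow, 0L) == n)) stop("chains of unequal length")
  p <- ncol(chains[[1]])
  rhat <- numeric(p)
  for (j in seq_len(p)) {
    means <- vapply(chains, function(ch) mean(ch[, j]), numeric(1))
    vars <- vapply(chains, function(ch) var(ch[, j]), numeric(1))
    W <- mean(vars)
    B <- n * var(means)
    if (W == 0) {
      rhat[j] <- if (B == 0) 1 else Inf
    } else {
      vhat <- (n - 1) / n * W + (1 + 1 / m) * B / n
      rhat[j] <- sqrt(vhat / W)
    }
  }
  nm <- colnames(chains[[1]])
  if (!is.null(nm)) names(rhat) <- nm
  rhat
}

#' Fit one model and summarise its posterior
#'
#' Runs \code{\link{sample_posterior}} and assembles per-parameter posterior
#' means, SDs and 95\% credible intervals, \eqn{\hat R}, DIC decomposition
#' and \eqn{R^2}.
#'
#' @inheritParams sample_posterior
#' @return object of class \code{ctag_fit}: \code{summary} (data frame:
#'   parameter, estimate, sd, q2.5, q97.5, rhat), \code{Dbar}, \code{pD},
#'   \code{DIC}, \code{R2}, \code{n_obs}, \code{spec}, \code{draws}.
#' @export
fit_model <- function(spec, data, mcmc = mcmc_config(),
                      priors = prior_config(), center = TRUE) {
  draws <- sample_posterior(spec, data, mcmc = mcmc, priors = priors,
                            center = center)
  pooled <- pool_draws(draws)
  summ <- data.frame(
    parameter = colnames(pooled),
    estimate = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    q2.5 = apply(pooled, 2, quantile, probs = 0.025, type = 7),
    q97.5 = apply(pooled, 2, quantile, probs = 0.975, type = 7),
    rhat = if (draws$mcmc$n_chains >= 2) compute_rhat(draws) else NA_real_,
    row.names = NULL)
  dic <- compute_dic(draws, data)
  structure(list(spec = spec, summary = summ, Dbar = dic$Dbar, pD = dic$pD,
                 DIC = dic$DIC, R2 = compute_r2(draws, data),
                 n_obs = nrow(data), draws = draws),
            class = "ctag_fit")
}

#' @export
print.ctag_fit <- function(x, ...) {
  cat("Threshold Poisson regression fit:", x$spec$label, "\n")
  cat(sprintf("  n = %d days; Dbar = %.1f, pD = %.2f, DIC = %.1f, R2 = %.3f\n",
              x$n_obs, x$Dbar, x$pD, x$DIC, x$R2))
  s <- x$summary
  s[-1] <- lapply(s[-1], signif, digits = 4)
  print(s, row.names = FALSE)
  invisible(x)
}

#' Rank fitted models by DIC
#'
#' Sorts fits ascending by DIC, computes \code{dDIC = DIC - min(DIC)} and
#' flags competitors within five DIC points of the best (a five-point
#' reduction being the usual bar for a meaningful improvement). Ties are
#' broken by fewer parameters, then input order.
#'
#' @param fits list of \code{ctag_fit} objects.
#' @return data frame: model, n_params, pD, DIC, dDIC, R2, within_5.
#' @export
select_best <- function(fits) {
  stopifnot(length(fits) >= 1)
  ok <- vapply(fits, function(f) is.finite(f$DIC), logical(1))
  if (!all(ok)) {
    warning("excluding ", sum(!ok), " fit(s) with undefined DIC")
    fits <- fits[ok]
    if (!length(fits)) stop("no fits with defined DIC")
  }
  tab <- data.frame(
    model = vapply(fits, function(f) f$spec$label, character(1)),
    n_params = vapply(fits, function(f) n_params(f$spec), integer(1)),
    pD = vapply(fits, function(f) f$pD, numeric(1)),
    DIC = vapply(fits, function(f) f$DIC, numeric(1)),
    R2 = vapply(fits, function(f) f$R2, numeric(1)),
    order_in = seq_along(fits))
  tab <- tab[order(tab$DIC, tab$n_params, tab$order_in), ]
  tab$dDIC <- tab$DIC - tab$DIC[1]
  tab$within_5 <- tab$dDIC < 5 & tab$dDIC > 0
  rownames(tab) <- NULL
  tab[, c("model", "n_params", "pD", "DIC", "dDIC", "R2", "within_5",
          "order_in")]
}

#' Posterior predictions of daily median heart rate
#'
#' For each day, the posterior distribution of \eqn{\mu_t} over retained
#' draws: posterior-mean prediction and a 95\% credible envelope.
#'
#' @param fit a \code{ctag_fit}.
#' @param data the daily table predictions are wanted for (defaults must
#'   contain the model covariates; centering constants from the fit are
#'   reused).
#' @return data frame: observed HRm (if present), fit, lwr, upr per row.
#' @export
predict_hrm <- function(fit, data) {
  stopifnot(inherits(fit, "ctag_fit"))
  draws <- fit$draws
  pooled <- pool_draws(draws)
  mu_mat <- mu_draw_matrix(draws, pooled, data)
  out <- data.frame(
    fit = colMeans(mu_mat),
    lwr = apply(mu_mat, 2, quantile, probs = 0.025),
    upr = apply(mu_mat, 2, quantile, probs = 0.975))
  if (!is.null(data$HRm)) out <- cbind(HRm = data$HRm, out)
  if (!is.null(data$date)) out <- cbind(date = data$date, out)
  out
}
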