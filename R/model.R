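#' Define a candidate model structure
#'
#' A model is an identity-link Poisson regression of daily median heart rate
#' (\code{HRm}) on a subset of the daily covariates \code{TF} (total feed,
#' tons), \code{TPm} (median peripheral temperature, deg C), \code{TPiq}
#' (temperature interquartile range, deg C) and \code{ACm} (median activity,
#' milli-g). Optionally one covariate's coefficient is switched between two
#' values (\code{beta_plus} / \code{beta_minus}) according to whether a
#' governing covariate exceeds an estimated threshold. At most one threshold
#' is allowed.
#'
#' @param covariates character vector, ordered subset of
#'   \code{c("TF","TPm","TPiq","ACm")}.
#' @param modulated name of the covariate whose coefficient switches at the
#'   threshold, or \code{NULL} for a plain linear model. Must be an element
#'   of \code{covariates}.
#' @param governing name of the covariate whose (uncentered) value is
#'   compared against the threshold. Need not be a model covariate: a feeding
#'   coefficient can switch on temperature even in a model without a linear
#'   temperature term. Defaults to \code{modulated}.
#' @param label optional display label; a default is built from the structure.
#' @return an object of class \code{ctag_spec}.
#' @export
model_spec <- function(covariates = character(), modulated = NULL,
                       governing = NULL, label = NULL) {
  covariates <- as.character(covariates)
  if (!all(covariates %in% COVARIATES))
    stop("unknown covariate(s): ",
         paste(setdiff(covariates, COVARIATES), collapse = ", "))
  if (anyDuplicated(covariates)) stop("duplicated covariates")
  if (!is.null(modulated)) {
    if (!modulated %in% covariates)
      stop("modulated covariate must be one of the model covariates")
    if (is.null(governing)) governing <- modulated
    if (!governing %in% COVARIATES)
      stop("governing covariate must be one of ", paste(COVARIATES, collapse = ", "))
  } else if (!is.null(governing)) {
    stop("governing covariate given without a modulated covariate")
  }
  if (is.null(label)) {
    parts <- vapply(covariates, function(cv) {
      if (!is.null(modulated) && cv == modulated) paste0(cv, ":thresh") else cv
    }, character(1))
    label <- paste(c("alpha", parts), collapse = " + ")
  }
  structure(list(covariates = covariates, modulated = modulated,
                 governing = governing, label = label),
            class = "ctag_spec")
}

#' @export
print.ctag_spec <- function(x, ...) {
  cat("Model:", x$label, "\n")
  if (!is.null(x$modulated))
    cat("  threshold on", x$modulated, "coefficient, governed by",
        x$governing, "\n")
  invisible(x)
}

# names of free parameters, in the fixed order used by the sampler
param_names <- function(spec) {
  lin <- setdiff(spec$covariates, spec$modulated)
  nm <- c("alpha", if (length(lin)) paste0("beta_", lin))
  if (!is.null(spec$modulated))
    nm <- c(nm, paste0("beta_plus_", spec$modulated),
            paste0("beta_minus_", spec$modulated), "thresh")
  nm
}

n_params <- function(spec) length(param_names(spec))

#' Bundle parameter values for a model structure
#'
#' @param spec a \code{\link{model_spec}}.
#' @param alpha intercept (bpm): expected HRm at average covariate conditions
#'   under the default mean-centered parameterisation.
#' @param betas named numeric vector of slopes for the non-switched
#'   covariates (bpm per covariate unit).
#' @param beta_plus,beta_minus switched slopes applying when the governing
#'   covariate is above (resp. at or below) the threshold. Required iff the
#'   spec has a threshold.
#' @param thresh threshold value in governing-covariate units.
#' @return an object of class \code{ctag_params}.
#' @export
model_params <- function(spec, alpha, betas = numeric(), beta_plus = NULL,
                         beta_minus = NULL, thresh = NULL) {
  stopifnot(inherits(spec, "ctag_spec"))
  lin <- setdiff(spec$covariates, spec$modulated)
  if (!setequal(names(betas), lin))
    stop("betas must be named exactly for: ",
         paste(lin, collapse = ", "))
  has_thr <- !is.null(spec$modulated)
  if (has_thr && (is.null(beta_plus) || is.null(beta_minus) || is.null(thresh)))
    stop("threshold model requires beta_plus, beta_minus and thresh")
  if (!has_thr && (!is.null(beta_plus) || !is.null(beta_minus) || !is.null(thresh)))
    stop("non-threshold model cannot take switched slopes or a threshold")
  vals <- c(alpha, unlist(betas)[lin], beta_plus, beta_minus, thresh)
  if (!all(is.finite(vals))) stop("parameters must be finite")
  structure(list(spec = spec, alpha = alpha,
                 betas = if (length(lin)) setNames(as.numeric(betas[lin]), lin)
                         else setNames(numeric(0), character(0)),
                 beta_plus = beta_plus, beta_minus = beta_minus,
                 thresh = thresh),
            class = "ctag_params")
}

# parameter object <-> flat vector in param_names() order
params_to_vector <- function(params) {
  spec <- params$spec
  v <- c(params$alpha, unname(params$betas),
         params$beta_plus, params$beta_minus, params$thresh)
  setNames(v, param_names(spec))
}

params_from_vector <- function(spec, theta) {
  nm <- param_names(spec)
  stopifnot(length(theta) == length(nm))
  theta <- setNames(as.numeric(theta), nm)
  lin <- setdiff(spec$covariates, spec$modulated)
  bnm <- paste0("beta_", lin, recycle0 = TRUE)
  if (is.null(spec$modulated)) {
    model_params(spec, alpha = theta[["alpha"]],
                 betas = setNames(theta[bnm], lin))
  } else {
    model_params(spec, alpha = theta[["alpha"]],
                 betas = setNames(theta[bnm], lin),
                 beta_plus = theta[[paste0("beta_plus_", spec$modulated)]],
                 beta_minus = theta[[paste0("beta_minus_", spec$modulated)]],
                 thresh = theta[["thresh"]])
  }
}

# covariate means used for centering; always over the full covariate set
# present in `data` so generator and fitter agree when sharing a table
covariate_centers <- function(data, covariates) {
  setNames(vapply(covariates, function(cv) mean(data[[cv]]), numeric(1)),
           covariates)
}

#' Expected daily heart rate under a model
#'
#' Evaluates the identity-link linear predictor
#' \eqn{\mu_t = \alpha + \sum_i \beta_i X_{i,t}}, where the modulated
#' covariate's slope is \code{beta_plus} when the governing covariate exceeds
#' the threshold and \code{beta_minus} otherwise (equality falls in the
#' "below" branch). There is no exponentiation: \eqn{\mu} is linear in the
#' covariates and may be non-positive; callers enforce positivity.
#'
#' By default covariates are mean-centered (at \code{centers}, computed from
#' \code{data} if not supplied) so that \code{alpha} is the expected HRm at
#' average conditions; the threshold comparison always uses the uncentered
#' governing covariate, so the threshold stays in natural units.
#'
#' @param params a \code{\link{model_params}} object.
#' @param data data frame with one row per day holding the covariate columns
#'   named in the spec (and the governing covariate).
#' @param center logical; mean-center covariates before applying slopes.
#' @param centers optional named vector of centering constants.
#' @return numeric vector of \eqn{\mu_t}, one per row of \code{data}.
#' @export
evaluate_mu <- function(params, data, center = TRUE, centers = NULL) {
  stopifnot(inherits(params, "ctag_params"))
  spec <- params$spec
  need <- union(spec$covariates, spec$governing)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("data lacks covariate column(s): ",
                         paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n == 0L) return(numeric(0))
  if (center && is.null(centers))
    centers <- covariate_centers(data, spec$covariates)
  ctr <- function(cv) {
    x <- data[[cv]]
    if (center) x - centers[[cv]] else x
  }
  mu <- rep(params$alpha, n)
  for (cv in names(params$betas)) mu <- mu + params$betas[[cv]] * ctr(cv)
  if (!is.null(spec$modulated)) {
    above <- data[[spec$governing]] > params$thresh
    slope <- ifelse(above, params$beta_plus, params$beta_minus)
    mu <- mu + slope * ctr(spec$modulated)
  }
  mu
}

#' Poisson log-likelihood of daily median heart rates
#'
#' \eqn{\sum_t [HRm_t \log\mu_t - \mu_t - \log(HRm_t!)]} with \eqn{\mu_t}
#' from \code{\link{evaluate_mu}}. Returns \code{-Inf} if any \eqn{\mu_t \le 0}
#' (the identity link does not guarantee positivity; the sampler rejects such
#' states).
#'
#' @inheritParams evaluate_mu
#' @param data data frame with integer column \code{HRm} plus the covariates.
#' @export
log_likelihood <- function(params, data, center = TRUE, centers = NULL) {
  y <- data$HRm
  if (is.null(y)) stop("data lacks an HRm column")
  if (any(y < 0) || any(y != round(y)))
    stop("HRm must be non-negative integers for the Poisson likelihood")
  mu <- evaluate_mu(params, data, center = center, centers = centers)
  if (any(mu <= 0)) return(-Inf)
  sum(dpois(y, mu, log = TRUE))
}

#' Enumerate the nested candidate model set
#'
#' All combinations of TF, TPm, TPiq and ACm considered in the analysis,
#' limited to at most one threshold: the null model, each covariate alone
#' with a self- or temperature-governed threshold, TF alone without one, and
#' the multi-covariate structures. For a thresholded covariate other than the
#' two temperature variables, the governing variable is daily median
#' temperature (TPm); TPm and TPiq threshold on themselves.
#'
#' @return list of 21 \code{\link{model_spec}} objects.
#' @export
enumerate_models <- function() {
  s <- function(cov, mod = NULL, gov = NULL) model_spec(cov, mod, gov)
  list(
    s(c("TF", "TPm"), "TF", "TPm"),
    s(c("TF", "TPm", "TPiq"), "TF", "TPm"),
    s(c("TF", "TPm", "TPiq", "ACm"), "TF", "TPm"),
    s(c("TPiq", "TF", "TPm", "ACm"), "TPiq", "TPiq"),
    s(c("ACm", "TF", "TPm"), "ACm", "TPm"),
    s(c("TF", "TPm")),
    s(c("TF", "TPm", "TPiq")),
    s(c("TF", "TPm", "TPiq", "ACm")),
    s(c("TPiq", "TF", "TPm"), "TPiq", "TPiq"),
    s(c("TPm", "TF"), "TPm", "TPm"),
    s(c("TPm", "TF", "TPiq", "ACm"), "TPm", "TPm"),
    s(c("TPm", "TF", "TPiq"), "TPm", "TPm"),
    s(c("ACm", "TF", "TPm", "TPiq"), "ACm", "TPm"),
    s(c("ACm", "TF"), "ACm", "TPm"),
    s("TF", "TF", "TPm"),
    s("TF"),
    s(c("TPiq", "TF"), "TPiq", "TPiq"),
    s("TPm", "TPm", "TPm"),
    s("ACm", "ACm", "TPm"),
    s(character(0)),
    s("TPiq", "TPiq", "TPiq")
  )
}

#' Structure and parameters of the best-supported model
#'
#' The selected structure for the cage deployment: a linear temperature
#' effect plus a feeding coefficient that switches at an estimated
#' temperature threshold. \code{best_model_params()} returns that structure
#' populated with the reported posterior-mean estimates (intercept 50.188
#' bpm, above/below-threshold feeding slopes 0.313 / 1.831 bpm per ton,
#' temperature slope 2.137 bpm per deg C, threshold 25.462 deg C), used as
#' generating truth in recovery simulations.
#'
#' @return \code{best_model_spec()}: a \code{\link{model_spec}};
#'   \code{best_model_params()}: a \code{\link{model_params}}.
#' @export
best_model_spec <- function() model_spec(c("TF", "TPm"), "TF", "TPm")

#' @rdname best_model_spec
#' @export
best_model_params <- function() {
  model_params(best_model_spec(),
               alpha = 50.188, betas = c(TPm = 2.137),
               beta_plus = 0.313, beta_minus = 1.831, thresh = 25.462)
}
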