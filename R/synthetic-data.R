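#' Configure a synthetic tag deployment
#'
#' Describes an archival heart-rate tag deployment on a caged fish: its
#' length, logging cadence, the seasonal temperature decline, the feeding
#' schedule, and the corruption processes that make records fail quality
#' control. Defaults emulate an 80-day late-summer-to-autumn deployment:
#' 10-minute cadence (144 records/day), daily median temperature declining
#' from 27.5 to 19 degC, daily feed between 0 and 20 tons with multi-day
#' fasting spells, and a quality-index corruption leaving about 85\% of
#' records usable.
#'
#' @param n_days deployment length in days.
#' @param records_per_day logger records per day (144 = 10-min cadence).
#' @param temp_start_C,temp_end_C daily median temperature at deployment
#'   start/end (degC); the trend between them is linear.
#' @param temp_daily_noise_sd SD of day-to-day noise on the temperature
#'   trend (degC).
#' @param tpiq_start,tpiq_end endpoints of the within-day temperature IQR
#'   trend (degC); daily variability increases as the season cools.
#' @param tpiq_noise_sd SD of noise on the IQR trend (degC); values floored
#'   at 0.05 degC.
#' @param acm_start,acm_end endpoints of the daily median activity trend
#'   (milli-g), slight upward drift.
#' @param acm_noise_sd SD of noise on the activity trend (milli-g).
#' @param feed_max_tons maximum daily feed (tons).
#' @param fasting_spell_prob probability per non-fasting day that a fasting
#'   spell starts.
#' @param fasting_spell_len mean fasting spell length in days (geometric,
#'   minimum 1).
#' @param qi_bad_prob probability a record draws quality index 2 or 3.
#' @param hr_oob_prob probability any record's HR is replaced by an
#'   out-of-bounds value, independent of its quality index.
#' @param oob_bad_frac fraction of QI-bad records whose HR is additionally
#'   out of bounds (realism only; those records fail QC anyway).
#' @param hr_bounds usable HR range in bpm (low, high).
#' @param hr_within_day_sd SD of the symmetric integer jitter of 10-min HR
#'   records around the daily level (bpm).
#' @param dropout_prob probability a scheduled record is missing.
#' @param generating_params \code{\link{model_params}} used to turn daily
#'   covariates into expected heart rate; defaults to the best-supported
#'   model structure at its reported posterior means.
#' @param start_date first calendar day (ISO date).
#' @param seed integer seed; all generators fan stage seeds out from it.
#' @return object of class \code{ctag_config}.
#' @export
deployment_config <- function(n_days = 80, records_per_day = 144,
                              temp_start_C = 27.5, temp_end_C = 19.0,
                              temp_daily_noise_sd = 0.3,
                              tpiq_start = 0.4, tpiq_end = 1.5,
                              tpiq_noise_sd = 0.15,
                              acm_start = 30, acm_end = 40, acm_noise_sd = 5,
                              feed_max_tons = 20,
                              fasting_spell_prob = 0.06,
                              fasting_spell_len = 2,
                              qi_bad_prob = 0.15,
                              hr_oob_prob = 0,
                              oob_bad_frac = 0.3,
                              hr_bounds = c(8, 120),
                              hr_within_day_sd = 6,
                              dropout_prob = 0,
                              generating_params = best_model_params(),
                              start_date = "2021-08-01",
                              seed = 1L) {
  if (n_days < 0) stop("configuration error: n_days must be >= 0")
  if (records_per_day < 1) stop("configuration error: records_per_day >= 1")
  for (p in c(qi_bad_prob, hr_oob_prob, oob_bad_frac, fasting_spell_prob,
              dropout_prob))
    if (p < 0 || p > 1) stop("configuration error: probabilities in [0, 1]")
  if (length(hr_bounds) != 2 || hr_bounds[1] >= hr_bounds[2])
    stop("configuration error: hr_bounds must be (low, high) with low < high")
  if (feed_max_tons < 0) stop("configuration error: feed_max_tons >= 0")
  stopifnot(inherits(generating_params, "ctag_params"))
  structure(list(n_days = as.integer(n_days),
                 records_per_day = as.integer(records_per_day),
                 temp_start_C = temp_start_C, temp_end_C = temp_end_C,
                 temp_daily_noise_sd = temp_daily_noise_sd,
                 tpiq_start = tpiq_start, tpiq_end = tpiq_end,
                 tpiq_noise_sd = tpiq_noise_sd,
                 acm_start = acm_start, acm_end = acm_end,
                 acm_noise_sd = acm_noise_sd,
                 feed_max_tons = feed_max_tons,
                 fasting_spell_prob = fasting_spell_prob,
                 fasting_spell_len = fasting_spell_len,
                 qi_bad_prob = qi_bad_prob, hr_oob_prob = hr_oob_prob,
                 oob_bad_frac = oob_bad_frac,
                 hr_bounds = hr_bounds,
                 hr_within_day_sd = hr_within_day_sd,
                 dropout_prob = dropout_prob,
                 generating_params = generating_params,
                 start_date = as.Date(start_date),
                 seed = as.integer(seed)),
            class = "ctag_config")
}

#' Generate true daily covariate trajectories
#'
#' Daily median temperature declines linearly between the configured
#' endpoints with seeded noise; the within-day temperature IQR and the
#' activity level follow noisy linear trends (IQR increasing as the season
#' cools, activity drifting slightly upward); daily total feed is drawn from
#' a right-skewed distribution on \[0, feed_max_tons\] with geometric-length
#' fasting spells of zero feed.
#'
#' @param config a \code{\link{deployment_config}}.
#' @return data frame with columns \code{date}, \code{TPm_true},
#'   \code{TPiq_true}, \code{ACm_true}, \code{TF}; \code{config$n_days} rows.
#' @export
generate_covariates <- function(config) {
  stopifnot(inherits(config, "ctag_config"))
  n <- config$n_days
  dates <- config$start_date + seq_len(n) - 1L
  if (n == 0L)
    return(data.frame(date = as.Date(character(0)), TPm_true = numeric(0),
                      TPiq_true = numeric(0), ACm_true = numeric(0),
                      TF = numeric(0)))
  set.seed(config$seed + 1L)
  trend <- function(a, b) if (n == 1L) a else seq(a, b, length.out = n)
  TPm <- trend(config$temp_start_C, config$temp_end_C) +
    rnorm(n, 0, config$temp_daily_noise_sd)
  TPiq <- pmax(0.05, trend(config$tpiq_start, config$tpiq_end) +
                 rnorm(n, 0, config$tpiq_noise_sd))
  ACm <- pmax(1, trend(config$acm_start, config$acm_end) +
                rnorm(n, 0, config$acm_noise_sd))
  # feeding: right-skewed daily rations spanning the full 0..max range over a
  # deployment-scale span; fasting spells force TF = 0
  TF <- config$feed_max_tons * rbeta(n, 1.1, 1.8)
  fast <- logical(n)
  d <- 1L
  while (d <= n) {
    if (runif(1) < config$fasting_spell_prob) {
      len <- 1L + rgeom(1, 1 / max(1, config$fasting_spell_len))
      fast[d:min(n, d + len - 1L)] <- TRUE
      d <- d + len
    } else d <- d + 1L
  }
  TF[fast] <- 0
  data.frame(date = dates, TPm_true = TPm, TPiq_true = TPiq,
             ACm_true = ACm, TF = TF)
}

#' Extract the daily feeding log
#'
#' @param covariates a covariate table from \code{\link{generate_covariates}}.
#' @return data frame \code{date}, \code{tf_tons}.
#' @export
feeding_log <- function(covariates) {
  data.frame(date = covariates$date, tf_tons = covariates$TF)
}

# covariate table under the model's column names
truth_as_model_data <- function(covariates) {
  data.frame(date = covariates$date, TF = covariates$TF,
             TPm = covariates$TPm_true, TPiq = covariates$TPiq_true,
             ACm = covariates$ACm_true)
}

#' Draw true daily median heart rates
#'
#' Each day's \code{HRm_true} is a Poisson draw with mean \eqn{\mu_t} from
#' \code{\link{evaluate_mu}} under the generating parameters (covariates
#' mean-centered over the deployment; the threshold compared on uncentered
#' temperature).
#'
#' @param covariates table from \code{\link{generate_covariates}}.
#' @param params generating \code{\link{model_params}}.
#' @param seed optional integer seed (set if supplied).
#' @return integer vector of daily \code{HRm_true}, one per covariate row.
#' @export
generate_hr_series <- function(covariates, params, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  md <- truth_as_model_data(covariates)
  if (nrow(md) == 0L) return(integer(0))
  mu <- evaluate_mu(params, md, center = TRUE)
  bad <- which(mu <= 0)
  if (length(bad))
    stop("generation error: non-positive expected HR on day(s) ",
         paste(head(bad, 5), collapse = ", "))
  rpois(nrow(md), mu)
}

#' Generate the 10-minute logger record stream
#'
#' Expands daily truth into per-record samples: heart rate jittered around
#' the day's level by discretized normal noise (so the within-day median
#' matches the daily truth), temperature scattered so its IQR matches the
#' day's true IQR, activity scattered multiplicatively around the daily
#' median, a quality index drawn 0/1 for clean records and 2/3 for corrupted
#' ones, and optional out-of-bounds HR corruption and record dropout.
#'
#' @param covariates table from \code{\link{generate_covariates}}.
#' @param hr_series integer daily \code{HRm_true} from
#'   \code{\link{generate_hr_series}}.
#' @param config the \code{\link{deployment_config}}.
#' @return data frame of logger records: \code{timestamp} (POSIXct UTC),
#'   \code{hr_bpm}, \code{qi}, \code{temp_c}, \code{avg_ea_mg}.
#' @export
generate_logger_records <- function(covariates, hr_series, config) {
  stopifnot(inherits(config, "ctag_config"))
  if (nrow(covariates) != length(hr_series))
    stop("generation error: covariate and HR series spans differ (",
         nrow(covariates), " vs ", length(hr_series), " days)")
  set.seed(config$seed + 3L)
  rpd <- config$records_per_day
  out <- vector("list", nrow(covariates))
  for (d in seq_len(nrow(covariates))) {
    t0 <- as.POSIXct(paste(covariates$date[d], "00:00:00"), tz = "UTC")
    ts <- t0 + (seq_len(rpd) - 1L) * (86400 / rpd)
    # antithetic +/- jitter pairs: the day's jitter multiset is exactly
    # symmetric, so the within-day median sits on the daily level by
    # construction; QI corruption strikes whole pairs so the multiset stays
    # symmetric after quality control (odd record counts fall back to an
    # unpaired leftover draw)
    m <- floor(rpd / 2)
    # jitter truncated at 3.5 SD (and at the distance to the measurable
    # band) so uncorrupted records never leave the tag's output range;
    # applied to the pair magnitude, preserving symmetry
    jmax <- min(3.5 * config$hr_within_day_sd,
                hr_series[d] - config$hr_bounds[1],
                config$hr_bounds[2] - hr_series[d])
    jmax <- max(0, floor(jmax))
    half <- pmin(jmax, pmax(-jmax,
      round_half_up(rnorm(m, 0, config$hr_within_day_sd))))
    jit <- c(half, -half)
    pid <- c(seq_len(m), seq_len(m))
    if (rpd %% 2L == 1L) {
      extra <- pmin(jmax, pmax(-jmax,
        round_half_up(rnorm(1, 0, config$hr_within_day_sd))))
      jit <- c(jit, extra)
      pid <- c(pid, m + 1L)
    }
    perm <- sample.int(rpd)
    jit <- jit[perm]
    pid <- pid[perm]
    hr <- pmax(0L, as.integer(hr_series[d] + jit))
    # normal IQR = 1.349 sd: scale so the within-day IQR matches truth
    temp <- covariates$TPm_true[d] +
      (covariates$TPiq_true[d] / 1.349) * rnorm(rpd)
    ea <- covariates$ACm_true[d] * exp(rnorm(rpd, 0, 0.3))
    bad <- (runif(max(pid)) < config$qi_bad_prob)[pid]
    qi <- integer(rpd)
    qi[!bad] <- sample(0:1, sum(!bad), replace = TRUE)
    qi[bad] <- sample(2:3, sum(bad), replace = TRUE)
    oob <- (runif(rpd) < config$hr_oob_prob) |
      (bad & runif(rpd) < config$oob_bad_frac)
    if (any(oob)) {
      pool <- c(seq_len(config$hr_bounds[1]) - 1L,
                seq(config$hr_bounds[2] + 1L, config$hr_bounds[2] + 60L))
      hr[oob] <- sample(pool, sum(oob), replace = TRUE)
    }
    keep <- runif(rpd) >= config$dropout_prob
    out[[d]] <- data.frame(timestamp = ts, hr_bpm = as.integer(hr),
                           qi = qi, temp_c = temp, avg_ea_mg = ea)[keep, ]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a full deployment
#'
#' Convenience wrapper chaining \code{\link{generate_covariates}},
#' \code{\link{generate_hr_series}} and
#' \code{\link{generate_logger_records}}.
#'
#' @param config a \code{\link{deployment_config}}.
#' @return list: \code{covariates}, \code{hr_true} (integer vector),
#'   \code{records}, \code{feeding} (daily feeding log).
#' @export
simulate_deployment <- function(config) {
  cov <- generate_covariates(config)
  hr <- generate_hr_series(cov, config$generating_params,
                           seed = config$seed + 2L)
  rec <- generate_logger_records(cov, hr, config)
  list(covariates = cov, hr_true = hr, records = rec,
       feeding = feeding_log(cov))
}

#' Synthesise an ECG burst
#'
#' Periodic PQRST-like pulse train built from Gaussian bumps, with R-R
#' interval \code{60 / hr_bpm} seconds. Only the R-peak timing carries
#' information; the surrounding P, Q, S and T bumps give the trace a
#' realistic morphology. Optional additive Gaussian noise.
#'
#' @param hr_bpm heart rate in beats per minute (> 0).
#' @param duration_s burst length in seconds (tag default 7.5).
#' @param sample_rate sampling rate in Hz (tag default 200).
#' @param noise_sd additive noise SD relative to unit R amplitude.
#' @param phase_s time of the first R peak (s).
#' @param seed optional seed for the noise.
#' @return object of class \code{ctag_ecg}: \code{t} (s), \code{amplitude},
#'   \code{sample_rate}, \code{duration}, \code{r_times} (injected R-peak
#'   times, s).
#' @export
synth_ecg <- function(hr_bpm, duration_s = 7.5, sample_rate = 200,
                      noise_sd = 0, phase_s = 0.3, seed = NULL) {
  if (hr_bpm <= 0 || duration_s <= 0 || sample_rate <= 0)
    stop("argument error: hr_bpm, duration_s and sample_rate must be > 0")
  n <- round(sample_rate * duration_s)
  t <- (seq_len(n) - 1L) / sample_rate
  rr <- 60 / hr_bpm
  r_times <- seq(phase_s, duration_s, by = rr)
  r_times <- r_times[r_times <= t[n]]
  bump <- function(center, amp, width) {
    a <- numeric(n)
    for (tc in center) a <- a + amp * exp(-0.5 * ((t - tc) / width)^2)
    a
  }
  amp <- bump(r_times, 1.0, 0.010) +          # R
    bump(r_times - 0.20, 0.12, 0.035) +       # P
    bump(r_times - 0.028, -0.12, 0.008) +     # Q
    bump(r_times + 0.028, -0.18, 0.009) +     # S
    bump(r_times + 0.22, 0.25, 0.045)         # T
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    amp <- amp + rnorm(n, 0, noise_sd)
  }
  structure(list(t = t, amplitude = amp, sample_rate = sample_rate,
                 duration = duration_s, r_times = r_times),
            class = "ctag_ecg")
}

#' Synthesise a tri-axial acceleration burst
#'
#' Static gravity along a fixed (configurable) orientation plus a dynamic
#' component whose magnitude averages \code{target_ea_mg}, so the external
#' acceleration metric of \code{\link{external_acceleration}} recovers the
#' target on average.
#'
#' @param target_ea_mg desired mean external acceleration (milli-g).
#' @param duration_s burst length (tag default 60 s).
#' @param sample_rate sampling rate (tag default 25 Hz).
#' @param gravity_mg gravity magnitude (milli-g).
#' @param orientation unit-ish 3-vector giving the gravity direction.
#' @param seed optional seed.
#' @return object of class \code{ctag_accel}: \code{t}, \code{ax}, \code{ay},
#'   \code{az} (milli-g, gravity included), \code{sample_rate},
#'   \code{duration}.
#' @export
synth_accel_burst <- function(target_ea_mg = 30, duration_s = 60,
                              sample_rate = 25, gravity_mg = 1000,
                              orientation = c(0, 0, 1), seed = NULL) {
  if (duration_s <= 0 || sample_rate <= 0 || target_ea_mg < 0)
    stop("argument error: non-positive burst geometry")
  if (!is.null(seed)) set.seed(seed)
  n <- round(sample_rate * duration_s)
  u <- orientation / sqrt(sum(orientation^2))
  # |half-normal| mean = sd * sqrt(2/pi); invert so the EA average hits target
  dyn <- abs(rnorm(n, 0, target_ea_mg * sqrt(pi / 2)))
  norm_t <- gravity_mg + dyn
  structure(list(t = (seq_len(n) - 1L) / sample_rate,
                 ax = norm_t * u[1], ay = norm_t * u[2], az = norm_t * u[3],
                 sample_rate = sample_rate, duration = duration_s),
            class = "ctag_accel")
}
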