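#' R-peak detection on a short ECG burst
#'
#' Local maxima exceeding \code{threshold_frac} times the maximum amplitude,
#' separated by at least \code{min_rr_s} seconds. Deterministic. The default
#' refractory period of 0.45 s corresponds to a ~133 bpm ceiling, just above
#' the 120 bpm quality-control bound.
#'
#' @param trace a \code{ctag_ecg} from \code{\link{synth_ecg}} or
#'   \code{\link{read_burst}}.
#' @param min_rr_s minimum separation between accepted peaks (s).
#' @param threshold_frac fraction of the maximum amplitude a peak must
#'   exceed, in (0, 1).
#' @return object of class \code{ctag_peaks}: strictly increasing 1-based
#'   sample \code{indices} and the \code{sample_rate}.
#' @export
detect_r_peaks <- function(trace, min_rr_s = 0.45, threshold_frac = 0.6) {
  x <- trace$amplitude
  if (length(x) == 0) stop("empty trace")
  if (threshold_frac <= 0 || threshold_frac >= 1)
    stop("threshold_frac must be in (0, 1)")
  if (max(x) == min(x)) stop("no-signal: flat trace")
  mind <- max(1L, round(min_rr_s * trace$sample_rate))
  pk <- pracma::findpeaks(x, minpeakheight = threshold_frac * max(x),
                          minpeakdistance = mind)
  if (is.null(pk)) stop("no-signal: no peaks above threshold")
  idx <- sort(pk[, 2])
  structure(list(indices = as.integer(idx),
                 sample_rate = trace$sample_rate),
            class = "ctag_peaks")
}

#' Heart rate from detected R-peaks
#'
#' 60 divided by the mean R-R interval in seconds, rounded half-up to an
#' integer, matching the tag's integer bpm output.
#'
#' @param peaks a \code{ctag_peaks} from \code{\link{detect_r_peaks}}.
#' @return integer heart rate (bpm).
#' @export
hr_from_peaks <- function(peaks) {
  idx <- peaks$indices
  if (length(idx) < 2) stop("insufficient peaks: need at least 2 R-peaks")
  rr <- diff(idx) / peaks$sample_rate
  as.integer(round_half_up(60 / mean(rr)))
}

#' Theoretical heart-rate floor for a finite ECG window
#'
#' The lowest measurable rate is reached when exactly one full inter-beat
#' interval spans the recording window: \code{60 / window_s} bpm. Returned
#' unrounded together with its rounded-up integer companion (the smallest
#' integer bpm at or above the floor).
#'
#' @param window_s ECG window length in seconds (> 0).
#' @return list: \code{bpm} (exact), \code{bpm_int} (ceiling, integer).
#' @export
theoretical_min_hr <- function(window_s) {
  if (!is.numeric(window_s) || window_s <= 0)
    stop("argument error: window_s must be > 0")
  bpm <- 60 / window_s
  list(bpm = bpm, bpm_int = as.integer(ceiling(bpm - 1e-9)))
}

#' External acceleration activity metric
#'
#' Per-sample external acceleration is the vector norm of the tri-axial
#' signal minus standard gravity; by default the absolute value is taken
#' (MSA-style), guaranteeing a non-negative activity series, with a signed
#' variant available. \code{avg_ea} is the arithmetic mean over the burst
#' (the tag's AvgEA statistic).
#'
#' @param burst a \code{ctag_accel} (or any list with equal-length numeric
#'   \code{ax}, \code{ay}, \code{az} in milli-g, gravity included).
#' @param gravity_mg standard gravity in milli-g (> 0).
#' @param mode \code{"absolute"} (default) or \code{"signed"}.
#' @return list: \code{ea_series} (milli-g, per sample), \code{avg_ea}
#'   (milli-g).
#' @export
external_acceleration <- function(burst, gravity_mg = 1000,
                                  mode = c("absolute", "signed")) {
  mode <- match.arg(mode)
  ax <- burst$ax; ay <- burst$ay; az <- burst$az
  if (length(ax) == 0) stop("argument error: empty burst")
  if (length(ay) != length(ax) || length(az) != length(ax))
    stop("argument error: axes of unequal length")
  if (gravity_mg <= 0) stop("argument error: gravity_mg must be > 0")
  ea <- sqrt(ax^2 + ay^2 + az^2) - gravity_mg
  if (mode == "absolute") ea <- abs(ea)
  list(ea_series = ea, avg_ea = mean(ea))
}
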