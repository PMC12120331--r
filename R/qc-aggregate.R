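#' Record-level quality control
#'
#' Applies the deployment's QC rules: drop records whose quality index is in
#' \code{qi_reject} (tag QI runs 0 = Excellent to 3 = Poor) and records with
#' heart rate strictly above \code{hr_high} or strictly below \code{hr_low}.
#' The bounds themselves are kept: the low bound is the theoretical floor of
#' measurable HR, so it must be admissible. For the drop tally, the first
#' failing rule wins in the order QI, high HR, low HR (this affects report
#' counts only, never membership).
#'
#' @param records logger record data frame (\code{timestamp}, \code{hr_bpm},
#'   \code{qi}, \code{temp_c}, \code{avg_ea_mg}).
#' @param hr_low,hr_high usable HR bounds in bpm (inclusive).
#' @param qi_reject quality-index values to eliminate.
#' @return list: \code{records} (kept rows, original order) and
#'   \code{report}, a \code{ctag_qc} with \code{n_total}, \code{n_kept},
#'   \code{n_dropped_qi}, \code{n_dropped_hr_high}, \code{n_dropped_hr_low},
#'   \code{pass_fraction} (1 for an empty stream).
#' @export
filter_records <- function(records, hr_low = 8, hr_high = 120,
                           qi_reject = c(2, 3)) {
  if (hr_low >= hr_high) stop("hr_low must be below hr_high")
  n <- nrow(records)
  if (n > 0) {
    bad_row <- which(!(records$qi %in% 0:3) | records$hr_bpm < 0)
    if (length(bad_row))
      stop("validation error: malformed record(s) at row(s) ",
           paste(head(bad_row, 10), collapse = ", "),
           " (qi outside 0..3 or negative HR)")
  }
  drop_qi <- records$qi %in% qi_reject
  drop_hi <- !drop_qi & records$hr_bpm > hr_high
  drop_lo <- !drop_qi & !drop_hi & records$hr_bpm < hr_low
  keep <- !(drop_qi | drop_hi | drop_lo)
  report <- structure(list(
    n_total = n, n_kept = sum(keep),
    n_dropped_qi = sum(drop_qi),
    n_dropped_hr_high = sum(drop_hi),
    n_dropped_hr_low = sum(drop_lo),
    pass_fraction = if (n == 0) 1 else sum(keep) / n), class = "ctag_qc")
  list(records = records[keep, , drop = FALSE], report = report)
}

#' @export
print.ctag_qc <- function(x, ...) {
  cat(sprintf(paste0(
    "QC report: %d records, %d kept (%.1f%%)\n",
    "  dropped: %d by quality index, %d HR too high, %d HR too low\n"),
    x$n_total, x$n_kept, 100 * x$pass_fraction,
    x$n_dropped_qi, x$n_dropped_hr_high, x$n_dropped_hr_low))
  invisible(x)
}

#' Collapse QC-passed records to the daily covariate table
#'
#' Per calendar day (UTC): \code{HRm} = median heart rate rounded half-up to
#' an integer (the Poisson likelihood needs integer observations);
#' \code{TPm} = median temperature; \code{TPiq} = Q3 - Q1 of temperature
#' under linear-interpolation quantiles (type 7 by default, configurable);
#' \code{ACm} = median activity; \code{TF} joined from the feeding log;
#' \code{n_records} the day's record count. Days with zero kept records are
#' omitted (not imputed); attribute \code{omitted_dates} lists any feeding
#' days without records.
#'
#' @param records QC-passed logger records.
#' @param feeding feeding log (\code{date}, \code{tf_tons}).
#' @param quantile_type quantile algorithm for \code{TPiq} (see
#'   \code{\link[stats]{quantile}}).
#' @return data frame: \code{date}, \code{HRm}, \code{TPm}, \code{TPiq},
#'   \code{ACm}, \code{TF}, \code{n_records}, ordered by date.
#' @export
daily_summaries <- function(records, feeding, quantile_type = 7) {
  if (nrow(records) == 0)
    return(structure(data.frame(date = as.Date(character(0)),
                                HRm = integer(0), TPm = numeric(0),
                                TPiq = numeric(0), ACm = numeric(0),
                                TF = numeric(0), n_records = integer(0)),
                     omitted_dates = feeding$date))
  day <- as.Date(records$timestamp, tz = "UTC")
  missing_days <- setdiff(as.character(unique(day)),
                          as.character(feeding$date))
  if (length(missing_days))
    stop("join error: record date(s) missing from feeding log: ",
         paste(missing_days, collapse = ", "))
  pieces <- lapply(split(seq_along(day), day), function(ix) {
    r <- records[ix, ]
    q <- quantile(r$temp_c, c(0.25, 0.75), type = quantile_type,
                  names = FALSE)
    data.frame(HRm = as.integer(round_half_up(median(r$hr_bpm))),
               TPm = median(r$temp_c), TPiq = q[2] - q[1],
               ACm = median(r$avg_ea_mg), n_records = length(ix))
  })
  out <- do.call(rbind, pieces)
  out <- data.frame(date = as.Date(names(pieces)), out, row.names = NULL)
  out$TF <- feeding$tf_tons[match(as.character(out$date),
                                  as.character(feeding$date))]
  out <- out[order(out$date),
             c("date", "HRm", "TPm", "TPiq", "ACm", "TF", "n_records")]
  rownames(out) <- NULL
  attr(out, "omitted_dates") <-
    feeding$date[!as.character(feeding$date) %in% as.character(out$date)]
  out
}
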