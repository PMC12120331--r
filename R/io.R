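#' Read and write pipeline files
#'
#' Plain-text interchange formats: logger records and the feeding log as
#' headed CSV (ISO-8601 timestamps, UTC), daily summaries as CSV, bursts as
#' two-column (\code{time_s}, \code{value}) or four-column
#' (\code{time_s}, \code{ax_mg}, \code{ay_mg}, \code{az_mg}) CSV, and flat
#' \code{key = value} configuration text.
#'
#' @param records,feeding,daily data frames as produced by the generators
#'   and aggregator.
#' @param path file path.
#' @name ctag_io
NULL

#' @rdname ctag_io
#' @export
write_logger_csv <- function(records, path) {
  out <- records
  out$timestamp <- format(records$timestamp, "%Y-%m-%dT%H:%M:%SZ",
                          tz = "UTC")
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ctag_io
#' @export
read_logger_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp", "hr_bpm", "qi", "temp_c", "avg_ea_mg")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("logger CSV lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$timestamp <- as.POSIXct(df$timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                             tz = "UTC")
  df
}

#' @rdname ctag_io
#' @export
write_feeding_csv <- function(feeding, path) {
  write.csv(data.frame(date = as.character(feeding$date),
                       tf_tons = feeding$tf_tons),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ctag_io
#' @export
read_feeding_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("date", "tf_tons") %in% names(df)))
    stop("feeding CSV needs columns date, tf_tons")
  df$date <- as.Date(df$date)
  df
}

#' @rdname ctag_io
#' @export
write_daily_csv <- function(daily, path) {
  out <- data.frame(date = as.character(daily$date), hrm = daily$HRm,
                    tpm = signif(daily$TPm, 6), tpiq = signif(daily$TPiq, 6),
                    acm = signif(daily$ACm, 6), tf = signif(daily$TF, 6),
                    n_records = daily$n_records)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ctag_io
#' @export
read_daily_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  data.frame(date = as.Date(df$date), HRm = as.integer(df$hrm),
             TPm = df$tpm, TPiq = df$tpiq, ACm = df$acm, TF = df$tf,
             n_records = df$n_records)
}

#' @rdname ctag_io
#' @param trace a \code{ctag_ecg} burst.
#' @export
write_burst <- function(trace, path) {
  write.csv(data.frame(time_s = trace$t, value = trace$amplitude),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ctag_io
#' @param sample_rate sampling rate used when the file's time column is not
#'   trusted; inferred from the time column when \code{NULL}.
#' @export
read_burst <- function(path, sample_rate = NULL) {
  df <- read.csv(path)
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(df$time_s))
  structure(list(t = df$time_s, amplitude = df$value,
                 sample_rate = sample_rate,
                 duration = length(df$time_s) / sample_rate),
            class = "ctag_ecg")
}

#' @rdname ctag_io
#' @param burst a \code{ctag_accel} burst.
#' @export
write_accel_burst <- function(burst, path) {
  write.csv(data.frame(time_s = burst$t, ax_mg = burst$ax, ay_mg = burst$ay,
                       az_mg = burst$az),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ctag_io
#' @export
read_accel_burst <- function(path, sample_rate = NULL) {
  df <- read.csv(path)
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(df$time_s))
  structure(list(t = df$time_s, ax = df$ax_mg, ay = df$ay_mg, az = df$az_mg,
                 sample_rate = sample_rate,
                 duration = length(df$time_s) / sample_rate),
            class = "ctag_accel")
}

#' @rdname ctag_io
#' @param x named list of scalar values.
#' @export
write_flat_config <- function(x, path) {
  lines <- vapply(names(x), function(k)
    paste0(k, " = ", paste(format(x[[k]]), collapse = ",")), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname ctag_io
#' @export
read_flat_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  out <- lapply(kv, function(p) {
    v <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(strsplit(v, ",")[[1]]))
    if (!anyNA(num)) num else v
  })
  names(out) <- vapply(kv, function(p) trimws(p[1]), character(1))
  out
}
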