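#!/usr/bin/env Rscript
# Stage 2: quality control and daily aggregation.
#
# Applies the record-level QC rules (drop quality index 2-3, drop heart
# rates above 120 or below 8 bpm -- the theoretical floor for a 7.5-s ECG
# window) and collapses surviving records to the daily covariate table:
# median heart rate (HRm), median temperature (TPm), temperature IQR
# (TPiq), median activity (ACm), joined with the feeding log (TF).

library(cardiotag)

records <- read_logger_csv("results/data/logger.csv")
feeding <- read_feeding_csv("results/data/feeding.csv")

qc <- filter_records(records)
print(qc$report)
writeLines(capture.output(print(qc$report)), "results/qc_report.txt")

daily <- daily_summaries(qc$records, feeding)
write_daily_csv(daily, "results/daily_summaries.csv")

truth <- read.csv("results/data/truth.csv")
agree <- mean(daily$HRm == truth$hrm_true[match(as.character(daily$date),
                                                truth$date)])
cat("Summarised", nrow(daily), "days;",
    length(attr(daily, "omitted_dates")), "omitted\n")
cat(sprintf("Daily median HR matches generator truth on %.1f%% of days\n",
            100 * agree))
cat("Deployment median of usable HR:", median(qc$records$hr_bpm), "bpm\n")
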