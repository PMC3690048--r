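# Published per-user confusion-count tables from the wearable ECG/SCR study
# that this package's methods follow, shipped as a fixture so the statistics
# layer can be validated by exact arithmetic against the printed results.
#
# Counts follow the table convention: row T/col P = TP, row T/col N = FN,
# row F/col P = FP, row F/col N = TN. One blank cell in the source (R-wave
# user 2, FN) is recorded as 0, consistent with its printed sensitivity of 1.

#' Published confusion-count tables
#'
#' Per-user (R-wave detection, SCR stress classification) and per-test
#' (extrasystole, arrhythmia) confusion counts from the study whose detection
#' and classification rules this package implements.
#'
#' @return data.frame with columns `study` (`"r_wave"`, `"extrasystole"`,
#'   `"arrhythmia"`, `"scr_stroop"`, `"scr_sounds"`), `unit` (user or test
#'   label) and integer counts `TP`, `FN`, `FP`, `TN`.
#' @export
study_tables <- function() {
  rbind(
    data.frame(study = "r_wave",
               unit = paste0("user", 1:12),
               TP = c(117, 538, 519, 217, 229, 444, 523, 292, 245, 306, 551, 327),
               FN = c(6, 0, 0, 1, 2, 0, 0, 0, 0, 0, 1, 2),
               FP = c(0, 0, 0, 0, 10, 3, 0, 0, 0, 0, 0, 0),
               TN = c(32901, 101606, 101625, 53458, 101903, 101697, 101621,
                      78710, 44800, 90162, 95460, 78610)),
    data.frame(study = "extrasystole",
               unit = paste0("test", 1:4),
               TP = c(189, 348, 225, 362), FN = c(0, 0, 8, 0),
               FP = c(0, 0, 0, 0), TN = c(210, 702, 236, 722)),
    data.frame(study = "arrhythmia",
               unit = paste0("test", 1:3),
               TP = c(16, 7, 20), FN = c(1, 0, 2),
               FP = c(0, 0, 0), TN = c(517, 401, 318)),
    data.frame(study = "scr_stroop",
               unit = paste0("user", c(4, 7, 8, 9, 12)),
               TP = c(221, 234, 134, 165, 235), FN = c(15, 2, 4, 1, 1),
               FP = c(1, 1, 18, 16, 3), TN = c(212, 231, 215, 216, 155)),
    data.frame(study = "scr_sounds",
               unit = paste0("user", c(2, 3, 5, 6, 10, 11, 12)),
               TP = c(33, 425, 707, 228, 437, 715, 511),
               FN = c(0, 7, 0, 3, 0, 0, 0),
               FP = c(1, 4, 1, 6, 1, 3, 1),
               TN = c(683, 294, 319, 391, 507, 353, 450)))
}

#' Published statistics printed alongside the count tables
#'
#' The values the study prints for each count table: per-user sensitivity,
#' specificity and "Precision" (= overall accuracy) for R-wave detection;
#' per-test and pooled sensitivity/specificity for extrasystoles and
#' arrhythmias; per-user correct rate for the SCR classifiers; and the
#' headline mean R-wave sensitivity. `digits` is the printed precision (for
#' fractions: decimal places; for percents: decimal places of the percent).
#' `consistent` is `FALSE` for the two printed values that disagree with their
#' own count table (SCR Stroop correct rate, users 7 and 9, off in the last
#' printed digit).
#'
#' @return data.frame with columns `study`, `unit`, `stat`, `printed`,
#'   `scale` (`"fraction"` or `"percent"`), `digits`, `consistent`.
#' @export
study_printed_stats <- function() {
  fr <- function(study, unit, stat, printed, digits, consistent = TRUE)
    data.frame(study = study, unit = unit, stat = stat, printed = printed,
               scale = "fraction", digits = digits, consistent = consistent)
  pc <- function(study, unit, stat, printed, digits = 2, consistent = TRUE)
    data.frame(study = study, unit = unit, stat = stat, printed = printed,
               scale = "percent", digits = digits, consistent = consistent)
  rbind(
    fr("r_wave", paste0("user", 1:12), "sensitivity",
       c(0.9512, 1, 1, 0.9954, 0.9913, 1, 1, 1, 1, 1, 0.9982, 0.9939),
       c(4, 0, 0, 4, 4, 0, 0, 0, 0, 0, 4, 4)),
    fr("r_wave", paste0("user", 1:12), "specificity",
       c(1, 1, 1, 1, 0.9999, 0.99997, 1, 1, 1, 1, 1, 1),
       c(0, 0, 0, 0, 4, 5, 0, 0, 0, 0, 0, 0)),
    fr("r_wave", paste0("user", 1:12), "accuracy",
       c(0.9998, 1, 1, 0.99998, 0.9999, 0.99997, 1, 1, 1, 1, 0.99999, 0.99997),
       c(4, 0, 0, 5, 4, 5, 0, 0, 0, 0, 5, 5)),
    pc("r_wave", "all", "mean_sensitivity", 99.42),
    pc("extrasystole", paste0("test", 1:4), "sensitivity",
       c(100, 100, 96.57, 100)),
    pc("extrasystole", paste0("test", 1:4), "specificity",
       c(100, 100, 100, 100)),
    pc("extrasystole", "pooled", "sensitivity", 99.29),
    pc("extrasystole", "pooled", "specificity", 100),
    pc("arrhythmia", paste0("test", 1:3), "sensitivity",
       c(94.12, 100, 90.91)),
    pc("arrhythmia", paste0("test", 1:3), "specificity", c(100, 100, 100)),
    pc("arrhythmia", "pooled", "sensitivity", 93.48),
    pc("arrhythmia", "pooled", "specificity", 100),
    pc("scr_stroop", paste0("user", c(4, 7, 8, 9, 12)), "correct_rate",
       c(96.44, 99.34, 94.07, 95.72, 98.98),
       consistent = c(TRUE, FALSE, TRUE, FALSE, TRUE)),
    pc("scr_sounds", paste0("user", c(2, 3, 5, 6, 10, 11, 12)), "correct_rate",
       c(99.86, 98.49, 99.90, 98.57, 99.89, 99.72, 99.90)))
}

#' Round half-up at a fixed number of decimals
#'
#' Table-comparison rounding: ties away from zero, as used when checking
#' computed statistics against printed table values (base `round()` rounds
#' half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
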