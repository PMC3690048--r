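# Confusion-matrix construction and diagnostics.
#
# Table convention (as used throughout the study's result tables): row T,
# column P = TP; row T, column N = FN; row F, column P = FP; row F, column
# N = TN. Note that the tables' "Precision" row equals overall accuracy
# (TP + TN)/total, not positive predictive value; both are provided here
# under unambiguous names.

#' Construct a confusion matrix
#'
#' @param TP,FN,FP,TN nonnegative integer counts.
#' @return object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(TP, FN, FP, TN) {
  v <- c(TP = TP, FN = FN, FP = FP, TN = TN)
  if (any(!is.finite(v)) || any(v < 0) || any(abs(v - round(v)) > 1e-9))
    stop("confusion-matrix counts must be nonnegative integers")
  structure(as.list(round(v)), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> TP %d  FN %d  FP %d  TN %d\n",
              x$TP, x$FN, x$FP, x$TN))
  invisible(x)
}

cm_total <- function(cm) cm$TP + cm$FN + cm$FP + cm$TN

check_denom <- function(value, name) {
  if (value <= 0) stop("statistic '", name, "' is undefined: zero denominator")
  value
}

#' Confusion-matrix statistics
#'
#' `sensitivity` = TP/(TP+FN); `specificity` = TN/(TN+FP); `accuracy` =
#' (TP+TN)/total, which is what the study tables label "Precision";
#' `correct_rate` = 100 * accuracy; `ppv` = TP/(TP+FP) is the true
#' positive-predictive value, provided under its correct name.
#'
#' @param cm a [confusion_matrix()].
#' @return fraction in [0, 1] (percent for `correct_rate`).
#' @export
sensitivity <- function(cm) cm$TP / check_denom(cm$TP + cm$FN, "sensitivity")

#' @rdname sensitivity
#' @export
specificity <- function(cm) cm$TN / check_denom(cm$TN + cm$FP, "specificity")

#' @rdname sensitivity
#' @export
accuracy <- function(cm) (cm$TP + cm$TN) / check_denom(cm_total(cm), "accuracy")

#' @rdname sensitivity
#' @export
correct_rate <- function(cm) 100 * accuracy(cm)

#' @rdname sensitivity
#' @export
ppv <- function(cm) cm$TP / check_denom(cm$TP + cm$FP, "ppv")

#' Pool confusion matrices and average statistics
#'
#' `pool()` sums counts elementwise (order-invariant, associative);
#' `mean_stat()` averages the per-matrix statistic unweighted.
#'
#' @param cms non-empty list of [confusion_matrix()] objects.
#' @param stat a statistic function, e.g. [sensitivity()].
#' @export
pool <- function(cms) {
  if (!length(cms)) stop("cannot pool an empty list")
  stopifnot(all(vapply(cms, inherits, logical(1), "confusion_matrix")))
  confusion_matrix(sum(vapply(cms, `[[`, numeric(1), "TP")),
                   sum(vapply(cms, `[[`, numeric(1), "FN")),
                   sum(vapply(cms, `[[`, numeric(1), "FP")),
                   sum(vapply(cms, `[[`, numeric(1), "TN")))
}

#' @rdname pool
#' @export
mean_stat <- function(cms, stat) {
  if (!length(cms)) stop("cannot average over an empty list")
  mean(vapply(cms, stat, numeric(1)))
}

#' Score detected events against ground truth
#'
#' Greedy one-to-one matching of sorted event lists within a tolerance:
#' matched pairs are TP, unmatched truth events FN, unmatched detections FP.
#' TN is counted at the sample level, `n_samples - TP - FN - FP`, mirroring
#' per-sample scoring of a detector that emits at most one event per sample.
#' For sorted lists the greedy sweep attains the maximum matching cardinality.
#'
#' @param truth,detected sorted event times (s).
#' @param tolerance_s match tolerance (s), > 0; default 0.05.
#' @param n_samples record length in samples, for the TN count.
#' @return a [confusion_matrix()].
#' @export
match_events <- function(truth, detected, tolerance_s = 0.05, n_samples) {
  if (tolerance_s <= 0) stop("tolerance_s must be positive")
  if (is.unsorted(truth) || is.unsorted(detected))
    stop("event lists must be sorted")
  nt <- length(truth); nd <- length(detected)
  tp <- 0L; i <- 1L; j <- 1L
  while (i <= nt && j <= nd) {
    d <- detected[j] - truth[i]
    if (abs(d) <= tolerance_s) { tp <- tp + 1L; i <- i + 1L; j <- j + 1L }
    else if (d < 0) j <- j + 1L
    else i <- i + 1L
  }
  fn <- nt - tp; fp <- nd - tp
  if (n_samples < nt + nd - tp)
    stop("n_samples (", n_samples, ") is smaller than the number of events")
  confusion_matrix(TP = tp, FN = fn, FP = fp,
                   TN = n_samples - tp - fn - fp)
}
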