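# Diagnostic-accuracy statistics: normal-vs-abnormal dichotomy, confusion
# counts, the five standard proportions, and exact (Clopper-Pearson)
# binomial confidence intervals computed from Beta quantiles.

#' Dichotomize a heart sound class as positive (abnormal) or negative
#'
#' Normal sounds are the negative class; S3, S4 and both murmur classes
#' are positive (abnormal).
#'
#' @param class Character vector of [PCG_CLASSES].
#' @return Character vector of `"POSITIVE"` / `"NEGATIVE"`.
#' @export
binarize_label <- function(class) {
  if (!all(class %in% PCG_CLASSES)) {
    abort_config(sprintf("unknown class: %s",
                         paste(setdiff(class, PCG_CLASSES), collapse = ", ")),
                 "class")
  }
  ifelse(class == "NORMAL", "NEGATIVE", "POSITIVE")
}

#' Confusion counts for dichotomized predictions
#'
#' @param predictions,truths Equal-length vectors of 5-way classes (or
#'   already-dichotomized `"POSITIVE"`/`"NEGATIVE"` labels).
#' @return List of class `confusion_counts` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion <- function(predictions, truths) {
  if (length(predictions) != length(truths) || !length(truths)) {
    abort_data("predictions and truths must have equal, positive length")
  }
  dich <- function(x) {
    if (all(x %in% c("POSITIVE", "NEGATIVE"))) x else binarize_label(x)
  }
  p <- dich(predictions); t <- dich(truths)
  structure(list(tp = sum(p == "POSITIVE" & t == "POSITIVE"),
                 fp = sum(p == "POSITIVE" & t == "NEGATIVE"),
                 fn = sum(p == "NEGATIVE" & t == "POSITIVE"),
                 tn = sum(p == "NEGATIVE" & t == "NEGATIVE")),
            class = "confusion_counts")
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, in the Beta
#' quantile form: `lower = qbeta(a/2, k, n-k+1)` (0 when `k = 0`) and
#' `upper = qbeta(1-a/2, k+1, n-k)` (1 when `k = n`).
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials (>= 1).
#' @param level Confidence level (default 0.95).
#' @return List of class `proportion_ci`: `k`, `n`, `estimate`, `level`,
#'   `lower`, `upper`.
#' @export
clopper_pearson <- function(k, n, level = 0.95) {
  if (n < 1 || k < 0 || k > n) abort_config("need 0 <= k <= n, n >= 1", "k")
  a <- 1 - level
  lower <- if (k == 0) 0 else stats::qbeta(a / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a / 2, k + 1, n - k)
  structure(list(k = as.integer(k), n = as.integer(n), estimate = k / n,
                 level = level, lower = lower, upper = upper),
            class = "proportion_ci")
}

#' @export
print.proportion_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% (%g%% CI %.1f-%.1f%%)\n", x$k, x$n,
              100 * x$estimate, 100 * x$level, 100 * x$lower,
              100 * x$upper))
  invisible(x)
}

metric_names <- c("accuracy", "sensitivity", "specificity", "ppv", "npv")

#' Diagnostic accuracy, sensitivity, specificity and predictive values
#'
#' Applies the standard formulas — accuracy `(TP+TN)/(TP+FP+FN+TN)`,
#' sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, PPV `TP/(TP+FP)`,
#' NPV `TN/(TN+FN)` — each with an exact [clopper_pearson()] interval on
#' its own numerator/denominator pair. A metric whose denominator is zero
#' is reported as undefined (`NA`), never as 0 or 100%.
#'
#' @param counts A `confusion_counts` (or list with `tp`, `fp`, `fn`,
#'   `tn`).
#' @param level Confidence level for the intervals.
#' @return Data frame of class `diagnostic_metrics` with one row per
#'   metric: `metric`, `k`, `n`, `estimate`, `lower`, `upper`,
#'   `percent` (whole-percent rounding), `percent_ci` (printed form,
#'   `"—"` when undefined).
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  c_ <- counts
  if ((c_$tp + c_$fp + c_$fn + c_$tn) < 1) {
    abort_data("confusion counts are empty")
  }
  pairs <- list(accuracy = c(c_$tp + c_$tn, c_$tp + c_$fp + c_$fn + c_$tn),
                sensitivity = c(c_$tp, c_$tp + c_$fn),
                specificity = c(c_$tn, c_$tn + c_$fp),
                ppv = c(c_$tp, c_$tp + c_$fp),
                npv = c(c_$tn, c_$tn + c_$fn))
  rows <- lapply(metric_names, function(m) {
    k <- pairs[[m]][1]; n <- pairs[[m]][2]
    if (n == 0) {
      data.frame(metric = m, k = NA_integer_, n = 0L, estimate = NA_real_,
                 lower = NA_real_, upper = NA_real_, percent = NA_real_,
                 percent_ci = "—", stringsAsFactors = FALSE)
    } else {
      ci <- clopper_pearson(k, n, level)
      data.frame(metric = m, k = as.integer(k), n = as.integer(n),
                 estimate = ci$estimate, lower = ci$lower,
                 upper = ci$upper, percent = round(100 * ci$estimate),
                 percent_ci = sprintf("%d (%d-%d)",
                                      round(100 * ci$estimate),
                                      round(100 * ci$lower),
                                      round(100 * ci$upper)),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  class(out) <- c("diagnostic_metrics", "data.frame")
  out
}

#' Evaluate a set of recording diagnoses, with optional subgroups
#'
#' Dichotomizes 5-way predictions and truths, computes
#' [diagnostic_metrics()] for the total set and for each subgroup, and
#' also returns the full 5-class confusion matrix.
#'
#' @param predictions Character vector of predicted classes.
#' @param truths Character vector of true classes.
#' @param subgroups Optional factor/character vector assigning each
#'   recording to a subgroup.
#' @param level Confidence level.
#' @return List of class `evaluation_table`: `metrics` (data frame with a
#'   `subgroup` column, `"Total"` first), `counts` (per-subgroup
#'   `confusion_counts`), `confusion_5class` (table).
#' @export
evaluate_dataset <- function(predictions, truths, subgroups = NULL,
                             level = 0.95) {
  if (length(predictions) != length(truths)) {
    abort_data("predictions and truths must align")
  }
  if (!is.null(subgroups) && length(subgroups) != length(truths)) {
    abort_config("subgroup labels must align with recordings", "subgroups")
  }
  groups <- list(Total = seq_along(truths))
  if (!is.null(subgroups)) {
    for (g in unique(as.character(subgroups))) {
      groups[[g]] <- which(as.character(subgroups) == g)
    }
  }
  counts <- list(); tables <- list()
  for (g in names(groups)) {
    idx <- groups[[g]]
    cc <- confusion(predictions[idx], truths[idx])
    counts[[g]] <- cc
    tb <- diagnostic_metrics(cc, level)
    tb <- cbind(subgroup = g, n_recordings = length(idx), tb)
    tables[[g]] <- tb
  }
  conf5 <- table(factor(predictions, PCG_CLASSES),
                 factor(truths, PCG_CLASSES), dnn = c("predicted", "truth"))
  structure(list(metrics = do.call(rbind, tables), counts = counts,
                 confusion_5class = conf5),
            class = "evaluation_table")
}

#' @export
print.evaluation_table <- function(x, ...) {
  df <- x$metrics[, c("subgroup", "metric", "percent_ci")]
  wide <- stats::reshape(df, idvar = "subgroup", timevar = "metric",
                         direction = "wide")
  names(wide) <- sub("percent_ci\\.", "", names(wide))
  print(wide, row.names = FALSE)
  invisible(x)
}
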