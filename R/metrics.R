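#' Confusion matrix
#'
#' K x K contingency table of true class (rows) against predicted class
#' (columns). The one-vs-rest reduction of this table defines the
#' TP/TN/FP/FN counts from which all scores derive.
#'
#' @param pred,truth Equal-length label sequences.
#' @param class_codes Class codes defining row/column order; defaults to
#'   the sorted union of observed labels.
#' @return An object of class `gait_confusion`: list with `counts`
#'   (integer matrix) and `class_codes`.
#' @export
confusion <- function(pred, truth, class_codes = NULL) {
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have equal length", call. = FALSE)
  if (is.null(class_codes))
    class_codes <- sort(unique(c(pred, truth)))
  bad <- setdiff(unique(c(pred, truth)), class_codes)
  if (length(bad))
    stop("labels outside `class_codes`: ", paste(bad, collapse = ", "),
         call. = FALSE)
  counts <- table(factor(truth, levels = class_codes),
                  factor(pred, levels = class_codes))
  counts <- matrix(as.integer(counts), nrow = length(class_codes),
                   dimnames = list(truth = as.character(class_codes),
                                   pred = as.character(class_codes)))
  structure(list(counts = counts, class_codes = class_codes),
            class = "gait_confusion")
}

#' @export
print.gait_confusion <- function(x, ...) {
  cat("<gait_confusion> (rows = truth, cols = predicted)\n")
  print(x$counts)
  invisible(x)
}

#' One-vs-rest scores for a single class
#'
#' Reduces the confusion matrix to this class's TP/FP/FN/TN and computes
#' accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)`, specificity `TN/(TN+FP)` and F1 (harmonic mean of
#' precision and sensitivity). A zero denominator yields a score of 0
#' with the corresponding `degenerate` flag set, so degeneracies stay
#' visible without propagating NaN into macro averages.
#'
#' @param cm A [confusion()] matrix.
#' @param class_code The class to score.
#' @return Named list of the five scores plus `tp`, `fp`, `fn`, `tn` and
#'   `degenerate` (character vector of flagged scores, possibly empty).
#' @export
per_class_metrics <- function(cm, class_code) {
  stopifnot(inherits(cm, "gait_confusion"))
  total <- sum(cm$counts)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  i <- match(class_code, cm$class_codes)
  if (is.na(i)) stop("class ", class_code, " not in matrix", call. = FALSE)
  tp <- cm$counts[i, i]
  fp <- sum(cm$counts[-i, i])
  fn <- sum(cm$counts[i, -i])
  tn <- total - tp - fp - fn
  flags <- character(0)
  div <- function(num, den, what) {
    if (den == 0) {
      flags <<- c(flags, what)
      0
    } else num / den
  }
  precision <- div(tp, tp + fp, "precision")
  sensitivity <- div(tp, tp + fn, "sensitivity")
  specificity <- div(tn, tn + fp, "specificity")
  f1 <- div(2 * precision * sensitivity, precision + sensitivity, "f1")
  list(accuracy = (tp + tn) / total, precision = precision,
       sensitivity = sensitivity, specificity = specificity, f1 = f1,
       tp = tp, fp = fp, fn = fn, tn = tn, degenerate = flags)
}

metric_names <- function() c("accuracy", "precision", "sensitivity",
                             "specificity", "f1")

#' Per-class and macro-averaged metric report
#'
#' Computes the five scores for every class one-vs-rest and their
#' unweighted mean across classes (macro averaging). The macro F1 is the
#' mean of the per-class F1 values, not the harmonic mean of the macro
#' precision and sensitivity. The plain fraction of correctly labelled
#' samples is reported separately as `overall_accuracy`; the `accuracy`
#' column is the macro-averaged one-vs-rest accuracy.
#'
#' @param cm A [confusion()] matrix.
#' @return An object of class `gait_metric_report`: list with
#'   `per_class` (data.frame), `macro` (named numeric of the five
#'   scores), `overall_accuracy`, `n_samples`, `degenerate`.
#' @export
macro_report <- function(cm) {
  stopifnot(inherits(cm, "gait_confusion"))
  rows <- lapply(cm$class_codes, function(k) per_class_metrics(cm, k))
  per_class <- data.frame(
    class = cm$class_codes,
    do.call(rbind, lapply(rows, function(r)
      unlist(r[metric_names()])))
  )
  macro <- colMeans(per_class[, metric_names()])
  degen <- unlist(lapply(seq_along(rows), function(i)
    if (length(rows[[i]]$degenerate))
      paste0("class ", cm$class_codes[i], ": ",
             paste(rows[[i]]$degenerate, collapse = ","))
    else character(0)))
  structure(
    list(per_class = per_class, macro = macro,
         overall_accuracy = sum(diag(cm$counts)) / sum(cm$counts),
         n_samples = sum(cm$counts), degenerate = degen),
    class = "gait_metric_report"
  )
}

#' @export
print.gait_metric_report <- function(x, digits = 4, ...) {
  cat("<gait_metric_report>", x$n_samples, "samples\n")
  print(round(x$per_class[, c("class", metric_names())], digits),
        row.names = FALSE)
  cat("macro:", paste(sprintf("%s=%.*f", metric_names(), digits,
                              x$macro[metric_names()]),
                      collapse = " "), "\n")
  cat(sprintf("overall accuracy (fraction correct): %.*f\n", digits,
              x$overall_accuracy))
  if (length(x$degenerate))
    cat("degenerate:", paste(x$degenerate, collapse = "; "), "\n")
  invisible(x)
}

#' Sample standard deviation (n - 1 denominator)
#'
#' Dispersion of a set of cross-validation scores around their mean,
#' \eqn{\sqrt{\sum_i (x_i - \bar x)^2 / (n - 1)}}.
#'
#' @param values Numeric vector with at least two entries.
#' @return Non-negative number.
#' @export
std_eq7 <- function(values) {
  if (length(values) < 2)
    stop("need at least 2 values", call. = FALSE)
  if (anyNA(values)) stop("NA in values", call. = FALSE)
  stats::sd(values)
}
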