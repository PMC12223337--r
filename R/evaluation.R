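#' Evaluate predictions on one split
#'
#' Image-level accuracy: exact label matches over the total, where a
#' `"no_detection"` prediction never matches (it is always an error).  The
#' confusion table is ground truth (rows `real`, `fake`) against prediction
#' (columns `real`, `fake`, `no_detection`).
#'
#' @param predictions character vector of predicted labels (`"real"`,
#'   `"fake"`, possibly `"no_detection"`).
#' @param gt character vector of ground-truth labels.
#' @param split_id name for this split.
#' @return an object of class `eval_report`.
#' @export
evaluate <- function(predictions, gt, split_id = "split1") {
  if (length(predictions) != length(gt)) stop("length mismatch")
  if (length(gt) == 0) stop("empty input")
  check_class_label(gt, "gt")
  ok <- predictions %in% c(CLASS_LEVELS, "no_detection")
  if (!all(ok)) stop("predictions must be real, fake or no_detection")
  acc <- mean(predictions == gt)
  confusion <- table(factor(gt, CLASS_LEVELS),
                     factor(predictions, c(CLASS_LEVELS, "no_detection")))
  structure(list(per_split_accuracy = setNames(acc, split_id),
                 average_accuracy = acc,
                 confusion = unclass(confusion),
                 n_no_detection = sum(predictions == "no_detection"),
                 n_images = length(gt)),
            class = "eval_report")
}

#' Average reports over data splits
#'
#' The final figure of merit: the unweighted mean of the per-split
#' accuracies (splits count equally even when their test sets differ in
#' size).  Confusion counts and image counts are summed.
#'
#' @param reports list of [evaluate()] reports (accepts a single report).
#' @return an `eval_report` covering all splits.
#' @export
average_splits <- function(reports) {
  if (inherits(reports, "eval_report")) reports <- list(reports)
  if (length(reports) == 0) stop("need at least one report")
  per <- do.call(c, lapply(reports, function(r) r$per_split_accuracy))
  structure(list(per_split_accuracy = per,
                 average_accuracy = mean(per),
                 confusion = Reduce(`+`, lapply(reports, function(r) r$confusion)),
                 n_no_detection = sum(vapply(reports, function(r)
                   r$n_no_detection, numeric(1))),
                 n_images = sum(vapply(reports, function(r) r$n_images,
                                       numeric(1)))),
            class = "eval_report")
}

#' Truncate a percentage for display
#'
#' Accuracies are computed at full precision and truncated toward zero to
#' two decimals only at display time, so an average of 95.895% prints as
#' 95.89%.
#'
#' @param pct numeric percentage(s).
#' @return truncated value(s).
#' @export
display_pct <- function(pct) {
  floor(round(pct * 100, 6)) / 100
}

#' @export
print.eval_report <- function(x, ...) {
  cat("<eval_report>\n")
  for (s in names(x$per_split_accuracy)) {
    cat(sprintf("  %s: %.2f%%\n", s, display_pct(100 * x$per_split_accuracy[[s]])))
  }
  cat(sprintf("  average: %.2f%% over %d images (%d no-detection)\n",
              display_pct(100 * x$average_accuracy), x$n_images,
              x$n_no_detection))
  invisible(x)
}

#' Method comparison table
#'
#' One row per method with per-split and average accuracies (percent,
#' truncated to two decimals for display), sorted by average accuracy
#' descending; ties keep the input order.  The best row is flagged.
#'
#' @param method_reports named list of `eval_report`s.
#' @return a `data.frame` with columns per split, `average`, and `best`.
#' @export
comparison_table <- function(method_reports) {
  if (length(method_reports) == 0) stop("need at least one method")
  split_names <- unique(unlist(lapply(method_reports, function(r)
    names(r$per_split_accuracy))))
  rows <- lapply(names(method_reports), function(m) {
    r <- method_reports[[m]]
    acc <- setNames(rep(NA_real_, length(split_names)), split_names)
    acc[names(r$per_split_accuracy)] <- display_pct(100 * r$per_split_accuracy)
    c(list(method = m), as.list(acc),
      list(average = display_pct(100 * r$average_accuracy)))
  })
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
  ord <- order(-df$average)  # stable: ties keep input order
  df <- df[ord, , drop = FALSE]
  df$best <- df$average == max(df$average)
  rownames(df) <- NULL
  df
}
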