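#' Instance matching cost
#'
#' The cost between a ground-truth instance and a detection is the sum of
#' the Euclidean distances between their shoulders and between their tails.
#' Ears are deliberately excluded: the shoulder-tail pair alone defines the
#' location and orientation of a complete instance.
#'
#' @param gt,det single-row data frames (or lists) carrying `shoulder_x`,
#'   `shoulder_y`, `tail_x`, `tail_y`.
#' @return Non-negative scalar.
#' @export
instance_cost <- function(gt, det) {
  euclidean_norm(c(gt$shoulder_x, gt$shoulder_y), c(det$shoulder_x, det$shoulder_y)) +
    euclidean_norm(c(gt$tail_x, gt$tail_y), c(det$tail_x, det$tail_y))
}

# full N x M cost matrix between instance tables
instance_cost_matrix <- function(gt, det) {
  n <- nrow(gt); m <- nrow(det)
  D <- matrix(0, n, m)
  if (n == 0 || m == 0) return(D)
  for (i in seq_len(n)) {
    D[i, ] <- sqrt((gt$shoulder_x[i] - det$shoulder_x)^2 +
                     (gt$shoulder_y[i] - det$shoulder_y)^2) +
      sqrt((gt$tail_x[i] - det$tail_x)^2 + (gt$tail_y[i] - det$tail_y)^2)
  }
  D
}

#' Precision, recall and F-measure from counts
#'
#' Micro-averaged metrics with the empty-set conventions: precision is 1
#' when there are no detections, recall is 1 when there is no ground truth,
#' and F is 0 when precision + recall is 0 (so a perfectly detected empty
#' frame scores perfectly).
#'
#' @param tp,fp,fn non-negative counts.
#' @return Named list `precision`, `recall`, `f_measure`.
#' @export
#' @examples
#' compute_metrics(19999, 13, 743)
compute_metrics <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  precision <- if (tp + fp == 0) 1 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 1 else tp / (tp + fn)
  f <- if (precision + recall == 0) 0 else 2 * precision * recall / (precision + recall)
  list(precision = precision, recall = recall, f_measure = f)
}

new_match_report <- function(tp, fp, fn, matched_pairs) {
  m <- compute_metrics(tp, fp, fn)
  structure(
    list(tp = tp, fp = fp, fn = fn, matched_pairs = matched_pairs,
         precision = m$precision, recall = m$recall, f_measure = m$f_measure),
    class = "match_report"
  )
}

#' Cross-check (mutual nearest-neighbour) instance matching
#'
#' A ground-truth instance `n` and a detection `m` are matched if and only
#' if `m` is the minimum-cost detection for `n` *and* `n` is the
#' minimum-cost ground truth for `m`, under the shoulder+tail cost of
#' [instance_cost()]. Unlike an ungated Hungarian assignment, this never
#' forces a far-away pairing just to minimise the global cost; it also needs
#' no distance threshold parameter. Argmin ties are broken by lowest index,
#' and a tie that leaves mutuality ambiguous counts as no match.
#'
#' @param gt a [frame_annotation()] or any instance table with shoulder and
#'   tail columns.
#' @param det a [detection_set()] or compatible table.
#' @return A `match_report`: counts `tp`, `fp`, `fn`, the matched index
#'   pairs, and derived precision / recall / F-measure.
#' @export
#' @examples
#' # two ground truths, two detections, mutual-minimum pair only
#' gt <- tibble::tibble(shoulder_x = c(0, 10), shoulder_y = 0, tail_x = c(5, 15), tail_y = 0)
#' cross_check_match(gt, gt) # identical sets: everything matches
cross_check_match <- function(gt, det) {
  n <- nrow(gt); m <- nrow(det)
  if (n == 0 || m == 0) {
    return(new_match_report(0L, m, n,
                            tibble::tibble(gt_index = integer(0), det_index = integer(0))))
  }
  D <- instance_cost_matrix(gt, det)
  match_report_from_cost(D)
}

# cross-check matching on an explicit cost matrix (rows = gt, cols = det)
match_report_from_cost <- function(D) {
  n <- nrow(D); m <- ncol(D)
  row_min <- apply(D, 1, which.min) # lowest-index tie break
  col_min <- apply(D, 2, which.min)
  # a tie that makes mutuality ambiguous resolves as no-match: require the
  # argmin to be strictly unique whenever mutuality would otherwise hold
  pairs <- list()
  for (i in seq_len(n)) {
    j <- row_min[i]
    if (col_min[j] != i) next
    ties_row <- sum(D[i, ] == D[i, j])
    ties_col <- sum(D[, j] == D[i, j])
    if (ties_row > 1 || ties_col > 1) next
    pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  mp <- if (length(pairs)) {
    tibble::tibble(gt_index = vapply(pairs, `[`, 0L, 1),
                   det_index = vapply(pairs, `[`, 0L, 2))
  } else {
    tibble::tibble(gt_index = integer(0), det_index = integer(0))
  }
  tp <- nrow(mp)
  new_match_report(tp, m - tp, n - tp, mp)
}

#' @export
print.match_report <- function(x, ...) {
  cat(sprintf(
    "<match_report> TP %d, FP %d, FN %d | precision %.3f, recall %.3f, F %.3f\n",
    x$tp, x$fp, x$fn, x$precision, x$recall, x$f_measure
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidiers for match reports
#'
#' `tidy()` returns the matched ground-truth/detection index pairs;
#' `glance()` returns the one-row count and metric summary.
#'
#' @param x a `match_report`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.match_report <- function(x, ...) {
  x$matched_pairs
}

#' @rdname tidy.match_report
#' @export
glance.match_report <- function(x, ...) {
  tibble::tibble(
    tp = x$tp, fp = x$fp, fn = x$fn,
    precision = x$precision, recall = x$recall, f_measure = x$f_measure
  )
}

#' Precision-recall sweep over part detection thresholds
#'
#' Decodes every frame at each detection threshold, cross-check matches the
#' detections against the ground truth, micro-averages the TP/FP/FN counts
#' over all frames and derives precision, recall and F-measure per
#' threshold.
#'
#' @param frames list of elements, each a list with `frame` (a
#'   [frame_annotation()]) and `maps` (its 16-channel map, ground truth or
#'   network output).
#' @param thresholds strictly increasing detection thresholds in (0, 1);
#'   default grid 0.10 to 0.90 in steps of 0.05.
#' @param config base [decoder_config()]; its threshold is replaced by each
#'   sweep value.
#' @return A `pr_curve` tibble with columns `threshold`, `tp`, `fp`, `fn`,
#'   `recall`, `precision`, `f_measure`.
#' @export
pr_sweep <- function(frames, thresholds = seq(0.10, 0.90, by = 0.05),
                     config = decoder_config()) {
  stopifnot(all(thresholds > 0), all(thresholds < 1),
            !is.unsorted(thresholds, strictly = TRUE))
  rows <- purrr::map(thresholds, function(th) {
    cfg <- config
    cfg$detection_threshold <- th
    counts <- purrr::map(frames, function(fr) {
      rep <- cross_check_match(fr$frame, decode_maps(fr$maps, cfg))
      c(tp = rep$tp, fp = rep$fp, fn = rep$fn)
    })
    tot <- Reduce(`+`, counts)
    m <- compute_metrics(tot[["tp"]], tot[["fp"]], tot[["fn"]])
    tibble::tibble(
      threshold = th, tp = tot[["tp"]], fp = tot[["fp"]], fn = tot[["fn"]],
      recall = m$recall, precision = m$precision, f_measure = m$f_measure
    )
  })
  out <- dplyr::bind_rows(rows)
  tibble::new_tibble(out, class = "pr_curve")
}

#' Plot a precision-recall curve
#'
#' @param object a `pr_curve` from [pr_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$threshold)) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision", colour = "Threshold") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Write a PR sweep as CSV
#'
#' Columns mirror the tabular layout used for threshold sweeps:
#' threshold, tp, fp, fn, recall, precision, f_measure.
#'
#' @param curve a `pr_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pr_csv <- function(curve, path) {
  utils::write.csv(tibble::as_tibble(curve), path, row.names = FALSE)
  invisible(path)
}
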