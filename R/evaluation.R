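# Detection/classification metrics: precision, recall, F1, all-point
# interpolated average precision, mAP, confusion matrices, and ethogram
# time-budget statistics. Behavior detection is scored at 1 Hz keyframes
# with class-wise greedy matching at a configurable IoU threshold (0.5 by
# default), the standard protocol for AVA-style spatiotemporal tasks.

#' Precision, recall and F1 from match counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`,
#' `F1 = 2 P R / (P + R)`. Zero-denominator cases return 0 and set the
#' `degenerate` flag (set `na_degenerate = TRUE` for NaN instead).
#'
#' @param tp,fp,fn Nonnegative counts.
#' @param na_degenerate Return NaN rather than 0 for 0/0 cases.
#' @return List with `precision`, `recall`, `f1`, `degenerate`.
#' @export
precision_recall_f1 <- function(tp, fp, fn, na_degenerate = FALSE) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  zero <- if (na_degenerate) NaN else 0
  p <- if (tp + fp > 0) tp / (tp + fp) else zero
  r <- if (tp + fn > 0) tp / (tp + fn) else zero
  f1 <- f1_measure(p, r, na_degenerate = na_degenerate)
  list(precision = p, recall = r, f1 = f1,
       degenerate = (tp + fp == 0) || (tp + fn == 0))
}

#' Harmonic mean of precision and recall
#'
#' Scale-free: precision and recall may be given as fractions or as
#' percentages and the F1 comes back on the same scale.
#'
#' @param precision,recall Nonnegative values on a common scale.
#' @param na_degenerate Return NaN rather than 0 when `P + R = 0`.
#' @export
f1_measure <- function(precision, recall, na_degenerate = FALSE) {
  s <- precision + recall
  ifelse(!is.na(s) & s > 0, 2 * precision * recall / s,
         if (na_degenerate) NaN else 0)
}

# AP of a ranked TP/FP outcome sequence under all-point interpolation.
ap_from_ranked <- function(tp_flags, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(tp_flags)) return(0)
  tp <- cumsum(tp_flags)
  fp <- cumsum(!tp_flags)
  prec <- tp / (tp + fp)
  rec <- tp / n_gt
  for (i in rev(seq_along(prec))[-1L]) prec[i] <- max(prec[i], prec[i + 1L])
  prev <- c(0, rec[-length(rec)])
  sum((rec - prev) * prec)
}

# Greedy confidence-descending matching of predictions to ground truth
# within (video_id, timestamp) groups; each GT box is matched at most once.
match_predictions <- function(pred, gt, iou_threshold = 0.5,
                              by_class = TRUE) {
  if (!nrow(pred))
    return(list(tp = logical(), matched_gt = integer(), order = integer()))
  ord <- order(-pred$score)
  matched <- rep(NA_integer_, nrow(pred))
  gt_taken <- rep(FALSE, nrow(gt))
  for (k in ord) {
    cand <- which(!gt_taken &
                    gt$video_id == pred$video_id[k] &
                    gt$timestamp == pred$timestamp[k] &
                    (!by_class | gt$action_id == pred$action_id[k]))
    if (!length(cand)) next
    ious <- vapply(cand, function(j)
      iou(as.numeric(pred[k, c("x1", "y1", "x2", "y2")]),
          as.numeric(gt[j, c("x1", "y1", "x2", "y2")])), numeric(1L))
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      matched[k] <- cand[best]
      gt_taken[cand[best]] <- TRUE
    }
  }
  list(tp = !is.na(matched), matched_gt = matched, order = ord)
}

#' Average precision of behavior predictions
#'
#' Confidence-descending greedy matching of predicted boxes to ground
#' truth of the same class at `IoU >= iou_threshold` (each ground-truth
#' box matched at most once), followed by the area under the all-point
#' interpolated precision-recall curve.
#'
#' @param predictions data.frame with `video_id`, `timestamp`, `x1`,
#'   `y1`, `x2`, `y2`, `action_id`, `score`.
#' @param ground_truth data.frame with the same box columns plus
#'   `action_id` (an AVA table from [read_ava_csv()] works).
#' @param iou_threshold Matching threshold.
#' @param class Single `action_id`; default computes one AP per class
#'   present in the ground truth.
#' @return Named numeric vector of AP values (fractions). Classes without
#'   ground truth are omitted with a warning.
#' @export
average_precision <- function(predictions, ground_truth, iou_threshold = 0.5,
                              class = NULL) {
  classes <- if (is.null(class)) sort(unique(ground_truth$action_id)) else class
  missing <- setdiff(unique(predictions$action_id), unique(ground_truth$action_id))
  if (is.null(class) && length(missing))
    warning("no ground truth for class(es) ",
            paste(missing, collapse = ", "), "; excluded from AP")
  ap <- vapply(classes, function(cl) {
    p <- predictions[predictions$action_id == cl, , drop = FALSE]
    g <- ground_truth[ground_truth$action_id == cl, , drop = FALSE]
    m <- match_predictions(p, g, iou_threshold)
    ap_from_ranked(m$tp[m$order], nrow(g))
  }, numeric(1L))
  names(ap) <- names(satsn_actions)[match(classes, satsn_actions)]
  ap
}

#' Mean average precision
#'
#' @param ap_values Numeric vector of per-class AP values (any scale).
#' @return Their arithmetic mean.
#' @export
mean_ap <- function(ap_values) {
  if (!length(ap_values)) stop("mean_ap needs at least one AP value")
  mean(ap_values)
}

#' Confusion matrix
#'
#' @param true_labels,pred_labels Integer labels in `1..k`.
#' @param k Number of classes.
#' @return `k x k` count matrix; entry `(i, j)` counts samples with true
#'   class `i` predicted as class `j`.
#' @export
confusion_matrix <- function(true_labels, pred_labels, k = 4L) {
  if (length(true_labels) != length(pred_labels))
    stop("label vectors differ in length")
  if (length(true_labels) &&
      (any(!true_labels %in% seq_len(k)) || any(!pred_labels %in% seq_len(k))))
    stop("labels must lie in 1..k")
  m <- matrix(0L, k, k,
              dimnames = list(true = satsn_action_names[seq_len(k)],
                              predicted = satsn_action_names[seq_len(k)]))
  for (i in seq_along(true_labels))
    m[true_labels[i], pred_labels[i]] <- m[true_labels[i], pred_labels[i]] + 1L
  m
}

#' Full evaluation of behavior predictions against ground truth
#'
#' Combines per-class AP with operating-point precision/recall/F1 (every
#' prediction counted: matched = TP, unmatched prediction = FP, unmatched
#' ground truth = FN) and a confusion matrix built from class-agnostic box
#' matches.
#'
#' @inheritParams average_precision
#' @return List of class `satsn_eval` with `per_class` (data.frame),
#'   `mAP`, `confusion`, `iou_threshold`.
#' @export
evaluate_predictions <- function(predictions, ground_truth,
                                 iou_threshold = 0.5) {
  classes <- sort(unique(ground_truth$action_id))
  ap <- average_precision(predictions, ground_truth, iou_threshold)
  rows <- lapply(seq_along(classes), function(ci) {
    cl <- classes[ci]
    p <- predictions[predictions$action_id == cl, , drop = FALSE]
    g <- ground_truth[ground_truth$action_id == cl, , drop = FALSE]
    m <- match_predictions(p, g, iou_threshold)
    tp <- sum(m$tp); fp <- sum(!m$tp); fn <- nrow(g) - tp
    pr <- precision_recall_f1(tp, fp, fn)
    data.frame(class = satsn_action_names[match(cl, satsn_actions)],
               action_id = cl, ap = unname(ap[ci]),
               precision = pr$precision, recall = pr$recall, f1 = pr$f1,
               tp = tp, fp = fp, fn = fn)
  })
  per_class <- do.call(rbind, rows)
  # class-agnostic matching for the confusion matrix
  m <- match_predictions(predictions, ground_truth, iou_threshold,
                         by_class = FALSE)
  keep <- which(m$tp)
  conf <- confusion_matrix(ground_truth$action_id[m$matched_gt[keep]],
                           predictions$action_id[keep],
                           k = max(satsn_actions))
  structure(list(per_class = per_class,
                 mAP = mean_ap(per_class$ap[!is.na(per_class$ap)]),
                 confusion = conf, iou_threshold = iou_threshold),
            class = "satsn_eval")
}

#' @export
print.satsn_eval <- function(x, ...) {
  cat(sprintf("Behavior detection evaluation (IoU >= %.2f)\n", x$iou_threshold))
  print(x$per_class[, c("class", "ap", "precision", "recall", "f1")],
        row.names = FALSE, digits = 4L)
  cat(sprintf("mAP: %.4f\n", x$mAP))
  invisible(x)
}

#' Ethogram time budget and event counts
#'
#' Durations are label-run lengths divided by `fps`; an event is a maximal
#' run of one behavior of at least `min_event_s` seconds. With a window
#' length the sequence is split into consecutive windows and statistics
#' are reported per window; per-window durations sum to the window length.
#'
#' @param labels Character or integer per-frame behavior labels of one
#'   tracked individual.
#' @param fps Frame rate.
#' @param window_s Optional window length in seconds.
#' @param min_event_s Minimum run length to count as one event (seconds).
#' @return data.frame with `window`, `behavior`, `duration_s`, `events`.
#' @export
time_budget <- function(labels, fps, window_s = NULL, min_event_s = 1) {
  if (is.numeric(labels)) labels <- satsn_action_names[labels]
  n <- length(labels)
  if (!n) {
    return(data.frame(window = integer(), behavior = character(),
                      duration_s = numeric(), events = integer()))
  }
  win_len <- if (is.null(window_s)) n else max(1L, round(window_s * fps))
  win_id <- (seq_len(n) - 1L) %/% win_len + 1L
  min_len <- max(1L, round(min_event_s * fps))
  out <- lapply(unique(win_id), function(w) {
    lab <- labels[win_id == w]
    r <- rle(lab)
    dur <- tapply(r$lengths, r$values, sum) / fps
    ev <- tapply(r$lengths >= min_len, r$values, sum)
    data.frame(window = w,
               behavior = satsn_action_names,
               duration_s = as.numeric(dur[satsn_action_names]) |>
                 (\(x) ifelse(is.na(x), 0, x))(),
               events = as.integer(ev[satsn_action_names]) |>
                 (\(x) ifelse(is.na(x), 0L, x))())
  })
  do.call(rbind, out)
}

#' Count identity switches of tracks against ground truth
#'
#' Each ground-truth agent is matched per frame to the track whose box
#' overlaps it most (IoU > 0.3); an identity switch is a change in the
#' matched track id across an agent's lifetime (gaps with no matched
#' track are skipped).
#'
#' @param tracks data.frame with `frame`, `track_id`, `x1`, `y1`, `x2`,
#'   `y2` (e.g. from [track_video()]).
#' @param gt Ground-truth data.frame from [render_scene()].
#' @return Integer number of identity switches summed over agents.
#' @export
id_switch_count <- function(tracks, gt) {
  switches <- 0L
  for (aid in unique(gt$agent_id)) {
    g <- gt[gt$agent_id == aid, , drop = FALSE]
    ids <- integer(0L)
    for (i in seq_len(nrow(g))) {
      tr <- tracks[tracks$frame == g$frame[i], , drop = FALSE]
      if (!nrow(tr)) next
      ious <- vapply(seq_len(nrow(tr)), function(j)
        iou(as.numeric(tr[j, c("x1", "y1", "x2", "y2")]),
            as.numeric(g[i, c("x1", "y1", "x2", "y2")])), numeric(1L))
      if (max(ious) > 0.3) ids <- c(ids, tr$track_id[which.max(ious)])
    }
    if (length(ids) > 1L) switches <- switches + sum(diff(ids) != 0L)
  }
  switches
}
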