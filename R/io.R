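# File formats: AVA-style behavior annotation CSV and JSON-lines detection
# streams, plus seeded dataset splitting.

#' Read an AVA-format behavior annotation CSV
#'
#' The dialect is fixed to eight comma-separated fields without a header:
#' `video_id, timestamp, x1, y1, x2, y2, action_id, entity_id`.
#' Timestamps are integer seconds (1 Hz keyframes); box coordinates are
#' normalized to `[0, 1]` by the frame width (x) and height (y);
#' `action_id` is one of [satsn_actions].
#'
#' @param path Path to the CSV file. An empty file yields a zero-row table.
#' @return data.frame with columns `video_id`, `timestamp`, `x1`, `y1`,
#'   `x2`, `y2`, `action_id`, `entity_id`.
#' @export
read_ava_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(video_id = character(), timestamp = integer(),
                      x1 = numeric(), y1 = numeric(),
                      x2 = numeric(), y2 = numeric(),
                      action_id = integer(), entity_id = integer())
  if (!length(lines)) return(empty)
  parts <- strsplit(lines, ",", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != 8L))
    stop("malformed AVA row(s) at line(s) ",
         paste(utils::head(which(nfield != 8L), 5L), collapse = ", "),
         ": expected 8 comma-separated fields")
  m <- do.call(rbind, parts)
  out <- data.frame(video_id = m[, 1L],
                    timestamp = as.integer(m[, 2L]),
                    x1 = as.numeric(m[, 3L]), y1 = as.numeric(m[, 4L]),
                    x2 = as.numeric(m[, 5L]), y2 = as.numeric(m[, 6L]),
                    action_id = as.integer(m[, 7L]),
                    entity_id = as.integer(m[, 8L]))
  num_bad <- which(!stats::complete.cases(out[c("timestamp", "x1", "y1", "x2",
                                                "y2", "action_id", "entity_id")]))
  if (length(num_bad))
    stop("non-numeric fields in AVA row(s) at line(s) ",
         paste(utils::head(num_bad, 5L), collapse = ", "))
  coord_bad <- which(out$x1 < 0 | out$y1 < 0 | out$x2 > 1 | out$y2 > 1 |
                       out$x1 >= out$x2 | out$y1 >= out$y2)
  if (length(coord_bad))
    stop("invalid normalized box (need 0 <= x1 < x2 <= 1, 0 <= y1 < y2 <= 1) ",
         "at line(s) ", paste(utils::head(coord_bad, 5L), collapse = ", "))
  act_bad <- which(!out$action_id %in% satsn_actions)
  if (length(act_bad))
    stop("unknown action_id at line(s) ",
         paste(utils::head(act_bad, 5L), collapse = ", "))
  out
}

#' Write an AVA-format behavior annotation CSV
#'
#' Deterministic text output; `read_ava_csv(write_ava_csv(x, p))` returns a
#' table equal to `x`. Coordinates are printed with six decimals, which is
#' the dialect's fixed precision (inputs are expected at that precision or
#' coarser).
#'
#' @param records data.frame as returned by [read_ava_csv()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ava_csv <- function(records, path) {
  if (nrow(records)) {
    lines <- sprintf("%s,%d,%s,%s,%s,%s,%d,%d",
                     records$video_id, as.integer(records$timestamp),
                     fmt6(records$x1), fmt6(records$y1),
                     fmt6(records$x2), fmt6(records$y2),
                     as.integer(records$action_id), as.integer(records$entity_id))
  } else lines <- character()
  writeLines(lines, path)
  invisible(path)
}

fmt6 <- function(x) formatC(x, digits = 6L, format = "f")

#' Read / write a JSON-lines detection stream
#'
#' One JSON object per line with fields `frame` (integer, >= 1), `box`
#' (`x1`, `y1`, `x2`, `y2` in pixels), `score` and `mouth` (`x`, `y`,
#' `visible`). A detection without a `mouth` field is accepted with
#' `visible = 0` and a warning. Output is grouped per frame and sorted by
#' frame index, making the round trip canonical.
#'
#' @param path File path.
#' @return `read_detection_stream` returns a detection data.frame (see
#'   [detection_table()]).
#' @export
read_detection_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(detection_table())
  n_missing_mouth <- 0L
  rows <- lapply(seq_along(lines), function(i) {
    obj <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                    error = function(e) stop("invalid JSON on line ", i, ": ",
                                             conditionMessage(e)))
    for (f in c("frame", "box", "score"))
      if (is.null(obj[[f]])) stop("detection on line ", i, " lacks field '", f, "'")
    mouth <- obj$mouth
    if (is.null(mouth)) {
      n_missing_mouth <<- n_missing_mouth + 1L
      mouth <- list(x = NA_real_, y = NA_real_, visible = 0)
    }
    data.frame(frame = as.integer(obj$frame),
               x1 = obj$box$x1, y1 = obj$box$y1,
               x2 = obj$box$x2, y2 = obj$box$y2,
               score = obj$score,
               mouth_x = as.numeric(mouth$x), mouth_y = as.numeric(mouth$y),
               mouth_visible = as.numeric(mouth$visible))
  })
  if (n_missing_mouth > 0L)
    warning(n_missing_mouth, " detection(s) lacked a mouth keypoint; ",
            "accepted with visible = 0")
  validate_detections(do.call(rbind, rows))
}

#' @rdname read_detection_stream
#' @param dets Detection data.frame.
#' @export
write_detection_stream <- function(dets, path) {
  dets <- validate_detections(dets)
  lines <- vapply(seq_len(nrow(dets)), function(i) {
    d <- dets[i, ]
    jsonlite::toJSON(list(
      frame = d$frame,
      box = list(x1 = d$x1, y1 = d$y1, x2 = d$x2, y2 = d$y2),
      score = d$score,
      mouth = list(x = d$mouth_x, y = d$mouth_y, visible = d$mouth_visible)),
      auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Split items into seeded, disjoint partitions
#'
#' Partition sizes are floor-allocated from the normalized ratios with the
#' remainder given to the first partition; this reproduces the published
#' splits exactly (2200 items at 8:1:1 give 1760/220/220; 420 items at 8:2
#' give 336/84). Items are shuffled with the given seed before allocation.
#'
#' @param item_ids Vector of item identifiers.
#' @param ratios Positive weights, normalized internally.
#' @param seed Integer seed for the shuffle.
#' @return List of partitions (same type as `item_ids`), one per ratio.
#' @export
split_dataset <- function(item_ids, ratios, seed = 1L) {
  if (any(ratios < 0)) stop("ratios must be nonnegative")
  if (sum(ratios) <= 0) stop("ratios must have a positive sum")
  p <- ratios / sum(ratios)
  n <- length(item_ids)
  sizes <- floor(n * p)
  sizes[1L] <- sizes[1L] + (n - sum(sizes))
  shuffled <- if (n > 0) item_ids[sample_seeded(n, seed)] else item_ids
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0L) item_ids[0L] else shuffled[starts[i]:ends[i]]
  })
}

# Seeded permutation that leaves the caller's RNG state untouched.
sample_seeded <- function(n, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  sample.int(n)
}

#' Evaluate an expression with a fixed RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded stages do not perturb each other.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
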