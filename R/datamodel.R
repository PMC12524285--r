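# Core domain types. Boxes are continuous pixel coordinates, origin at the
# top-left corner, x growing right and y growing down; frames are arrays of
# dim c(H, W, 3) with intensities in [0, 1].

#' Construct a bounding box
#'
#' @param x1,y1,x2,y2 Box corners in pixels (origin top-left, closed
#'   intervals). Must satisfy `x1 < x2`, `y1 < y2` and be finite.
#' @return Named numeric vector of class `satsn_bbox`.
#' @export
bbox <- function(x1, y1, x2, y2) {
  b <- c(x1 = as.numeric(x1), y1 = as.numeric(y1),
         x2 = as.numeric(x2), y2 = as.numeric(y2))
  validate_bbox(b)
  class(b) <- "satsn_bbox"
  b
}

validate_bbox <- function(b) {
  if (any(!is.finite(b))) stop("bounding box coordinates must be finite")
  if (b[["x1"]] >= b[["x2"]] || b[["y1"]] >= b[["y2"]])
    stop("degenerate bounding box: need x1 < x2 and y1 < y2")
  invisible(b)
}

#' Construct a keypoint
#'
#' @param x,y Pixel coordinates.
#' @param visible Visibility flag: 0 = absent (x, y are ignored by all
#'   consumers), 1 = present but occluded, 2 = visible.
#' @return Named numeric vector of class `satsn_keypoint`.
#' @export
keypoint <- function(x, y, visible = 2L) {
  if (!visible %in% c(0L, 1L, 2L)) stop("keypoint visibility must be 0, 1 or 2")
  k <- c(x = as.numeric(x), y = as.numeric(y), visible = as.numeric(visible))
  class(k) <- "satsn_keypoint"
  k
}

#' Construct a video clip
#'
#' @param frames List of frames, each an array of dim `c(H, W, 3)` with
#'   values in `[0, 1]`; all frames must share the same size.
#' @param clip_id Character identifier.
#' @param fps Frame rate (frames/second, default 30).
#' @return Object of class `video_clip` with fields `clip_id`, `frames`,
#'   `fps`, `height`, `width`.
#' @export
video_clip <- function(frames, clip_id = "clip", fps = 30) {
  if (length(frames) < 1L) stop("a clip needs at least one frame")
  if (fps <= 0) stop("fps must be positive")
  d <- dim(frames[[1L]])
  if (length(d) != 3L || d[3L] != 3L) stop("frames must be H x W x 3 arrays")
  same <- vapply(frames, function(f) identical(dim(f), d), logical(1L))
  if (!all(same)) stop("all frames must share the same dimensions")
  structure(list(clip_id = clip_id, frames = frames, fps = fps,
                 height = d[1L], width = d[2L]),
            class = "video_clip")
}

#' @export
print.video_clip <- function(x, ...) {
  cat(sprintf("<video_clip %s: %d frames, %dx%d px, %.3g fps>\n",
              x$clip_id, length(x$frames), x$height, x$width, x$fps))
  invisible(x)
}

#' Detection tables
#'
#' Detections are held as a data.frame with one row per detection and
#' columns `frame` (integer, first frame = 1), `x1`, `y1`, `x2`, `y2`
#' (body box, pixels), `score` (confidence in `[0, 1]`), `mouth_x`,
#' `mouth_y`, `mouth_visible` (0/1/2). `detection_table()` builds and
#' validates such a table.
#'
#' @param frame,x1,y1,x2,y2,score,mouth_x,mouth_y,mouth_visible Column
#'   vectors, recycled to a common length.
#' @return A validated detection data.frame sorted by frame.
#' @export
detection_table <- function(frame = integer(), x1 = numeric(), y1 = numeric(),
                            x2 = numeric(), y2 = numeric(), score = numeric(),
                            mouth_x = numeric(), mouth_y = numeric(),
                            mouth_visible = numeric()) {
  d <- data.frame(frame = as.integer(frame), x1 = x1, y1 = y1, x2 = x2, y2 = y2,
                  score = score, mouth_x = mouth_x, mouth_y = mouth_y,
                  mouth_visible = mouth_visible)
  validate_detections(d)
}

validate_detections <- function(d) {
  req <- c("frame", "x1", "y1", "x2", "y2", "score",
           "mouth_x", "mouth_y", "mouth_visible")
  miss <- setdiff(req, names(d))
  if (length(miss)) stop("detection table missing columns: ",
                         paste(miss, collapse = ", "))
  if (nrow(d)) {
    if (any(d$frame < 1L)) stop("detection frame indices must be >= 1")
    if (any(d$score < 0 | d$score > 1)) stop("detection scores must lie in [0, 1]")
    bad <- which(d$x1 >= d$x2 | d$y1 >= d$y2)
    if (length(bad)) stop("degenerate detection boxes at rows ",
                          paste(utils::head(bad, 5L), collapse = ", "))
    if (any(!d$mouth_visible %in% c(0, 1, 2)))
      stop("mouth_visible must be 0, 1 or 2")
  }
  d[order(d$frame), , drop = FALSE]
}

#' Pipeline configuration
#'
#' Assembles the configuration shared by routing, the network and training.
#' Defaults follow the published training setup (batch size 4, 200 epochs,
#' learning rate 0.02, momentum 0.9) and a slow/fast sampling plan of
#' `T` slow frames at temporal stride `tau` with `alpha * T` fast frames.
#'
#' @param T Number of slow-pathway frames.
#' @param tau Temporal stride of the slow pathway (frames).
#' @param alpha Fast/slow frame-rate ratio (> 1 in the two-stream design;
#'   `alpha = 1` is accepted for degenerate testing).
#' @param beta Fast-pathway channel fraction (0 < beta < 1).
#' @param crop_size Side length in pixels of the mouth-region crop
#'   (128 for full-resolution zoo video; scale down with the frame size).
#' @param routing_scheme One of `"A"` (full body in both pathways), `"B"`
#'   (mouth crop in the fast pathway) or `"C"` (mouth crop in the slow
#'   pathway).
#' @param num_classes Number of behavior classes (4).
#' @param seed Integer seed recorded in the config.
#' @param batch_size,epochs,learning_rate,momentum Training block.
#' @return A list of class `satsn_config`.
#' @export
satsn_config <- function(T = 4L, tau = 4L, alpha = 4L, beta = 1 / 8,
                         crop_size = 128L, routing_scheme = "B",
                         num_classes = 4L, seed = 1L,
                         batch_size = 4L, epochs = 200L,
                         learning_rate = 0.02, momentum = 0.9) {
  if (!(beta > 0 && beta < 1)) stop("beta must lie in (0, 1)")
  if (crop_size < 1) stop("crop_size must be positive")
  if (!routing_scheme %in% c("A", "B", "C")) stop("routing_scheme must be A, B or C")
  if (alpha < 1) stop("alpha must be >= 1")
  cfg <- list(T = as.integer(T), tau = as.integer(tau), alpha = as.integer(alpha),
              beta = beta, crop_size = as.integer(crop_size),
              routing_scheme = routing_scheme,
              num_classes = as.integer(num_classes), seed = as.integer(seed),
              training = list(batch_size = as.integer(batch_size),
                              epochs = as.integer(epochs),
                              learning_rate = learning_rate,
                              momentum = momentum))
  class(cfg) <- "satsn_config"
  cfg
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path File path.
#' @param cfg A `satsn_config`.
#' @return `read_config` returns a `satsn_config`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  tr <- raw$training %||% list()
  do.call(satsn_config, c(
    raw[intersect(names(raw), c("T", "tau", "alpha", "beta", "crop_size",
                                "routing_scheme", "num_classes", "seed"))],
    tr[intersect(names(tr), c("batch_size", "epochs", "learning_rate", "momentum"))]))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
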