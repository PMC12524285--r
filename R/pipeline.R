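# Pipeline orchestration: the command functions behind the CLI script
# (inst/cli/satsn.R). Every command honors an explicit seed, works from
# the formats defined in the I/O module, and writes a machine-readable
# run manifest next to its outputs.

write_run_manifest <- function(out_dir, stage, config, seed, inputs,
                               outputs, t_start) {
  manifest <- list(stage = stage,
                   package_version = as.character(utils::packageVersion("satsn")),
                   seed = seed, config = config,
                   inputs = inputs, outputs = outputs,
                   elapsed_s = as.numeric(Sys.time()) - t_start)
  path <- file.path(out_dir, paste0("manifest_", stage, ".json"))
  tmp <- paste0(path, ".tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  file.rename(tmp, path)
  invisible(path)
}

#' Pipeline commands
#'
#' Thin orchestration wrappers over the package's stages, used by the
#' `satsn` CLI script: `cmd_simulate` writes a synthetic fixture dataset,
#' `cmd_track` runs the tracker over a detection stream, `cmd_train`
#' trains on a fixture dataset, `cmd_infer` classifies tracked boxes at
#' keyframes, `cmd_evaluate` scores predictions against ground truth and
#' `cmd_stats` computes ethogram statistics from predictions.
#'
#' @param out_dir Output directory.
#' @param n_clips Number of clips to simulate.
#' @param seed Integer seed.
#' @param scene A [scene_config()].
#' @param pipeline A [satsn_config()].
#' @param write_frames Write PNG frames for each clip.
#' @param force Overwrite an existing dataset.
#' @return Each command invisibly returns its primary output path.
#' @export
cmd_simulate <- function(out_dir, n_clips = 40L, seed = 1L,
                         scene = scene_config(), pipeline = satsn_config(),
                         write_frames = FALSE, force = FALSE) {
  t0 <- as.numeric(Sys.time())
  make_fixture_dataset(out_dir, n_clips = n_clips, cfg = scene,
                       pipeline = pipeline, seed = seed,
                       write_frames = write_frames, force = force)
  write_run_manifest(out_dir, "simulate",
                     list(n_clips = n_clips, scene = unclass(scene)),
                     seed, list(), list(dataset = out_dir), t0)
  invisible(out_dir)
}

#' @rdname cmd_simulate
#' @param detections Path to a JSON-lines detection stream.
#' @param out_csv Output MOT CSV path.
#' @param tracker A [tracker_config()].
#' @export
cmd_track <- function(detections, out_csv, tracker = tracker_config()) {
  if (!file.exists(detections)) stop("missing detection stream: ", detections)
  t0 <- as.numeric(Sys.time())
  dets <- read_detection_stream(detections)
  tracks <- track_video(dets, tracker)
  write_mot_csv(tracks, out_csv)
  write_run_manifest(dirname(out_csv), "track", unclass(tracker), NA,
                     list(detections = detections), list(mot = out_csv), t0)
  invisible(out_csv)
}

# Load a fixture clip directory (PNG frames written by cmd_simulate).
load_fixture_clip <- function(clip_dir, fps = 16) {
  files <- sort(list.files(clip_dir, pattern = "^frame_\\d+\\.png$",
                           full.names = TRUE))
  if (!length(files)) stop("no frames in ", clip_dir)
  frames <- lapply(files, function(f) {
    img <- png::readPNG(f)
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), dim = c(dim(img), 3L))
    img[, , 1:3, drop = FALSE]
  })
  video_clip(frames, clip_id = basename(clip_dir), fps = fps)
}

route_fixture_samples <- function(data_dir, split, pipeline, arch,
                                  mode = "training", scheme = "B") {
  manifest <- jsonlite::read_json(file.path(data_dir, "manifest.json"),
                                  simplifyVector = TRUE)
  fps <- manifest$scene$fps
  ava <- read_ava_csv(file.path(data_dir, paste0(split, ".csv")))
  W <- manifest$scene$width; H <- manifest$scene$height
  samples <- list(); labels <- integer(); boxes <- list()
  for (i in seq_len(nrow(ava))) {
    rec <- ava[i, ]
    cdir <- file.path(data_dir, rec$video_id)
    clip <- load_fixture_clip(cdir, fps = fps)
    dets <- read_detection_stream(file.path(cdir, "detections.jsonl"))
    f <- keyframe_index(rec$timestamp, fps)
    cand <- dets[abs(dets$frame - f) <= 3L, , drop = FALSE]
    if (!nrow(cand)) next
    d <- cand[which.min(abs(cand$frame - f)), ]
    lab <- satsn_action_names[rec$action_id]
    samples[[length(samples) + 1L]] <- route_inputs(
      clip, bbox(d$x1, d$y1, d$x2, d$y2),
      keypoint(d$mouth_x, d$mouth_y, d$mouth_visible),
      scheme = scheme, config = pipeline, input_size = arch$input_size,
      label_hint = if (mode == "training") lab else NULL,
      center_frame = f)
    labels <- c(labels, rec$action_id)
    boxes[[length(boxes) + 1L]] <-
      data.frame(video_id = rec$video_id, timestamp = rec$timestamp,
                 x1 = d$x1 / W, y1 = d$y1 / H, x2 = d$x2 / W, y2 = d$y2 / H)
  }
  list(samples = samples, labels = labels, boxes = do.call(rbind, boxes))
}

#' @rdname cmd_simulate
#' @param data_dir Fixture dataset directory (from `cmd_simulate` with
#'   frames).
#' @param checkpoint Checkpoint path (output for `cmd_train`, input for
#'   `cmd_infer`).
#' @param arch A [satsn_arch_config()].
#' @param epochs Training epochs.
#' @param scheme Routing scheme.
#' @export
cmd_train <- function(data_dir, checkpoint, arch = satsn_arch_config("tiny"),
                      pipeline = satsn_config(crop_size = 32L),
                      epochs = 15L, scheme = "B", seed = 1L) {
  t0 <- as.numeric(Sys.time())
  set <- route_fixture_samples(data_dir, "train", pipeline, arch,
                               mode = "training", scheme = scheme)
  if (!length(set$samples)) stop("no trainable samples in ", data_dir)
  model <- train_satsn(set$samples, set$labels, arch = arch, epochs = epochs,
                       batch_size = pipeline$training$batch_size,
                       learning_rate = pipeline$training$learning_rate,
                       momentum = pipeline$training$momentum, seed = seed)
  save_checkpoint(model, checkpoint)
  log <- attr(model, "log")
  utils::write.csv(log, paste0(checkpoint, ".log.csv"), row.names = FALSE)
  write_run_manifest(dirname(checkpoint), "train",
                     list(arch = unclass(arch), epochs = epochs,
                          scheme = scheme),
                     seed, list(data = data_dir),
                     list(checkpoint = checkpoint), t0)
  invisible(checkpoint)
}

#' Read / write a predictions CSV
#'
#' AVA dialect plus a ninth `score` column.
#'
#' @param path File path.
#' @export
read_predictions_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(cbind(read_ava_csv_empty(), score = numeric()))
  m <- do.call(rbind, strsplit(lines, ",", fixed = TRUE))
  data.frame(video_id = m[, 1L], timestamp = as.integer(m[, 2L]),
             x1 = as.numeric(m[, 3L]), y1 = as.numeric(m[, 4L]),
             x2 = as.numeric(m[, 5L]), y2 = as.numeric(m[, 6L]),
             action_id = as.integer(m[, 7L]), entity_id = as.integer(m[, 8L]),
             score = as.numeric(m[, 9L]))
}

#' @rdname read_predictions_csv
#' @param preds Prediction data.frame.
#' @export
write_predictions_csv <- function(preds, path) {
  lines <- if (nrow(preds)) sprintf("%s,%d,%s,%s,%s,%s,%d,%d,%s",
                                    preds$video_id, preds$timestamp,
                                    fmt6(preds$x1), fmt6(preds$y1),
                                    fmt6(preds$x2), fmt6(preds$y2),
                                    preds$action_id, preds$entity_id,
                                    fmt6(preds$score)) else character()
  writeLines(lines, path)
  invisible(path)
}

#' @rdname cmd_simulate
#' @param out_pred Output predictions CSV.
#' @export
cmd_infer <- function(data_dir, checkpoint, out_pred,
                      pipeline = satsn_config(crop_size = 32L),
                      scheme = "B", seed = 1L) {
  t0 <- as.numeric(Sys.time())
  model <- load_checkpoint(checkpoint)
  set <- route_fixture_samples(data_dir, "test", pipeline, model$arch,
                               mode = "inference", scheme = scheme)
  if (length(set$samples)) {
    probs <- satsn_predict(model, set$samples)
    top <- max.col(probs)
    preds <- cbind(set$boxes, action_id = top,
                   entity_id = seq_along(top),
                   score = probs[cbind(seq_along(top), top)])
  } else {
    preds <- cbind(read_ava_csv_empty(), score = numeric())
  }
  write_predictions_csv(preds, out_pred)
  write_run_manifest(dirname(out_pred), "infer",
                     list(scheme = scheme), seed,
                     list(data = data_dir, checkpoint = checkpoint),
                     list(predictions = out_pred), t0)
  invisible(out_pred)
}

#' @rdname cmd_simulate
#' @param pred_csv Predictions CSV path.
#' @param gt_csv Ground-truth AVA CSV path.
#' @param out_json Output report path.
#' @param iou_threshold Matching threshold.
#' @export
cmd_evaluate <- function(pred_csv, gt_csv, out_json, iou_threshold = 0.5) {
  t0 <- as.numeric(Sys.time())
  preds <- read_predictions_csv(pred_csv)
  gt <- read_ava_csv(gt_csv)
  ev <- evaluate_predictions(preds, gt, iou_threshold)
  report <- list(per_class = ev$per_class, mAP = ev$mAP,
                 confusion = ev$confusion, iou_threshold = iou_threshold)
  jsonlite::write_json(report, out_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  write_run_manifest(dirname(out_json), "evaluate",
                     list(iou_threshold = iou_threshold), NA,
                     list(pred = pred_csv, gt = gt_csv),
                     list(report = out_json), t0)
  invisible(out_json)
}

#' @rdname cmd_simulate
#' @param fps Frame rate used to convert run lengths to seconds.
#' @param window_s Window length for the statistics (seconds).
#' @param out_csv Output CSV path.
#' @export
cmd_stats <- function(pred_csv, out_csv, fps = 16, window_s = NULL) {
  t0 <- as.numeric(Sys.time())
  preds <- read_predictions_csv(pred_csv)
  out <- list()
  for (ent in unique(preds$entity_id)) {
    p <- preds[preds$entity_id == ent, , drop = FALSE]
    p <- p[order(p$timestamp), , drop = FALSE]
    # per-keyframe labels expanded to 1 s of frames each
    labels <- rep(p$action_id, each = max(1L, round(fps)))
    tb <- time_budget(labels, fps, window_s = window_s)
    tb$entity_id <- ent
    out[[length(out) + 1L]] <- tb
  }
  stats <- if (length(out)) do.call(rbind, out) else
    data.frame(window = integer(), behavior = character(),
               duration_s = numeric(), events = integer(),
               entity_id = integer())
  utils::write.csv(stats, out_csv, row.names = FALSE)
  write_run_manifest(dirname(out_csv), "stats",
                     list(fps = fps, window_s = window_s), NA,
                     list(pred = pred_csv), list(stats = out_csv), t0)
  invisible(out_csv)
}
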