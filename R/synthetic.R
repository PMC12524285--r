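# Synthetic multi-agent scenes. Agents are textured ellipses with a neck and
# head appendage moving over a static background that contains the two
# behavioral anchor objects: a vertical tree column and a horizontal feeding
# trough band. The four behaviors are encoded through motion signatures:
#   walking  - body translation (>= 2 px/frame),
#   standing - static body, head up (sway <= 0.2 px/frame),
#   eating   - static body, head lowered so the mouth sits in the trough
#              band, slow mouth-patch intensity oscillation,
#   licking  - static body, head up with the mouth within contact distance
#              of the tree column, fast small-amplitude mouth-patch
#              oscillation.
# Licking and eating therefore differ from standing only through mouth-region
# dynamics and head placement, which is exactly the signal the keypoint-
# guided routing is designed to exploit.

# Fixed agent geometry (pixels): body ellipse semi-axes, head offsets.
.AG <- list(body_a = 15, body_b = 8, head_dx = 22, head_dy_up = -20,
            head_dy_down = 18, head_a = 6, head_b = 5, mouth_dx = 6,
            mouth_down_dy = 3, mouth_reach = 28)

#' Synthetic scene configuration
#'
#' @param height,width Frame size in pixels.
#' @param n_frames Frames per clip.
#' @param fps Frame rate (frames/second).
#' @param tree_x Left edge of the vertical tree column.
#' @param tree_width Width of the tree column.
#' @param trough_y Two-vector: row range of the feeding-trough band.
#' @param img_noise Per-frame sensor noise s.d. (intensity units).
#' @param noise_sigma Detection box corner noise s.d. (pixels).
#' @param kp_sigma Mouth keypoint noise s.d. (pixels).
#' @param miss_rate Probability that a visible agent yields no detection.
#' @param occluders List of x-ranges `c(x1, x2)`; an agent whose center
#'   falls inside a strip is occluded (no detection).
#' @param seed Mandatory integer seed.
#' @return List of class `scene_config`.
#' @export
scene_config <- function(height = 160L, width = 256L, n_frames = 64L,
                         fps = 16, tree_x = 44, tree_width = 6,
                         trough_y = c(140, 157), img_noise = 0.01,
                         noise_sigma = 1.0, kp_sigma = 0.5, miss_rate = 0.02,
                         occluders = list(), seed = 1L) {
  stopifnot(height > 0, width > 0, n_frames >= 1, fps > 0,
            img_noise >= 0, noise_sigma >= 0, kp_sigma >= 0, miss_rate >= 0)
  if (is.null(seed)) stop("a seed is mandatory for scene generation")
  structure(list(height = as.integer(height), width = as.integer(width),
                 n_frames = as.integer(n_frames), fps = fps,
                 tree_x = tree_x, tree_width = tree_width, trough_y = trough_y,
                 img_noise = img_noise, noise_sigma = noise_sigma,
                 kp_sigma = kp_sigma, miss_rate = miss_rate,
                 occluders = occluders, seed = as.integer(seed)),
            class = "scene_config")
}

#' Script for one synthetic agent
#'
#' @param agent_id Integer id (entity id in the annotations).
#' @param behavior Either a single behavior name covering the whole clip or
#'   a data.frame with columns `start`, `end` (frame indices, 1-based,
#'   inclusive) and `behavior`; intervals must tile the clip without
#'   overlap.
#' @param start Numeric `c(x, y)` starting body-center position.
#' @param velocity `c(vx, vy)` pixels/frame, used while walking.
#' @param facing -1 (facing left) or +1 (facing right).
#' @return List of class `agent_script`.
#' @export
agent_script <- function(agent_id, behavior, start, velocity = c(0, 0),
                         facing = -1) {
  if (is.character(behavior) && length(behavior) == 1L)
    behavior <- data.frame(start = 1L, end = NA_integer_, behavior = behavior)
  stopifnot(all(behavior$behavior %in% satsn_action_names))
  structure(list(agent_id = as.integer(agent_id), behavior = behavior,
                 start = as.numeric(start), velocity = as.numeric(velocity),
                 facing = facing),
            class = "agent_script")
}

behavior_at <- function(script, t, n_frames) {
  b <- script$behavior
  b$end[is.na(b$end)] <- n_frames
  if (any(sort(b$start) != b$start) ||
      !identical(as.integer(c(1L, b$end[-nrow(b)] + 1L)), as.integer(b$start)) ||
      b$end[nrow(b)] != n_frames)
    stop("behavior intervals must tile frames 1..n_frames without overlap")
  b$behavior[which(t >= b$start & t <= b$end)[1L]]
}

# Per-frame kinematics and geometry for one agent. Returns centers, head and
# mouth positions and tight bounding boxes for every frame.
agent_trajectory <- function(script, cfg) {
  n <- cfg$n_frames
  g <- .AG
  pos <- matrix(NA_real_, n, 2L)
  p <- script$start
  clamped <- FALSE
  beh <- character(n)
  for (t in seq_len(n)) {
    beh[t] <- behavior_at(script, t, n)
    if (t > 1L) {
      if (beh[t] == "walking") p <- p + script$velocity
      else p <- script$start + c(0.1 * sin(0.25 * t), 0) # sub-0.2 px sway
      lo <- c(g$body_a + g$head_a + 2, abs(g$head_dy_up) + g$head_b + 2)
      hi <- c(cfg$width - lo[1L], cfg$height - g$head_dy_down - g$head_b - 4)
      if (any(p < lo) || any(p > hi)) clamped <- TRUE
      p <- pmin(pmax(p, lo), hi)
    }
    pos[t, ] <- p
  }
  if (clamped) warning("agent ", script$agent_id,
                       " clamped at the frame border")
  d <- ifelse(beh == "walking" & script$velocity[1L] != 0,
              sign(script$velocity[1L]), script$facing)
  head_dy <- ifelse(beh == "eating", g$head_dy_down, g$head_dy_up)
  head <- cbind(pos[, 1L] + d * g$head_dx, pos[, 2L] + head_dy)
  mouth <- cbind(head[, 1L] + d * g$mouth_dx,
                 head[, 2L] + ifelse(beh == "eating", g$mouth_down_dy, 0))
  x1 <- pmin(pos[, 1L] - g$body_a, head[, 1L] - g$head_a) - 1
  x2 <- pmax(pos[, 1L] + g$body_a, head[, 1L] + g$head_a) + 1
  y1 <- pmin(pos[, 2L] - g$body_b, head[, 2L] - g$head_b) - 1
  y2 <- pmax(pos[, 2L] + g$body_b, head[, 2L] + g$head_b) + 1
  list(pos = pos, head = head, mouth = mouth, behavior = beh, facing = d,
       box = cbind(x1 = x1, y1 = y1, x2 = x2, y2 = y2))
}

scene_background <- function(cfg) {
  H <- cfg$height; W <- cfg$width
  base <- array(0, dim = c(H, W, 3L))
  tex <- matrix(stats::rnorm(H * W, 0, 0.02), H, W)
  base[, , 1L] <- 0.55 + tex; base[, , 2L] <- 0.57 + tex; base[, , 3L] <- 0.5 + tex
  tx <- max(1L, round(cfg$tree_x)):min(W, round(cfg$tree_x + cfg$tree_width))
  base[, tx, 1L] <- 0.35; base[, tx, 2L] <- 0.22; base[, tx, 3L] <- 0.1
  ty <- max(1L, round(cfg$trough_y[1L])):min(H, round(cfg$trough_y[2L]))
  base[ty, , 1L] <- 0.3; base[ty, , 2L] <- 0.35; base[ty, , 3L] <- 0.45
  pmin(pmax(base, 0), 1)
}

# Paint one agent into a frame (in place). Pure array composition over the
# agent's local window; no graphics device involved.
paint_agent <- function(frame, center, head, mouth, facing, behavior, t,
                        spots, cfg) {
  H <- dim(frame)[1L]; W <- dim(frame)[2L]; g <- .AG
  x_lo <- max(1L, floor(min(center[1L] - g$body_a, head[1L] - g$head_a) - 2))
  x_hi <- min(W, ceiling(max(center[1L] + g$body_a, head[1L] + g$head_a) + 2))
  y_lo <- max(1L, floor(min(center[2L] - g$body_b, head[2L] - g$head_b) - 2))
  y_hi <- min(H, ceiling(max(center[2L] + g$body_b, head[2L] + g$head_b) + 2))
  if (x_lo > x_hi || y_lo > y_hi) return(frame)
  xs <- x_lo:x_hi; ys <- y_lo:y_hi
  X <- matrix(xs, length(ys), length(xs), byrow = TRUE)
  Y <- matrix(ys, length(ys), length(xs))
  body <- ((X - center[1L]) / g$body_a)^2 + ((Y - center[2L]) / g$body_b)^2 <= 1
  headm <- ((X - head[1L]) / g$head_a)^2 + ((Y - head[2L]) / g$head_b)^2 <= 1
  # neck: thick segment from body shoulder to head base
  p0 <- c(center[1L] + facing * (g$body_a - 4), center[2L] - 2)
  p1 <- head
  v <- p1 - p0; L2 <- sum(v^2)
  tt <- pmin(pmax(((X - p0[1L]) * v[1L] + (Y - p0[2L]) * v[2L]) / L2, 0), 1)
  neck <- (X - (p0[1L] + tt * v[1L]))^2 + (Y - (p0[2L] + tt * v[2L]))^2 <= 2.5^2
  coat <- c(0.85, 0.62, 0.25)
  dark <- c(0.45, 0.3, 0.12)
  spot_ph <- spots # per-agent texture phase
  spot <- 0.12 * sin(X * 0.9 + spot_ph) * sin(Y * 0.9 + 1.7 * spot_ph)
  mask <- body | neck | headm
  for (ch in 1:3) {
    plane <- frame[ys, xs, ch]
    col <- coat[ch] + spot
    col[headm] <- dark[ch]
    plane[mask] <- col[mask]
    frame[ys, xs, ch] <- plane
  }
  # mouth patch: 3x3-ish disc whose brightness oscillates per behavior
  osc <- switch(behavior,
                licking = 0.4 * sin(2 * pi * 0.33 * t),
                eating  = 0.4 * sin(2 * pi * 0.07 * t),
                0)
  mm <- (X - mouth[1L])^2 + (Y - mouth[2L])^2 <= 2.2^2
  mcol <- pmin(pmax(0.5 + osc, 0), 1)
  for (ch in 1:3) {
    plane <- frame[ys, xs, ch]
    plane[mm] <- mcol * c(1, 0.55, 0.55)[ch]
    frame[ys, xs, ch] <- plane
  }
  frame
}

#' Render a synthetic scene
#'
#' Deterministic given `cfg$seed`: the same configuration and scripts
#' produce bit-identical frames and ground truth.
#'
#' @param cfg A [scene_config()].
#' @param scripts List of [agent_script()]s.
#' @return List with `clip` (a [video_clip()]) and `gt`, a data.frame with
#'   one row per frame per agent: `frame`, `agent_id`, `x1`, `y1`, `x2`,
#'   `y2`, `mouth_x`, `mouth_y`, `mouth_visible`, `behavior`, `occluded`.
#' @export
render_scene <- function(cfg, scripts) {
  with_seed(cfg$seed, {
    trajs <- lapply(scripts, agent_trajectory, cfg = cfg)
    bg <- scene_background(cfg)
    spots <- stats::runif(length(scripts), 0, 2 * pi)
    # sensor noise: a small bank of pre-clamped noisy backgrounds, cycled
    n_fields <- min(8L, cfg$n_frames)
    bank <- if (cfg$img_noise > 0)
      lapply(seq_len(n_fields), function(i)
        pmin(pmax(bg + stats::rnorm(length(bg), 0, cfg$img_noise), 0), 1))
      else list(bg)
    frames <- vector("list", cfg$n_frames)
    for (t in seq_len(cfg$n_frames)) {
      fr <- bank[[(t - 1L) %% length(bank) + 1L]]
      for (i in seq_along(scripts)) {
        tr <- trajs[[i]]
        fr <- paint_agent(fr, tr$pos[t, ], tr$head[t, ], tr$mouth[t, ],
                          tr$facing[t], tr$behavior[t], t, spots[i], cfg)
      }
      # occluder strips are drawn on top of the agents
      for (o in cfg$occluders) {
        ox <- max(1L, round(o[1L])):min(cfg$width, round(o[2L]))
        fr[, ox, 1L] <- 0.2; fr[, ox, 2L] <- 0.25; fr[, ox, 3L] <- 0.2
      }
      frames[[t]] <- fr
    }
    gt <- do.call(rbind, lapply(seq_along(scripts), function(i) {
      tr <- trajs[[i]]
      data.frame(frame = seq_len(cfg$n_frames),
                 agent_id = scripts[[i]]$agent_id,
                 x1 = tr$box[, 1L], y1 = tr$box[, 2L],
                 x2 = tr$box[, 3L], y2 = tr$box[, 4L],
                 mouth_x = tr$mouth[, 1L], mouth_y = tr$mouth[, 2L],
                 mouth_visible = 2, behavior = tr$behavior,
                 occluded = vapply(tr$pos[, 1L], in_occluder, logical(1L),
                                   occluders = cfg$occluders))
    }))
    gt <- gt[order(gt$frame, gt$agent_id), ]
    rownames(gt) <- NULL
    list(clip = video_clip(frames, clip_id = sprintf("scene%06d", cfg$seed),
                           fps = cfg$fps),
         gt = gt)
  })
}

in_occluder <- function(x, occluders) {
  for (o in occluders) if (x >= o[1L] && x <= o[2L]) return(TRUE)
  FALSE
}

#' Perturb ground truth into a noisy detection stream
#'
#' Emulates an upstream pose detector: box corners receive zero-mean
#' Gaussian noise `sigma`, the mouth keypoint receives noise `kp_sigma`, a
#' detection is dropped when the agent center lies inside an occluder strip
#' or independently with probability `miss_rate`, and confidences are drawn
#' uniformly from `[0.5, 1]`.
#'
#' @param gt Ground-truth data.frame from [render_scene()].
#' @param sigma,kp_sigma Noise standard deviations (pixels); 0 allowed.
#' @param miss_rate Drop probability in `[0, 1)`.
#' @param occluders List of x-range strips.
#' @param seed Integer seed.
#' @param dropouts Optional list of `c(agent_id, from, to)` triples whose
#'   detections are removed (mutual occlusion between animals, which the
#'   x-strip occluders cannot express).
#' @return A detection data.frame (see [detection_table()]) with an extra
#'   `agent_id` column retained for evaluation convenience.
#' @export
perturb_detections <- function(gt, sigma = 1.0, kp_sigma = 0.5,
                               miss_rate = 0.02, occluders = list(),
                               seed = 1L, dropouts = list()) {
  stopifnot(sigma >= 0, kp_sigma >= 0, miss_rate >= 0, miss_rate < 1)
  with_seed(seed, {
    cx <- (gt$x1 + gt$x2) / 2
    occ <- vapply(cx, in_occluder, logical(1L), occluders = occluders)
    for (dr in dropouts)
      occ <- occ | (gt$agent_id == dr[1L] & gt$frame >= dr[2L] &
                      gt$frame <= dr[3L])
    keep <- !occ & !gt$occluded & stats::runif(nrow(gt)) >= miss_rate
    g <- gt[keep, , drop = FALSE]
    n <- nrow(g)
    if (n == 0L) {
      d <- detection_table()
      d$agent_id <- integer()
      return(d)
    }
    jit <- function(v, s) v + if (s > 0) stats::rnorm(n, 0, s) else 0
    x1 <- jit(g$x1, sigma); x2 <- jit(g$x2, sigma)
    y1 <- jit(g$y1, sigma); y2 <- jit(g$y2, sigma)
    # keep boxes non-degenerate under extreme draws
    xlo <- pmin(x1, x2); xhi <- pmax(x1, x2)
    ylo <- pmin(y1, y2); yhi <- pmax(y1, y2)
    xhi <- pmax(xhi, xlo + 1); yhi <- pmax(yhi, ylo + 1)
    d <- data.frame(frame = g$frame, x1 = xlo, y1 = ylo, x2 = xhi, y2 = yhi,
                    score = stats::runif(n, 0.5, 1),
                    mouth_x = jit(g$mouth_x, kp_sigma),
                    mouth_y = jit(g$mouth_y, kp_sigma),
                    mouth_visible = g$mouth_visible,
                    agent_id = g$agent_id)
    validate_detections(d)
  })
}

#' Rule-based behavior baseline on clean ground truth
#'
#' Classifies each agent from thresholds on centroid displacement, mouth
#' height relative to the trough band, and horizontal mouth-to-tree
#' distance. Serves as the class-separability check for the generator: on
#' clean ground truth this rule must be nearly perfect, guaranteeing the
#' learning task is solvable.
#'
#' @param gt Ground truth from [render_scene()].
#' @param cfg The matching [scene_config()].
#' @return data.frame with one row per agent: `agent_id`, `behavior`
#'   (predicted).
#' @export
rule_classify <- function(gt, cfg) {
  out <- lapply(split(gt, gt$agent_id), function(g) {
    cx <- (g$x1 + g$x2) / 2; cy <- (g$y1 + g$y2) / 2
    disp <- if (nrow(g) > 1L) mean(sqrt(diff(cx)^2 + diff(cy)^2)) else 0
    tree_d <- stats::median(pmax(0, pmax(cfg$tree_x - g$mouth_x,
                                         g$mouth_x - (cfg$tree_x + cfg$tree_width))))
    mouth_y <- stats::median(g$mouth_y)
    beh <- if (disp >= 1) "walking"
      else if (mouth_y >= cfg$trough_y[1L]) "eating"
      else if (tree_d <= 6) "licking"
      else "standing"
    data.frame(agent_id = g$agent_id[1L], behavior = beh)
  })
  do.call(rbind, unname(out))
}

# Seeded scripted placement for a single-agent clip of one behavior,
# including the deliberately ambiguous "standing near the tree" variant.
place_agent <- function(behavior, cfg, agent_id = 1L) {
  g <- .AG
  tree_e <- cfg$tree_x + cfg$tree_width
  y <- stats::runif(1L, 58, 108)
  if (behavior == "walking") {
    # start so the whole 2.2 px/frame path stays inside the frame
    v <- 2.2
    travel <- v * (cfg$n_frames - 1L)
    margin <- 46
    dir <- sample(c(1, -1), 1L)
    x0 <- if (dir > 0) stats::runif(1L, margin, cfg$width - margin - travel)
          else stats::runif(1L, margin + travel, cfg$width - margin)
    return(agent_script(agent_id, "walking", c(x0, y),
                        velocity = c(v * dir, 0), facing = dir))
  }
  if (behavior == "licking") {
    cx <- tree_e + g$mouth_reach + stats::runif(1L, 0.5, 2)
    return(agent_script(agent_id, "licking", c(cx, y), facing = -1))
  }
  if (behavior == "eating") {
    cx <- stats::runif(1L, cfg$width * 0.45, cfg$width * 0.85)
    cy <- cfg$trough_y[1L] - g$head_dy_down - g$mouth_down_dy + 4
    return(agent_script(agent_id, "eating", c(cx, cy),
                        facing = sample(c(-1, 1), 1L)))
  }
  # standing: half the draws stand close to the tree (mouth 10-22 px away)
  if (stats::runif(1L) < 0.5) {
    cx <- tree_e + g$mouth_reach + stats::runif(1L, 10, 22)
    agent_script(agent_id, "standing", c(cx, y), facing = -1)
  } else {
    cx <- stats::runif(1L, cfg$width * 0.45, cfg$width * 0.8)
    agent_script(agent_id, "standing", c(cx, y), facing = sample(c(-1, 1), 1L))
  }
}

#' Adversarial crossing-occlusion tracking fixture
#'
#' Two agents: one walks across the full scene; the other walks toward it,
#' is hidden for `gap` frames while they overlap (its detections are
#' dropped), and stops walking during the occlusion. A coasting
#' constant-velocity prediction overshoots the stopped animal, so plain
#' IoU association loses the identity; the observation-centric recovery
#' and re-update mechanisms are designed to keep it.
#'
#' @param seed Integer seed (controls detector noise).
#' @param gap Length of the detection dropout (frames).
#' @param sigma Detection noise passed to [perturb_detections()].
#' @return List with `gt`, `dets` (detection data.frame), `cfg`.
#' @export
make_crossing_fixture <- function(seed = 1L, gap = 14L, sigma = 0.5) {
  cfg <- scene_config(n_frames = 64L, miss_rate = 0, seed = seed)
  t_stop <- 30L
  a <- agent_script(1L, "walking", c(215, 66), velocity = c(-2.4, 0),
                    facing = -1)
  b <- agent_script(2L, data.frame(start = c(1L, t_stop + 1L),
                                   end = c(t_stop, 64L),
                                   behavior = c("walking", "standing")),
                    c(62, 78), velocity = c(2.2, 0), facing = 1)
  sc <- render_scene(cfg, list(a, b))
  dets <- perturb_detections(sc$gt, sigma = sigma, kp_sigma = 0.5,
                             miss_rate = 0, seed = seed + 1L,
                             dropouts = list(c(2L, t_stop + 1L,
                                               t_stop + gap)))
  list(gt = sc$gt, dets = dets, cfg = cfg)
}

#' Generate a labeled fixture dataset on disk
#'
#' Writes `n_clips` single-agent clips with balanced behavior classes, the
#' per-split AVA annotation CSVs, one JSON-lines detection stream per clip,
#' and a manifest recording the seed and configuration. Keyframes are the
#' 1 Hz timestamps whose two-stream sampling window fits inside the clip.
#'
#' @param out_dir Output directory (must not already contain a manifest
#'   unless `force = TRUE`).
#' @param n_clips Number of clips.
#' @param cfg A [scene_config()] used as template (its seed is combined
#'   with the clip index).
#' @param pipeline Two-stream sampling parameters, a [satsn_config()].
#' @param split Named ratios for the train/test split.
#' @param seed Master seed.
#' @param write_frames Write PNG frames (`frame_%06d.png` per clip
#'   directory)? Disable to keep fixtures light when only annotations and
#'   detections are needed.
#' @param force Overwrite an existing dataset.
#' @return Invisibly, the manifest list.
#' @export
make_fixture_dataset <- function(out_dir, n_clips = 40L, cfg = scene_config(),
                                 pipeline = satsn_config(),
                                 split = c(train = 0.8, test = 0.2),
                                 seed = 1L, write_frames = FALSE,
                                 force = FALSE) {
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !force)
    stop("dataset already exists at ", out_dir, " (use force = TRUE)")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  behaviors <- rep(satsn_action_names, length.out = n_clips)
  clip_ids <- sprintf("clip%04d", seq_len(n_clips))
  parts <- split_dataset(clip_ids, split, seed = seed)
  names(parts) <- names(split)
  ava <- stats::setNames(vector("list", length(parts)), names(parts))
  for (i in seq_len(n_clips)) {
    clip_seed <- as.integer((as.numeric(seed) * 10000 + i) %% 2000000011)
    ccfg <- cfg; ccfg$seed <- clip_seed
    script <- with_seed(clip_seed, place_agent(behaviors[i], ccfg))
    scene <- render_scene(ccfg, list(script))
    dets <- perturb_detections(scene$gt, sigma = ccfg$noise_sigma,
                               kp_sigma = ccfg$kp_sigma,
                               miss_rate = ccfg$miss_rate,
                               occluders = ccfg$occluders,
                               seed = clip_seed + 1L)
    cdir <- file.path(out_dir, clip_ids[i])
    dir.create(cdir, showWarnings = FALSE)
    write_detection_stream(dets[setdiff(names(dets), "agent_id")],
                           file.path(cdir, "detections.jsonl"))
    if (write_frames)
      for (t in seq_along(scene$clip$frames))
        png::writePNG(scene$clip$frames[[t]],
                      file.path(cdir, sprintf("frame_%06d.png", t)))
    part <- names(parts)[vapply(parts, function(p) clip_ids[i] %in% p, logical(1L))]
    ava[[part]][[length(ava[[part]]) + 1L]] <-
      gt_to_ava(scene$gt, ccfg, pipeline, clip_ids[i])
  }
  for (p in names(parts)) {
    tab <- if (length(ava[[p]])) do.call(rbind, ava[[p]]) else read_ava_csv_empty()
    write_ava_csv(tab, file.path(out_dir, paste0(p, ".csv")))
  }
  manifest <- list(seed = seed, n_clips = n_clips,
                   behaviors = as.list(table(behaviors)),
                   scene = unclass(cfg), pipeline = unclass(pipeline),
                   split = as.list(split),
                   clips = stats::setNames(lapply(parts, as.list), names(parts)))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

read_ava_csv_empty <- function() {
  data.frame(video_id = character(), timestamp = integer(),
             x1 = numeric(), y1 = numeric(), x2 = numeric(), y2 = numeric(),
             action_id = integer(), entity_id = integer())
}

#' Convert scene ground truth to AVA keyframe records
#'
#' @param gt Ground truth from [render_scene()].
#' @param cfg The [scene_config()] (for frame size and fps).
#' @param pipeline [satsn_config()] defining the sampling window.
#' @param video_id Clip identifier.
#' @return AVA record data.frame (normalized boxes, 1 Hz keyframes).
#' @export
gt_to_ava <- function(gt, cfg, pipeline, video_id) {
  ts <- valid_keyframes(cfg$n_frames, cfg$fps, pipeline)
  rows <- lapply(ts, function(t0) {
    f <- keyframe_index(t0, cfg$fps)
    g <- gt[gt$frame == f, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(video_id = video_id, timestamp = t0,
               x1 = pmax(0, g$x1 / cfg$width), y1 = pmax(0, g$y1 / cfg$height),
               x2 = pmin(1, g$x2 / cfg$width), y2 = pmin(1, g$y2 / cfg$height),
               action_id = unname(satsn_actions[g$behavior]),
               entity_id = g$agent_id)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) read_ava_csv_empty() else out
}

#' Keyframe helpers
#'
#' A timestamp `t` (integer seconds) maps to frame `round(t * fps) + 1`;
#' `valid_keyframes` lists the timestamps whose slow/fast sampling window
#' fits inside an `n_frames` clip.
#'
#' @param t Timestamp in seconds.
#' @param fps Frame rate.
#' @export
keyframe_index <- function(t, fps) as.integer(round(t * fps)) + 1L

#' @rdname keyframe_index
#' @param n_frames Clip length in frames.
#' @param pipeline A [satsn_config()].
#' @export
valid_keyframes <- function(n_frames, fps, pipeline) {
  ts <- 0:floor((n_frames - 1L) / fps)
  ok <- vapply(ts, function(t0) {
    f <- keyframe_index(t0, fps)
    !inherits(try(sample_two_stream_frames(n_frames, pipeline$T, pipeline$tau,
                                           pipeline$alpha, center = f),
                  silent = TRUE), "try-error")
  }, logical(1L))
  ts[ok]
}
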