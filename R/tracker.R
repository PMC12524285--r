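# Observation-centric multi-object tracking. A constant-velocity Kalman
# filter over the state [cx, cy, s, r, vcx, vcy, vs] (center, box area,
# aspect ratio, velocities; aspect held constant) is combined with three
# observation-centric mechanisms: re-update along a virtual trajectory
# interpolated between the last observation before an occlusion and the
# re-detection (ORU), a momentum term penalizing angular inconsistency
# between the observation-derived track direction and the track-to-
# candidate direction in the association cost (OCM), and a recovery pass
# matching unmatched tracks' last observations to detections by
# generalized IoU (OCR).

#' Tracker configuration
#'
#' The published description fixes the mechanisms but not the numeric
#' settings; these defaults are the package's own and are all exposed
#' here.
#'
#' @param lambda Weight of the momentum (direction-consistency) term in
#'   the association cost.
#' @param delta_t Direction baseline: the track direction is computed from
#'   the observation `delta_t` steps back to the latest observation.
#' @param iou_min Association gate; assigned pairs below this IoU are
#'   rejected.
#' @param max_age Frames a track survives without an observation.
#' @param min_hits Consecutive hits before a track is reported.
#' @param ocr_giou_min Minimum generalized IoU for the recovery pass.
#' @param use_oru,use_ocm,use_ocr Ablation switches for the three
#'   observation-centric mechanisms.
#' @return List of class `tracker_config`.
#' @export
tracker_config <- function(lambda = 0.2, delta_t = 3L, iou_min = 0.3,
                           max_age = 30L, min_hits = 3L, ocr_giou_min = -0.2,
                           use_oru = TRUE, use_ocm = TRUE, use_ocr = TRUE) {
  stopifnot(lambda >= 0, delta_t >= 1L, max_age >= 1L, min_hits >= 1L)
  structure(list(lambda = lambda, delta_t = as.integer(delta_t),
                 iou_min = iou_min, max_age = as.integer(max_age),
                 min_hits = as.integer(min_hits),
                 ocr_giou_min = ocr_giou_min,
                 use_oru = use_oru, use_ocm = use_ocm, use_ocr = use_ocr),
            class = "tracker_config")
}

# ---- Kalman filter ----------------------------------------------------------

box_to_obs <- function(box) {
  w <- box[3L] - box[1L]; h <- box[4L] - box[2L]
  c(cx = (box[1L] + box[3L]) / 2, cy = (box[2L] + box[4L]) / 2,
    s = w * h, r = w / h)
}

obs_to_box <- function(z) {
  s <- max(z[3L], 1e-6); r <- max(z[4L], 1e-6)
  w <- sqrt(s * r); h <- s / w
  c(x1 = z[1L] - w / 2, y1 = z[2L] - h / 2,
    x2 = z[1L] + w / 2, y2 = z[2L] + h / 2)
}

#' Initialize a Kalman state from an observation
#'
#' State vector `[cx, cy, s, r, vcx, vcy, vs]` with a constant-velocity
#' transition for the center and area, constant aspect ratio, and
#' SORT-style diagonal noise scales.
#'
#' @param z Observation `c(cx, cy, s, r)` (see `box_to_obs`).
#' @return List of class `kalman_state` with `x`, `P`, `F`, `H`, `Q`,
#'   `R`.
#' @export
kf_init <- function(z) {
  F <- diag(7)
  F[1L, 5L] <- 1; F[2L, 6L] <- 1; F[3L, 7L] <- 1
  H <- cbind(diag(4), matrix(0, 4L, 3L))
  R <- diag(c(1, 1, 10, 10))
  P <- diag(c(10, 10, 10, 10, 1e4, 1e4, 1e4))
  Q <- diag(c(1, 1, 1, 1, 0.01, 0.01, 1e-4))
  structure(list(x = c(z, 0, 0, 0), P = P, F = F, H = H, Q = Q, R = R),
            class = "kalman_state")
}

#' Kalman predict step
#'
#' `x <- F x`, `P <- F P F' + Q`; with positive semidefinite `Q` the
#' covariance trace cannot decrease.
#'
#' @param state A `kalman_state`.
#' @return The predicted state.
#' @export
kf_predict <- function(state) {
  if (any(!is.finite(state$x))) stop("non-finite Kalman state")
  if (state$x[3L] + state$x[7L] <= 0) state$x[7L] <- 0 # keep area positive
  state$x <- as.vector(state$F %*% state$x)
  state$P <- state$F %*% state$P %*% t(state$F) + state$Q
  state
}

#' Kalman update step
#'
#' `K = P H' (H P H' + R)^-1`; `x <- x + K (z - H x)`;
#' `P <- (I - K H) P`, symmetrized.
#'
#' @param state A `kalman_state` (after [kf_predict()]).
#' @param z Observation `c(cx, cy, s, r)`.
#' @return The updated state.
#' @export
kf_update <- function(state, z) {
  H <- state$H
  S <- H %*% state$P %*% t(H) + state$R
  if (!is.finite(rcond(S)) || rcond(S) < 1e-14)
    stop("singular innovation covariance")
  K <- state$P %*% t(H) %*% solve(S)
  state$x <- as.vector(state$x + K %*% (z - H %*% state$x))
  P <- (diag(7) - K %*% H) %*% state$P
  state$P <- (P + t(P)) / 2
  state
}

predicted_box <- function(state) obs_to_box(as.vector(state$H %*% state$x))

#' Virtual trajectory between two observations
#'
#' Linear interpolation per box coordinate between the last observation
#' before an occlusion (`z_t1` at `t1`) and the re-detection (`z_t2` at
#' `t2`), evaluated at `t` with `t1 < t < t2`. For a target moving at
#' constant velocity the interpolated boxes equal the true ones.
#'
#' @param z_t1,z_t2 Boxes `c(x1, y1, x2, y2)`.
#' @param t1,t2,t Frame indices.
#' @return Interpolated box at `t`.
#' @export
virtual_trajectory <- function(z_t1, t1, z_t2, t2, t) {
  if (!(t1 < t && t < t2))
    stop("virtual trajectory requires t1 < t < t2")
  w <- (t - t1) / (t2 - t1)
  z_t1 + w * (z_t2 - z_t1)
}

# ---- track bookkeeping ------------------------------------------------------

new_track <- function(id, box, score, t) {
  list(id = id, kf = kf_init(box_to_obs(box)),
       obs = data.frame(t = t, x1 = box[1L], y1 = box[2L],
                        x2 = box[3L], y2 = box[4L]),
       last_obs = box, last_obs_t = t,
       snapshot = NULL, # posterior (x, P) at the last real observation
       hit_streak = 1L, time_since_update = 0L, score = score)
}

take_snapshot <- function(track) {
  track$snapshot <- list(x = track$kf$x, P = track$kf$P, t = track$last_obs_t)
  track
}

#' Observation-centric re-update of a reactivated track
#'
#' Rolls the filter back to its posterior at the last real observation,
#' then runs predict+update along the [virtual_trajectory()] for every
#' occluded frame and finally against the re-detection, suppressing the
#' drift accumulated while coasting.
#'
#' @param track Internal track record (with a stored posterior snapshot).
#' @param z_box Re-detected box `c(x1, y1, x2, y2)`.
#' @param t2 Frame of the re-detection.
#' @return The track with a re-updated filter.
#' @export
oru_reupdate <- function(track, z_box, t2) {
  if (is.null(track$snapshot)) stop("no stored posterior for re-update")
  t1 <- track$snapshot$t
  track$kf$x <- track$snapshot$x
  track$kf$P <- track$snapshot$P
  if (t2 > t1 + 1L) {
    for (t in (t1 + 1L):(t2 - 1L)) {
      vb <- virtual_trajectory(track$last_obs, t1, z_box, t2, t)
      track$kf <- kf_update(kf_predict(track$kf), box_to_obs(vb))
    }
  }
  track$kf <- kf_update(kf_predict(track$kf), box_to_obs(z_box))
  track
}

#' Momentum association cost
#'
#' `C = C_IoU + lambda * C_v` with `C_IoU = 1 - IoU(predicted box,
#' detection)` and `C_v = theta / pi`, the angle between the
#' observation-derived track direction (latest observation center minus
#' the center `delta_t` observations back) and the direction from the
#' latest observation to the candidate. Tracks with too short a history or
#' zero-length directions contribute `C_v = 0`.
#'
#' @param track Internal track record.
#' @param det_box Candidate box.
#' @param lambda,delta_t See [tracker_config()].
#' @return Scalar cost.
#' @export
ocm_cost <- function(track, det_box, lambda = 0.2, delta_t = 3L) {
  c_iou <- 1 - iou(predicted_box(track$kf), det_box)
  if (lambda == 0) return(c_iou)
  c_iou + lambda * direction_cost(track, det_box, delta_t)
}

direction_cost <- function(track, det_box, delta_t) {
  n <- nrow(track$obs)
  if (n < delta_t + 1L) return(0)
  c_now <- obs_center(track$obs[n, ])
  c_old <- obs_center(track$obs[n - delta_t, ])
  u <- c_now - c_old
  v <- c((det_box[1L] + det_box[3L]) / 2, (det_box[2L] + det_box[4L]) / 2) - c_now
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu < 1e-9 || nv < 1e-9) return(0)
  theta <- acos(pmin(pmax(sum(u * v) / (nu * nv), -1), 1))
  theta / pi
}

obs_center <- function(o) c((o$x1 + o$x2) / 2, (o$y1 + o$y2) / 2)

# ---- assignment -------------------------------------------------------------

# O(n^3) Hungarian algorithm (potentials formulation); rows <= cols.
solve_assignment_rect <- function(a) {
  n <- nrow(a); m <- ncol(a)
  stopifnot(n <= m)
  BIG <- 1e15
  u <- numeric(n + 1L); v <- numeric(m + 1L)
  p <- integer(m + 1L); way <- integer(m + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(BIG, m + 1L)
    used <- rep(FALSE, m + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]; delta <- BIG; j1 <- 0L
      for (j in seq_len(m)) if (!used[j + 1L]) {
        cur <- a[i0, j] - u[i0 + 1L] - v[j + 1L]
        if (cur < minv[j + 1L]) { minv[j + 1L] <- cur; way[j + 1L] <- j0 }
        if (minv[j + 1L] < delta) { delta <- minv[j + 1L]; j1 <- j }
      }
      for (j in 0:m) {
        if (used[j + 1L]) {
          u[p[j + 1L] + 1L] <- u[p[j + 1L] + 1L] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else minv[j + 1L] <- minv[j + 1L] - delta
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) assign[p[j + 1L]] <- j
  assign
}

# Minimum-cost assignment for any shape; returns row -> col (NA if
# unassigned).
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0L || m == 0L) return(rep(NA_integer_, n))
  cost[!is.finite(cost)] <- 1e9
  if (n <= m) return(solve_assignment_rect(cost))
  back <- solve_assignment_rect(t(cost))
  assign <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (!is.na(back[j])) assign[back[j]] <- j
  assign
}

#' Associate tracks with detections
#'
#' Minimum-cost bipartite assignment under the momentum cost
#' ([ocm_cost()]); assigned pairs whose IoU falls below the gate are
#' rejected. Ties are resolved deterministically by the assignment
#' algorithm's fixed scan order.
#'
#' @param tracks List of internal track records.
#' @param det_boxes `m x 4` matrix of detection boxes.
#' @param config A [tracker_config()].
#' @return List with `matches` (2-column matrix of track/detection
#'   indices), `unmatched_tracks`, `unmatched_dets`.
#' @export
associate <- function(tracks, det_boxes, config = tracker_config()) {
  n <- length(tracks); m <- if (is.null(det_boxes)) 0L else nrow(det_boxes)
  if (n == 0L || m == 0L)
    return(list(matches = matrix(0L, 0L, 2L),
                unmatched_tracks = seq_len(n), unmatched_dets = seq_len(m)))
  lam <- if (config$use_ocm) config$lambda else 0
  cost <- matrix(0, n, m)
  iou_m <- matrix(0, n, m)
  for (i in seq_len(n)) {
    pb <- predicted_box(tracks[[i]]$kf)
    for (j in seq_len(m)) {
      iou_m[i, j] <- iou(pb, det_boxes[j, ])
      cost[i, j] <- (1 - iou_m[i, j]) +
        if (lam > 0) lam * direction_cost(tracks[[i]], det_boxes[j, ],
                                          config$delta_t) else 0
    }
  }
  assign <- solve_assignment(cost)
  matches <- matrix(0L, 0L, 2L)
  for (i in seq_len(n)) {
    j <- assign[i]
    if (!is.na(j) && iou_m[i, j] >= config$iou_min)
      matches <- rbind(matches, c(i, j))
  }
  list(matches = matches,
       unmatched_tracks = setdiff(seq_len(n), matches[, 1L]),
       unmatched_dets = setdiff(seq_len(m), matches[, 2L]))
}

#' Recovery pass over unmatched tracks and detections
#'
#' Greedy best-first matching of the tracks' last real observations (not
#' their predictions) to remaining detections by generalized IoU, accepted
#' while `GIoU >= ocr_giou_min`. Recovers stationary or briefly occluded
#' targets whose predictions have drifted.
#'
#' @param tracks List of internal track records (the unmatched ones).
#' @param det_boxes Matrix of remaining detection boxes.
#' @param config A [tracker_config()].
#' @return 2-column matrix of (track index, detection index) extra
#'   matches, indices relative to the supplied lists.
#' @export
ocr_pass <- function(tracks, det_boxes, config = tracker_config()) {
  matches <- matrix(0L, 0L, 2L)
  if (!length(tracks) || is.null(det_boxes) || !nrow(det_boxes))
    return(matches)
  g <- matrix(-Inf, length(tracks), nrow(det_boxes))
  for (i in seq_along(tracks)) for (j in seq_len(nrow(det_boxes)))
    g[i, j] <- giou(tracks[[i]]$last_obs, det_boxes[j, ])
  repeat {
    best <- which(g == max(g), arr.ind = TRUE)[1L, , drop = TRUE]
    if (g[best[1L], best[2L]] < config$ocr_giou_min) break
    matches <- rbind(matches, as.integer(best))
    g[best[1L], ] <- -Inf
    g[, best[2L]] <- -Inf
    if (all(!is.finite(g))) break
  }
  matches
}

#' Track a detection stream through a video
#'
#' Per frame: predict every live track, associate with the momentum cost,
#' run the recovery pass over the leftovers, re-update reactivated tracks
#' along their virtual trajectories, apply the Kalman update, and manage
#' track lifecycle (`min_hits` to report, `max_age` to terminate). Track
#' ids are never reused within a video. Deterministic given the stream
#' and configuration.
#'
#' @param dets Detection data.frame (see [detection_table()]).
#' @param config A [tracker_config()].
#' @param n_frames Total frame count (defaults to the last detection).
#' @return data.frame with `frame`, `track_id`, `x1`, `y1`, `x2`, `y2`,
#'   `score` for every reported track-frame.
#' @export
track_video <- function(dets, config = tracker_config(), n_frames = NULL) {
  if (is.null(n_frames))
    n_frames <- if (nrow(dets)) max(dets$frame) else 0L
  tracks <- list()
  next_id <- 1L
  out <- list()
  for (t in seq_len(n_frames)) {
    df <- dets[dets$frame == t, , drop = FALSE]
    det_boxes <- if (nrow(df)) as.matrix(df[, c("x1", "y1", "x2", "y2")]) else NULL
    for (i in seq_along(tracks)) tracks[[i]]$kf <- kf_predict(tracks[[i]]$kf)
    as1 <- associate(tracks, det_boxes, config)
    matches <- as1$matches
    if (config$use_ocr && length(as1$unmatched_tracks) &&
        length(as1$unmatched_dets)) {
      rec <- ocr_pass(tracks[as1$unmatched_tracks],
                      det_boxes[as1$unmatched_dets, , drop = FALSE], config)
      if (nrow(rec))
        matches <- rbind(matches,
                         cbind(as1$unmatched_tracks[rec[, 1L]],
                               as1$unmatched_dets[rec[, 2L]]))
    }
    matched_tracks <- if (nrow(matches)) matches[, 1L] else integer()
    for (k in seq_len(nrow(matches))) {
      i <- matches[k, 1L]; j <- matches[k, 2L]
      box <- det_boxes[j, ]
      tr <- tracks[[i]]
      if (tr$time_since_update >= 2L && config$use_oru &&
          !is.null(tr$snapshot)) {
        tr <- oru_reupdate(tr, box, t)
      } else {
        tr$kf <- kf_update(tr$kf, box_to_obs(box))
      }
      tr$obs <- rbind(tr$obs, data.frame(t = t, x1 = box[1L], y1 = box[2L],
                                         x2 = box[3L], y2 = box[4L]))
      tr$last_obs <- box
      tr$last_obs_t <- t
      tr$hit_streak <- if (tr$time_since_update == 0L ||
                           tr$time_since_update == 1L) tr$hit_streak + 1L else 1L
      tr$time_since_update <- 0L
      tr$score <- df$score[j]
      tr <- take_snapshot(tr)
      tracks[[i]] <- tr
    }
    for (i in setdiff(seq_along(tracks), matched_tracks)) {
      tracks[[i]]$time_since_update <- tracks[[i]]$time_since_update + 1L
      tracks[[i]]$hit_streak <- 0L
    }
    unmatched_dets <- setdiff(seq_len(if (is.null(det_boxes)) 0L else
      nrow(det_boxes)), if (nrow(matches)) matches[, 2L] else integer())
    for (j in unmatched_dets) {
      tr <- take_snapshot(new_track(next_id, det_boxes[j, ], df$score[j], t))
      tracks[[length(tracks) + 1L]] <- tr
      next_id <- next_id + 1L
    }
    keep <- vapply(tracks, function(tr)
      tr$time_since_update <= config$max_age, logical(1L))
    tracks <- tracks[keep]
    for (tr in tracks) {
      if (tr$time_since_update == 0L &&
          (tr$hit_streak >= config$min_hits || t <= config$min_hits)) {
        b <- predicted_box(tr$kf)
        out[[length(out) + 1L]] <-
          data.frame(frame = t, track_id = tr$id, x1 = b[1L], y1 = b[2L],
                     x2 = b[3L], y2 = b[4L], score = tr$score)
      }
    }
  }
  if (!length(out))
    return(data.frame(frame = integer(), track_id = integer(),
                      x1 = numeric(), y1 = numeric(), x2 = numeric(),
                      y2 = numeric(), score = numeric()))
  do.call(rbind, out)
}

#' Write tracks as a MOT-challenge style CSV
#'
#' Columns `frame, id, x, y, w, h, score` with a header line.
#'
#' @param tracks Output of [track_video()].
#' @param path Output path.
#' @export
write_mot_csv <- function(tracks, path) {
  df <- data.frame(frame = tracks$frame, id = tracks$track_id,
                   x = tracks$x1, y = tracks$y1,
                   w = tracks$x2 - tracks$x1, h = tracks$y2 - tracks$y1,
                   score = tracks$score)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
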