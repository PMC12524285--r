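# Independent oracles used across the suite. Each is written as the
# textbook formulation of its quantity, separate from the package's
# implementation path.

# Information-filter formulation of the Kalman recursion: the update is
# performed on the inverse covariance (Y = P^-1) and the information
# vector (y = Y x), which is algebraically distinct from the gain-based
# update it cross-checks.
info_filter_step <- function(x, P, F, H, Q, R, z) {
  # predict (covariance form)
  xp <- as.vector(F %*% x)
  Pp <- F %*% P %*% t(F) + Q
  # update (information form)
  Y <- solve(Pp)
  yv <- Y %*% xp
  Rinv <- solve(R)
  Y2 <- Y + t(H) %*% Rinv %*% H
  y2 <- yv + t(H) %*% Rinv %*% z
  P2 <- solve(Y2)
  list(x = as.vector(P2 %*% y2), P = P2)
}

# All-point interpolated AP computed directly from an outcome sequence:
# for every achieved recall level, take the maximum precision at any
# equal-or-higher recall and accumulate recall increments.
ap_oracle <- function(outcomes, n_gt) {
  if (n_gt == 0L) return(NA_real_)
  if (!length(outcomes)) return(0)
  tp <- cumsum(outcomes)
  prec_at <- tp / seq_along(outcomes)
  rec_at <- tp / n_gt
  levels <- unique(rec_at[outcomes])
  ap <- 0
  prev <- 0
  for (r in levels) {
    p_max <- max(prec_at[rec_at >= r])
    ap <- ap + (r - prev) * p_max
    prev <- r
  }
  ap
}

# Construct a prediction/ground-truth table pair whose greedy matching
# realizes a given ranked TP/FP outcome sequence: ground-truth boxes are
# laid out far apart, true positives coincide with successive GT boxes,
# false positives sit in empty space.
tables_for_outcomes <- function(outcomes, n_gt, class_id = 1L) {
  gt_boxes <- lapply(seq_len(n_gt), function(i)
    c(x1 = 10 * i, y1 = 0, x2 = 10 * i + 5, y2 = 5))
  gt <- do.call(rbind, lapply(seq_len(n_gt), function(i)
    data.frame(video_id = "v", timestamp = 0L,
               x1 = gt_boxes[[i]][1], y1 = gt_boxes[[i]][2],
               x2 = gt_boxes[[i]][3], y2 = gt_boxes[[i]][4],
               action_id = class_id, entity_id = i)))
  if (!length(outcomes)) {
    pred <- data.frame(video_id = character(), timestamp = integer(),
                       x1 = numeric(), y1 = numeric(), x2 = numeric(),
                       y2 = numeric(), action_id = integer(),
                       score = numeric())
    return(list(pred = pred, gt = gt))
  }
  used_gt <- 0L
  fp_x <- 1000
  rows <- lapply(seq_along(outcomes), function(k) {
    if (outcomes[k]) {
      used_gt <<- used_gt + 1L
      b <- gt_boxes[[used_gt]]
    } else {
      fp_x <<- fp_x + 20
      b <- c(fp_x, 0, fp_x + 5, 5)
    }
    data.frame(video_id = "v", timestamp = 0L,
               x1 = b[1], y1 = b[2], x2 = b[3], y2 = b[4],
               action_id = class_id, score = 1 - k / 100)
  })
  list(pred = do.call(rbind, rows), gt = gt)
}

# Exhaustive minimum-cost assignment by permutation enumeration (n <= m).
brute_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  best <- Inf; best_cols <- NULL
  for (p in perms(seq_len(m))) {
    cols <- p[seq_len(n)]
    tot <- sum(cost[cbind(seq_len(n), cols)])
    if (tot < best - 1e-12) { best <- tot; best_cols <- cols }
  }
  list(cost = best, cols = best_cols)
}

tiny_arch <- function() {
  satsn_arch_config(profile = "tiny", input_size = 16L,
                    tubelet = c(2L, 8L, 8L), embed_dim = 32L, depth = 1L,
                    n_heads = 4L, base_channels = c(32L, 64L),
                    fusion_after = c(1L, 1L), T = 2L, alpha = 2L, ta_r = 2L)
}

rand_sample <- function(arch, seed = 1L) {
  with_seed(seed, list(
    slow = array(runif(arch$input_size^2 * 3 * arch$T),
                 c(arch$input_size, arch$input_size, 3L, arch$T)),
    fast = array(runif(arch$input_size^2 * 3 * arch$alpha * arch$T),
                 c(arch$input_size, arch$input_size, 3L,
                   arch$alpha * arch$T))))
}

quick_scene <- function(seed = 1L, n_frames = 32L)
  scene_config(n_frames = n_frames, seed = seed)
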