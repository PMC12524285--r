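test_that("IoU and GIoU match area arithmetic", {
  a <- c(0, 0, 2, 2)
  expect_equal(iou(a, a), 1)
  expect_equal(giou(a, a), 1)
  b <- c(1, 1, 3, 3)
  expect_equal(iou(a, b), 1 / 7)
  far <- c(10, 10, 11, 11)
  expect_equal(iou(a, far), 0)
  expect_lt(giou(a, far), 0)
  # symmetry and ordering
  expect_equal(iou(a, b), iou(b, a))
  expect_lte(giou(a, b), iou(a, b))
})

test_that("Kalman prediction follows the constant-velocity model", {
  st <- kf_init(c(50, 40, 400, 1.2))
  st$Q <- diag(7) * 0
  p1 <- kf_predict(st)
  expect_equal(p1$x[1:4], st$x[1:4]) # zero velocity: position unchanged

  st$x[5] <- 2 # vx = 2
  p2 <- kf_predict(st)
  expect_equal(p2$x[1], 52)

  # 20 predictions equal the closed-form matrix power
  st20 <- st
  for (i in 1:20) st20 <- kf_predict(st20)
  F20 <- diag(7)
  for (i in 1:20) F20 <- F20 %*% st$F
  expect_equal(st20$x, as.vector(F20 %*% st$x), tolerance = 1e-10)

  # covariance trace never decreases under prediction
  st2 <- kf_init(c(0, 0, 100, 1))
  tr0 <- sum(diag(st2$P))
  expect_gte(sum(diag(kf_predict(st2)$P)), tr0)
  st2$x[1] <- NaN
  expect_error(kf_predict(st2), "non-finite")
})

test_that("Kalman update implements the textbook gain", {
  # P = I, R = I: K = 0.5 on the observed components
  st <- kf_init(c(10, 10, 100, 1))
  st$P <- diag(7)
  st$R <- diag(4)
  z <- c(12, 14, 110, 1.1)
  up <- kf_update(st, z)
  expect_equal(up$x[1:4], st$x[1:4] + 0.5 * (z - st$x[1:4]))

  # zero prior covariance: the observation is ignored
  st0 <- st
  st0$P <- matrix(0, 7, 7)
  st0$R <- diag(4)
  up0 <- kf_update(st0, z)
  expect_equal(up0$x, st$x)

  # posterior trace does not exceed the prior trace
  expect_lte(sum(diag(up$P)), sum(diag(st$P)))
})

test_that("the filter matches an information-filter oracle over 50 steps", {
  st <- kf_init(c(30, 30, 300, 1))
  x <- st$x; P <- st$P
  zs <- with_seed(13, matrix(c(stats::rnorm(50, 30, 2), stats::rnorm(50, 30, 2),
                               stats::rnorm(50, 300, 10),
                               stats::runif(50, 0.8, 1.2)), 50, 4))
  for (k in 1:50) {
    st <- kf_update(kf_predict(st), zs[k, ])
    or <- info_filter_step(x, P, st$F, st$H, st$Q, st$R, zs[k, ])
    x <- or$x; P <- or$P
    expect_equal(st$x, x, tolerance = 1e-8)
    expect_equal(st$P, P, tolerance = 1e-8)
  }
})

test_that("covariances stay symmetric and positive semidefinite", {
  st <- kf_init(c(10, 10, 200, 1))
  zs <- with_seed(17, cbind(stats::rnorm(1000, 10, 3), stats::rnorm(1000, 10, 3),
                            stats::runif(1000, 100, 400),
                            stats::runif(1000, 0.5, 2)))
  for (k in seq_len(nrow(zs))) {
    st <- kf_update(kf_predict(st), zs[k, ])
  }
  expect_equal(st$P, t(st$P))
  expect_gte(min(eigen(st$P, symmetric = TRUE, only.values = TRUE)$values),
             -1e-9)
})

test_that("virtual trajectories interpolate boxes linearly", {
  z1 <- c(0, 0, 10, 10); z2 <- c(20, 4, 30, 14)
  expect_equal(virtual_trajectory(z1, 0, z2, 10, 5), c(10, 2, 20, 12))
  expect_equal(virtual_trajectory(z1, 0, z2, 10, 1e-9),
               z1, tolerance = 1e-7)
  expect_error(virtual_trajectory(z1, 0, z2, 10, 12), "t1 < t < t2")

  # constant-velocity truth is recovered exactly at every gap frame
  v <- c(3, -1)
  truth <- function(t) c(t * v[1], t * v[2], t * v[1] + 8, t * v[2] + 8)
  for (t in 1:9)
    expect_equal(virtual_trajectory(truth(0), 0, truth(10), 10, t), truth(t))
})

test_that("re-update along the virtual trajectory suppresses coasting drift", {
  # noiseless constant-velocity target with an 8-frame detection gap
  truth <- function(t) c(10 + 2 * t, 50, 10 + 2 * t + 20, 50 + 15)
  tr <- satsn:::new_track(1L, truth(0), 1, 0L)
  for (t in 1:5) {
    tr$kf <- kf_update(kf_predict(tr$kf), satsn:::box_to_obs(truth(t)))
    tr$obs <- rbind(tr$obs, data.frame(t = t, x1 = truth(t)[1],
                                       y1 = truth(t)[2], x2 = truth(t)[3],
                                       y2 = truth(t)[4]))
    tr$last_obs <- truth(t); tr$last_obs_t <- t
  }
  tr <- satsn:::take_snapshot(tr)
  coast <- tr$kf
  for (t in 6:13) coast <- kf_predict(coast)
  oru <- oru_reupdate(tr, truth(13), 13L)
  err <- function(kf) sum(abs(satsn:::predicted_box(kf) - truth(13)))
  expect_lt(err(oru$kf), err(coast))
  expect_lte(sum(diag(oru$kf$P)), sum(diag(coast$P)))

  # gap of one frame reduces to a plain predict + update
  plain <- kf_update(kf_predict(tr$kf), satsn:::box_to_obs(truth(6)))
  one <- oru_reupdate(tr, truth(6), 6L)
  expect_equal(one$kf$x, plain$x, tolerance = 1e-12)
  expect_equal(one$kf$P, plain$P, tolerance = 1e-12)
  # deterministic
  expect_identical(oru_reupdate(tr, truth(13), 13L), oru)
})

test_that("the momentum cost prefers direction-consistent candidates", {
  mk_track <- function(dirx) {
    tr <- satsn:::new_track(1L, c(0, 0, 10, 10), 1, 0L)
    for (t in 1:5) {
      b <- c(dirx * 2 * t, 0, dirx * 2 * t + 10, 10)
      tr$kf <- kf_update(kf_predict(tr$kf), satsn:::box_to_obs(b))
      tr$obs <- rbind(tr$obs, data.frame(t = t, x1 = b[1], y1 = b[2],
                                         x2 = b[3], y2 = b[4]))
      tr$last_obs <- b
    }
    tr
  }
  tr <- mk_track(1) # moving +x, last box at x = 10..20
  ahead <- c(14, 0, 24, 10)  # displaced +x
  behind <- c(6, 0, 16, 10)  # displaced -x, same IoU with the last box
  expect_equal(iou(tr$last_obs, ahead), iou(tr$last_obs, behind))
  expect_lt(ocm_cost(tr, ahead, lambda = 0.5),
            ocm_cost(tr, behind, lambda = 0.5))

  # lambda = 0 recovers the pure IoU cost
  expect_equal(ocm_cost(tr, ahead, lambda = 0),
               1 - iou(satsn:::predicted_box(tr$kf), ahead))
  # a candidate exactly on the motion ray has zero direction cost
  on_ray <- c(30, 0, 40, 10)
  expect_equal(satsn:::direction_cost(tr, on_ray, 3L), 0)
})

test_that("the assignment solver is optimal against brute force", {
  for (trial in 1:50) {
    n <- with_seed(trial, sample(1:4, 1))
    extras <- 0:(4 - n)
    m <- n + with_seed(trial + 100, extras[sample.int(length(extras), 1)])
    cost <- with_seed(trial + 200, matrix(runif(n * m), n, m))
    got <- satsn:::solve_assignment(cost)
    want <- brute_assignment(cost)
    expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                 tolerance = 1e-10)
  }
})

test_that("association matches, gates and resolves crossings", {
  cfgT <- tracker_config()
  tr <- satsn:::take_snapshot(satsn:::new_track(1L, c(0, 0, 10, 10), 1, 1L))
  tr$kf <- kf_predict(tr$kf)
  res <- associate(list(tr), matrix(c(1, 1, 11, 11), 1), cfgT)
  expect_equal(nrow(res$matches), 1L)

  res0 <- associate(list(tr), NULL, cfgT)
  expect_equal(res0$unmatched_tracks, 1L)
  expect_equal(length(res0$unmatched_dets), 0L)

  far <- associate(list(tr), matrix(c(100, 100, 110, 110), 1), cfgT)
  expect_equal(nrow(far$matches), 0L)
})

test_that("the recovery pass re-acquires stationary dropouts by GIoU", {
  cfg <- quick_scene(seed = 31, n_frames = 40L)
  sc <- render_scene(cfg, list(agent_script(1, "standing", c(130, 80))))
  d <- perturb_detections(sc$gt, sigma = 0.3, kp_sigma = 0, miss_rate = 0,
                          seed = 2, dropouts = list(c(1L, 15L, 19L)))
  tracks <- track_video(d[setdiff(names(d), "agent_id")], tracker_config())
  expect_equal(length(unique(tracks$track_id)), 1L)
  expect_equal(id_switch_count(tracks, sc$gt), 0L)

  # ocr threshold semantics: a detection below the GIoU floor is no match
  tr <- satsn:::take_snapshot(satsn:::new_track(1L, c(0, 0, 10, 10), 1, 1L))
  expect_equal(nrow(ocr_pass(list(tr), matrix(c(500, 500, 510, 510), 1),
                             tracker_config())), 0L)
  expect_equal(nrow(ocr_pass(list(), NULL, tracker_config())), 0L)
})

test_that("tracking a noiseless stream yields one stable id per agent", {
  cfg <- quick_scene(seed = 33, n_frames = 48L)
  scripts <- list(agent_script(1, "standing", c(90, 70)),
                  agent_script(2, "standing", c(170, 100)),
                  agent_script(3, "walking", c(70, 120), velocity = c(2, 0),
                               facing = 1))
  sc <- render_scene(cfg, scripts)
  d <- perturb_detections(sc$gt, sigma = 0, kp_sigma = 0, miss_rate = 0,
                          seed = 3)
  tracks <- track_video(d[setdiff(names(d), "agent_id")], tracker_config())
  expect_equal(length(unique(tracks$track_id)), 3L)
  expect_equal(id_switch_count(tracks, sc$gt), 0L)
  # deterministic rerun
  tracks2 <- track_video(d[setdiff(names(d), "agent_id")], tracker_config())
  expect_identical(tracks, tracks2)
})

test_that("observation-centric mechanisms prevent the crossing identity switch", {
  fx <- make_crossing_fixture(seed = 1)
  d <- fx$dets[setdiff(names(fx$dets), "agent_id")]
  full <- track_video(d, tracker_config())
  ablation <- track_video(d, tracker_config(lambda = 0, use_oru = FALSE,
                                            use_ocm = FALSE,
                                            use_ocr = FALSE))
  expect_equal(id_switch_count(full, fx$gt), 0L)
  expect_gte(id_switch_count(ablation, fx$gt), 1L)
})
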