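test_that("rendering is bit-identical under a fixed seed", {
  cfg <- quick_scene(seed = 7)
  s1 <- render_scene(cfg, list(agent_script(1, "licking", c(100, 80))))
  s2 <- render_scene(cfg, list(agent_script(1, "licking", c(100, 80))))
  expect_identical(s1$clip$frames, s2$clip$frames)
  expect_identical(s1$gt, s2$gt)
})

test_that("behavior kinematics match their construction", {
  cfg <- quick_scene(seed = 3)
  # walking at velocity (2, 0): centroid advances 2 px/frame
  sc <- render_scene(cfg, list(agent_script(1, "walking", c(80, 80),
                                            velocity = c(2, 0), facing = 1)))
  cx <- (sc$gt$x1 + sc$gt$x2) / 2
  expect_equal(diff(cx), rep(2, cfg$n_frames - 1L))
  expect_true(all(sc$gt$behavior == "walking"))

  # standing: body sway below 0.2 px/frame, label standing everywhere
  st <- render_scene(cfg, list(agent_script(1, "standing", c(120, 80))))
  cx <- (st$gt$x1 + st$gt$x2) / 2
  cy <- (st$gt$y1 + st$gt$y2) / 2
  expect_lt(max(sqrt(diff(cx)^2 + diff(cy)^2)), 0.2)
  expect_true(all(st$gt$behavior == "standing"))

  # mouth keypoint stays inside the body box when visible
  for (sc2 in list(sc, st)) {
    ok <- sc2$gt$mouth_x >= sc2$gt$x1 & sc2$gt$mouth_x <= sc2$gt$x2 &
      sc2$gt$mouth_y >= sc2$gt$y1 & sc2$gt$mouth_y <= sc2$gt$y2
    expect_true(all(ok[sc2$gt$mouth_visible == 2]))
  }
})

test_that("noiseless perturbation returns the ground truth boxes", {
  cfg <- quick_scene(seed = 9)
  sc <- render_scene(cfg, list(agent_script(1, "standing", c(120, 80))))
  d <- perturb_detections(sc$gt, sigma = 0, kp_sigma = 0, miss_rate = 0,
                          seed = 1)
  expect_equal(nrow(d), nrow(sc$gt))
  expect_equal(d$x1, sc$gt$x1)
  expect_equal(d$y2, sc$gt$y2)
  expect_equal(d$mouth_x, sc$gt$mouth_x)
  expect_true(all(d$score >= 0.5 & d$score <= 1))
})

test_that("occluder strips and dropout intervals remove detections", {
  cfg <- quick_scene(seed = 9)
  sc <- render_scene(cfg, list(agent_script(1, "standing", c(120, 80))))
  d <- perturb_detections(sc$gt, sigma = 0, kp_sigma = 0, miss_rate = 0,
                          occluders = list(c(100, 140)), seed = 1)
  expect_equal(nrow(d), 0L) # agent center always inside the strip

  d2 <- perturb_detections(sc$gt, sigma = 0, kp_sigma = 0, miss_rate = 0,
                           seed = 1, dropouts = list(c(1L, 10L, 19L)))
  expect_false(any(d2$frame %in% 10:19))
  expect_equal(nrow(d2), nrow(sc$gt) - 10L)
})

test_that("detection noise matches its stated Gaussian model", {
  cfg <- scene_config(n_frames = 250L, seed = 21)
  sc <- render_scene(cfg, list(agent_script(1, "standing", c(150, 80))))
  gt4 <- rbind(sc$gt, sc$gt, sc$gt, sc$gt) # 1000 boxes
  gt4$frame <- seq_len(nrow(gt4))
  sigma <- 2
  d <- perturb_detections(gt4, sigma = sigma, kp_sigma = 0, miss_rate = 0,
                          seed = 2)
  resid <- c(d$x1 - gt4$x1, d$y1 - gt4$y1, d$x2 - gt4$x2, d$y2 - gt4$y2)
  n <- length(resid)
  expect_lt(abs(mean(resid)), 3 * sigma / sqrt(n))
  expect_lt(abs(stats::sd(resid) - sigma), 3 * sigma / sqrt(2 * n))
})

test_that("a threshold rule separates the four behaviors on clean truth", {
  n <- 24L
  correct <- 0L
  for (i in seq_len(n)) {
    beh <- satsn_action_names[(i - 1L) %% 4L + 1L]
    cfg <- quick_scene(seed = 4000L + i)
    script <- with_seed(4000L + i, satsn:::place_agent(beh, cfg))
    sc <- render_scene(cfg, list(script))
    if (rule_classify(sc$gt, cfg)$behavior == beh) correct <- correct + 1L
  }
  expect_gte(correct / n, 0.95)
})

test_that("fixture datasets are balanced, counted and reproducible", {
  d1 <- withr::local_tempdir()
  man <- cmd_simulate(d1, n_clips = 8L, seed = 5L,
                      scene = quick_scene(seed = 5))
  manifest <- jsonlite::read_json(file.path(d1, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(manifest$seed, 5L)
  expect_equal(unlist(manifest$behaviors),
               c(eating = 2L, licking = 2L, standing = 2L, walking = 2L))
  ava <- read_ava_csv(file.path(d1, "train.csv"))
  # one AVA row per labeled keyframe per agent
  pl <- satsn_config()
  ks <- valid_keyframes(32L, quick_scene()$fps, pl)
  train_ids <- unlist(manifest$clips$train)
  expect_equal(nrow(ava), length(ks) * length(train_ids))
  expect_error(make_fixture_dataset(d1, n_clips = 8L, seed = 5L),
               "force")

  d2 <- withr::local_tempdir()
  make_fixture_dataset(d2, n_clips = 8L, cfg = quick_scene(seed = 5),
                       seed = 5L)
  expect_identical(readLines(file.path(d1, "train.csv")),
                   readLines(file.path(d2, "train.csv")))
  expect_identical(readLines(file.path(d1, "clip0001/detections.jsonl")),
                   readLines(file.path(d2, "clip0001/detections.jsonl")))
})
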