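test_that("crop windows center on the keypoint and clamp at borders", {
  fr <- with_seed(1, array(runif(400 * 600 * 3), c(400, 600, 3)))
  kp <- c(300, 200)
  patch <- crop_region(fr, kp, 128)
  expect_equal(dim(patch), c(128L, 128L, 3L))
  # patch center pixel equals the frame pixel at the keypoint
  expect_equal(patch[65, 65, ], fr[200, 300, ])

  # keypoint at the top-left corner: window clamps to the first pixels
  p2 <- crop_region(fr, c(1, 1), 128)
  expect_equal(p2[, , 1], fr[1:128, 1:128, 1])

  # index-arithmetic oracle for an arbitrary clamped case
  p3 <- crop_region(fr, c(10, 390), 128)
  expect_equal(p3[, , 2], fr[(400 - 127):400, 1:128, 2])
})

test_that("crops of frames smaller than the window zero-pad symmetrically", {
  fr <- array(1, c(64, 64, 3))
  p <- crop_region(fr, c(32, 32), 128)
  expect_equal(dim(p), c(128L, 128L, 3L))
  expect_equal(p[33:96, 33:96, ], fr)
  expect_true(all(p[1:32, , ] == 0))
  expect_true(all(p[, 97:128, ] == 0))
})

test_that("crop output shape is invariant over fuzzed geometries", {
  cases <- with_seed(77, data.frame(
    H = sample(5:200, 300, TRUE), W = sample(5:200, 300, TRUE),
    x = runif(300, -10, 220), y = runif(300, -10, 220),
    size = sample(c(16L, 31L, 64L, 128L), 300, TRUE)))
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    fr <- array(0, c(cs$H, cs$W, 3))
    p <- crop_region(fr, c(cs$x, cs$y), cs$size)
    expect_identical(dim(p), c(cs$size, cs$size, 3L))
  }
})

test_that("cropping around an absent keypoint is an error", {
  fr <- array(0, c(50, 50, 3))
  expect_error(crop_region(fr, keypoint(10, 10, visible = 0L), 16),
               "visible = 0")
  expect_silent(crop_region(fr, keypoint(10, 10, visible = 1L), 16))
})

test_that("two-stream sampling covers a shared window at both rates", {
  s <- sample_two_stream_frames(16L, T = 4L, tau = 4L, alpha = 2L)
  expect_length(s$slow, 4L)
  expect_length(s$fast, 8L)
  expect_true(all(s$slow >= min(s$fast) & s$slow <= max(s$fast)))
  expect_equal(diff(s$slow), rep(4L, 3L))

  s2 <- sample_two_stream_frames(10L, T = 4L, tau = 1L, alpha = 1L)
  expect_identical(s2$slow, s2$fast)

  expect_error(sample_two_stream_frames(63L, T = 4L, tau = 16L, alpha = 2L),
               "64")
  # centered windows respect clip bounds
  expect_error(sample_two_stream_frames(64L, 4L, 4L, 2L, center = 2L),
               "window")
})

test_that("routing substitutes the mouth crop exactly per scheme and label", {
  cfg <- quick_scene(seed = 12)
  sc <- render_scene(cfg, list(agent_script(1, "licking", c(100, 80))))
  g <- sc$gt[sc$gt$frame == 16, ][1, ]
  box <- bbox(g$x1, g$y1, g$x2, g$y2)
  kp <- keypoint(g$mouth_x, g$mouth_y, 2L)
  pl <- satsn_config(crop_size = 32L)

  lickB <- route_inputs(sc$clip, box, kp, scheme = "B", config = pl,
                        input_size = 32L, label_hint = "licking",
                        center_frame = 16L)
  expect_equal(lickB$fast_content, "mouth_crop")
  expect_equal(lickB$slow_content, "full_body")
  expect_equal(dim(lickB$fast), c(32L, 32L, 3L, 16L))
  expect_equal(dim(lickB$slow), c(32L, 32L, 3L, 4L))

  eatB <- route_inputs(sc$clip, box, kp, scheme = "B", config = pl,
                       input_size = 32L, label_hint = "eating",
                       center_frame = 16L)
  expect_equal(eatB$fast_content, "full_body")
  expect_equal(eatB$slow_content, "full_body")

  lickC <- route_inputs(sc$clip, box, kp, scheme = "C", config = pl,
                        input_size = 32L, label_hint = "licking",
                        center_frame = 16L)
  expect_equal(lickC$slow_content, "mouth_crop")
  expect_equal(lickC$fast_content, "full_body")

  # scheme A ignores the label entirely
  lickA <- route_inputs(sc$clip, box, kp, scheme = "A", config = pl,
                        input_size = 32L, label_hint = "licking",
                        center_frame = 16L)
  expect_equal(lickA$fast_content, "full_body")
  expect_identical(lickA$slow, eatB$slow)
  expect_identical(lickA$fast, eatB$fast)

  # inference mode applies the scheme whenever the keypoint is visible
  infB <- route_inputs(sc$clip, box, kp, scheme = "B", config = pl,
                       input_size = 32L, center_frame = 16L)
  expect_equal(infB$fast_content, "mouth_crop")
  hidden <- route_inputs(sc$clip, box, keypoint(0, 0, 0L), scheme = "B",
                         config = pl, input_size = 32L, center_frame = 16L)
  expect_equal(hidden$fast_content, "full_body")

  # routing is a pure function
  again <- route_inputs(sc$clip, box, kp, scheme = "B", config = pl,
                        input_size = 32L, label_hint = "licking",
                        center_frame = 16L)
  expect_identical(again, lickB)

  degen <- c(x1 = 10, y1 = 10, x2 = 9, y2 = 9)
  expect_error(route_inputs(sc$clip, degen, kp, scheme = "B", config = pl,
                            input_size = 32L),
               "degenerate")
})
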