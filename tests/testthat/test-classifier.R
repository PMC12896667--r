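test_that("body length is the hip-shoulder Euclidean distance", {
  expect_identical(body_length(list(shoulder_x = 0, shoulder_y = 0,
                                    hip_x = 3, hip_y = 4)), 5)
  expect_identical(body_length(list(shoulder_x = 7, shoulder_y = 7,
                                    hip_x = 7, hip_y = 7)), 0)
  expect_true(is.na(body_length(list(shoulder_x = NA, shoulder_y = NA,
                                     hip_x = 1, hip_y = 1))))
  set.seed(2)
  for (i in 1:20) {
    p <- runif(4, 0, 1000)
    expect_equal(body_length(list(shoulder_x = p[1], shoulder_y = p[2],
                                  hip_x = p[3], hip_y = p[4])),
                 sqrt((p[3] - p[1])^2 + (p[4] - p[2])^2))
  }
})

test_that("static rules follow the documented precedence", {
  cfg <- rule_config()
  # head 70 px below shoulder: foraging by the head rule
  expect_identical(classify_static(list(shoulder_x = 500,
                                        shoulder_y = 300,
                                        head_x = 500, head_y = 370,
                                        hip_x = 600, hip_y = 300), cfg),
                   "Foraging/Feeding")
  # nose rule alone also fires it
  expect_identical(classify_static(list(shoulder_x = 500,
                                        shoulder_y = 300,
                                        nose_x = 510, nose_y = 395,
                                        hip_x = 600, hip_y = 300), cfg),
                   "Foraging/Feeding")
  # "at least" is inclusive: drop of exactly 60 qualifies
  expect_identical(classify_static(list(shoulder_x = 500,
                                        shoulder_y = 300,
                                        head_x = 500, head_y = 360,
                                        hip_x = 600, hip_y = 300), cfg),
                   "Foraging/Feeding")
  # shoulder inside the lying zone wins regardless of head position
  expect_identical(classify_static(list(shoulder_x = 1400,
                                        shoulder_y = 300,
                                        head_x = 1400, head_y = 380,
                                        hip_x = 1000, hip_y = 500), cfg),
                   "Lying Down")
  # zone boundaries are closed
  expect_identical(classify_static(list(shoulder_x = 1080,
                                        shoulder_y = 270,
                                        hip_x = 900, hip_y = 500), cfg),
                   "Lying Down")
  # nothing qualifies: the default behavior
  expect_identical(classify_static(list(shoulder_x = 500,
                                        shoulder_y = 300,
                                        head_x = 500, head_y = 280,
                                        hip_x = 600, hip_y = 300), cfg),
                   "Standing")
  # all keypoints absent
  expect_identical(classify_static(list(shoulder_x = NA,
                                        shoulder_y = NA, hip_x = NA,
                                        hip_y = NA), cfg),
                   "Not Labeled")
  # missing head and nose skip the foraging rule but keep the frame
  expect_identical(classify_static(list(shoulder_x = 500,
                                        shoulder_y = 300,
                                        hip_x = 600, hip_y = 300), cfg),
                   "Standing")
})

test_that("displacement rule is strict and needs a Standing static label", {
  base <- make_frames(0:2, shoulder_x = c(500, 500, 600),
                      shoulder_y = 700)
  # body length 200; second 2 moves both anchors by exactly 100 = 0.5 L
  tr <- pose_track("a", base)
  lab <- classify_track(tr)
  expect_identical(lab$behavior, rep("Standing", 3))

  # just over half a body length fires
  over <- make_frames(0:2, shoulder_x = c(500, 500, 601),
                      shoulder_y = 700)
  expect_identical(classify_track(pose_track("a", over))$behavior,
                   c("Standing", "Standing", "Locomotion"))

  # a large jump on the first observed second cannot be Locomotion
  first <- make_frames(0:1, shoulder_x = c(500, 900), shoulder_y = 700)
  expect_identical(classify_track(pose_track("a", first))$behavior[1],
                   "Standing")

  # a foraging pose moving fast stays Foraging (rule requires Standing)
  run_forage <- make_frames(0:1, shoulder_x = c(500, 900),
                            shoulder_y = 700)
  run_forage$head_y <- run_forage$shoulder_y + 80
  expect_identical(classify_track(pose_track("a",
                                             run_forage))$behavior[2],
                   "Foraging/Feeding")

  # zero body length can never fire the rule
  degen <- make_frames(0:1, shoulder_x = c(500, 900), shoulder_y = 700,
                       hip_x = c(500, 900), hip_y = 700)
  expect_identical(classify_track(pose_track("a", degen))$behavior[2],
                   "Standing")
})

test_that("every second gets exactly one of the five categories", {
  cfg <- sim_config(duration_s = 800, jitter_px = 8, miss_prob = 0.15,
                    seed = 21)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  lab <- classify_track(sim$track)
  expect_identical(nrow(lab), nrow(sim$track$frames))
  expect_true(all(lab$behavior %in% automated_categories()))

  empty <- pose_track("e", make_frames(integer(0), numeric(0),
                                       numeric(0)))
  expect_identical(nrow(classify_track(empty)), 0L)
})

test_that("an occluded middle second is Not Labeled, neighbors intact", {
  f <- make_frames(0:2, shoulder_x = 500, shoulder_y = 700)
  f[2, 3:14] <- NA
  lab <- classify_track(pose_track("a", f))
  expect_identical(lab$behavior, c("Standing", "Not Labeled", "Standing"))
})

test_that("raising drop thresholds never increases Foraging counts", {
  cfg <- sim_config(duration_s = 600, jitter_px = 15, seed = 33)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  counts <- vapply(c(40, 60, 80, 120), function(th) {
    rc <- rule_config(head_drop_px = th, nose_drop_px = th * 1.5)
    sum(classify_track(sim$track, rc)$behavior == "Foraging/Feeding")
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("locomotion vanishes as the displacement threshold grows", {
  cfg <- sim_config(duration_s = 600, seed = 12)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  rc <- rule_config(locomotion_fraction = 1e9)
  expect_identical(sum(classify_track(sim$track,
                                      rc)$behavior == "Locomotion"), 0L)
})

test_that("noise-free synthetic tracks are recovered perfectly", {
  cfg <- sim_config(duration_s = 2000, seed = 77)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  pred <- classify_track(sim$track)
  expect_identical(pred$behavior, sim$truth$behavior)
})

test_that("classifier matches the straight-line rule oracle", {
  cfg <- sim_config(duration_s = 1000, jitter_px = 12, miss_prob = 0.1,
                    seed = 55)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  expect_identical(classify_track(sim$track)$behavior,
                   oracle_classify(sim$track))

  # also under the alternative displacement modes on clean data
  for (mode in c("max", "both")) {
    rc <- rule_config(displacement = mode)
    lab <- classify_track(sim$track, rc)
    expect_true(all(lab$behavior %in% automated_categories()))
  }
})

test_that("rule configs round-trip through YAML", {
  tmp <- withr::local_tempfile(fileext = ".yaml")
  rc <- rule_config(head_drop_px = 55, nose_drop_px = 80,
                    locomotion_fraction = 0.6)
  write_rule_yaml(rc, tmp)
  expect_equal(read_rule_yaml(tmp), rc)
})
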