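test_that("behavior sequences respect absorbing and empty configs", {
  k <- length(terrestrial_behaviors())
  cfg <- sim_config(duration_s = 50,
                    transition_matrix = diag(k),
                    mean_dwell_s = stats::setNames(rep(2, k),
                                                   terrestrial_behaviors()),
                    seed = 5)
  s <- simulate_behavior_sequence(cfg)
  expect_true(all(s$behavior == "Standing"))

  empty <- simulate_behavior_sequence(sim_config(duration_s = 0))
  expect_identical(nrow(empty), 0L)

  bad <- sim_config(duration_s = 10)
  bad$transition_matrix[1, 1] <- 5
  expect_error(sim_config(duration_s = 10,
                          transition_matrix = bad$transition_matrix),
               "row-stochastic")
})

test_that("state frequencies match the effective chain's stationary law", {
  k <- 4
  tm <- matrix(0.25, k, k)
  cfg <- sim_config(duration_s = 10000, transition_matrix = tm,
                    mean_dwell_s = stats::setNames(rep(1, k),
                                                   terrestrial_behaviors()),
                    seed = 101)
  s <- simulate_behavior_sequence(cfg)
  # with mean dwell 1 the per-second chain IS the jump matrix; its
  # stationary law comes from the leading left eigenvector
  stay <- 1 - 1 / cfg$mean_dwell_s
  p_eff <- diag(stay, k) + (1 - stay) * tm
  ev <- eigen(t(p_eff))
  pi_hat <- Re(ev$vectors[, which.max(Re(ev$values))])
  pi_hat <- pi_hat / sum(pi_hat)
  emp <- as.vector(table(factor(s$behavior,
                                levels = cfg$behaviors))) / nrow(s)
  se <- sqrt(pi_hat * (1 - pi_hat) / nrow(s))
  expect_true(all(abs(emp - pi_hat) <= 3 * se))
})

test_that("dwell self-transition frequency matches the geometric model", {
  cfg <- sim_config(duration_s = 20000, seed = 7)
  s <- simulate_behavior_sequence(cfg)
  b <- s$behavior
  for (beh in c("Standing", "Lying Down")) {
    at <- which(b[-length(b)] == beh)
    stay_hat <- mean(b[at + 1L] == beh)
    p <- 1 - 1 / cfg$mean_dwell_s[[beh]]
    se <- sqrt(p * (1 - p) / length(at))
    expect_lt(abs(stay_hat - p), 3 * se + 1e-12)
  }
})

test_that("generators are bit-reproducible given seed and config", {
  cfg <- sim_config(duration_s = 300, jitter_px = 3, miss_prob = 0.1,
                    seed = 42)
  a <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  b <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  expect_identical(a$track$frames, b$track$frames)
  expect_identical(a$truth$behavior, b$truth$behavior)

  cfg2 <- sim_config(duration_s = 300, jitter_px = 3, miss_prob = 0.1,
                     seed = 43)
  c2 <- realize_keypoints(simulate_behavior_sequence(cfg2), cfg2)
  expect_false(identical(a$track$frames, c2$track$frames))
})

test_that("realized geometry fires each behavior's rule by construction", {
  cfg <- sim_config(duration_s = 2000, seed = 9)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  f <- sim$track$frames
  z <- cfg$lying_zone
  forag <- sim$truth$behavior == "Foraging/Feeding"
  expect_true(all(f$head_y[forag] - f$shoulder_y[forag] >= 60))
  lying <- sim$truth$behavior == "Lying Down"
  expect_true(all(f$shoulder_x[lying] >= z$x_min &
                    f$shoulder_x[lying] <= z$x_max &
                    f$shoulder_y[lying] >= z$y_min &
                    f$shoulder_y[lying] <= z$y_max))
  standing <- sim$truth$behavior == "Standing"
  expect_true(all(f$head_y[standing] < f$shoulder_y[standing]))
})

test_that("total occlusion drops every keypoint", {
  cfg <- sim_config(duration_s = 50, miss_prob = 1, seed = 3)
  sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
  expect_true(all(is.na(sim$track$frames$shoulder_x)))
  expect_true(all(classify_track(sim$track)$behavior == "Not Labeled"))
})

test_that("margin at or below jitter triggers the noise warning", {
  cfg <- sim_config(duration_s = 10, jitter_px = 30, margin_px = 25,
                    seed = 1)
  expect_warning(realize_keypoints(simulate_behavior_sequence(cfg), cfg),
                 "jitter")
})

test_that("simulated observers degrade annotations at the stated rates", {
  truth <- annotation_series("a", 0:4999,
                             sample(terrestrial_behaviors(), 5000, TRUE))
  expect_identical(simulate_observer(truth, 0, 0, seed = 1)$behavior,
                   truth$behavior)

  two_cat <- annotation_series("a", 0:99,
                               rep(c("Standing", "Lying Down"), 50),
                               categories = c("Standing", "Lying Down"))
  flipped <- simulate_observer(two_cat, 1, 0, seed = 1)
  expect_true(all(flipped$behavior != two_cat$behavior))

  noisy <- simulate_observer(truth, 0.2, 0, seed = 8)
  dis <- mean(noisy$behavior != truth$behavior)
  expect_lt(abs(dis - 0.2), 3 * sqrt(0.2 * 0.8 / 5000))

  oos <- simulate_observer(truth, 0, 0.3, seed = 8)
  expect_lt(abs(mean(oos$behavior == "Out of Sight") - 0.3),
            3 * sqrt(0.3 * 0.7 / 5000))
})

test_that("study tables are valid daily Dirichlet draws", {
  cfg <- study_sim_config(n_days_per_period = 1, seed = 2)
  tab <- simulate_study_table(cfg)
  for (ind in cfg$individuals) {
    expect_identical(nrow(unique(tab[tab$individual == ind,
                                     c("period", "day")])), 2L)
  }
  cfg8 <- study_sim_config(n_days_per_period = 8, seed = 2)
  tab8 <- simulate_study_table(cfg8)
  sums <- tapply(tab8$proportion,
                 paste(tab8$individual, tab8$period, tab8$day), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("a concentration shift onto Scenting raises its test median", {
  cfg <- study_sim_config(individuals = "calf", scent_effect = 20,
                          seed = 4)
  tab <- simulate_study_table(cfg)
  ctl <- daily_medians(tab, "calf", "control", "Scenting")
  tst <- daily_medians(tab, "calf", "test", "Scenting")
  expect_gt(tst, ctl)
})

test_that("tracking points follow the mixture and stay in bounds", {
  one <- simulate_tracking_points(25, data.frame(weight = 1, x = 300,
                                                 y = 200, sd = 0),
                                  seed = 1)
  expect_true(all(one$x == 300 & one$y == 200))

  none <- simulate_tracking_points(0, data.frame(weight = 1, x = 0,
                                                 y = 0, sd = 1))
  expect_identical(nrow(none), 0L)

  two <- simulate_tracking_points(
    10000, data.frame(weight = c(0.8, 0.2), x = c(400, 1500),
                      y = c(600, 300), sd = 50), seed = 6)
  occ <- mean(two$component == 1L)
  expect_lt(abs(occ - 0.8), 3 * sqrt(0.8 * 0.2 / 10000))
  expect_true(all(two$x >= 0 & two$x <= 1920 &
                    two$y >= 0 & two$y <= 1080))

  expect_error(simulate_tracking_points(
    5, data.frame(weight = c(0.5, 0.2), x = 0, y = 0, sd = 1)),
    "sum to 1")
})
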