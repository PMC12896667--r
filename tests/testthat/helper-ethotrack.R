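# shared fixtures and independent oracles, all built in code

round_half_up <- function(x, digits = 3) {
  floor(x * 10^digits + 0.5) / 10^digits
}

# published-style validation counts: rows = predicted, cols = manual
validation_counts <- function() {
  m <- rbind(c(100, 2, 158, 27, 0),
             c(9, 225, 3, 0, 0),
             c(1, 0, 221, 2, 0),
             c(0, 0, 0, 26, 0),
             c(85, 41, 11, 3, 286))
  cats <- c("Standing", "Lying Down", "Foraging/Feeding", "Locomotion",
            "Out of View/Not Labeled")
  dimnames(m) <- list(predicted = cats, manual = cats)
  m
}

# expected per-class metrics at 3 decimals for the validation counts
validation_metrics_3dp <- function() {
  rbind(precision   = c(0.348, 0.949, 0.987, 1, 0.671),
        accuracy    = c(0.765, 0.954, 0.854, 0.973, 0.883),
        sensitivity = c(0.513, 0.840, 0.562, 0.448, 1),
        specificity = c(0.814, 0.987, 0.996, 1, 0.847),
        tss         = c(0.327, 0.827, 0.559, 0.448, 0.847))
}

# quick wide-frame pose track builder; coords default to a standing pose
make_frames <- function(time_s, shoulder_x, shoulder_y,
                        hip_x = shoulder_x - 200, hip_y = shoulder_y,
                        head_x = shoulder_x + 20,
                        head_y = shoulder_y - 25,
                        nose_x = shoulder_x + 40,
                        nose_y = shoulder_y - 25, score = 1) {
  n <- length(time_s)
  r <- function(v) rep_len(v, n)
  data.frame(frame = time_s, time_s = time_s,
             nose_x = r(nose_x), nose_y = r(nose_y),
             head_x = r(head_x), head_y = r(head_y),
             shoulder_x = r(shoulder_x), shoulder_y = r(shoulder_y),
             hip_x = r(hip_x), hip_y = r(hip_y),
             nose_score = r(score), head_score = r(score),
             shoulder_score = r(score), hip_score = r(score))
}

# straight-line re-implementation of the classification rules: explicit
# per-second loop, independent of the package's vectorized code path
oracle_classify <- function(track, cfg = rule_config()) {
  f <- track$frames
  z <- cfg$lying_zone
  n <- nrow(f)
  lab <- character(n)
  for (t in seq_len(n)) {
    hip_ok <- !is.na(f$hip_x[t]) && !is.na(f$hip_y[t])
    sho_ok <- !is.na(f$shoulder_x[t]) && !is.na(f$shoulder_y[t])
    if (!hip_ok && !sho_ok) {
      lab[t] <- "Not Labeled"
      next
    }
    inz <- function(x, y) {
      x >= z$x_min && x <= z$x_max && y >= z$y_min && y <= z$y_max
    }
    if ((hip_ok && inz(f$hip_x[t], f$hip_y[t])) ||
        (sho_ok && inz(f$shoulder_x[t], f$shoulder_y[t]))) {
      lab[t] <- "Lying Down"
      next
    }
    forage <- FALSE
    if (sho_ok) {
      if (!is.na(f$head_y[t]) &&
          f$head_y[t] - f$shoulder_y[t] >= cfg$head_drop_px) forage <- TRUE
      if (!is.na(f$nose_y[t]) &&
          f$nose_y[t] - f$shoulder_y[t] >= cfg$nose_drop_px) forage <- TRUE
    }
    lab[t] <- if (forage) "Foraging/Feeding" else "Standing"
  }
  for (t in seq_len(n)) {
    if (t == 1L || lab[t] != "Standing") next
    if (f$time_s[t] - f$time_s[t - 1L] != 1) next
    ok <- all(!is.na(c(f$hip_x[t], f$hip_y[t], f$shoulder_x[t],
                       f$shoulder_y[t], f$hip_x[t - 1L], f$hip_y[t - 1L],
                       f$shoulder_x[t - 1L], f$shoulder_y[t - 1L])))
    if (!ok) next
    dh <- sqrt((f$hip_x[t] - f$hip_x[t - 1L])^2 +
                 (f$hip_y[t] - f$hip_y[t - 1L])^2)
    ds <- sqrt((f$shoulder_x[t] - f$shoulder_x[t - 1L])^2 +
                 (f$shoulder_y[t] - f$shoulder_y[t - 1L])^2)
    bl <- sqrt((f$hip_x[t] - f$shoulder_x[t])^2 +
                 (f$hip_y[t] - f$shoulder_y[t])^2)
    if (bl > 0 && (dh + ds) / 2 > cfg$locomotion_fraction * bl) {
      lab[t] <- "Locomotion"
    }
  }
  lab
}

# Kendall's W from the rank definition, via the alternative closed form
# 12*sum(R_j^2) - 3 m^2 n (n+1)^2 in the numerator
oracle_kendalls_w <- function(x) {
  m <- nrow(x); n <- ncol(x)
  r <- matrix(0, m, n)
  tie_term <- 0
  for (i in seq_len(m)) {
    r[i, ] <- rank(x[i, ])
    for (v in unique(r[i, ])) {
      t <- sum(r[i, ] == v)
      tie_term <- tie_term + (t^3 - t)
    }
  }
  rj <- colSums(r)
  num <- 12 * sum(rj^2) - 3 * m^2 * n * (n + 1)^2
  num / (m^2 * (n^3 - n) - m * tie_term)
}

# U statistic for x by direct pair counting (half credit for ties)
oracle_u <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  u
}
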