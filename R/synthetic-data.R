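#' Simulate a per-second behavior sequence
#'
#' Draws a behavior label for every second from the semi-Markov model in
#' the config: geometric dwell in the current behavior (mean
#' `mean_dwell_s`), then a jump according to `transition_matrix`. The
#' start state is the first entry of `config$behaviors`.
#'
#' @param config A [sim_config()].
#' @return A data frame with columns `second` (0-based) and `behavior`,
#'   `duration_s` rows. Deterministic given `config$seed`.
#' @examples
#' cfg <- sim_config(duration_s = 10, seed = 7)
#' simulate_behavior_sequence(cfg)
#' @export
simulate_behavior_sequence <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$behaviors)
  stay <- 1 - 1 / config$mean_dwell_s
  # per-second chain: stay put with prob stay[i], else jump by row i
  p_eff <- diag(stay, k) + (1 - stay) * config$transition_matrix
  n <- config$duration_s
  if (n == 0L) {
    return(data.frame(second = integer(0), behavior = character(0),
                      stringsAsFactors = FALSE))
  }
  states <- with_seed(config$seed, {
    s <- integer(n)
    s[1L] <- 1L
    if (n > 1L) {
      u <- stats::runif(n - 1L)
      cum <- t(apply(p_eff, 1L, cumsum))
      for (t in 2:n) {
        s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ]) + 1L
      }
    }
    s
  })
  data.frame(second = 0:(n - 1L), behavior = config$behaviors[states],
             stringsAsFactors = FALSE)
}

#' Realize keypoint geometry for a behavior sequence
#'
#' Converts each second's ground-truth behavior into nose/head/shoulder/hip
#' pixel coordinates that satisfy that behavior's classification rule and
#' violate all the others by at least `config$margin_px`:
#'
#' * **Lying Down** — shoulder and hip placed inside the lying rectangle,
#'   at least one margin away from its edges.
#' * **Foraging/Feeding** — head and nose dropped below the shoulder by the
#'   rule thresholds plus a margin (y-down image convention: "below" means
#'   larger y).
#' * **Locomotion** — the body translates 0.75 body lengths from the
#'   previous frame while the static pose stays Standing-like.
#' * **Standing** — upright pose outside the lying zone, drifting less than
#'   half the margin per second so the displacement rule cannot fire.
#'
#' Gaussian jitter and whole-frame occlusion are applied after the
#' geometry, so noise-free output is classified perfectly by construction.
#'
#' @param sequence Output of [simulate_behavior_sequence()].
#' @param config The same [sim_config()].
#' @param rules A [rule_config()]; the generator places keypoints relative
#'   to these thresholds so generator and classifier agree on the geometry.
#' @return A list of class `sim_track` with elements `track` (a
#'   [pose_track()]) and `truth` (an [annotation_series()] of ground-truth
#'   behaviors).
#' @export
realize_keypoints <- function(sequence, config, rules = rule_config()) {
  stopifnot(inherits(config, "sim_config"))
  m <- config$margin_px
  L <- config$body_length_px
  z <- config$lying_zone
  if (m <= config$jitter_px) {
    warning("margin_px <= jitter_px: classification rules may flip under ",
            "coordinate noise", call. = FALSE)
  }
  # standing plane sits 2 margins below the zone so the lying <-> standing
  # step (3 margins) stays safely under the locomotion threshold
  if (3 * m > rules$locomotion_fraction * L - m) {
    warning("margin_px too large relative to body length: lying-standing ",
            "transitions may trigger the displacement rule", call. = FALSE)
  }
  ty <- z$y_max + 2 * m             # terrestrial shoulder/hip y
  ly <- z$y_max - m                 # lying shoulder/hip y (inside zone)
  if (ly <= z$y_min) stop("lying zone too shallow for margin_px",
                          call. = FALSE)
  x_lo <- L + m
  x_hi <- config$frame_width - m
  lx_lo <- z$x_min + m + L          # keeps hip = shoulder - L inside too
  lx_hi <- z$x_max - m
  if (lx_lo >= lx_hi) stop("lying zone too narrow for body_length_px",
                           call. = FALSE)

  n <- nrow(sequence)
  beh <- sequence$behavior
  sx <- numeric(n); sy <- numeric(n)
  cur_x <- (x_lo + x_hi) / 2
  dir <- 1
  for (t in seq_len(n)) {
    b <- beh[t]
    if (b == "Lying Down") {
      cur_x <- min(max(cur_x, lx_lo), lx_hi)
      sx[t] <- cur_x; sy[t] <- ly
    } else if (b == "Locomotion") {
      step <- 0.75 * L
      if (cur_x + dir * step < x_lo || cur_x + dir * step > x_hi) dir <- -dir
      cur_x <- cur_x + dir * step
      sx[t] <- cur_x; sy[t] <- ty
    } else {
      if (t > 1L && beh[t - 1L] != "Lying Down") {
        drift <- m / 2
        if (cur_x + dir * drift < x_lo || cur_x + dir * drift > x_hi) {
          dir <- -dir
        }
        cur_x <- cur_x + dir * drift
      }
      sx[t] <- cur_x; sy[t] <- ty
    }
  }
  hx <- sx - L; hy <- sy            # rigid horizontal body: hip trails
  forag <- beh == "Foraging/Feeding"
  head_x <- sx + 0.1 * L
  head_y <- ifelse(forag, sy + rules$head_drop_px + m, sy - m)
  nose_x <- sx + 0.2 * L
  nose_y <- ifelse(forag, sy + rules$nose_drop_px + m, sy - m)

  one <- rep(1, n)
  frames <- data.frame(frame = sequence$second, time_s = sequence$second,
                       nose_x = nose_x, nose_y = nose_y,
                       head_x = head_x, head_y = head_y,
                       shoulder_x = sx, shoulder_y = sy,
                       hip_x = hx, hip_y = hy,
                       nose_score = one, head_score = one,
                       shoulder_score = one, hip_score = one)
  frames <- with_seed(config$seed + 1L, {
    if (config$jitter_px > 0 && n > 0) {
      coord_cols <- c("nose_x", "nose_y", "head_x", "head_y",
                      "shoulder_x", "shoulder_y", "hip_x", "hip_y")
      for (cc in coord_cols) {
        frames[[cc]] <- frames[[cc]] +
          stats::rnorm(n, 0, config$jitter_px)
      }
    }
    if (config$miss_prob > 0 && n > 0) {
      gone <- stats::runif(n) < config$miss_prob
      frames[gone, 3:14] <- NA_real_
    }
    frames
  })
  truth <- annotation_series("sim", sequence$second, beh,
                             categories = config$behaviors)
  structure(list(track = pose_track("sim", frames), truth = truth),
            class = "sim_track")
}

#' Simulate an imperfect manual observer
#'
#' Degrades a ground-truth annotation series the way a human coder might:
#' each second is independently replaced by a uniformly random *different*
#' category with probability `error_rate`, or by the out-of-sight label
#' with probability `out_of_sight_rate`.
#'
#' @param truth An [annotation_series()].
#' @param error_rate,out_of_sight_rate Probabilities in `[0, 1]`; their sum
#'   must not exceed 1.
#' @param seed Integer seed.
#' @param categories Category set to draw confusions from; defaults to the
#'   truth's declared categories.
#' @param oos_label Label used for invisible seconds.
#' @return An [annotation_series()] of the same length.
#' @export
simulate_observer <- function(truth, error_rate, out_of_sight_rate = 0,
                              seed = 1L,
                              categories = attr(truth, "categories"),
                              oos_label = "Out of Sight") {
  stopifnot_scalar_number(error_rate, "error_rate", 0, 1)
  stopifnot_scalar_number(out_of_sight_rate, "out_of_sight_rate", 0, 1)
  if (error_rate + out_of_sight_rate > 1) {
    stop("error_rate + out_of_sight_rate must not exceed 1", call. = FALSE)
  }
  n <- nrow(truth)
  lab <- truth$behavior
  lab <- with_seed(seed, {
    u <- stats::runif(n)
    flip <- u < error_rate
    oos <- !flip & u < error_rate + out_of_sight_rate
    for (i in which(flip)) {
      others <- setdiff(categories, lab[i])
      if (length(others)) lab[i] <- others[sample.int(length(others), 1L)]
    }
    lab[oos] <- oos_label
    lab
  })
  annotation_series(truth$individual[1L] %||% "sim", truth$time_s, lab,
                    categories = union(categories, oos_label))
}

#' Simulate daily behavior-proportion tables for a two-period study
#'
#' Draws each observation day's time-budget proportions from the
#' individual- and period-specific Dirichlet distributions in the config.
#' Days are exchangeable within an individual-period cell.
#'
#' @param config A [study_sim_config()].
#' @return A daily table: data frame with columns `individual`, `period`
#'   (`control`/`test`), `day`, `category`, `proportion`; proportions sum
#'   to 1 within each individual-period-day.
#' @examples
#' tab <- simulate_study_table(study_sim_config(n_days_per_period = 2))
#' head(tab)
#' @export
simulate_study_table <- function(config) {
  stopifnot(inherits(config, "study_sim_config"))
  k <- length(config$categories)
  nd <- config$n_days_per_period
  with_seed(config$seed, {
    rows <- lapply(config$individuals, function(ind) {
      lapply(c("control", "test"), function(per) {
        alpha <- config$concentrations[[ind]][[per]]
        g <- matrix(stats::rgamma(nd * k, shape = rep(alpha, each = nd)),
                    nrow = nd)
        p <- g / rowSums(g)
        data.frame(individual = ind, period = per,
                   day = rep(seq_len(nd), k),
                   category = rep(config$categories, each = nd),
                   proportion = as.vector(p), stringsAsFactors = FALSE)
      })
    })
    out <- do.call(rbind, unlist(rows, recursive = FALSE))
    rownames(out) <- NULL
    out
  })
}

#' Simulate enclosure tracking points from a Gaussian mixture
#'
#' Emulates interval-sampled position fixes on an enclosure blueprint: each
#' point picks a mixture component by weight, then draws an axis-aligned
#' Gaussian position around the component center. Points are clipped to
#' the blueprint bounds.
#'
#' @param n_points Number of points to draw.
#' @param components Data frame with columns `weight`, `x`, `y`, `sd`
#'   (or `sdx`/`sdy` for anisotropic spread); weights must sum to 1.
#' @param seed Integer seed.
#' @param width,height Blueprint size in pixels.
#' @param individual,period Metadata copied onto every row.
#' @param interval_s Nominal sampling interval used to assign `time_s`.
#' @return Data frame `individual`, `period`, `time_s`, `x`, `y`,
#'   `component`.
#' @export
simulate_tracking_points <- function(n_points, components, seed = 1L,
                                     width = 1920, height = 1080,
                                     individual = "sim",
                                     period = "control", interval_s = 15) {
  stopifnot_scalar_number(n_points, "n_points", lower = 0)
  components <- as.data.frame(components)
  if (is.null(components$sdx)) components$sdx <- components$sd
  if (is.null(components$sdy)) components$sdy <- components$sd
  if (abs(sum(components$weight) - 1) > 1e-9) {
    stop("component weights must sum to 1", call. = FALSE)
  }
  n_points <- as.integer(n_points)
  with_seed(seed, {
    comp <- if (n_points > 0) {
      sample.int(nrow(components), n_points, replace = TRUE,
                 prob = components$weight)
    } else integer(0)
    x <- stats::rnorm(n_points, components$x[comp], components$sdx[comp])
    y <- stats::rnorm(n_points, components$y[comp], components$sdy[comp])
    data.frame(individual = rep_len(individual, n_points),
               period = rep_len(period, n_points),
               time_s = as.integer(interval_s) * (seq_len(n_points) - 1L),
               x = pmin(pmax(x, 0), width),
               y = pmin(pmax(y, 0), height),
               component = comp, stringsAsFactors = FALSE)
  })
}
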