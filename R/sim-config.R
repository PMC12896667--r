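#' Configuration for the synthetic pose-track generator
#'
#' Bundles everything [simulate_behavior_sequence()] and
#' [realize_keypoints()] need: the behavior repertoire, a semi-Markov model
#' of how behaviors follow each other, the camera frame, the lying-area
#' rectangle, body size, and the two noise knobs (coordinate jitter and
#' whole-frame occlusion).
#'
#' Dwell times are geometric per behavior: each second the animal stays in
#' its current behavior with probability `1 - 1/mean_dwell_s[b]`, otherwise
#' it jumps according to the corresponding row of `transition_matrix`. With
#' a zero-diagonal jump matrix (the default) the realized mean dwell equals
#' `mean_dwell_s[b]` exactly; self-mass in a row simply lengthens dwells.
#'
#' @param duration_s Length of the simulated observation, in seconds.
#' @param behaviors Ordered behavior names; must contain at least the four
#'   terrestrial categories. The first behavior is the start state.
#' @param transition_matrix Row-stochastic jump matrix over `behaviors`
#'   (rows sum to 1 within 1e-9). Default: uniform over the other
#'   behaviors, zero diagonal.
#' @param mean_dwell_s Named positive vector of mean dwell times (seconds);
#'   values below 1 are not representable at 1 fps.
#' @param jitter_px Standard deviation of isotropic Gaussian noise added to
#'   every emitted coordinate, in pixels.
#' @param miss_prob Probability that a frame's keypoints are all dropped
#'   (occlusion), in `[0, 1]`.
#' @param lying_zone Rectangle `list(x_min, x_max, y_min, y_max)` in pixels
#'   marking the resting area on the image; image convention is y-down.
#' @param body_length_px Hip-to-shoulder distance of the simulated animal.
#' @param margin_px Geometric safety margin: generated frames satisfy their
#'   own behavior's classification rule, and violate the others, by at
#'   least this many pixels.
#' @param frame_width,frame_height Camera frame size in pixels.
#' @param seed Integer seed; all generator randomness derives from it.
#' @return A list of class `sim_config`.
#' @examples
#' cfg <- sim_config(duration_s = 600, seed = 42)
#' seqs <- simulate_behavior_sequence(cfg)
#' table(seqs$behavior)
#' @export
sim_config <- function(duration_s = 3600,
                       behaviors = terrestrial_behaviors(),
                       transition_matrix = NULL,
                       mean_dwell_s = c("Standing" = 20, "Lying Down" = 60,
                                        "Foraging/Feeding" = 30,
                                        "Locomotion" = 5),
                       jitter_px = 0,
                       miss_prob = 0,
                       lying_zone = list(x_min = 1080, x_max = 1720,
                                         y_min = 270, y_max = 400),
                       body_length_px = 200,
                       margin_px = 25,
                       frame_width = 1920,
                       frame_height = 1080,
                       seed = 1L) {
  stopifnot_scalar_number(duration_s, "duration_s", lower = 0)
  if (!all(terrestrial_behaviors() %in% behaviors)) {
    stop("`behaviors` must contain at least: ",
         paste(terrestrial_behaviors(), collapse = ", "), call. = FALSE)
  }
  k <- length(behaviors)
  if (is.null(transition_matrix)) {
    transition_matrix <- matrix(1 / (k - 1), k, k,
                                dimnames = list(behaviors, behaviors))
    diag(transition_matrix) <- 0
  }
  transition_matrix <- as.matrix(transition_matrix)
  if (!all(dim(transition_matrix) == k)) {
    stop("`transition_matrix` must be ", k, "x", k, call. = FALSE)
  }
  if (any(transition_matrix < 0) ||
      any(abs(rowSums(transition_matrix) - 1) > 1e-9)) {
    stop("invalid config: `transition_matrix` must be row-stochastic ",
         "(non-negative rows summing to 1 within 1e-9)", call. = FALSE)
  }
  dimnames(transition_matrix) <- list(behaviors, behaviors)
  if (is.null(names(mean_dwell_s))) names(mean_dwell_s) <- behaviors
  mean_dwell_s <- mean_dwell_s[behaviors]
  if (anyNA(mean_dwell_s) || any(mean_dwell_s < 1)) {
    stop("`mean_dwell_s` must give a value >= 1 for every behavior",
         call. = FALSE)
  }
  stopifnot_scalar_number(jitter_px, "jitter_px", lower = 0)
  stopifnot_scalar_number(miss_prob, "miss_prob", lower = 0, upper = 1)
  z <- lying_zone
  if (!(z$x_min < z$x_max && z$y_min < z$y_max)) {
    stop("`lying_zone` must satisfy x_min < x_max and y_min < y_max",
         call. = FALSE)
  }
  stopifnot_scalar_number(body_length_px, "body_length_px", lower = 1)
  stopifnot_scalar_number(margin_px, "margin_px", lower = 0)
  structure(list(duration_s = as.integer(duration_s), behaviors = behaviors,
                 transition_matrix = transition_matrix,
                 mean_dwell_s = mean_dwell_s, jitter_px = jitter_px,
                 miss_prob = miss_prob, lying_zone = z,
                 body_length_px = body_length_px, margin_px = margin_px,
                 frame_width = frame_width, frame_height = frame_height,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Configuration for a simulated two-period enrichment study
#'
#' Describes a multi-individual study with a `control` and a `test` period
#' and a fixed number of observation days per period. Each individual's
#' daily behavior proportions are drawn from a period-specific Dirichlet
#' distribution, so an enrichment effect is expressed as a shift of
#' concentration mass between categories (e.g., onto Scenting in the test
#' period).
#'
#' @param individuals Character vector of individual names.
#' @param n_days_per_period Number of observation days in each period.
#' @param categories Ethogram category names (configurable; the default is
#'   a generic captive-ungulate repertoire).
#' @param concentrations Optional named list: one entry per individual,
#'   each a `list(control =, test =)` of strictly positive concentration
#'   vectors over `categories`. Defaults to the same baseline vector
#'   everywhere (no effect).
#' @param scent_effect Convenience knob: added to the Scenting (last-named
#'   matching category) concentration in every individual's test period.
#'   `0` means no between-period effect.
#' @param seed Integer seed.
#' @return A list of class `study_sim_config`.
#' @export
study_sim_config <- function(individuals = c("male", "female", "calf"),
                             n_days_per_period = 8,
                             categories = c("Inactive", "Activity in Water",
                                            "Foraging", "Locomotion",
                                            "Scenting", "Other"),
                             concentrations = NULL,
                             scent_effect = 0,
                             seed = 1L) {
  stopifnot_scalar_number(n_days_per_period, "n_days_per_period", lower = 1)
  stopifnot_scalar_number(scent_effect, "scent_effect", lower = 0)
  k <- length(categories)
  if (is.null(concentrations)) {
    base <- c(6, 4, 5, 2, 0.5, 2.5)
    base <- if (k == 6L) base else rep(20 / k, k)
    names(base) <- categories
    concentrations <- stats::setNames(lapply(individuals, function(i) {
      test <- base
      if (scent_effect > 0) {
        sc <- if ("Scenting" %in% categories) "Scenting" else categories[k]
        test[sc] <- test[sc] + scent_effect
      }
      list(control = base, test = test)
    }), individuals)
  }
  for (i in individuals) {
    for (p in c("control", "test")) {
      a <- concentrations[[i]][[p]]
      if (is.null(a) || length(a) != k || any(a <= 0)) {
        stop("concentrations must be strictly positive vectors over all ",
             "categories, for both periods, for every individual",
             call. = FALSE)
      }
    }
  }
  structure(list(individuals = individuals,
                 n_days_per_period = as.integer(n_days_per_period),
                 categories = categories, concentrations = concentrations,
                 seed = as.integer(seed)),
            class = "study_sim_config")
}
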