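#' Geometric classification rules
#'
#' Thresholds for the rule-based behavior classifier, in image pixels with
#' the y-down convention (origin top-left, so "below" means larger y):
#'
#' * **Foraging/Feeding** fires when the head is at least `head_drop_px`
#'   below the shoulder, or the nose at least `nose_drop_px` below the
#'   shoulder ("at least" is inclusive, `>=`).
#' * **Lying Down** fires when the hip or the shoulder lies inside
#'   `lying_zone` (closed boundaries).
#' * **Locomotion** fires when a second statically classified as Standing
#'   displaces its hip and shoulder by more than `locomotion_fraction`
#'   body lengths between consecutive seconds ("exceeded" is strict, `>`).
#' * **Standing** is the default when no other rule qualifies.
#'
#' @param head_drop_px,nose_drop_px Head/nose drop thresholds below the
#'   shoulder, pixels.
#' @param locomotion_fraction Displacement threshold as a fraction of body
#'   length (hip-to-shoulder distance).
#' @param lying_zone Rectangle `list(x_min, x_max, y_min, y_max)`, pixels.
#' @param displacement How hip and shoulder displacement are combined for
#'   the locomotion rule: arithmetic `"mean"` (default), `"max"`, or
#'   `"both"` (each keypoint must exceed the threshold on its own).
#' @return A list of class `rule_config`.
#' @export
rule_config <- function(head_drop_px = 60, nose_drop_px = 90,
                        locomotion_fraction = 0.5,
                        lying_zone = list(x_min = 1080, x_max = 1720,
                                          y_min = 270, y_max = 400),
                        displacement = c("mean", "max", "both")) {
  stopifnot_scalar_number(head_drop_px, "head_drop_px", lower = 1e-9)
  stopifnot_scalar_number(nose_drop_px, "nose_drop_px", lower = 1e-9)
  stopifnot_scalar_number(locomotion_fraction, "locomotion_fraction",
                          lower = 1e-9)
  z <- lying_zone
  if (!(z$x_min < z$x_max && z$y_min < z$y_max)) {
    stop("`lying_zone` must satisfy x_min < x_max and y_min < y_max",
         call. = FALSE)
  }
  structure(list(head_drop_px = head_drop_px, nose_drop_px = nose_drop_px,
                 locomotion_fraction = locomotion_fraction, lying_zone = z,
                 displacement = match.arg(displacement)),
            class = "rule_config")
}

#' Read/write a rule configuration as YAML
#' @param path File path.
#' @param config A [rule_config()].
#' @return `read_rule_yaml()` returns a [rule_config()].
#' @export
read_rule_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(rule_config, y)
}

#' @rdname read_rule_yaml
#' @export
write_rule_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Body length of a pose frame
#'
#' Euclidean hip-to-shoulder distance, the animal's size reference for the
#' locomotion displacement rule.
#'
#' @param frame One-row data frame (or list) with `shoulder_x`,
#'   `shoulder_y`, `hip_x`, `hip_y`.
#' @return Length in pixels; `NA` when either keypoint is missing
#'   (undefined length).
#' @examples
#' body_length(list(shoulder_x = 0, shoulder_y = 0, hip_x = 3, hip_y = 4))
#' @export
body_length <- function(frame) {
  dx <- frame$hip_x - frame$shoulder_x
  dy <- frame$hip_y - frame$shoulder_y
  unname(sqrt(dx^2 + dy^2))
}

# vectorized static rules over a wide frames data.frame; returns labels
classify_static_frames <- function(f, config) {
  z <- config$lying_zone
  n <- nrow(f)
  in_zone <- function(x, y) {
    !is.na(x) & !is.na(y) &
      x >= z$x_min & x <= z$x_max & y >= z$y_min & y <= z$y_max
  }
  has_anchor <- (!is.na(f$hip_x) & !is.na(f$hip_y)) |
    (!is.na(f$shoulder_x) & !is.na(f$shoulder_y))
  lying <- in_zone(f$hip_x, f$hip_y) | in_zone(f$shoulder_x, f$shoulder_y)
  head_drop <- f$head_y - f$shoulder_y
  nose_drop <- f$nose_y - f$shoulder_y
  foraging <- (!is.na(head_drop) & head_drop >= config$head_drop_px) |
    (!is.na(nose_drop) & nose_drop >= config$nose_drop_px)
  out <- rep("Standing", n)
  out[foraging] <- "Foraging/Feeding"
  out[lying] <- "Lying Down"          # zone membership outranks head drop
  out[!has_anchor] <- "Not Labeled"
  out
}

#' Classify a single frame from static geometry
#'
#' Applies the positional rules (not the displacement rule, which needs
#' two consecutive frames — see [apply_locomotion()]). Rule precedence:
#' a frame with no usable anchor keypoint (hip and shoulder both missing)
#' is **Not Labeled**; otherwise **Lying Down** when hip or shoulder falls
#' inside the lying zone; otherwise **Foraging/Feeding** when the head or
#' nose drop fires; otherwise **Standing**. A missing head and nose simply
#' prevent the foraging rule from firing rather than voiding the frame.
#'
#' @param frame One-row data frame or list with `<node>_x`/`<node>_y`
#'   entries (missing nodes `NA`).
#' @param config A [rule_config()].
#' @return One of `"Standing"`, `"Lying Down"`, `"Foraging/Feeding"`,
#'   `"Not Labeled"`.
#' @examples
#' classify_static(list(shoulder_x = 500, shoulder_y = 300,
#'                      head_x = 500, head_y = 370,
#'                      hip_x = 600, hip_y = 300,
#'                      nose_x = NA, nose_y = NA),
#'                 rule_config())
#' @export
classify_static <- function(frame, config = rule_config()) {
  f <- as.data.frame(lapply(frame, function(v) {
    if (is.null(v)) NA_real_ else as.numeric(v)[1L]
  }))
  for (col in paste0(rep(POSE_NODES, each = 2), c("_x", "_y"))) {
    if (is.null(f[[col]])) f[[col]] <- NA_real_
  }
  classify_static_frames(f, config)
}

#' Relabel Standing seconds as Locomotion from frame-to-frame displacement
#'
#' A second becomes Locomotion when (a) its static label is Standing, (b)
#' hip and shoulder are present in both it and the immediately preceding
#' second, and (c) the combined hip/shoulder displacement between the two
#' frames exceeds `locomotion_fraction` times the current frame's body
#' length (strictly). The first observed second can never be Locomotion,
#' and a zero body length never fires the rule.
#'
#' @param static_labels Character vector from [classify_static()] /
#'   [classify_static_frames], one per frame of `track`.
#' @param track The [pose_track()] the labels came from (1 fps).
#' @param config A [rule_config()].
#' @return An [annotation_series()] over the five automated categories.
#' @export
apply_locomotion <- function(static_labels, track,
                             config = rule_config()) {
  f <- track$frames
  n <- nrow(f)
  stopifnot(length(static_labels) == n)
  labels <- static_labels
  if (n > 1L) {
    i <- 2:n
    consec <- (f$time_s[i] - f$time_s[i - 1L]) == 1
    have <- !is.na(f$hip_x[i]) & !is.na(f$shoulder_x[i]) &
      !is.na(f$hip_x[i - 1L]) & !is.na(f$shoulder_x[i - 1L])
    dh <- sqrt((f$hip_x[i] - f$hip_x[i - 1L])^2 +
                 (f$hip_y[i] - f$hip_y[i - 1L])^2)
    ds <- sqrt((f$shoulder_x[i] - f$shoulder_x[i - 1L])^2 +
                 (f$shoulder_y[i] - f$shoulder_y[i - 1L])^2)
    disp <- switch(config$displacement,
                   mean = (dh + ds) / 2,
                   max = pmax(dh, ds),
                   both = pmin(dh, ds))
    bl <- body_length(f[i, , drop = FALSE])
    fire <- labels[i] == "Standing" & consec & have &
      !is.na(disp) & !is.na(bl) & bl > 0 &
      disp > config$locomotion_fraction * bl
    labels[i][fire] <- "Locomotion"
  }
  annotation_series(track$individual, f$time_s, labels,
                    categories = automated_categories())
}

#' Classify every second of a pose track
#'
#' Composition of the static rules and the displacement rule: every second
#' of the (1 fps) track receives exactly one of the five automated
#' categories.
#'
#' @param track A [pose_track()] down-sampled to 1 fps.
#' @param config A [rule_config()].
#' @return An [annotation_series()] with one label per track frame.
#' @examples
#' cfg <- sim_config(duration_s = 30, seed = 3)
#' sim <- realize_keypoints(simulate_behavior_sequence(cfg), cfg)
#' pred <- classify_track(sim$track)
#' mean(pred$behavior == sim$truth$behavior)  # 1 when noise-free
#' @export
classify_track <- function(track, config = rule_config()) {
  stopifnot(inherits(track, "pose_track"))
  if (nrow(track$frames) == 0L) {
    return(annotation_series(track$individual, integer(0), character(0),
                             categories = automated_categories()))
  }
  static <- classify_static_frames(track$frames, config)
  apply_locomotion(static, track, config)
}
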