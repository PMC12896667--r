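POSE_NODES <- c("nose", "head", "shoulder", "hip")

#' Keypoint track for one individual
#'
#' A pose track stores one row per frame with pixel coordinates for the
#' four tracked body points (nose, head, shoulder, hip) and their detection
#' scores. Missing detections are `NA`. Image convention is y-down:
#' larger y means lower in the frame.
#'
#' @param individual Name of the tracked individual.
#' @param frames Data frame with columns `frame`, `time_s` and, for each
#'   node, `<node>_x`, `<node>_y`, `<node>_score` (score optional,
#'   defaults to `NA`). `time_s` must be strictly increasing.
#' @return A list of class `pose_track` with elements `individual` and
#'   `frames`.
#' @export
pose_track <- function(individual, frames) {
  frames <- as.data.frame(frames)
  for (nd in POSE_NODES) {
    for (suf in c("_x", "_y")) {
      col <- paste0(nd, suf)
      if (is.null(frames[[col]])) frames[[col]] <- NA_real_
    }
    sc <- paste0(nd, "_score")
    if (is.null(frames[[sc]])) frames[[sc]] <- NA_real_
  }
  if (is.null(frames$frame)) frames$frame <- frames$time_s
  if (nrow(frames) > 1L && any(diff(frames$time_s) <= 0)) {
    stop("format error: time_s must be strictly increasing", call. = FALSE)
  }
  coord <- unlist(frames[paste0(rep(POSE_NODES, each = 2),
                                c("_x", "_y"))], use.names = FALSE)
  if (any(is.infinite(coord))) {
    stop("format error: coordinates must be finite when present",
         call. = FALSE)
  }
  structure(list(individual = as.character(individual), frames = frames),
            class = "pose_track")
}

#' @export
print.pose_track <- function(x, ...) {
  cat("<pose_track> individual:", x$individual, "-", nrow(x$frames),
      "frames\n")
  invisible(x)
}

#' Read and write pose-track CSV files
#'
#' The on-disk dialect is long-format CSV with a header and columns
#' `individual, frame, time_s, node, x, y, score` (UTF-8), one row per
#' detected-or-missing keypoint, as exported from pose-estimation
#' software. Missing nodes may be absent rows or rows with empty `x`/`y`;
#' both read back as `NA`.
#'
#' @param path File path.
#' @return `read_pose_csv()` returns a list of [pose_track()], one per
#'   individual; `write_pose_csv()` returns `path` invisibly.
#' @export
read_pose_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("individual", "frame", "time_s", "node", "x", "y")
  if (!all(need %in% names(df))) {
    stop("format error: pose CSV needs columns ",
         paste(c(need, "score"), collapse = ", "), call. = FALSE)
  }
  if (is.null(df$score)) df$score <- NA_real_
  if (nrow(df) == 0L) return(list())
  bad <- which(!df$node %in% POSE_NODES)
  if (length(bad)) {
    stop("format error: unknown node '", df$node[bad[1L]], "' at row ",
         bad[1L], call. = FALSE)
  }
  lapply(split(df, df$individual), function(d) {
    d <- d[order(d$frame), ]
    by_frame <- split(d, d$frame)
    times <- vapply(by_frame, function(f) f$time_s[1L], numeric(1))
    if (length(times) > 1L && any(diff(times) <= 0)) {
      stop("format error: non-monotone time_s for individual '",
           d$individual[1L], "'", call. = FALSE)
    }
    frames <- data.frame(frame = as.numeric(names(by_frame)),
                         time_s = times)
    for (nd in POSE_NODES) {
      frames[[paste0(nd, "_x")]] <- vapply(by_frame, function(f) {
        v <- f$x[f$node == nd]; if (length(v)) v[1L] else NA_real_
      }, numeric(1))
      frames[[paste0(nd, "_y")]] <- vapply(by_frame, function(f) {
        v <- f$y[f$node == nd]; if (length(v)) v[1L] else NA_real_
      }, numeric(1))
      frames[[paste0(nd, "_score")]] <- vapply(by_frame, function(f) {
        v <- f$score[f$node == nd]; if (length(v)) v[1L] else NA_real_
      }, numeric(1))
    }
    rownames(frames) <- NULL
    pose_track(d$individual[1L], frames)
  })
}

#' @param tracks A [pose_track()] or list of them.
#' @rdname read_pose_csv
#' @export
write_pose_csv <- function(tracks, path) {
  if (inherits(tracks, "pose_track")) tracks <- list(tracks)
  rows <- lapply(tracks, function(tr) {
    f <- tr$frames
    do.call(rbind, lapply(POSE_NODES, function(nd) {
      data.frame(individual = rep_len(tr$individual, nrow(f)),
                 frame = f$frame,
                 time_s = f$time_s, node = rep_len(nd, nrow(f)),
                 x = f[[paste0(nd, "_x")]], y = f[[paste0(nd, "_y")]],
                 score = f[[paste0(nd, "_score")]],
                 stringsAsFactors = FALSE)
    }))
  })
  df <- do.call(rbind, rows)
  df <- df[order(df$individual, df$frame, match(df$node, POSE_NODES)), ]
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Down-sample a pose track to a lower frame rate
#'
#' Keeps the first frame of each output-rate bin (a per-second snapshot,
#' matching manual coding semantics) rather than averaging poses. After
#' down-sampling, `time_s` is reassigned as whole seconds from the start
#' of the track.
#'
#' @param track A [pose_track()].
#' @param from_fps,to_fps Input and output frame rates; `from_fps` must be
#'   an integer multiple of `to_fps`.
#' @return A [pose_track()] with `ceiling(n * to_fps / from_fps)` frames.
#' @examples
#' fr <- data.frame(frame = 0:89, time_s = (0:89) / 30,
#'                  shoulder_x = 1, shoulder_y = 1)
#' downsample(pose_track("a", fr), 30, 1)$frames$frame  # 0, 30, 60
#' @export
downsample <- function(track, from_fps, to_fps) {
  stopifnot(inherits(track, "pose_track"))
  if (from_fps %% to_fps != 0) {
    stop("unsupported rate: from_fps must be divisible by to_fps",
         call. = FALSE)
  }
  step <- from_fps / to_fps
  n <- nrow(track$frames)
  keep <- seq.int(1L, n, by = step)
  frames <- track$frames[keep, , drop = FALSE]
  # elapsed time from the track start; whole seconds once at 1 fps
  tt <- (seq_along(keep) - 1) / to_fps
  frames$time_s <- if (to_fps == 1) as.integer(tt) else tt
  rownames(frames) <- NULL
  pose_track(track$individual, frames)
}

# mean distance between two tracks' common keypoints over co-visible
# seconds; NA when the tracks never co-occur
track_distance <- function(a, b) {
  fa <- a$frames; fb <- b$frames
  common <- intersect(fa$time_s, fb$time_s)
  if (!length(common)) return(NA_real_)
  ia <- match(common, fa$time_s); ib <- match(common, fb$time_s)
  d <- numeric(0)
  for (nd in POSE_NODES) {
    dx <- fa[[paste0(nd, "_x")]][ia] - fb[[paste0(nd, "_x")]][ib]
    dy <- fa[[paste0(nd, "_y")]][ia] - fb[[paste0(nd, "_y")]][ib]
    d <- c(d, sqrt(dx^2 + dy^2))
  }
  if (all(is.na(d))) return(NA_real_)
  mean(d, na.rm = TRUE)
}

track_mean_score <- function(tr) {
  s <- unlist(tr$frames[paste0(POSE_NODES, "_score")], use.names = FALSE)
  if (all(is.na(s))) -Inf else mean(s, na.rm = TRUE)
}

#' Remove duplicate pose tracks
#'
#' Multi-animal trackers occasionally assign two track identities to the
#' same animal. Two tracks are considered duplicates when their mean
#' keypoint distance over co-visible seconds falls below
#' `overlap_threshold_px`; the one with the lower mean detection score
#' (or, on a tie, the shorter duration) is dropped. Tracks that never
#' co-occur are always kept. The operation is idempotent.
#'
#' @param tracks List of [pose_track()] sharing a time base.
#' @param overlap_threshold_px Mean-distance threshold in pixels.
#' @return Filtered list of tracks, in the original order.
#' @export
dedupe_tracks <- function(tracks, overlap_threshold_px) {
  keep <- rep(TRUE, length(tracks))
  repeat {
    dropped <- FALSE
    idx <- which(keep)
    if (length(idx) < 2L) break
    for (i in idx) {
      for (j in idx[idx > i]) {
        if (!keep[i] || !keep[j]) next
        d <- track_distance(tracks[[i]], tracks[[j]])
        if (!is.na(d) && d < overlap_threshold_px) {
          si <- track_mean_score(tracks[[i]])
          sj <- track_mean_score(tracks[[j]])
          loser <- if (si < sj) {
            i
          } else if (sj < si) {
            j
          } else if (nrow(tracks[[i]]$frames) < nrow(tracks[[j]]$frames)) {
            i
          } else {
            j
          }
          keep[loser] <- FALSE
          dropped <- TRUE
        }
      }
    }
    if (!dropped) break
  }
  tracks[keep]
}

#' Read and write tracking-point CSV files
#'
#' Tracking points (interval-sampled blueprint positions) are exchanged as
#' CSV with columns `individual, period, time_s, x, y`.
#'
#' @param path File path.
#' @param points Data frame of tracking points.
#' @return `read_tracking_csv()` returns the data frame;
#'   `write_tracking_csv()` returns `path` invisibly.
#' @export
read_tracking_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("individual", "period", "time_s", "x", "y")
  if (!all(need %in% names(df))) {
    stop("tracking CSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_tracking_csv
#' @export
write_tracking_csv <- function(points, path) {
  cols <- intersect(c("individual", "period", "time_s", "x", "y"),
                    names(points))
  utils::write.csv(points[cols], path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
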