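#' Behavior category sets
#'
#' The automated classifier emits five categories: the four terrestrial
#' behaviors plus `"Not Labeled"` for seconds where the required keypoints
#' are missing. Manual ethograms use the same four terrestrial behaviors
#' plus `"Out of Sight"` (also written "Out of View") for seconds where the
#' animal is invisible to the observer.
#'
#' @return Character vector of category names.
#' @export
automated_categories <- function() {
  c("Standing", "Lying Down", "Foraging/Feeding", "Locomotion", "Not Labeled")
}

#' @rdname automated_categories
#' @export
terrestrial_behaviors <- function() {
  c("Standing", "Lying Down", "Foraging/Feeding", "Locomotion")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG stream is untouched. All exported generators go through this
# so results are bit-reproducible given (seed, config) alone.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# 32-bit FNV-1a over a string; used for the pipeline manifest so a run can
# be matched to its configuration without an external hashing package.
fnv1a32 <- function(x) {
  bytes <- utf8ToInt(enc2utf8(x))
  h <- 2166136261
  for (b in bytes) {
    # XOR only touches the low byte (b < 256); keep h as a double since
    # it exceeds R's 32-bit signed integer range
    lo <- h %% 256
    h <- h - lo + bitwXor(as.integer(lo), as.integer(b))
    # 32-bit modular multiply by the FNV prime 16777619
    h <- (h * 16777619) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
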