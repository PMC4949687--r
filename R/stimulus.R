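#' Word display-duration schedule for a comprehension block
#'
#' Assigns per-word display durations as a piecewise-linear function of
#' rendered word width. Words no wider than `clamp_fraction` of the mean
#' width receive the clamped minimum duration,
#' `clamp_fraction * block_s / n` (175 ms for the study's 64-word, 16 s
#' blocks, i.e. 70% of the 250 ms average word duration); wider words
#' receive linearly increasing durations with the slope solved in closed
#' form so the total paragraph duration equals the block length.
#'
#' @param widths positive rendered word widths (arbitrary units).
#' @param block_s block length in seconds (default 16).
#' @param clamp_fraction minimum duration as a fraction of the average
#'   word duration (default 0.70).
#' @return data frame with columns `width`, `duration_s` and
#'   `duration_ms` (rounded to the millisecond); attributes `clamp_s`
#'   and `slope`.
#' @export
schedule_word_durations <- function(widths, block_s = 16,
                                    clamp_fraction = 0.70) {
  widths <- as.numeric(widths)
  if (length(widths) < 1L || any(!is.finite(widths)) || any(widths <= 0)) {
    stop("`widths` must be positive and non-empty")
  }
  if (block_s <= 0) stop("`block_s` must be positive")
  if (clamp_fraction <= 0 || clamp_fraction >= 1) {
    stop("`clamp_fraction` must lie in (0, 1)")
  }
  n <- length(widths)
  clamp_s <- clamp_fraction * block_s / n
  w_cut <- clamp_fraction * mean(widths)
  wide <- widths > w_cut
  excess <- sum(widths[wide] - w_cut)
  if (excess <= 0) {
    stop("no word is wider than the clamp cutoff; slope is undefined")
  }
  slope <- (block_s - n * clamp_s) / excess
  dur <- rep(clamp_s, n)
  dur[wide] <- clamp_s + slope * (widths[wide] - w_cut)
  out <- data.frame(width = widths, duration_s = dur,
                    duration_ms = round(1000 * dur))
  attr(out, "clamp_s") <- clamp_s
  attr(out, "slope") <- slope
  out
}

#' Balanced random block order
#'
#' Random order of condition blocks for one run, balanced so every
#' condition appears equally often (the study design: 32 blocks of 4
#' conditions, 8 each); deterministic for a fixed seed.
#'
#' @param n_blocks total number of blocks; must be divisible by the
#'   number of conditions.
#' @param conditions character vector of condition names.
#' @param seed RNG seed.
#' @return character vector of length `n_blocks`.
#' @export
generate_block_order <- function(n_blocks, conditions, seed) {
  n_blocks <- as.integer(n_blocks)
  k <- length(conditions)
  if (k < 1L || n_blocks %% k != 0L) {
    stop("`n_blocks` must be divisible by the number of conditions")
  }
  with_seed(seed, sample(rep(conditions, each = n_blocks %/% k)))
}

#' Score target detections against button presses
#'
#' A target is detected if at least one press falls in the window from
#' target onset to one second (by default) after the target event ended;
#' the window end is inclusive. Presses are credited greedily to the
#' earliest eligible target, each press to at most one target. Reaction
#' time is measured from target onset (set `rt_origin = "end"` to use
#' the event end instead).
#'
#' @param targets data frame with columns `onset` and `end` (seconds,
#'   sorted by onset).
#' @param presses numeric vector of press times (sorted).
#' @param window_s response window after event end (default 1).
#' @param rt_origin `"onset"` or `"end"`.
#' @return list with `hit_rate`, `mean_rt` (`NA` if no hits), `hits`
#'   (logical per target) and `rt` (per-target reaction time, `NA` for
#'   misses).
#' @export
score_detections <- function(targets, presses, window_s = 1,
                             rt_origin = c("onset", "end")) {
  rt_origin <- match.arg(rt_origin)
  if (window_s <= 0) stop("`window_s` must be positive")
  targets <- as.data.frame(targets)
  n <- nrow(targets)
  hits <- logical(n)
  rt <- rep(NA_real_, n)
  used <- logical(length(presses))
  for (i in seq_len(n)) {
    lo <- targets$onset[i]
    hi <- targets$end[i] + window_s
    ok <- which(!used & presses > lo & presses <= hi)
    if (length(ok) > 0L) {
      j <- ok[[1L]]
      used[j] <- TRUE
      hits[i] <- TRUE
      origin <- if (rt_origin == "onset") targets$onset[i] else targets$end[i]
      rt[i] <- presses[j] - origin
    }
  }
  list(hit_rate = if (n > 0L) mean(hits) else NA_real_,
       mean_rt = if (any(hits)) mean(rt[hits]) else NA_real_,
       hits = hits, rt = rt)
}

#' Compare detection performance between conditions
#'
#' Paired Wilcoxon signed-rank comparison of a per-subject performance
#' measure (reaction time or hit rate) between two conditions; thin
#' wrapper over [stats::wilcox.test()].
#'
#' @param x,y paired per-subject values for the two conditions.
#' @return the `htest` object.
#' @export
compare_conditions <- function(x, y) {
  stats::wilcox.test(x, y, paired = TRUE, exact = FALSE)
}
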