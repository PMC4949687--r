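#' Phase-encoded run design
#'
#' Describes one traveling-wave mapping run: a periodic stimulus sweeps a
#' map dimension (visual polar angle, auditory frequency, body part) so
#' that the response phase at the stimulation frequency encodes the map
#' coordinate. The study design is 8 cycles of 64 s per run.
#'
#' @param samples_per_run number of time samples T; must be divisible by
#'   `cycles_per_run`.
#' @param tr repetition time in seconds.
#' @param cycles_per_run stimulus cycles per run (stimulus frequency bin).
#' @param direction `"forward"` or `"reverse"` sweep.
#' @param modality `"visual"`, `"auditory"` or `"somatomotor"`.
#' @return a `phase_design` object.
#' @export
phase_design <- function(samples_per_run, tr, cycles_per_run = 8L,
                         direction = c("forward", "reverse"),
                         modality = c("visual", "auditory", "somatomotor")) {
  direction <- match.arg(direction)
  modality <- match.arg(modality)
  samples_per_run <- as.integer(samples_per_run)
  cycles_per_run <- as.integer(cycles_per_run)
  if (cycles_per_run < 1L) stop("`cycles_per_run` must be >= 1")
  if (samples_per_run %% cycles_per_run != 0L) {
    stop("`samples_per_run` must be divisible by `cycles_per_run`")
  }
  structure(list(samples_per_run = samples_per_run, tr = tr,
                 cycles_per_run = cycles_per_run, direction = direction,
                 modality = modality),
            class = "phase_design")
}

#' Per-vertex time-series container
#'
#' @param data numeric matrix, T rows (time) by V columns (vertices).
#' @param design the [phase_design()] (or other design metadata) the
#'   series were acquired under.
#' @return a `vertex_ts` object.
#' @export
vertex_ts <- function(data, design = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  structure(list(data = data, design = design), class = "vertex_ts")
}

# Phase lag (radians per cycle) induced by a haemodynamic delay of
# `delay` seconds for a given design.
delay_phase <- function(design, delay) {
  cycle_s <- design$samples_per_run * design$tr / design$cycles_per_run
  2 * pi * delay / cycle_s
}

#' Combine forward- and reverse-direction runs
#'
#' Reverse-direction runs are circularly time-reversed (so their phase
#' encoding matches the forward runs) and then circularly shifted by
#' `round(2 * delay / TR)` samples: the reversal negates the haemodynamic
#' phase lag, so restoring it requires twice the one-way shift relative
#' to forward runs. After this both run types carry phase
#' `phi + omega * delay` at the stimulus bin, and all runs are averaged
#' sample-wise. The residual common lag can be removed at decoding with
#' the known (or estimated, see [estimate_delay()]) delay.
#'
#' @param runs list of [vertex_ts()] objects, each with a `phase_design`
#'   whose `direction` is set.
#' @param delay haemodynamic delay in seconds (default 2).
#' @return a single [vertex_ts()] with direction `"forward"`.
#' @export
combine_runs <- function(runs, delay = 2) {
  if (length(runs) < 1L) stop("need at least one run")
  if (delay < 0) stop("`delay` must be >= 0")
  t0 <- nrow(runs[[1L]]$data)
  v0 <- ncol(runs[[1L]]$data)
  for (r in runs) {
    if (is.null(r$design) || is.null(r$design$direction)) {
      stop("every run must carry a design with a labeled direction")
    }
    if (nrow(r$data) != t0 || ncol(r$data) != v0) {
      stop("all runs must share the same dimensions")
    }
  }
  des <- runs[[1L]]$design
  shift <- as.integer(round(2 * delay / des$tr))
  acc <- matrix(0, t0, v0)
  for (r in runs) {
    x <- r$data
    if (r$design$direction == "reverse") {
      x <- circular_reverse(x)
      x <- circular_shift(x, shift)
    }
    acc <- acc + x
  }
  out_design <- des
  out_design$direction <- "forward"
  vertex_ts(acc / length(runs), out_design)
}

# x'(t) = x(-t) on the circular time axis (row 1 fixed).
circular_reverse <- function(x) {
  t0 <- nrow(x)
  idx <- c(1L, rev(seq_len(t0)[-1L]))
  x[idx, , drop = FALSE]
}

# Delay a circular series by k samples: y(t) = x(t - k).
circular_shift <- function(x, k) {
  t0 <- nrow(x)
  k <- ((k %% t0) + t0) %% t0
  if (k == 0L) return(x)
  x[c((t0 - k + 1L):t0, 1L:(t0 - k)), , drop = FALSE]
}

#' Frequency bins excluded from the Fourier noise estimate
#'
#' The noise power estimate for the traveling-wave F-statistic omits the
#' lowest `n_low` temporal frequencies (motion artifact), the DC and
#' Nyquist bins, and the first three harmonics of the stimulus frequency
#' together with one bin above and below each; the stimulus bin itself is
#' the signal bin, never counted as noise.
#'
#' @param design a [phase_design()].
#' @param n_low number of low-frequency bins to exclude (default 3).
#' @return list with `signal_bin`, `noise_bins` (bins retained for the
#'   noise estimate, in cycles/run units) and `excluded` (all excluded
#'   bins including DC and Nyquist).
#' @export
build_exclusion_set <- function(design, n_low = 3L) {
  t0 <- design$samples_per_run
  s <- design$cycles_per_run
  nyq <- t0 %/% 2L
  harm <- as.integer(outer(s * (1:3), -1:1, `+`))
  if (any(harm > nyq)) {
    warning("harmonic exclusion bins above the Nyquist frequency are clipped")
    harm <- harm[harm <= nyq]
  }
  low <- if (n_low > 0L) seq_len(n_low) else integer(0)
  excluded <- sort(unique(c(0L, nyq, low, harm)))
  noise <- setdiff(seq_len(nyq - 1L), excluded)
  list(signal_bin = s, noise_bins = noise, excluded = excluded)
}

#' Fourier statistics at the stimulus frequency
#'
#' Per vertex: the discrete Fourier transform of the (mean-removed)
#' combined time series is taken; the complex response at the stimulus
#' bin is returned, together with an F-statistic comparing the power at
#' the stimulus frequency with the average power over the retained noise
#' bins. Under white noise the statistic is exactly F-distributed with
#' df1 = 2 and df2 = 2 x (number of noise bins).
#'
#' The complex value is scaled so its modulus is the amplitude of a
#' cosine response `A * cos(omega * t - phi)` and its argument is `phi`.
#' Vertices with zero amplitude have an undefined phase (`NA`); vertices
#' with zero noise power get `F = Inf`, `p = 0`.
#'
#' @param ts a [vertex_ts()] of combined runs.
#' @param excl exclusion set from [build_exclusion_set()]; computed from
#'   the design if omitted.
#' @return list with `complex` (per-vertex complex response),
#'   `amplitude`, `phase` (radians in `[-pi, pi)`), `f`, `df1`, `df2`,
#'   `p`, and `power` (per-bin power matrix, bins 0..T/2 by vertex).
#' @export
fourier_stat <- function(ts, excl = NULL) {
  des <- ts$design
  if (is.null(excl)) excl <- build_exclusion_set(des)
  x <- ts$data
  t0 <- nrow(x)
  x <- sweep(x, 2L, colMeans(x))
  ft <- stats::mvfft(x)
  nyq <- t0 %/% 2L
  power <- Mod(ft[seq_len(nyq + 1L), , drop = FALSE])^2 / t0
  s <- excl$signal_bin
  noise <- excl$noise_bins
  if (length(noise) == 0L) stop("exclusion set leaves no noise bins")
  sig_p <- power[s + 1L, ]
  noise_p <- colMeans(power[noise + 1L, , drop = FALSE])
  # treat noise power at rounding level as zero (noiseless limit)
  zero_noise <- noise_p <= sig_p * 1e-12
  f <- ifelse(zero_noise, ifelse(sig_p > 0, Inf, 0), sig_p / noise_p)
  df2 <- 2L * length(noise)
  p <- ifelse(is.infinite(f), 0, stats::pf(f, 2, df2, lower.tail = FALSE))
  z <- 2 * Conj(ft[s + 1L, ]) / t0
  amp <- Mod(z)
  phase <- ifelse(amp > 0, wrap_pi(Arg(z)), NA_real_)
  list(complex = z, amplitude = amp, phase = phase,
       f = f, df1 = 2L, df2 = df2, p = p, power = power)
}

#' Critical statistic value for a vertex-level threshold
#'
#' Upper-tail critical value of the F distribution, used to express
#' vertex p thresholds as statistic thresholds.
#'
#' @param p upper-tail probability (e.g. 0.001).
#' @param df1,df2 degrees of freedom.
#' @return critical F value.
#' @export
critical_f <- function(p, df1, df2) {
  stop_if_not_scalar_prob(p, "p")
  stats::qf(p, df1, df2, lower.tail = FALSE)
}

#' Decode response phase into a map coordinate
#'
#' Maps the response phase (cycle fraction) into the stimulated
#' dimension: contralateral polar angle in degrees for visual runs, a
#' position on the logarithmic 150--9600 Hz frequency ramp for auditory
#' runs, or a body-part index 1..11 (tongue to toe) for somatomotor
#' runs. The phase corresponding to the start of the stimulus cycle
#' (upper vertical meridian / ramp start / tongue) is `origin`, by
#' default 0; a haemodynamic lag can be removed by passing
#' `origin = delay_lag` from the known delay.
#'
#' @param phase per-vertex phase in radians (from [fourier_stat()]).
#' @param modality `"visual"`, `"auditory"` or `"somatomotor"`.
#' @param origin phase (radians) mapped to the start of the coordinate
#'   range.
#' @param freq_range auditory ramp endpoints in Hz.
#' @param n_parts number of somatomotor body parts.
#' @return numeric per-vertex coordinates; `NA` where phase is undefined.
#' @export
decode_phase <- function(phase,
                         modality = c("visual", "auditory", "somatomotor"),
                         origin = 0,
                         freq_range = c(150, 9600),
                         n_parts = 11L) {
  modality <- match.arg(modality)
  th <- wrap_2pi(phase - origin)
  switch(modality,
    visual = 360 * th / (2 * pi),
    auditory = freq_range[1L] *
      (freq_range[2L] / freq_range[1L])^(th / (2 * pi)),
    somatomotor = pmin(floor(n_parts * th / (2 * pi)) + 1L, n_parts))
}

#' Estimate the haemodynamic delay from opposite-direction runs
#'
#' Scans candidate shifts (in samples) applied to the reversed runs and
#' returns the delay maximising the mean stimulus-bin amplitude over the
#' most responsive vertices, making the otherwise unstated compensation
#' constant recoverable from the data.
#'
#' @param runs list of [vertex_ts()] runs with labeled directions.
#' @param delays candidate delays in seconds.
#' @param top_frac fraction of vertices (by F value at delay 0) used.
#' @return list with `delay` (best candidate) and `amplitude` profile.
#' @export
estimate_delay <- function(runs, delays = seq(0, 8, by = 0.5),
                           top_frac = 0.1) {
  base <- fourier_stat(combine_runs(runs, delay = 0))
  keep <- order(base$f, decreasing = TRUE)
  keep <- keep[seq_len(max(1L, floor(length(keep) * top_frac)))]
  amp <- vapply(delays, function(d) {
    mean(fourier_stat(combine_runs(runs, delay = d))$amplitude[keep])
  }, numeric(1))
  list(delay = delays[which.max(amp)],
       amplitude = stats::setNames(amp, delays))
}
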