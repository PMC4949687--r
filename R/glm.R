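#' Block-design specification for the reading experiment
#'
#' Event table for one run of a random-order block design. In the study
#' design a run is 32 blocks of 16 s drawn from English text, Hindi
#' (matched script) text, dot "text" and fixation; the three non-fixation
#' conditions are modeled as 16 s blocks and button presses to target
#' events as a fourth 1 s condition.
#'
#' @param events data frame with columns `condition`, `onset` (s),
#'   `duration` (s).
#' @param run_s run length in seconds.
#' @param tr repetition time in seconds.
#' @param highpass_s high-pass cutoff in seconds (default 100).
#' @return a `block_design` object.
#' @export
block_design <- function(events, run_s, tr, highpass_s = 100) {
  events <- as.data.frame(events)
  stopifnot(all(c("condition", "onset", "duration") %in% names(events)))
  events$condition <- as.character(events$condition)
  if (nrow(events) > 0L) {
    if (any(events$onset < 0) ||
        any(events$onset + events$duration > run_s + 1e-9)) {
      stop("event onsets/durations must lie within the run")
    }
    for (cond in unique(events$condition)) {
      e <- events[events$condition == cond, ]
      e <- e[order(e$onset), ]
      if (nrow(e) > 1L &&
          any(e$onset[-1L] < (e$onset + e$duration)[-nrow(e)] - 1e-9)) {
        stop("overlapping blocks within condition '", cond, "'")
      }
    }
  }
  structure(list(events = events, run_s = run_s, tr = tr,
                 highpass_s = highpass_s),
            class = "block_design")
}

#' Double-gamma haemodynamic response model
#'
#' Canonical HRF modeled as a difference of two gamma densities, each
#' parameterised by its mean delay and dispersion (standard deviation) in
#' seconds, with the undershoot scaled down by `ratio`.
#'
#' @param peak_delay_s mean of the positive lobe (default 6 s).
#' @param undershoot_delay_s mean of the undershoot (default 16 s).
#' @param peak_disp_s,undershoot_disp_s dispersions (default 3 s).
#' @param ratio peak:undershoot amplitude ratio (default 6).
#' @return an `hrf_model` object.
#' @export
hrf_model <- function(peak_delay_s = 6, undershoot_delay_s = 16,
                      peak_disp_s = 3, undershoot_disp_s = 3, ratio = 6) {
  stopifnot(peak_delay_s > 0, undershoot_delay_s > 0,
            peak_disp_s > 0, undershoot_disp_s > 0, ratio > 0)
  structure(list(peak_delay_s = peak_delay_s,
                 undershoot_delay_s = undershoot_delay_s,
                 peak_disp_s = peak_disp_s,
                 undershoot_disp_s = undershoot_disp_s,
                 ratio = ratio),
            class = "hrf_model")
}

#' Sample the double-gamma kernel
#'
#' @param hrf an [hrf_model()].
#' @param t times in seconds (>= 0).
#' @return kernel values; the positive lobe integrates to 1.
#' @export
hrf_kernel <- function(hrf, t) {
  g <- function(m, s) {
    shape <- (m / s)^2
    scale <- s^2 / m
    stats::dgamma(t, shape = shape, scale = scale)
  }
  g(hrf$peak_delay_s, hrf$peak_disp_s) -
    g(hrf$undershoot_delay_s, hrf$undershoot_disp_s) / hrf$ratio
}

# Discrete-cosine high-pass basis: K = floor(2 * run_s / cutoff) columns,
# periods longer than the cutoff.
dct_highpass_basis <- function(n_scans, run_s, cutoff_s) {
  k_max <- floor(2 * run_s / cutoff_s)
  if (k_max < 1L) return(matrix(numeric(0), n_scans, 0L))
  t0 <- seq_len(n_scans) - 0.5
  b <- vapply(seq_len(k_max),
              function(k) cos(pi * k * t0 / n_scans), numeric(n_scans))
  colnames(b) <- paste0("hp", seq_len(k_max))
  b
}

#' Build the GLM design matrix for a block design
#'
#' One boxcar per condition is convolved with the double-gamma HRF on an
#' oversampled grid and sampled at the TR; the temporal derivative of
#' every convolved regressor is included to absorb small timing
#' deviations. A discrete-cosine high-pass basis with periods above the
#' design's cutoff is appended as nuisance regressors, together with an
#' intercept.
#'
#' @param design a [block_design()].
#' @param hrf an [hrf_model()].
#' @param oversample samples per TR used for the convolution grid.
#' @return list with `X` (T x p matrix, labeled columns), `conditions`
#'   (condition column names), `derivatives`, `nuisance`, `tr`.
#' @export
build_design_matrix <- function(design, hrf = hrf_model(),
                                oversample = 16L) {
  tr <- design$tr
  n_scans <- as.integer(round(design$run_s / tr))
  conds <- sort(unique(design$events$condition))
  dt <- tr / oversample
  grid_n <- n_scans * oversample
  kern <- hrf_kernel(hrf, seq(0, 32, by = dt)) * dt
  cols <- list(intercept = rep(1, n_scans))
  for (cond in conds) {
    e <- design$events[design$events$condition == cond, ]
    box <- numeric(grid_n)
    for (i in seq_len(nrow(e))) {
      i0 <- floor(e$onset[i] / dt) + 1L
      i1 <- min(grid_n, ceiling((e$onset[i] + e$duration[i]) / dt))
      box[i0:i1] <- 1
    }
    conv <- stats::filter(c(box, numeric(length(kern))), kern,
                          method = "convolution", sides = 1L)
    conv <- as.numeric(conv)[seq_len(grid_n)]
    conv[is.na(conv)] <- 0
    reg <- conv[seq(1L, grid_n, by = oversample)]
    dreg <- c(0, diff(reg)) / tr
    cols[[cond]] <- reg
    cols[[paste0(cond, "_deriv")]] <- dreg
  }
  hp <- dct_highpass_basis(n_scans, design$run_s, design$highpass_s)
  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  x <- cbind(x, hp)
  list(X = x, conditions = conds,
       derivatives = paste0(conds, "_deriv"),
       nuisance = c("intercept", colnames(hp)), tr = tr)
}

# Signed p-to-Z conversion robust to extreme t values.
z_from_t <- function(t_stat, df) {
  lp <- stats::pt(t_stat, df, lower.tail = FALSE, log.p = TRUE)
  stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

expand_contrast <- function(weights, columns) {
  cvec <- stats::setNames(numeric(length(columns)), columns)
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("contrast weights must be named by condition column")
  }
  missing <- setdiff(names(weights), columns)
  if (length(missing) > 0L) {
    stop("contrast names not in design: ", paste(missing, collapse = ", "))
  }
  cvec[names(weights)] <- weights
  cvec
}

#' Fit the GLM at every vertex
#'
#' Mass-univariate least squares of each vertex time series on the
#' design matrix, with optional single-pass AR(1) (Cochrane-Orcutt)
#' prewhitening using a lag-1 autocorrelation pooled across vertices.
#' For each contrast the effect (COPE), its variance (VARCOPE), t, a
#' one-sided upper-tail p and the signed normal-equivalent Z are
#' returned; Z = 3.09 corresponds to p < 0.001.
#'
#' @param y T x V matrix of vertex time series (or a [vertex_ts()]).
#' @param dm design from [build_design_matrix()], or a plain matrix.
#' @param contrasts named list of contrasts; each contrast is a named
#'   numeric vector of weights over design columns (derivative and
#'   nuisance columns are implicitly 0), e.g.
#'   `list(EnglishVsHindi = c(English = 1, Hindi = -1))`.
#' @param prewhiten apply AR(1) prewhitening (default `FALSE`).
#' @return a `glm_result`: list with matrices `cope`, `varcope`, `t`,
#'   `z`, `p` (vertices x contrasts), `df`, `rho` (estimated AR(1)
#'   coefficient if prewhitened), `contrasts`.
#' @export
fit_glm <- function(y, dm, contrasts, prewhiten = FALSE) {
  if (inherits(y, "vertex_ts")) y <- y$data
  x <- if (is.list(dm)) dm$X else dm
  if (nrow(x) != nrow(y)) stop("design matrix rows must equal time points")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[-seq_len(qx$rank)]]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  rho <- 0
  if (prewhiten) {
    res0 <- y - x %*% qr.coef(qx, y)
    t0 <- nrow(res0)
    rho <- sum(res0[-1L, ] * res0[-t0, ]) / sum(res0^2)
    w <- sqrt(1 - rho^2)
    yw <- rbind(y[1L, ] * w, y[-1L, , drop = FALSE] -
                  rho * y[-t0, , drop = FALSE])
    xw <- rbind(x[1L, ] * w, x[-1L, , drop = FALSE] -
                  rho * x[-t0, , drop = FALSE])
    colnames(xw) <- colnames(x)
    y <- yw
    x <- xw
    qx <- qr(x)
  }
  beta <- qr.coef(qx, y)
  resid <- y - x %*% beta
  df <- nrow(x) - ncol(x)
  sigma2 <- colSums(resid^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  dimnames(xtx_inv) <- list(colnames(x), colnames(x))
  cn <- names(contrasts)
  if (is.null(cn)) stop("`contrasts` must be a named list")
  nvert <- ncol(y)
  cope <- varcope <- matrix(NA_real_, nvert, length(contrasts),
                            dimnames = list(NULL, cn))
  for (k in seq_along(contrasts)) {
    cvec <- expand_contrast(contrasts[[k]], colnames(x))
    cope[, k] <- as.numeric(crossprod(cvec, beta))
    varcope[, k] <- sigma2 * as.numeric(cvec %*% xtx_inv %*% cvec)
  }
  t_stat <- ifelse(varcope > 0, cope / sqrt(varcope),
                   ifelse(cope == 0, 0, Inf * sign(cope)))
  glm_result(cope, varcope, t_stat, df,
             rho = if (prewhiten) rho else NULL)
}

# Assemble a glm_result from effect/variance/t matrices.
glm_result <- function(cope, varcope, t_stat, df, rho = NULL) {
  p <- matrix(stats::pt(t_stat, df, lower.tail = FALSE),
              nrow(t_stat), dimnames = dimnames(t_stat))
  p[is.infinite(t_stat) & t_stat > 0] <- 0
  p[is.infinite(t_stat) & t_stat < 0] <- 1
  z <- matrix(z_from_t(t_stat, df), nrow(t_stat),
              dimnames = dimnames(t_stat))
  z[is.infinite(t_stat)] <- t_stat[is.infinite(t_stat)]
  structure(list(cope = cope, varcope = varcope, t = t_stat, z = z,
                 p = p, df = df, rho = rho,
                 contrasts = colnames(cope)),
            class = "glm_result")
}

#' Fixed-effects combination of runs
#'
#' Inverse-variance-weighted combination of per-run effect estimates
#' within a subject: `COPE* = sum(COPE_i / V_i) / sum(1 / V_i)`,
#' `VARCOPE* = 1 / sum(1 / V_i)`. Degrees of freedom are pooled across
#' runs.
#'
#' @param runs list of `glm_result` objects with identical contrasts.
#' @return a combined `glm_result`.
#' @export
fixed_effects <- function(runs) {
  if (length(runs) < 1L) stop("need at least one run")
  cn <- runs[[1L]]$contrasts
  for (r in runs) {
    if (!identical(r$contrasts, cn)) stop("runs have different contrasts")
    if (any(r$varcope <= 0, na.rm = TRUE)) {
      stop("fixed effects undefined with zero variance estimates")
    }
  }
  wsum <- num <- 0
  df <- 0
  for (r in runs) {
    w <- 1 / r$varcope
    wsum <- wsum + w
    num <- num + r$cope * w
    df <- df + r$df
  }
  cope <- num / wsum
  varcope <- 1 / wsum
  glm_result(cope, varcope, cope / sqrt(varcope), df)
}

#' Group inference across subjects
#'
#' Per-vertex one-sample t-test on the subjects' combined effect
#' estimates for one contrast (ordinary-least-squares group model,
#' subjects as the random factor, df = n - 1). The resulting p/Z maps
#' are suitable input for [apply_cluster_exclusion()].
#'
#' @param subject_results list of `glm_result` objects (n >= 3),
#'   vertex-corresponded.
#' @param contrast contrast name to test.
#' @return a `glm_result` with one column.
#' @export
group_inference <- function(subject_results, contrast) {
  n <- length(subject_results)
  if (n < 3L) stop("group inference needs at least 3 subjects")
  copes <- vapply(subject_results, function(r) {
    if (!contrast %in% r$contrasts) {
      stop("contrast '", contrast, "' missing from a subject result")
    }
    r$cope[, contrast]
  }, numeric(nrow(subject_results[[1L]]$cope)))
  mu <- rowMeans(copes)
  v <- pmax(0, (rowSums(copes^2) - n * mu^2) / (n - 1L)) / n
  t_stat <- ifelse(v > 0, mu / sqrt(v), ifelse(mu == 0, 0, Inf * sign(mu)))
  cope <- matrix(mu, ncol = 1L, dimnames = list(NULL, contrast))
  varcope <- matrix(v, ncol = 1L, dimnames = list(NULL, contrast))
  tm <- matrix(t_stat, ncol = 1L, dimnames = list(NULL, contrast))
  glm_result(cope, varcope, tm, df = n - 1L)
}
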