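#' Icosphere mesh
#'
#' Closed triangulated sphere obtained by subdividing an icosahedron and
#' projecting onto the sphere; the standard synthetic stand-in for a
#' cortical hemisphere mesh. Vertex count is `10 * 4^s + 2`.
#'
#' @param subdivisions number of 4-to-1 subdivision rounds (>= 0).
#' @param radius_mm sphere radius in mm (default 50, giving a total area
#'   of the order of a hemisphere's).
#' @return a [triangle_mesh()].
#' @export
make_icosphere <- function(subdivisions = 2L, radius_mm = 50) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdivisions)) {
    edge_key <- function(a, b) paste0(pmin(a, b), "_", pmax(a, b))
    mids <- new.env(parent = emptyenv())
    new_v <- v
    midpoint <- function(a, b) {
      key <- edge_key(a, b)
      if (!is.null(mids[[key]])) return(mids[[key]])
      new_v <<- rbind(new_v, (v[a, ] + v[b, ]) / 2)
      mids[[key]] <- nrow(new_v)
      nrow(new_v)
    }
    new_f <- matrix(0L, 4L * nrow(f), 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1L]; b <- f[i, 2L]; cc <- f[i, 3L]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      new_f[4L * i - 3L, ] <- c(a, ab, ca)
      new_f[4L * i - 2L, ] <- c(b, bc, ab)
      new_f[4L * i - 1L, ] <- c(cc, ca, bc)
      new_f[4L * i, ] <- c(ab, bc, ca)
    }
    v <- new_v
    f <- new_f
  }
  v <- v / sqrt(rowSums(v^2)) * radius_mm
  triangle_mesh(v, f)
}

#' Paint a ground-truth topological map patch on a mesh
#'
#' Marks all vertices within a geodesic (edge-path) radius of a center
#' vertex as carrying a topological map, with the true phase varying
#' linearly along a direction in space across the patch over a stated
#' phase range — a smooth, neighbor-preserving coordinate gradient.
#' Vertices outside the patch carry no map (`NA` phase).
#'
#' @param mesh a [triangle_mesh()].
#' @param center_vertex patch center (1-based index).
#' @param radius_mm geodesic radius of the patch in mm.
#' @param direction length-3 vector; phases increase along it.
#' @param phase_range length-2 phase interval spanned across the patch
#'   (default `c(0, 2 * pi)`, a full cycle).
#' @return list with `phase` (per-vertex, `NA` off-patch) and `patch`
#'   (vertex indices).
#' @export
paint_map_patch <- function(mesh, center_vertex, radius_mm,
                            direction = c(1, 0, 0),
                            phase_range = c(0, 2 * pi)) {
  if (radius_mm < 0) stop("`radius_mm` must be >= 0")
  d <- geodesic_distances(mesh, center_vertex)
  patch <- which(d <= radius_mm)
  phase <- rep(NA_real_, n_vertices(mesh))
  if (length(patch) > 0L) {
    proj <- as.numeric(mesh$vertices[patch, , drop = FALSE] %*%
                         (direction / sqrt(sum(direction^2))))
    if (length(patch) == 1L || diff(range(proj)) == 0) {
      phase[patch] <- phase_range[1L]
    } else {
      u <- (proj - min(proj)) / diff(range(proj))
      phase[patch] <- phase_range[1L] + u * diff(phase_range)
    }
  }
  list(phase = phase, patch = patch)
}

# Single-source shortest path distances along mesh edges (Dijkstra with
# Euclidean edge lengths).
geodesic_distances <- function(mesh, source) {
  nb <- mesh_adjacency(mesh)$neighbors
  nv <- n_vertices(mesh)
  dist <- rep(Inf, nv)
  dist[source] <- 0
  done <- logical(nv)
  for (iter in seq_len(nv)) {
    u <- which.min(ifelse(done, Inf, dist))
    if (!is.finite(dist[u])) break
    done[u] <- TRUE
    for (w in nb[[u]]) {
      if (done[w]) next
      len <- sqrt(sum((mesh$vertices[u, ] - mesh$vertices[w, ])^2))
      if (dist[u] + len < dist[w]) dist[w] <- dist[u] + len
    }
  }
  dist
}

#' Ground truth for synthetic phase-encoded data
#'
#' @param phase per-vertex true response phase (`NA` where no map).
#' @param amplitude per-vertex true response amplitude (scalar recycled).
#' @param delay_s true haemodynamic delay in seconds.
#' @param noise_sd white-noise standard deviation.
#' @param drift_amplitude amplitude of sinusoidal low-frequency drift
#'   components added at the excluded low-frequency bins.
#' @return a `ground_truth` list.
#' @export
phase_ground_truth <- function(phase, amplitude = 1, delay_s = 2,
                               noise_sd = 1, drift_amplitude = 0) {
  nv <- length(phase)
  structure(list(phase = phase,
                 amplitude = rep_len(amplitude, nv),
                 delay_s = delay_s, noise_sd = noise_sd,
                 drift_amplitude = drift_amplitude),
            class = "ground_truth")
}

#' Simulate phase-encoded traveling-wave runs
#'
#' Generates per-vertex periodic responses
#' `A * cos(2*pi*s*t/T - phi - omega*delay)` for forward runs (reversed
#' runs sweep the opposite direction, so the sign of `phi` flips), adds
#' white Gaussian noise and optional sinusoidal drift at the three
#' lowest temporal frequencies, and returns one [vertex_ts()] per run.
#' Vertices without a map (`NA` phase) carry noise only. Bit-exactly
#' reproducible for a fixed seed.
#'
#' @param truth a [phase_ground_truth()].
#' @param design a [phase_design()] (its `direction` field is ignored;
#'   per-run directions come from `directions`).
#' @param directions character vector, one per run, of
#'   `"forward"`/`"reverse"`.
#' @param seed RNG seed.
#' @return list of [vertex_ts()] runs, with the truth attached as
#'   attribute `ground_truth`.
#' @export
simulate_phase_runs <- function(truth, design,
                                directions = c("forward", "reverse"),
                                seed = 1L) {
  t0 <- design$samples_per_run
  s <- design$cycles_per_run
  nv <- length(truth$phase)
  tt <- 0:(t0 - 1L)
  omega_d <- delay_phase(design, truth$delay_s)
  amp <- ifelse(is.na(truth$phase), 0, truth$amplitude)
  phi <- ifelse(is.na(truth$phase), 0, truth$phase)
  runs <- with_seed(seed, lapply(seq_along(directions), function(r) {
    dir <- match.arg(directions[[r]], c("forward", "reverse"))
    sgn <- if (dir == "forward") 1 else -1
    arg <- outer(2 * pi * s * tt / t0, sgn * phi + omega_d, `-`)
    sig <- sweep(cos(arg), 2L, amp, `*`)
    if (truth$noise_sd > 0) {
      sig <- sig + matrix(stats::rnorm(t0 * nv, sd = truth$noise_sd),
                          t0, nv)
    }
    if (truth$drift_amplitude > 0) {
      for (k in 1:3) {
        ph <- stats::runif(nv, 0, 2 * pi)
        sig <- sig + truth$drift_amplitude *
          cos(outer(2 * pi * k * tt / t0, ph, `-`))
      }
    }
    des <- design
    des$direction <- dir
    vertex_ts(sig, des)
  }))
  attr(runs, "ground_truth") <- truth
  runs
}

#' Simulate a multi-subject phase-encoded cohort
#'
#' Each subject shares the group ground-truth map on one common mesh but
#' receives von Mises phase jitter (concentration `kappa`) and a random
#' amplitude scaling, emulating between-subject variability without
#' spatial misregistration.
#'
#' @param truth group-level [phase_ground_truth()].
#' @param design a [phase_design()].
#' @param n_subjects number of subjects.
#' @param kappa von Mises concentration of the phase jitter (default 8).
#' @param amp_sd standard deviation of the log-normal amplitude scaling.
#' @param directions per-run directions for every subject.
#' @param seed RNG seed.
#' @return list of per-subject run lists; subject truths attached.
#' @export
simulate_phase_cohort <- function(truth, design, n_subjects, kappa = 8,
                                  amp_sd = 0.2,
                                  directions = c("forward", "reverse"),
                                  seed = 1L) {
  if (n_subjects < 1L) stop("`n_subjects` must be >= 1")
  seeds <- with_seed(seed, sample.int(2^30, n_subjects + 1L))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    st <- with_seed(seeds[i], {
      jitter <- rvonmises(length(truth$phase), kappa)
      scale <- exp(stats::rnorm(1L, 0, amp_sd))
      tr <- truth
      tr$phase <- wrap_pi(truth$phase + jitter)
      tr$amplitude <- truth$amplitude * scale
      tr
    })
    simulate_phase_runs(st, design, directions,
                        seed = seeds[n_subjects + 1L] + i)
  })
  attr(subjects, "ground_truth") <- truth
  subjects
}

# von Mises sampler (Best & Fisher rejection algorithm), mean 0.
rvonmises <- function(n, kappa) {
  if (kappa <= 0) return(stats::runif(n, -pi, pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3L)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2L] > 0 || log(cc / u[2L]) + 1 - cc >= 0) {
      out[i] <- sign(u[3L] - 0.5) * acos(f)
      i <- i + 1L
    }
  }
  out
}

#' Simulate a block-design reading cohort
#'
#' Generates per-subject, per-run block-design time series on a mesh:
#' each run is a balanced random order of 16 s English / Hindi / Dot /
#' Fixation blocks (fixation unmodeled baseline) plus 1 s button-press
#' events, with per-condition vertex effect maps convolved with the
#' double-gamma HRF, white Gaussian noise (optionally AR(1)) and
#' low-frequency drift. Designed patches carry an English > Hindi
#' effect so the English-vs-Hindi contrast recovers them.
#'
#' @param effects named list of per-vertex effect-size vectors, one per
#'   modeled condition (conditions absent from the list get effect 0).
#' @param mesh a [triangle_mesh()].
#' @param n_subjects number of subjects (>= 3 for group inference).
#' @param runs_per_subject runs per subject (study design: 4).
#' @param n_blocks blocks per run (study design: 32).
#' @param block_s block length in seconds (16).
#' @param tr repetition time (1 s).
#' @param noise_sd white-noise standard deviation.
#' @param ar1 lag-1 autocorrelation of the noise (0 = white).
#' @param drift_sd standard deviation of random-walk-free cosine drift
#'   added below the high-pass cutoff.
#' @param effect_sd between-subject standard deviation of a
#'   multiplicative effect scaling.
#' @param seed RNG seed.
#' @return list with `design` (the shared [block_design()] template is
#'   per run inside each subject), `subjects` (list of lists of
#'   [vertex_ts()] with attached `block_design`), and `truth`.
#' @export
simulate_reading_cohort <- function(effects, mesh, n_subjects = 3L,
                                    runs_per_subject = 2L, n_blocks = 32L,
                                    block_s = 16, tr = 1, noise_sd = 1,
                                    ar1 = 0, drift_sd = 0,
                                    effect_sd = 0.1, seed = 1L) {
  if (n_subjects < 3L) stop("`n_subjects` must be >= 3")
  nv <- n_vertices(mesh)
  conds <- c("English", "Hindi", "Dot", "Fixation")
  run_s <- n_blocks * block_s
  n_scans <- as.integer(round(run_s / tr))
  hrf <- hrf_model()
  beta0 <- matrix(0, nv, 3L,
                  dimnames = list(NULL, c("English", "Hindi", "Dot")))
  for (nm in intersect(names(effects), colnames(beta0))) {
    beta0[, nm] <- rep_len(effects[[nm]], nv)
  }
  seeds <- with_seed(seed, sample.int(2^30, n_subjects))
  subjects <- lapply(seq_len(n_subjects), function(i) {
    with_seed(seeds[i], {
      scale <- exp(stats::rnorm(1L, 0, effect_sd))
      lapply(seq_len(runs_per_subject), function(r) {
        blocks <- sample(rep(conds, each = n_blocks %/% 4L))
        onsets <- (seq_len(n_blocks) - 1L) * block_s
        ev <- data.frame(condition = blocks, onset = onsets,
                         duration = block_s)
        ev <- ev[ev$condition != "Fixation", ]
        press_slots <- seq(0.5, run_s - 2, by = 2)  # keep 1 s events apart
        press <- data.frame(condition = "ButtonPress",
                            onset = sort(sample(press_slots, 8L)) +
                              round(stats::runif(8L, 0, 0.9), 3),
                            duration = 1)
        des <- block_design(rbind(ev, press), run_s, tr)
        dm <- build_design_matrix(des, hrf)
        xb <- dm$X[, colnames(beta0), drop = FALSE] %*%
          t(beta0 * scale)
        noise <- matrix(stats::rnorm(n_scans * nv, sd = noise_sd),
                        n_scans, nv)
        if (ar1 != 0) {
          noise <- apply(noise, 2L, function(e) {
            as.numeric(stats::filter(e, ar1, method = "recursive"))
          }) * sqrt(1 - ar1^2)
        }
        y <- xb + noise
        if (drift_sd > 0) {
          hp <- dct_highpass_basis(n_scans, run_s, des$highpass_s)
          if (ncol(hp) > 0L) {
            y <- y + hp %*% matrix(stats::rnorm(ncol(hp) * nv,
                                                sd = drift_sd),
                                   ncol(hp), nv)
          }
        }
        out <- vertex_ts(y, des)
        out$design_matrix <- dm
        out
      })
    })
  })
  list(subjects = subjects,
       truth = list(beta = beta0, noise_sd = noise_sd, ar1 = ar1,
                    seed = seed))
}
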