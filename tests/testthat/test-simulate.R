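test_that("icospheres have the expected combinatorics", {
  ico0 <- make_icosphere(0)
  expect_identical(n_vertices(ico0), 12L)
  expect_identical(nrow(ico0$faces), 20L)

  ico2 <- make_icosphere(2)
  expect_identical(n_vertices(ico2), 162L)  # 10 * 4^2 + 2

  for (s in 0:2) {
    m <- make_icosphere(s)
    v <- n_vertices(m)
    e <- nrow(mesh_adjacency(m)$edges)
    f <- nrow(m$faces)
    expect_identical(v - e + f, 2L)  # closed genus-0 surface
    expect_equal(sqrt(rowSums(m$vertices^2)),
                 rep(50, v), tolerance = 1e-12)
  }
})

test_that("map patches paint smooth phase gradients of the requested extent", {
  ico <- make_icosphere(3, radius_mm = 20)
  res <- paint_map_patch(ico, 1L, radius_mm = 15,
                         phase_range = c(0, 2 * pi))
  expect_setequal(which(!is.na(res$phase)), res$patch)
  expect_equal(range(res$phase[res$patch]), c(0, 2 * pi))
  # full cycle decodes across (nearly all of) the coordinate range;
  # the extreme-projection vertices are sparse on a spherical cap
  coord <- decode_phase(res$phase[res$patch], "visual")
  expect_gt(diff(range(coord)), 300)
  expect_lt(min(coord), 10)

  single <- paint_map_patch(ico, 7L, radius_mm = 0)
  expect_identical(single$patch, 7L)

  # mirrored gradients flip the phase-ordering along the direction
  a <- paint_map_patch(ico, 1L, 10, direction = c(0, 0, 1))
  b <- paint_map_patch(ico, 1L, 10, direction = c(0, 0, -1))
  proj <- ico$vertices[a$patch, 3]
  expect_gt(cor(proj, a$phase[a$patch]), 0.9)
  expect_lt(cor(proj, b$phase[b$patch]), -0.9)
})

test_that("simulated phase runs obey the forward model exactly at zero noise", {
  des <- phase_design(64, 2, 8)
  phi <- c(0.3, -1.2)
  truth <- phase_ground_truth(phi, amplitude = 2, delay_s = 3,
                              noise_sd = 0)
  runs <- simulate_phase_runs(truth, des, c("forward", "reverse"),
                              seed = 1)
  tt <- 0:63
  lag <- cortimap:::delay_phase(des, 3)
  fwd_oracle <- 2 * cos(outer(2 * pi * 8 * tt / 64, phi + lag, `-`))
  rev_oracle <- 2 * cos(outer(2 * pi * 8 * tt / 64, -phi + lag, `-`))
  expect_equal(runs[[1]]$data, fwd_oracle, tolerance = 1e-12)
  expect_equal(runs[[2]]$data, rev_oracle, tolerance = 1e-12)
})

test_that("null simulations give uniform p-values and fixed seeds reproduce", {
  des <- phase_design(128, 2, 8)
  truth <- phase_ground_truth(rep(NA_real_, 3000), amplitude = 0,
                              noise_sd = 1)
  runs <- simulate_phase_runs(truth, des, c("forward", "reverse"),
                              seed = 17)
  st <- fourier_stat(combine_runs(runs, delay = 2))
  expect_gt(suppressWarnings(ks.test(st$p, "punif")$p.value), 0.01)

  runs2 <- simulate_phase_runs(truth, des, c("forward", "reverse"),
                               seed = 17)
  expect_identical(runs[[1]]$data, runs2[[1]]$data)
  runs3 <- simulate_phase_runs(truth, des, c("forward", "reverse"),
                               seed = 18)
  expect_false(identical(runs[[1]]$data, runs3[[1]]$data))
})

test_that("low-frequency drift lands in the excluded bins", {
  des <- phase_design(128, 2, 8)
  truth <- phase_ground_truth(rep(NA_real_, 100), amplitude = 0,
                              noise_sd = 0.1, drift_amplitude = 3)
  runs <- simulate_phase_runs(truth, des, "forward", seed = 2)
  st <- fourier_stat(combine_runs(runs, delay = 2))
  # drift power is confined to bins 1..3, which the exclusion rule
  # removes, so the F statistic stays calibrated
  expect_lt(mean(st$p < 0.01), 0.1)
  drift_power <- colMeans(t(st$power[2:4, ]))
  noise_power <- colMeans(t(st$power[11:14, ]))
  expect_gt(mean(drift_power) / mean(noise_power), 50)
})

test_that("phase cohorts share the truth up to jitter and amplitude scaling", {
  ico <- make_icosphere(1)
  des <- phase_design(64, 2, 8)
  truth <- phase_ground_truth(rep(1, n_vertices(ico)), amplitude = 2,
                              delay_s = 2, noise_sd = 0)
  cohort <- simulate_phase_cohort(truth, des, n_subjects = 4,
                                  kappa = 50, seed = 5)
  expect_length(cohort, 4)
  phases <- vapply(cohort, function(runs) {
    fourier_stat(combine_runs(runs, delay = 2))$phase[1]
  }, numeric(1))
  lag <- cortimap:::delay_phase(des, 2)
  err <- cortimap:::wrap_pi(phases - lag - 1)
  expect_lt(max(abs(err)), 0.6)       # small von Mises jitter
  expect_gt(stats::sd(err), 1e-6)     # but subjects do differ
  cohort2 <- simulate_phase_cohort(truth, des, n_subjects = 4,
                                   kappa = 50, seed = 5)
  expect_identical(cohort[[2]][[1]]$data, cohort2[[2]][[1]]$data)
})

test_that("reading cohorts embed the designed English effect", {
  ico <- make_icosphere(1)
  nv <- n_vertices(ico)
  eff <- numeric(nv); eff[1:10] <- 1.5
  cohort <- simulate_reading_cohort(list(English = eff), ico,
                                    n_subjects = 3, runs_per_subject = 2,
                                    n_blocks = 16, block_s = 16, tr = 2,
                                    noise_sd = 0.5, seed = 8)
  expect_length(cohort$subjects, 3)
  expect_length(cohort$subjects[[1]], 2)
  run <- cohort$subjects[[1]][[1]]
  expect_identical(nrow(run$data), 128L)
  fit <- fit_glm(run, run$design_matrix,
                 list(EvH = c(English = 1, Hindi = -1)))
  expect_gt(mean(fit$cope[1:10, 1]), 5 * mean(abs(fit$cope[11:nv, 1])))

  cohort2 <- simulate_reading_cohort(list(English = eff), ico,
                                     n_subjects = 3, runs_per_subject = 2,
                                     n_blocks = 16, block_s = 16, tr = 2,
                                     noise_sd = 0.5, seed = 8)
  expect_identical(cohort$subjects[[2]][[1]]$data,
                   cohort2$subjects[[2]][[1]]$data)
})
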