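make_events <- function() {
  data.frame(condition = rep(c("English", "Hindi", "Dot"), times = 8),
             onset = seq(0, 368, by = 16), duration = 16)
}

test_that("block designs validate event tables", {
  expect_error(block_design(data.frame(condition = "a", onset = -1,
                                       duration = 16), 512, 1),
               "within the run")
  expect_error(block_design(data.frame(condition = c("a", "a"),
                                       onset = c(0, 8), duration = 16),
                            512, 1),
               "overlapping")
})

test_that("design matrices contain HRF-convolved boxcars, derivatives and DCT basis", {
  empty <- block_design(data.frame(condition = character(0),
                                   onset = numeric(0),
                                   duration = numeric(0)), 512, 1)
  dm0 <- build_design_matrix(empty)
  expect_identical(colnames(dm0$X), c("intercept", paste0("hp", 1:10)))

  des <- block_design(data.frame(condition = "English", onset = 64,
                                 duration = 16), 512, 1)
  dm <- build_design_matrix(des)
  # independent convolution oracle on a fine grid
  hrf <- hrf_model()
  dt <- 1 / 16
  tfine <- seq(0, 512 - dt, by = dt)
  box <- as.numeric(tfine >= 64 & tfine < 80)
  kern <- hrf_kernel(hrf, seq(0, 32, by = dt)) * dt
  conv <- stats::convolve(box, rev(kern), type = "open")
  oracle <- conv[seq(1, length(tfine), by = 16)]
  reg <- dm$X[, "English"]
  expect_gt(cor(reg, oracle), 0.9999)
  expect_lt(abs(which.max(reg) - which.max(oracle)), 2)
  # an isolated short event peaks about one HRF peak delay after onset
  short <- build_design_matrix(block_design(
    data.frame(condition = "Press", onset = 100, duration = 1), 512, 1))
  peak_t <- which.max(short$X[, "Press"]) - 1
  expect_true(peak_t >= 103 && peak_t <= 108)
  expect_identical(sum(grepl("^hp", colnames(dm$X))), 10L)
})

test_that("fit_glm recovers effects exactly on noiseless data and flags rank deficiency", {
  des <- block_design(make_events(), 512, 1)
  dm <- build_design_matrix(des)
  contrasts <- list(EvH = c(English = 1, Hindi = -1),
                    Eng = c(English = 1))
  y0 <- matrix(0, 512, 4)
  fit0 <- fit_glm(y0, dm, contrasts)
  expect_true(all(fit0$cope == 0))
  expect_true(all(fit0$t == 0))

  beta <- c(English = 1.25, Hindi = 0.5, Dot = -0.3)
  y <- dm$X[, names(beta)] %*% beta
  fit <- fit_glm(cbind(y, y), dm, contrasts)
  expect_equal(unname(fit$cope[, "EvH"]), rep(0.75, 2), tolerance = 1e-9)
  expect_equal(unname(fit$cope[, "Eng"]), rep(1.25, 2), tolerance = 1e-9)

  bad <- cbind(dm$X, dup = dm$X[, "English"])
  expect_error(fit_glm(cbind(y), bad, contrasts), "dup")
})

test_that("fit_glm is calibrated and unbiased under simulation", {
  des <- block_design(make_events(), 512, 1)
  dm <- build_design_matrix(des)
  set.seed(30)
  nv <- 1000
  y <- dm$X[, "English"] %*% t(rep(1, nv)) +
    matrix(rnorm(512 * nv), 512, nv)
  fit <- fit_glm(y, dm, list(Eng = c(English = 1)))
  se <- sd(fit$cope) / sqrt(nv)
  expect_lt(abs(mean(fit$cope) - 1), 2 * se)
  # Z/p pairing: Z = 3.09 <-> one-sided p < 0.001
  expect_equal(fit$z[fit$p < 0.25] ,
               qnorm(fit$p[fit$p < 0.25], lower.tail = FALSE),
               tolerance = 1e-6)
})

test_that("AR(1) prewhitening estimates the serial correlation", {
  des <- block_design(make_events(), 512, 1)
  dm <- build_design_matrix(des)
  set.seed(31)
  nv <- 200
  noise <- apply(matrix(rnorm(512 * nv), 512, nv), 2, function(e) {
    as.numeric(stats::filter(e, 0.4, method = "recursive"))
  })
  fit <- fit_glm(noise, dm, list(Eng = c(English = 1)), prewhiten = TRUE)
  # pooled single-pass estimate; OLS residuals bias it slightly low
  expect_equal(fit$rho, 0.4, tolerance = 0.15)
  expect_gt(fit$rho, 0.25)
  # calibration is preserved after whitening
  expect_lt(abs(mean(fit$p < 0.05) - 0.05), 0.05)
})

test_that("fixed effects combine runs by inverse variance", {
  des <- block_design(make_events(), 512, 1)
  dm <- build_design_matrix(des)
  set.seed(32)
  y <- matrix(rnorm(512 * 3), 512, 3)
  fit <- fit_glm(y, dm, list(Eng = c(English = 1)))
  expect_equal(fixed_effects(list(fit))$cope, fit$cope)

  # equal variances, copes 1 and 3 -> cope 2, variance halved
  g1 <- cortimap:::glm_result(matrix(1, 2, 1, dimnames = list(NULL, "c")),
                              matrix(0.5, 2, 1), matrix(1, 2, 1), df = 100)
  g3 <- cortimap:::glm_result(matrix(3, 2, 1, dimnames = list(NULL, "c")),
                              matrix(0.5, 2, 1), matrix(3, 2, 1), df = 100)
  fe <- fixed_effects(list(g1, g3))
  expect_equal(unname(fe$cope[, 1]), c(2, 2))
  expect_equal(unname(fe$varcope[, 1]), c(0.25, 0.25))

  # heterogeneous variances match the brute-force weighted mean
  set.seed(33)
  runs <- lapply(1:4, function(i) {
    cope <- matrix(rnorm(5), 5, 1, dimnames = list(NULL, "c"))
    v <- matrix(runif(5, 0.2, 2), 5, 1)
    cortimap:::glm_result(cope, v, cope / sqrt(v), df = 50)
  })
  fe <- fixed_effects(runs)
  copes <- sapply(runs, function(r) r$cope[, 1])
  vars <- sapply(runs, function(r) r$varcope[, 1])
  oracle <- rowSums(copes / vars) / rowSums(1 / vars)
  expect_equal(unname(fe$cope[, 1]), oracle)
  expect_equal(unname(fe$varcope[, 1]), 1 / rowSums(1 / vars))
})

test_that("high-pass nuisance columns leave orthogonal effects untouched", {
  des <- block_design(make_events(), 512, 1)
  dm <- build_design_matrix(des)
  x_task <- dm$X[, c("intercept", "English", "English_deriv")]
  hp <- dm$X[, grepl("^hp", colnames(dm$X))]
  # nuisance columns orthogonalised against the task design; data in
  # the task span is then orthogonal to them and the COPE is untouched
  hpo <- hp - x_task %*% solve(crossprod(x_task), crossprod(x_task, hp))
  y <- x_task %*% c(0.3, 1.2, 0)
  f1 <- fit_glm(cbind(y), x_task, list(Eng = c(English = 1)))
  f2 <- fit_glm(cbind(y), cbind(x_task, hpo), list(Eng = c(English = 1)))
  expect_equal(f1$cope, f2$cope, tolerance = 1e-9)
  expect_equal(unname(f1$cope[1, 1]), 1.2, tolerance = 1e-9)
})

test_that("group inference is a one-sample t over subject effects", {
  same <- lapply(1:5, function(i) {
    cortimap:::glm_result(matrix(2, 3, 1, dimnames = list(NULL, "c")),
                          matrix(1, 3, 1), matrix(2, 3, 1), df = 10)
  })
  g <- group_inference(same, "c")
  expect_true(all(is.infinite(g$t)))
  expect_true(all(g$p == 0))
  expect_error(group_inference(same[1:2], "c"), "at least 3")

  set.seed(34)
  subj <- lapply(1:8, function(i) {
    cope <- matrix(rnorm(50, mean = 0.5), 50, 1,
                   dimnames = list(NULL, "c"))
    cortimap:::glm_result(cope, matrix(1, 50, 1), cope, df = 10)
  })
  g <- group_inference(subj, "c")
  copes <- sapply(subj, function(r) r$cope[, 1])
  oracle_t <- as.numeric(apply(copes, 1, function(x) t.test(x)$statistic))
  expect_equal(unname(g$t[, 1]), oracle_t, tolerance = 1e-9)
  expect_identical(g$df, 7L)
})

test_that("true effects survive vertex and cluster thresholds by construction", {
  # designated effect patch, 14 subjects: the patch must survive
  # vertex p < 0.01 plus cluster exclusion in at least 95% of datasets
  ico <- make_icosphere(2)
  areas <- vertex_areas(ico)
  patch <- grow_patch(ico, areas, 1L, 2500)
  eff <- numeric(n_vertices(ico))
  eff[patch] <- 1
  crit <- estimate_cluster_threshold(ico, 3, 0.01, 0.05, 300, seed = 40)
  n_rep <- 20L
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    cohort <- simulate_reading_cohort(list(English = eff), ico,
                                      n_subjects = 14, runs_per_subject = 1,
                                      n_blocks = 16, block_s = 16, tr = 2,
                                      noise_sd = 1, effect_sd = 0.05,
                                      seed = 100 + r)
    fits <- lapply(cohort$subjects, function(runs) {
      fit <- fit_glm(runs[[1]], runs[[1]]$design_matrix,
                     list(EvH = c(English = 1, Hindi = -1)))
      fit$cope[, 1] <- smooth_map(fit$cope[, 1], ico, 3)
      fit
    })
    g <- group_inference(fits, "EvH")
    surv <- apply_cluster_exclusion(g$p[, 1], ico, crit)
    ok[r] <- mean(patch %in% surv) > 0.5
  }
  expect_gte(mean(ok), 0.95)
})
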