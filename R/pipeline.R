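#' Validate a scenario configuration
#'
#' A scenario config (YAML file or list) describes one end-to-end
#' synthetic run: mesh, phase-encoded design and cohort, reading design
#' and cohort, thresholds and seeds. Every stochastic stage must have an
#' explicit seed; thresholds must be probabilities.
#'
#' @param config list or path to a YAML file.
#' @return the validated config list, invisibly on error-free input.
#' @export
validate_scenario <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      stop("scenario config is missing `", where, field, "`")
    }
    x[[field]]
  }
  need(config, "seed", "")
  mesh <- need(config, "mesh", "")
  need(mesh, "subdivisions", "mesh$")
  phase <- need(config, "phase", "")
  for (f in c("samples_per_run", "tr", "cycles_per_run", "n_subjects",
              "delay_s", "noise_sd", "amplitude")) {
    need(phase, f, "phase$")
  }
  reading <- need(config, "reading", "")
  for (f in c("n_subjects", "runs_per_subject", "noise_sd", "effect")) {
    need(reading, f, "reading$")
  }
  thr <- need(config, "thresholds", "")
  for (f in c("vertex_p", "alpha", "iterations")) need(thr, f, "thresholds$")
  stop_if_not_scalar_prob(thr$vertex_p, "thresholds$vertex_p")
  stop_if_not_scalar_prob(thr$alpha, "thresholds$alpha")
  if (is.null(config$smoothing_steps)) config$smoothing_steps <- 10L
  config
}

#' Run a full synthetic mapping-and-overlap scenario
#'
#' End-to-end orchestration: generate a mesh and ground-truth map patch,
#' simulate a phase-encoded cohort, run the single-subject Fourier
#' analysis and cross-subject vector average, estimate and apply the
#' surface cluster-size criterion to the group map; simulate a reading
#' cohort, fit the block-design GLM per run, combine runs by fixed
#' effects, run group inference and cluster-correct it; finally quantify
#' the overlap of the surviving reading activation with the surviving
#' map mask by vertex-wise area. All stages derive their seeds from the
#' config, so a rerun with the same config is bit-identical.
#'
#' @param config scenario config (list or YAML path); see
#'   [validate_scenario()].
#' @param out_dir output directory; created if needed. Intermediate
#'   surfaces/maps (GIFTI), masks (label files), the overlap report
#'   (CSV + JSON) and a provenance log are written there.
#' @return list with `overlap` (report data frame), `map_mask`,
#'   `reading_mask`, `criterion`, `group_phase`, `config`, and `files`.
#' @export
run_scenario <- function(config, out_dir) {
  config <- validate_scenario(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "provenance.jsonl")
  unlink(log_path)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage), list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), "\n",
        file = log_path, append = TRUE, sep = "")
  }
  seed <- as.integer(config$seed)
  steps <- as.integer(config$smoothing_steps)

  mesh <- make_icosphere(config$mesh$subdivisions,
                         config$mesh$radius_mm %||% 50)
  areas <- vertex_areas(mesh)
  f_mesh <- file.path(out_dir, "mesh.surf.gii")
  write_gifti_surface(mesh, f_mesh)
  log_stage("mesh", vertices = n_vertices(mesh),
            area_mm2 = sum(areas), file = basename(f_mesh))

  # --- phase-encoded chain -------------------------------------------
  ph <- config$phase
  design <- phase_design(ph$samples_per_run, ph$tr, ph$cycles_per_run,
                         modality = ph$modality %||% "visual")
  patch <- paint_map_patch(mesh, ph$patch$center_vertex %||% 1L,
                           ph$patch$radius_mm %||% 40)
  truth <- phase_ground_truth(patch$phase, amplitude = ph$amplitude,
                              delay_s = ph$delay_s,
                              noise_sd = ph$noise_sd,
                              drift_amplitude = ph$drift_amplitude %||% 0)
  cohort <- simulate_phase_cohort(truth, design, ph$n_subjects,
                                  seed = seed)
  subject_maps <- lapply(cohort, function(runs) {
    fourier_stat(combine_runs(runs, delay = ph$delay_s))$complex
  })
  grp <- vector_average(subject_maps, mesh, smooth_steps = steps)
  gf <- group_f(lapply(seq_len(ncol(grp$subject_smoothed)),
                       function(i) grp$subject_smoothed[, i]))
  thr <- config$thresholds
  criterion <- estimate_cluster_threshold(mesh, steps, thr$vertex_p,
                                          thr$alpha, thr$iterations,
                                          seed = seed + 1L)
  map_mask <- apply_cluster_exclusion(gf$p, mesh, criterion)
  f_group <- file.path(out_dir, "group_phase.func.gii")
  write_gifti_metric(grp$mean, f_group)
  f_mapmask <- file.path(out_dir, "map_mask.label")
  write_label(map_mask, f_mapmask)
  log_stage("phase_group", n_subjects = ph$n_subjects,
            min_area_mm2 = criterion$min_area_mm2,
            surviving_vertices = length(map_mask),
            files = c(basename(f_group), basename(f_mapmask)))

  # --- reading chain -------------------------------------------------
  rd <- config$reading
  r_patch <- paint_map_patch(mesh, rd$patch$center_vertex %||% 1L,
                             rd$patch$radius_mm %||% 35)
  eff <- numeric(n_vertices(mesh))
  eff[r_patch$patch] <- rd$effect
  cohortr <- simulate_reading_cohort(
    list(English = eff), mesh, n_subjects = rd$n_subjects,
    runs_per_subject = rd$runs_per_subject,
    n_blocks = rd$n_blocks %||% 32L, block_s = rd$block_s %||% 16,
    tr = rd$tr %||% 1, noise_sd = rd$noise_sd,
    ar1 = rd$ar1 %||% 0, seed = seed + 2L)
  contrast <- list(EnglishVsHindi = c(English = 1, Hindi = -1))
  subj_results <- lapply(cohortr$subjects, function(runs) {
    fits <- lapply(runs, function(run) {
      fit_glm(run, run$design_matrix, contrast,
              prewhiten = isTRUE(rd$prewhiten))
    })
    fe <- fixed_effects(fits)
    fe$cope[, 1L] <- smooth_map(fe$cope[, 1L], mesh, steps)
    fe
  })
  ginf <- group_inference(subj_results, "EnglishVsHindi")
  reading_mask <- apply_cluster_exclusion(ginf$p[, 1L], mesh, criterion)
  f_readmask <- file.path(out_dir, "reading_mask.label")
  write_label(reading_mask, f_readmask)
  log_stage("reading_group", n_subjects = rd$n_subjects,
            surviving_vertices = length(reading_mask),
            files = basename(f_readmask))

  # --- overlap -------------------------------------------------------
  report <- overlap_percentage(reading_mask, map_mask, areas)
  f_csv <- file.path(out_dir, "overlap.csv")
  utils::write.csv(report, f_csv, row.names = FALSE)
  f_json <- file.path(out_dir, "overlap.json")
  jsonlite::write_json(report, f_json, dataframe = "rows",
                       auto_unbox = TRUE, digits = NA, na = "null")
  log_stage("overlap", overall_percent = report$percent[1L],
            files = c(basename(f_csv), basename(f_json)))

  files <- c(f_mesh, f_group, f_mapmask, f_readmask, f_csv, f_json)
  log_stage("done", md5 = as.list(tools::md5sum(files)))
  list(overlap = report, map_mask = map_mask,
       reading_mask = reading_mask, criterion = criterion,
       group_phase = grp$phase, config = config, files = files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
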