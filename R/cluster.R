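#' Monte-Carlo estimation of the surface cluster-size threshold
#'
#' Estimates the minimum cluster surface area that achieves a familywise
#' corrected alpha when vertex-level statistics are thresholded at
#' `vertex_p`. Each iteration draws white Gaussian noise on the mesh
#' vertices, applies the same surface smoothing as the analysed maps,
#' standardises each vertex by the exact per-vertex standard deviation of
#' the smoothed noise (computable from the linear smoothing operator),
#' thresholds the resulting p map at `vertex_p`, and records the largest
#' suprathreshold cluster area. The returned area threshold is the
#' (1 - alpha) quantile of the max-cluster-area distribution, so that
#' the probability of any surviving cluster on a matching null map is
#' alpha. Results are bit-reproducible for a fixed seed.
#'
#' @param mesh a [triangle_mesh()].
#' @param smooth_steps smoothing steps matching the analysed data.
#' @param vertex_p vertex-level (uncorrected, one-sided) p threshold.
#' @param alpha familywise corrected alpha; `alpha = 1` returns a zero
#'   threshold (no exclusion).
#' @param iterations Monte-Carlo iterations (>= 100).
#' @param seed RNG seed.
#' @return a `cluster_criterion` list with `vertex_p`, `min_area_mm2`,
#'   `alpha`, `smooth_steps`, `iterations`, `seed` and the sampled
#'   `max_areas`.
#' @export
estimate_cluster_threshold <- function(mesh, smooth_steps, vertex_p, alpha,
                                       iterations = 1000L, seed = 1L) {
  stop_if_not_scalar_prob(vertex_p, "vertex_p")
  stop_if_not_scalar_prob(alpha, "alpha", closed_upper = TRUE)
  iterations <- as.integer(iterations)
  if (iterations < 100L) stop("`iterations` must be >= 100")
  areas <- vertex_areas(mesh)
  max_areas <- with_seed(seed, {
    pm <- null_p_maps(mesh, smooth_steps, iterations)
    apply(pm, 2L, function(p) max_cluster_area(p, mesh, areas, vertex_p))
  })
  thr <- if (alpha >= 1) 0 else
    as.numeric(stats::quantile(max_areas, 1 - alpha, names = FALSE))
  structure(list(vertex_p = vertex_p, min_area_mm2 = thr, alpha = alpha,
                 smooth_steps = smooth_steps, iterations = iterations,
                 seed = seed, max_areas = max_areas),
            class = "cluster_criterion")
}

# Matrix of one-sided null p maps: smoothed standardised Gaussian noise.
# Uses the exact per-vertex sd of the k-step smoothed white noise (row
# norms of the smoothing operator).
null_p_maps <- function(mesh, smooth_steps, n_maps) {
  nv <- n_vertices(mesh)
  m <- smoothing_matrix(mesh, as.integer(smooth_steps))
  sd_v <- sqrt(Matrix::rowSums(m * m))
  e <- matrix(stats::rnorm(nv * n_maps), nv, n_maps)
  z <- as.matrix(m %*% e) / sd_v
  stats::pnorm(z, lower.tail = FALSE)
}

max_cluster_area <- function(p_map, mesh, areas, vertex_p) {
  mask <- which(p_map < vertex_p)
  if (length(mask) == 0L) return(0)
  comps <- connected_components(mask, mesh)
  max(vapply(comps, function(cc) region_area(areas, cc), numeric(1)))
}

#' Apply cluster-size exclusion to a vertex p map
#'
#' Thresholds the map at the criterion's vertex-level p, clusters the
#' suprathreshold vertices by edge connectivity, and removes clusters
#' whose summed vertex-wise area is below the criterion's minimum area.
#' For two-sided maps set `two_sided = TRUE` to threshold `p/2` on the
#' magnitude before clustering (sign handling is up to the caller's map).
#'
#' @param p_map per-vertex (one-sided) p values.
#' @param mesh a [triangle_mesh()].
#' @param criterion a `cluster_criterion` from
#'   [estimate_cluster_threshold()], or a list with `vertex_p` and
#'   `min_area_mm2`.
#' @param two_sided halve the vertex threshold before clustering.
#' @return integer vector of surviving vertex indices (possibly empty).
#' @export
apply_cluster_exclusion <- function(p_map, mesh, criterion,
                                    two_sided = FALSE) {
  vp <- criterion$vertex_p
  if (two_sided) vp <- vp / 2
  mask <- which(p_map < vp)
  if (length(mask) == 0L) return(integer(0))
  areas <- vertex_areas(mesh)
  comps <- connected_components(mask, mesh)
  keep <- vapply(comps, function(cc) {
    region_area(areas, cc) >= criterion$min_area_mm2
  }, logical(1))
  sort(unlist(comps[keep], use.names = FALSE))
}

#' @export
print.cluster_criterion <- function(x, ...) {
  cat(sprintf(paste0("cluster criterion: vertex p < %g, clusters < %.2f ",
                     "mm^2 excluded, corrected alpha %g (%d iterations)\n"),
              x$vertex_p, x$min_area_mm2, x$alpha, x$iterations))
  invisible(x)
}
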