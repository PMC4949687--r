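#' Named anatomical region partition
#'
#' Named vertex masks (e.g. frontal, temporal, occipito-parietal) used to
#' break an overlap report down by region, plus an optional list of
#' "treat-as-map" patches: vertex sets counted as belonging to the
#' topological map even where no periodic signal is measurable (the
#' foveal confluence under central fixation is the canonical case).
#'
#' @param regions named list of integer vertex-index vectors; regions
#'   must be disjoint.
#' @param treat_as_map optional list of vertex-index vectors appended to
#'   every map mask before intersection.
#' @return a `region_partition` object.
#' @export
region_partition <- function(regions, treat_as_map = list()) {
  stopifnot(is.list(regions))
  if (length(regions) > 0L) {
    if (is.null(names(regions)) || any(!nzchar(names(regions)))) {
      stop("`regions` must be a named list")
    }
    all_idx <- unlist(regions, use.names = FALSE)
    if (anyDuplicated(all_idx)) stop("regions must be disjoint")
  }
  structure(list(regions = lapply(regions, as.integer),
                 treat_as_map = lapply(treat_as_map, as.integer)),
            class = "region_partition")
}

#' Overlap of a task-activation mask with a topological-map mask
#'
#' Computes, overall and per named region, the surface area of the
#' activation mask, the area of its intersection with the map mask, and
#' the overlap expressed as a percentage of the activation area (the
#' primary statistic; the map mask is never the denominator). All areas
#' use vertex-wise areas, so boundary vertices contribute their full
#' vertex area. A symmetric Dice coefficient is included as a secondary
#' column. An empty activation mask (overall or within a region) yields
#' `NA` percentages, not 0.
#'
#' @param reading_mask integer vertex indices of the thresholded task
#'   activation.
#' @param map_mask integer vertex indices of the thresholded map.
#' @param areas per-vertex areas from [vertex_areas()].
#' @param partition optional [region_partition()]; its `treat_as_map`
#'   patches are unioned into `map_mask` before intersection.
#' @return data frame with columns `region`, `reading_mm2`,
#'   `overlap_mm2`, `percent`, `dice`; first row is `Overall`.
#' @export
overlap_percentage <- function(reading_mask, map_mask, areas,
                               partition = NULL) {
  reading_mask <- unique(as.integer(reading_mask))
  map_mask <- unique(as.integer(map_mask))
  if (!is.null(partition)) {
    for (patch in partition$treat_as_map) {
      map_mask <- union(map_mask, patch)
    }
  }
  row_for <- function(name, rmask) {
    inter <- intersect(rmask, map_mask)
    r_area <- region_area(areas, rmask)
    o_area <- region_area(areas, inter)
    m_area <- region_area(areas, map_mask)
    data.frame(region = name,
               reading_mm2 = r_area,
               overlap_mm2 = o_area,
               percent = if (r_area > 0) 100 * o_area / r_area else NA_real_,
               dice = if (r_area + m_area > 0) {
                 2 * o_area / (r_area + m_area)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }
  out <- row_for("Overall", reading_mask)
  if (!is.null(partition)) {
    for (nm in names(partition$regions)) {
      out <- rbind(out,
                   row_for(nm, intersect(reading_mask,
                                         partition$regions[[nm]])))
    }
  }
  rownames(out) <- NULL
  out
}

#' Overlap report against several maps and their union
#'
#' Runs [overlap_percentage()] for each named map mask and for the union
#' of all map masks, mirroring the summary statistic "share of task
#' activation falling within any topological map". The union row's
#' percentages are never below any single map's.
#'
#' @param reading_mask activation vertex indices.
#' @param map_masks named list of map vertex-index vectors.
#' @param areas per-vertex areas.
#' @param partition optional [region_partition()].
#' @return data frame with a `map` column (`Union` last) followed by the
#'   [overlap_percentage()] columns.
#' @export
multimap_report <- function(reading_mask, map_masks, areas,
                            partition = NULL) {
  if (length(map_masks) < 1L) stop("need at least one map mask")
  if (is.null(names(map_masks)) || any(!nzchar(names(map_masks)))) {
    stop("`map_masks` must be a named list")
  }
  rows <- lapply(names(map_masks), function(nm) {
    cbind(map = nm,
          overlap_percentage(reading_mask, map_masks[[nm]], areas,
                             partition))
  })
  union_mask <- unique(unlist(map_masks, use.names = FALSE))
  rows[[length(rows) + 1L]] <-
    cbind(map = "Union",
          overlap_percentage(reading_mask, union_mask, areas, partition))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
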