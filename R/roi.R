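#' Resolve a named region to label values
#'
#' Regions follow the label convention 1 = cortex, 2 = medulla; the whole
#' kidney is their union. Vessel-outlier pixels (3) belong to no tissue
#' region.
#' @keywords internal
region_labels <- function(region) {
  switch(region,
         cortex = LBL_CORTEX,
         medulla = LBL_MEDULLA,
         kidney = c(LBL_CORTEX, LBL_MEDULLA),
         stop(sprintf("unknown region '%s'", region)))
}

#' Regional mean and sd of a pixel map
#'
#' Arithmetic mean and sd of a map over the valid pixels of a region.
#' T1 is summarised for cortex, medulla and whole kidney; perfusion for
#' cortex and whole kidney (the medulla's heterogeneous appearance makes
#' medullary perfusion unstable — it is computed on request but flagged).
#'
#' @param map numeric matrix (perfusion or T1).
#' @param label_map integer matrix (0 background, 1 cortex, 2 medulla).
#' @param region `"cortex"`, `"medulla"` or `"kidney"`.
#' @param valid_mask optional logical matrix; only TRUE pixels enter.
#' @param metric label recorded in the output row.
#' @param kidney_id,visit_id identifiers carried through to the output.
#' @return one-row data.frame: region, metric, mean, sd, n_pixels,
#'   kidney_id, visit_id, note. If the region has no valid pixels the mean
#'   and sd are `NA` and `note` says why.
#' @export
roi_mean <- function(map, label_map, region, valid_mask = NULL,
                     metric = "perfusion_ml_min_100g",
                     kidney_id = NA_character_, visit_id = NA_integer_) {
  stopifnot(identical(dim(map), dim(label_map)))
  labs <- region_labels(region)
  if (!any(label_map %in% labs))
    stop(sprintf("region '%s' not present in label map", region))
  sel <- matrix(label_map %in% labs, nrow(map))
  if (!is.null(valid_mask)) {
    stopifnot(identical(dim(valid_mask), dim(map)))
    sel <- sel & valid_mask
  }
  sel <- sel & !is.na(map)
  note <- if (region == "medulla" && metric == "perfusion_ml_min_100g")
    "unstable: medullary perfusion is heterogeneous" else ""
  if (!any(sel)) {
    return(data.frame(region = region, metric = metric, mean = NA_real_,
                      sd = NA_real_, n_pixels = 0L, kidney_id = kidney_id,
                      visit_id = visit_id,
                      note = "no valid pixels in region"))
  }
  v <- map[sel]
  data.frame(region = region, metric = metric, mean = mean(v),
             sd = stats::sd(v), n_pixels = length(v), kidney_id = kidney_id,
             visit_id = visit_id, note = note)
}

#' Regional summary table for one kidney and visit
#'
#' The per-kidney measurement set: T1 for cortex, medulla and whole kidney;
#' perfusion for cortex and whole kidney (plus the flagged medullary value
#' if requested).
#'
#' @param perfusion_map a `perfusion_map` from [quantify()].
#' @param t1_map T1 map (ms) on the same grid.
#' @param label_map integer label map.
#' @param kidney_id,visit_id identifiers.
#' @param include_medullary_perfusion logical.
#' @return long-format data.frame, one row per region x metric.
#' @export
roi_summary_table <- function(perfusion_map, t1_map, label_map,
                              kidney_id = NA_character_,
                              visit_id = NA_integer_,
                              include_medullary_perfusion = FALSE) {
  stopifnot(inherits(perfusion_map, "perfusion_map"))
  t1 <- as_plain_matrix(t1_map)
  rows <- list()
  for (r in c("cortex", "medulla", "kidney")) {
    rows[[length(rows) + 1L]] <- roi_mean(
      t1, label_map, r, metric = "T1_ms",
      kidney_id = kidney_id, visit_id = visit_id)
  }
  perf_regions <- c("cortex", "kidney",
                    if (include_medullary_perfusion) "medulla")
  for (r in perf_regions) {
    rows[[length(rows) + 1L]] <- roi_mean(
      perfusion_map$values, label_map, r,
      valid_mask = perfusion_map$valid_mask,
      metric = "perfusion_ml_min_100g",
      kidney_id = kidney_id, visit_id = visit_id)
  }
  do.call(rbind, rows)
}
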