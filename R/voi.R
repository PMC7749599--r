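# Volume-of-interest feature extraction: average each CPC element over
# labeled regions, and compute the direct longitudinal probability-ratio
# baseline (gm(t')/gm(t) etc.) the CPC method is compared against.

#' Integer label volume
#'
#' @param labels Integer 3-D array; label 0 is reserved for unlabeled
#'   background and never averaged over.
#' @param name_map Optional named character vector mapping label ids (as
#'   names) to region names.
#' @return Object of class `label_volume`.
#' @export
label_volume <- function(labels, name_map = NULL) {
  if (length(dim(labels)) != 3L) stopf("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  if (any(labels < 0L, na.rm = TRUE)) stopf("labels must be >= 0")
  structure(list(labels = labels, name_map = name_map),
            class = "label_volume")
}

region_name <- function(labels, id) {
  nm <- labels$name_map[[as.character(id)]]
  if (is.null(nm)) as.character(id) else nm
}

#' Average CPC elements within VOIs
#'
#' For every (region, element) pair: the arithmetic mean of the element over
#' voxels carrying that label whose CPC fit is valid. Regions with no valid
#' voxels get `NA` and are logged.
#'
#' @param cpc A [compute_cpc_volume()] result.
#' @param labels A [label_volume()] on the same grid.
#' @return `data.frame(region, element, value, n_voxels)`, 16 rows per
#'   region.
#' @export
average_in_voi <- function(cpc, labels) {
  stopifnot(inherits(cpc, "cpc_volume"), inherits(labels, "label_volume"))
  if (!identical(dim(labels$labels), dim(cpc$validity_mask))) {
    stopf("label volume and CPC volume are on different grids")
  }
  ids <- sort(setdiff(unique(as.integer(labels$labels)), 0L))
  elems <- cpc_element_names()
  out <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    sel <- labels$labels == ids[k] & cpc$validity_mask
    n <- sum(sel)
    vals <- if (n == 0L) rep(NA_real_, 16L) else {
      vapply(seq_len(16L), function(e) mean(cpc$channels[, , , e][sel]),
             numeric(1))
    }
    if (n == 0L) {
      cpc_log("region %s has no valid voxels; features set to NA",
              region_name(labels, ids[k]))
    }
    out[[k]] <- data.frame(region = region_name(labels, ids[k]),
                           element = elems, value = vals, n_voxels = n,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Direct longitudinal probability-ratio features
#'
#' The simple comparator to CPC: per region and tissue, the mean over voxels
#' of `p(t') / p(t)`. Voxels whose baseline probability is below
#' `prob_threshold` are excluded from the mean (mirroring the CPC threshold
#' and bounding the ratio); with `mode = "ratio_of_means"` the region means
#' are taken before dividing instead.
#'
#' @param maps_t,maps_tt [probability_map_set]s on one grid.
#' @param labels A [label_volume()].
#' @param prob_threshold Baseline exclusion threshold (default 0.2).
#' @param mode `"mean_of_ratios"` (default) or `"ratio_of_means"`.
#' @return `data.frame(region, element, value, n_voxels)` with elements
#'   `gm_ratio`, `wm_ratio`, `csf_ratio`.
#' @export
direct_ratio_features <- function(maps_t, maps_tt, labels,
                                  prob_threshold = 0.2,
                                  mode = c("mean_of_ratios", "ratio_of_means")) {
  mode <- match.arg(mode)
  stopifnot(inherits(labels, "label_volume"))
  if (!identical(dim(maps_t$g), dim(labels$labels)) ||
      !identical(dim(maps_t$g), dim(maps_tt$g))) {
    stopf("maps and labels are on different grids")
  }
  tissue_of <- c(gm_ratio = "g", wm_ratio = "w", csf_ratio = "c")
  ids <- sort(setdiff(unique(as.integer(labels$labels)), 0L))
  valid <- maps_t$valid & maps_tt$valid
  out <- list()
  for (id in ids) {
    in_region <- labels$labels == id & valid
    for (feat in names(tissue_of)) {
      p0 <- maps_t[[tissue_of[[feat]]]]
      p1 <- maps_tt[[tissue_of[[feat]]]]
      sel <- in_region & p0 >= prob_threshold
      n <- sum(sel)
      value <- if (n == 0L) NA_real_
      else if (mode == "mean_of_ratios") mean(p1[sel] / p0[sel])
      else mean(p1[sel]) / mean(p0[sel])
      out[[length(out) + 1L]] <- data.frame(
        region = region_name(labels, id), element = feat,
        value = value, n_voxels = n, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Build the cohort VOI feature table
#'
#' Extracts, per subject, the 16 VOI-averaged CPC elements and the 3 direct
#' ratio features for every region, in long format.
#'
#' @param subjects List of subject entries as returned by [make_cohort()]
#'   (fields `subject_id`, `group`, `maps_t`, `maps_tt`).
#' @param labels A [label_volume()] shared across subjects.
#' @param config A [cpc_config()].
#' @param cpc_volumes Optional named list of precomputed `cpc_volume`s keyed
#'   by subject id; missing entries are computed on the fly.
#' @return `data.frame(subject_id, group, region, element, value, n_voxels)`
#'   of class `voi_feature_table`.
#' @export
voi_feature_table <- function(subjects, labels, config = cpc_config(),
                              cpc_volumes = NULL) {
  rows <- lapply(subjects, function(s) {
    cpc <- cpc_volumes[[s$subject_id]]
    if (is.null(cpc)) cpc <- compute_cpc_volume(s$maps_t, s$maps_tt, config)
    feats <- rbind(average_in_voi(cpc, labels),
                   direct_ratio_features(s$maps_t, s$maps_tt, labels,
                                         prob_threshold = config$prob_threshold))
    cbind(data.frame(subject_id = s$subject_id, group = s$group,
                     stringsAsFactors = FALSE), feats)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("voi_feature_table", "data.frame")
  out
}

#' Reshape a long feature table to one row per subject
#'
#' Column names are `region|element`. The subject id and group columns are
#' kept as the first two columns.
#'
#' @param features A [voi_feature_table()].
#' @return `data.frame` with one row per subject.
#' @export
feature_wide <- function(features) {
  key <- paste(features$region, features$element, sep = "|")
  subjects <- unique(features$subject_id)
  cols <- unique(key)
  m <- matrix(NA_real_, length(subjects), length(cols),
              dimnames = list(subjects, cols))
  m[cbind(match(features$subject_id, subjects), match(key, cols))] <-
    features$value
  grp <- features$group[match(subjects, features$subject_id)]
  cbind(data.frame(subject_id = subjects, group = grp,
                   stringsAsFactors = FALSE),
        as.data.frame(m, check.names = FALSE))
}
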