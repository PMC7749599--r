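# Coefficients of probability change (CPC): at each voxel a non-negative
# 4x4 matrix F maps the tissue probability vector p(t) = (g, w, c, b) to
# p(t') = F p(t). F is fitted over the voxel's 3x3x3 neighborhood by four
# independent non-negative least-squares solves (one per target tissue),
# after sub-threshold probabilities are zeroed and the survivors
# renormalized; elements are capped at 1/threshold.

#' CPC fitting configuration
#'
#' @param prob_threshold Probabilities below this are neglected (zeroed and
#'   the remainder renormalized) before fitting; default 0.2.
#' @param cpc_cap Upper bound applied to fitted elements; defaults to
#'   `1 / prob_threshold` (5.0 at threshold 0.2), the largest ratio two
#'   surviving probabilities can form.
#' @param neighborhood_radius Neighborhood half-width; 1 gives 3x3x3, i.e.
#'   27 equations per target tissue and 108 stacked equations for the 16
#'   unknowns.
#' @param min_valid_voxels Minimum usable neighborhood voxels to attempt a
#'   fit; default 14, a majority of 27.
#' @return Object of class `cpc_config`.
#' @export
cpc_config <- function(prob_threshold = 0.2,
                       cpc_cap = 1 / prob_threshold,
                       neighborhood_radius = 1L,
                       min_valid_voxels = 14L) {
  if (prob_threshold <= 0 || prob_threshold >= 1) {
    stopf("prob_threshold must be in (0, 1)")
  }
  if (cpc_cap <= 0) stopf("cpc_cap must be positive")
  neighborhood_radius <- as.integer(neighborhood_radius)
  if (neighborhood_radius < 1L) stopf("neighborhood_radius must be >= 1")
  min_valid_voxels <- as.integer(min_valid_voxels)
  if (min_valid_voxels < 4L) stopf("min_valid_voxels must be >= 4")
  structure(list(prob_threshold = prob_threshold, cpc_cap = cpc_cap,
                 neighborhood_radius = neighborhood_radius,
                 min_valid_voxels = min_valid_voxels),
            class = "cpc_config")
}

#' Close the background channel
#'
#' The probability of background is obtained by subtracting the total GM,
#' WM and CSF probability from 1 (clipped to \[0, 1\]). Voxels whose three
#' tissue probabilities already exceed 1 by more than 1e-3 are flagged
#' invalid and excluded from fitting.
#'
#' @param g,w,c 3-D tissue probability arrays of one shape, values in \[0,1\].
#' @param timepoint Label stored on the result.
#' @return A [probability_map_set] with the background channel filled in.
#' @export
close_background <- function(g, w, c, timepoint = "t") {
  if (!identical(dim(g), dim(w)) || !identical(dim(g), dim(c))) {
    stopf("close_background: input volumes differ in shape")
  }
  tot <- g + w + c
  valid <- tot <= 1 + 1e-3
  b <- clip01(1 - tot)
  probability_map_set(g, w, c, b, valid = valid, timepoint = timepoint,
                      sum_tol = 1e-3)
}

#' Threshold and renormalize probability vectors
#'
#' Components below `tau` are set to 0 and the surviving components rescaled
#' to sum exactly 1. For a probability 4-vector with `tau < 0.25` at least
#' one component always survives.
#'
#' @param p Numeric 4-vector, or an n x 4 matrix of row vectors, each summing
#'   to 1 within 1e-3.
#' @param tau Threshold in (0, 1).
#' @return Object of the same shape as `p`.
#' @export
threshold_and_renormalize <- function(p, tau) {
  if (tau <= 0 || tau >= 1) stopf("tau must be in (0, 1)")
  m <- if (is.matrix(p)) p else matrix(p, nrow = 1L)
  if (ncol(m) != 4L) stopf("expected 4 tissue components")
  if (any(abs(rowSums(m) - 1) > 1e-3)) {
    stopf("input rows must sum to 1 within 1e-3")
  }
  m[m < tau] <- 0
  s <- rowSums(m)
  if (any(s <= 0)) stopf("all components fell below the threshold")
  out <- m / s
  if (is.matrix(p)) out else drop(out)
}

#' Assemble the per-target linear system
#'
#' For one target tissue, stacks the neighborhood's source probability
#' vectors at baseline as design rows and the target tissue's follow-up
#' probabilities as the response. Across the four targets a full 3x3x3
#' neighborhood yields 27 x 4 = 108 equations for the 16 unknowns.
#'
#' @param neigh_t,neigh_tt m x 4 matrices of thresholded, renormalized
#'   probabilities at baseline and follow-up (rows = neighborhood voxels).
#' @param target Target tissue: index 1-4 or one of `"g","w","c","b"`.
#' @return List with `design` (m x 4) and `response` (length m).
#' @export
assemble_system <- function(neigh_t, neigh_tt, target) {
  if (!is.matrix(neigh_t) || !is.matrix(neigh_tt) ||
      ncol(neigh_t) != 4L || ncol(neigh_tt) != 4L ||
      nrow(neigh_t) != nrow(neigh_tt)) {
    stopf("neighborhoods must be m x 4 matrices with equal row counts")
  }
  if (is.character(target)) target <- match(target, TISSUES)
  if (is.na(target) || target < 1L || target > 4L) stopf("unknown target tissue")
  list(design = unname(neigh_t), response = unname(neigh_tt[, target]))
}

#' Non-negative least squares
#'
#' Solves `min || design %*% coef - response ||` subject to `coef >= 0`
#' (Lawson-Hanson active set). Design columns that are identically zero are
#' unidentifiable: their coefficient is 0 and they are flagged.
#'
#' @param design m x 4 matrix, `m >= 4`.
#' @param response Length-m numeric vector.
#' @return List: `coef` (non-negative 4-vector), `residual` (sum of squared
#'   residuals), `identifiable` (logical 4-vector, `FALSE` for zero columns).
#' @export
solve_nnls <- function(design, response) {
  design <- as.matrix(design)
  if (nrow(design) < ncol(design)) {
    stopf("underdetermined system: %d rows < %d unknowns",
          nrow(design), ncol(design))
  }
  fit <- .cpp_nnls(design, as.numeric(response))
  list(coef = as.numeric(fit$coef), residual = fit$rss,
       identifiable = apply(design != 0, 2L, any))
}

#' Fit the CPC matrix on one neighborhood
#'
#' Runs four independent NNLS solves (one per target tissue) on thresholded,
#' renormalized neighborhood probabilities and caps every element at
#' `config$cpc_cap`. When follow-up equals baseline and the design has full
#' column rank the fitted matrix is the identity: the probabilities show no
#' structural change.
#'
#' @param neigh_t,neigh_tt m x 4 matrices of thresholded, renormalized
#'   probabilities (see [threshold_and_renormalize()]).
#' @param config A [cpc_config()].
#' @return Object of class `cpc_matrix`: `elements` is the 4x4 matrix with
#'   rows = source tissues and columns = target tissues (`elements["g","c"]`
#'   is `F_gc`), plus per-target `fit_residual` and per-source `identifiable`.
#' @export
fit_voxel <- function(neigh_t, neigh_tt, config = cpc_config()) {
  if (nrow(neigh_t) < config$min_valid_voxels) {
    stopf("neighborhood has %d rows, fewer than min_valid_voxels = %d",
          nrow(neigh_t), config$min_valid_voxels)
  }
  elements <- matrix(0, 4L, 4L, dimnames = list(TISSUES, TISSUES))
  fit_residual <- stats::setNames(numeric(4L), TISSUES)
  identifiable <- stats::setNames(rep(TRUE, 4L), TISSUES)
  for (tgt in seq_len(4L)) {
    sys <- assemble_system(neigh_t, neigh_tt, tgt)
    fit <- solve_nnls(sys$design, sys$response)
    elements[, tgt] <- pmin(fit$coef, config$cpc_cap)
    fit_residual[tgt] <- fit$residual
    identifiable <- identifiable & fit$identifiable
  }
  structure(list(elements = elements, fit_residual = fit_residual,
                 identifiable = identifiable),
            class = "cpc_matrix")
}

#' @export
print.cpc_matrix <- function(x, ...) {
  cat("CPC matrix (rows = source tissue, cols = target tissue):\n")
  print(round(x$elements, 4))
  invisible(x)
}

#' Compute a CPC volume
#'
#' Slides a (2r+1)^3 neighborhood over every interior voxel of a co-registered
#' probability map pair, thresholds and renormalizes the per-voxel
#' probability vectors at both time points, fits the 4x4 CPC matrix by four
#' NNLS solves, caps the elements, and stores them at the neighborhood's
#' center voxel. Border voxels (incomplete neighborhoods) and voxels whose
#' neighborhoods hold fewer than `min_valid_voxels` usable voxels are marked
#' invalid. Deterministic given inputs and configuration.
#'
#' @param maps_t,maps_tt [probability_map_set]s on one grid.
#' @param config A [cpc_config()].
#' @return Object of class `cpc_volume`: `channels` (4-D array, 16 element
#'   channels named as in [cpc_element_names()]), `validity_mask`,
#'   `identifiable` (4-D, one logical channel per source tissue),
#'   `fit_residual` (4-D, per target tissue), and `config_used`.
#' @export
compute_cpc_volume <- function(maps_t, maps_tt, config = cpc_config()) {
  stopifnot(inherits(maps_t, "probability_map_set"),
            inherits(maps_tt, "probability_map_set"))
  dims <- dim(maps_t$g)
  if (!identical(dims, dim(maps_tt$g))) {
    stopf("map sets are on different grids (%s vs %s)",
          paste(dims, collapse = "x"), paste(dim(maps_tt$g), collapse = "x"))
  }
  stack4 <- function(m) array(c(m$g, m$w, m$c, m$b), c(dims, 4L))
  valid <- maps_t$valid & maps_tt$valid
  res <- .cpp_cpc_sweep(stack4(maps_t), stack4(maps_tt), valid,
                        dims, config$prob_threshold, config$cpc_cap,
                        config$neighborhood_radius, config$min_valid_voxels)
  dimnames(res$channels) <- list(NULL, NULL, NULL, cpc_element_names())
  structure(list(channels = res$channels,
                 validity_mask = res$validity_mask,
                 identifiable = res$identifiable,
                 fit_residual = res$fit_residual,
                 config_used = config),
            class = "cpc_volume")
}

#' @export
print.cpc_volume <- function(x, ...) {
  cat(sprintf("cpc_volume: grid %s, %d fitted voxels (threshold %.3g, cap %.3g)\n",
              paste(dim(x$validity_mask), collapse = "x"),
              sum(x$validity_mask), x$config_used$prob_threshold,
              x$config_used$cpc_cap))
  invisible(x)
}

#' Extract one element channel from a CPC volume
#'
#' @param cpc A [compute_cpc_volume()] result.
#' @param element Element name, e.g. `"F_gc"`.
#' @return 3-D array; voxels outside the validity mask are `NA`.
#' @export
cpc_channel <- function(cpc, element) {
  idx <- match(element, cpc_element_names())
  if (is.na(idx)) stopf("unknown CPC element '%s'", element)
  out <- cpc$channels[, , , idx]
  out[!cpc$validity_mask] <- NA_real_
  out
}

#' Write a CPC volume to disk
#'
#' Writes the 16 element channels as one 4-D NIfTI-1 file (channel order as
#' in [cpc_element_names()]), the validity mask as a 3-D volume, and a JSON
#' sidecar recording the configuration, channel order and package version.
#'
#' @param cpc A `cpc_volume`.
#' @param prefix Output path prefix; files `<prefix>_cpc.nii.gz`,
#'   `<prefix>_mask.nii.gz` and `<prefix>_cpc.json` are created.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_cpc_volume <- function(cpc, prefix) {
  paths <- c(channels = paste0(prefix, "_cpc.nii.gz"),
             mask = paste0(prefix, "_mask.nii.gz"),
             sidecar = paste0(prefix, "_cpc.json"))
  write_nifti(cpc$channels, paths[["channels"]])
  write_nifti(array(as.integer(cpc$validity_mask), dim(cpc$validity_mask)),
              paths[["mask"]])
  sidecar <- list(config = unclass(cpc$config_used),
                  channel_order = cpc_element_names(),
                  software = sprintf("cpcmorph %s",
                                     as.character(packageVersion("cpcmorph"))))
  jsonlite::write_json(sidecar, paths[["sidecar"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}

#' Read a CPC volume written by [write_cpc_volume()]
#'
#' @param prefix Path prefix used at write time.
#' @return A `cpc_volume` (without identifiability and residual channels,
#'   which are not serialized).
#' @export
read_cpc_volume <- function(prefix) {
  ch <- read_nifti(paste0(prefix, "_cpc.nii.gz"))
  mask <- read_nifti(paste0(prefix, "_mask.nii.gz")) > 0
  sidecar <- jsonlite::read_json(paste0(prefix, "_cpc.json"))
  cfg <- do.call(cpc_config, sidecar$config[c("prob_threshold", "cpc_cap",
                                              "neighborhood_radius",
                                              "min_valid_voxels")])
  dimnames(ch) <- list(NULL, NULL, NULL, cpc_element_names())
  structure(list(channels = ch, validity_mask = array(mask, dim(ch)[1:3]),
                 identifiable = NULL, fit_residual = NULL,
                 config_used = cfg),
            class = "cpc_volume")
}
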