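# Shared fixtures: small phantoms and hand-built neighborhoods.

quiet <- function(code) withr::with_options(list(cpcmorph.quiet = TRUE), code)

small_sphere_spec <- function(...) {
  args <- utils::modifyList(
    list(grid_shape = c(14L, 14L, 14L), structure_radii = c(2.5, 4.5, 6),
         blur_sigma = 1, noise_sd = 0, atrophy_rate = 0, seed = 7L),
    list(...))
  do.call(phantom_spec, args)
}

# 3x3x3 neighborhood (27 x 4 rows) containing all four pure-tissue rows and
# assorted threshold-inactive mixtures; full column rank by construction.
pure_mixed_neighborhood <- function() {
  rows <- rbind(
    diag(4),
    c(0.5, 0.3, 0.0, 0.2),
    c(0.4, 0.0, 0.4, 0.2),
    c(0.2, 0.2, 0.3, 0.3),
    c(0.0, 0.5, 0.5, 0.0),
    c(0.6, 0.0, 0.2, 0.2),
    c(0.0, 0.0, 0.5, 0.5))
  m <- rows[c(1:4, rep(5:10, length.out = 23)), ]
  colnames(m) <- c("g", "w", "c", "b")
  m
}

# Neighborhood rows safe for exact GM->CSF transfer recovery at fraction phi
# <= 0.5: every component of every row stays in {0} U [0.2, 1] at both time
# points, so thresholding is a no-op.
transfer_safe_neighborhood <- function() {
  rows <- rbind(
    c(0.6, 0.0, 0.2, 0.2),
    c(0.4, 0.2, 0.2, 0.2),
    c(0.5, 0.0, 0.3, 0.2),
    c(0.0, 0.5, 0.2, 0.3),
    c(0.0, 0.0, 0.6, 0.4),
    c(0.4, 0.0, 0.4, 0.2),
    c(0.0, 1.0, 0.0, 0.0),
    c(0.0, 0.0, 0.0, 1.0),
    c(0.6, 0.2, 0.2, 0.0))
  rows[rep(1:9, 3), ]
}

apply_gm_to_csf <- function(rows, phi) {
  out <- rows
  out[, 3] <- rows[, 3] + phi * rows[, 1]
  out[, 1] <- (1 - phi) * rows[, 1]
  out
}

# Extract the thresholded 27 x 4 neighborhood matrices around center voxel
# (i, j, k) of a probability map set; mirrors the sweep's gather step but
# implemented independently in R.
gather_neighborhood <- function(maps, center, tau = 0.2) {
  idx <- expand.grid(i = center[1] + (-1):1, j = center[2] + (-1):1,
                     k = center[3] + (-1):1)
  m <- cbind(maps$g[as.matrix(idx)], maps$w[as.matrix(idx)],
             maps$c[as.matrix(idx)], maps$b[as.matrix(idx)])
  threshold_and_renormalize(m, tau)
}

# Rank of the thresholded design restricted to its nonzero columns equals
# the number of nonzero columns: the condition for a unique exact solution.
design_full_rank <- function(design) {
  nz <- which(apply(design != 0, 2, any))
  qr(design[, nz, drop = FALSE])$rank == length(nz)
}
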