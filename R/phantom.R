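# Synthetic longitudinal atrophy phantom: co-registered tissue probability
# map pairs with known, parametric GM -> CSF probability transfer at the
# GM/CSF boundary, partial-volume blur and additive noise. Stands in for
# real longitudinal segmentations so every downstream stage is testable
# with ground truth.

#' Probability map set
#'
#' A per-subject, per-timepoint stack of four co-registered 3-D probability
#' volumes (gray matter, white matter, cerebrospinal fluid, background) on a
#' common grid, plus a voxel validity mask. At every valid voxel the four
#' probabilities lie in \[0, 1\] and sum to 1 within `sum_tol`.
#'
#' @param g,w,c,b 3-D arrays of tissue probabilities on one grid.
#' @param valid Logical 3-D array; defaults to all `TRUE`.
#' @param timepoint Label, conventionally `"t"` or `"tt"`.
#' @param sum_tol Tolerance for the sum-to-one check at valid voxels.
#' @return Object of class `probability_map_set`.
#' @export
probability_map_set <- function(g, w, c, b, valid = NULL, timepoint = "t",
                                sum_tol = 1e-6) {
  dims <- dim(g)
  for (v in list(w, c, b)) {
    if (!identical(dim(v), dims)) stopf("probability volumes differ in shape")
  }
  if (is.null(valid)) valid <- array(TRUE, dims)
  if (!identical(dim(valid), dims)) stopf("validity mask shape mismatch")
  rng <- range(g, w, c, b)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9) {
    stopf("probabilities outside [0, 1] (range %.4g..%.4g)", rng[1], rng[2])
  }
  tot <- g + w + c + b
  bad <- abs(tot - 1) > sum_tol & valid
  if (any(bad)) {
    stopf("%d valid voxels violate sum-to-one beyond %g (max |sum-1| = %.3g)",
          sum(bad), sum_tol, max(abs(tot[valid] - 1)))
  }
  structure(list(g = g, w = w, c = c, b = b, valid = valid,
                 timepoint = timepoint),
            class = "probability_map_set")
}

#' @export
print.probability_map_set <- function(x, ...) {
  cat(sprintf("probability_map_set [%s]: grid %s, %d/%d valid voxels\n",
              x$timepoint, paste(dim(x$g), collapse = "x"),
              sum(x$valid), length(x$valid)))
  invisible(x)
}

#' Atrophy phantom parameters
#'
#' Describes one synthetic longitudinal phantom. The phantom is a nested
#' structure (concentric spheres or parallel slabs) of CSF core, GM shell and
#' WM surround inside background. Between the two time points a fraction
#' `atrophy_rate` of the GM probability is moved to CSF in the GM band within
#' `boundary_width` voxels of the CSF core (the classic GM erosion /
#' CSF dilation signature of atrophy). Maps are partial-volume blurred
#' (shared across time points) and perturbed by independent truncated
#' Gaussian noise re-projected onto the probability simplex.
#'
#' @param grid_shape Integer triple, each >= 7.
#' @param geometry `"nested_spheres"` or `"slab_stack"` (slabs are stacked
#'   along the first axis, mirrored about the volume center).
#' @param structure_radii Increasing radii in voxels: CSF core, outer GM
#'   boundary, outer WM boundary.
#' @param atrophy_rate Fraction in \[0, 1\] of GM probability transferred to
#'   CSF per affected voxel.
#' @param blur_sigma Gaussian partial-volume blur width in voxels.
#' @param noise_sd Standard deviation of additive probability noise.
#' @param boundary_width Thickness in voxels of the affected GM band adjacent
#'   to the CSF core; `Inf` affects the entire GM compartment.
#' @param seed RNG seed.
#' @return Object of class `atrophy_phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(24L, 24L, 24L),
                         geometry = c("nested_spheres", "slab_stack"),
                         structure_radii = c(4, 8, 11),
                         atrophy_rate = 0,
                         blur_sigma = 1,
                         noise_sd = 0.01,
                         boundary_width = 3,
                         seed = 1L) {
  geometry <- match.arg(geometry)
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 7L)) {
    stopf("grid_shape must be a triple with every axis >= 7")
  }
  if (length(structure_radii) != 3L || any(diff(structure_radii) <= 0) ||
      structure_radii[1] <= 0) {
    stopf("structure_radii must be 3 increasing positive lengths")
  }
  extent <- if (geometry == "slab_stack") grid_shape[1] else min(grid_shape)
  if (structure_radii[3] >= extent / 2) {
    stopf("degenerate geometry: outer radius %.1f does not fit grid %s",
          structure_radii[3], paste(grid_shape, collapse = "x"))
  }
  if (atrophy_rate < 0 || atrophy_rate > 1) stopf("atrophy_rate must be in [0, 1]")
  if (blur_sigma < 0 || noise_sd < 0) stopf("blur_sigma and noise_sd must be >= 0")
  if (boundary_width <= 0) stopf("boundary_width must be positive")
  structure(list(grid_shape = grid_shape, geometry = geometry,
                 structure_radii = as.numeric(structure_radii),
                 atrophy_rate = atrophy_rate, blur_sigma = blur_sigma,
                 noise_sd = noise_sd, boundary_width = boundary_width,
                 seed = as.integer(seed)),
            class = "atrophy_phantom_spec")
}

# Distance field of the phantom geometry: Euclidean distance from the volume
# center (nested_spheres) or from the central plane of axis 1 (slab_stack).
phantom_distance <- function(spec) {
  d <- spec$grid_shape
  ctr <- (d + 1) / 2
  if (spec$geometry == "nested_spheres") {
    dx2 <- (seq_len(d[1]) - ctr[1])^2
    dy2 <- (seq_len(d[2]) - ctr[2])^2
    dz2 <- (seq_len(d[3]) - ctr[3])^2
    sqrt(outer(outer(dx2, dy2, `+`), dz2, `+`))
  } else {
    array(rep(abs(seq_len(d[1]) - ctr[1]), times = d[2] * d[3]), dim = d)
  }
}

# Separable Gaussian blur with edge renormalization so channel sums are
# preserved exactly (kernel truncated at 3 sigma).
gaussian_blur3d <- function(a, sigma) {
  if (sigma <= 0) return(a)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r):r)^2 / (2 * sigma^2))
  k <- k / sum(k)
  blur_axis <- function(a, axis) {
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(a, perm)
    n <- dim(ap)[1]
    m <- matrix(0, n, n)
    for (j in seq_len(n)) {
      idx <- (j - r):(j + r)
      keep <- idx >= 1 & idx <= n
      m[idx[keep], j] <- k[keep]
    }
    out <- crossprod(m, matrix(ap, nrow = n))
    aperm(array(out, dim = dim(ap)), order(perm))
  }
  out <- blur_axis(blur_axis(blur_axis(a, 1L), 2L), 3L)
  ones <- blur_axis(blur_axis(blur_axis(array(1, dim(a)), 1L), 2L), 3L)
  out / ones
}

# Clip each channel to [0,1] and renormalize voxelwise to the simplex.
renormalize_simplex <- function(g, w, c, b) {
  g <- clip01(g); w <- clip01(w); c <- clip01(c); b <- clip01(b)
  s <- g + w + c + b
  dead <- s <= 0
  if (any(dead)) { b[dead] <- 1; s[dead] <- 1 }
  list(g = g / s, w = w / s, c = c / s, b = b / s)
}

#' Generate one longitudinal phantom pair
#'
#' Builds the baseline map set, injects the specified GM -> CSF probability
#' transfer in the boundary band to form the follow-up set, and applies
#' independent noise to both. With `atrophy_rate = 0` and `noise_sd = 0` the
#' two map sets are identical; with `noise_sd = 0` total GM loss equals total
#' CSF gain exactly. Identical seeds give bit-identical output.
#'
#' @param spec An [phantom_spec()] object.
#' @return List with elements `t` and `tt` ([probability_map_set]s) and
#'   `truth` (list: logical `atrophy_mask`, numeric `injected_gm_loss`).
#' @export
generate_phantom_pair <- function(spec) {
  stopifnot(inherits(spec, "atrophy_phantom_spec"))
  d <- phantom_distance(spec)
  r <- spec$structure_radii
  g <- array(as.numeric(d >= r[1] & d < r[2]), dim(d))
  w <- array(as.numeric(d >= r[2] & d < r[3]), dim(d))
  c_ <- array(as.numeric(d < r[1]), dim(d))
  if (spec$blur_sigma > 0) {
    g <- gaussian_blur3d(g, spec$blur_sigma)
    w <- gaussian_blur3d(w, spec$blur_sigma)
    c_ <- gaussian_blur3d(c_, spec$blur_sigma)
  }
  b <- clip01(1 - g - w - c_)  # background is the closure channel
  # snap blur dust to exact zero so "tissue absent" stays crisp
  snap <- function(v) { v[v < 1e-12] <- 0; v }
  g <- snap(g); w <- snap(w); c_ <- snap(c_); b <- snap(b)

  mask <- g > 0 & d < r[1] + spec$boundary_width
  loss <- array(0, dim(d))
  loss[mask] <- spec$atrophy_rate * g[mask]
  g2 <- g - loss
  c2 <- c_ + loss

  add_noise <- function(g, w, c, b, seeds) {
    if (spec$noise_sd == 0) return(list(g = g, w = w, c = c, b = b))
    n <- length(g)
    pert <- with_seed(seeds, {
      list(g = g + rnorm(n, sd = spec$noise_sd),
           w = w + rnorm(n, sd = spec$noise_sd),
           c = c + rnorm(n, sd = spec$noise_sd),
           b = b + rnorm(n, sd = spec$noise_sd))
    })
    renormalize_simplex(array(pert$g, dim(g)), array(pert$w, dim(g)),
                        array(pert$c, dim(g)), array(pert$b, dim(g)))
  }
  seeds <- derive_seeds(spec$seed, 2L)
  m1 <- add_noise(g, w, c_, b, seeds[1])
  m2 <- add_noise(g2, w, c2, b, seeds[2])

  list(t = probability_map_set(m1$g, m1$w, m1$c, m1$b, timepoint = "t"),
       tt = probability_map_set(m2$g, m2$w, m2$c, m2$b, timepoint = "tt"),
       truth = list(atrophy_mask = mask, injected_gm_loss = loss))
}

#' Label volume matching the phantom geometry
#'
#' Regions: 1 = GM boundary band (where atrophy is injected), 2 = outer GM
#' shell, 3 = WM surround, 4 = CSF core; 0 = background. Labels are assigned
#' from the noise-free geometry, so they are identical across time points and
#' subjects sharing a geometry.
#'
#' @param spec An [phantom_spec()] object.
#' @return A [label_volume] on the phantom grid.
#' @export
phantom_labels <- function(spec) {
  d <- phantom_distance(spec)
  r <- spec$structure_radii
  lab <- array(0L, dim(d))
  lab[d < r[1]] <- 4L
  lab[d >= r[1] & d < r[2]] <- ifelse(
    d[d >= r[1] & d < r[2]] < r[1] + spec$boundary_width, 1L, 2L)
  lab[d >= r[2] & d < r[3]] <- 3L
  label_volume(lab, c(`1` = "gm_boundary", `2` = "gm_outer",
                      `3` = "wm_surround", `4` = "csf_core"))
}

#' Generate a synthetic diagnostic cohort
#'
#' Creates `n_per_group` phantom subjects per diagnostic group; groups differ
#' only in their atrophy rate (plus independent noise). Per-subject seeds are
#' derived deterministically from `seed`.
#'
#' @param n_per_group Subjects per group (>= 1).
#' @param atrophy_rates_by_group Named numeric vector, one atrophy rate per
#'   group (names are the group labels, e.g. `c(NL = 0, AD = 0.6)`).
#' @param base_spec Template [phantom_spec()]; its `atrophy_rate` and `seed`
#'   are overridden per subject.
#' @param seed Cohort seed.
#' @return List of subjects, each a list with `subject_id`, `group`, `maps_t`,
#'   `maps_tt`, `truth`, and `spec`.
#' @export
make_cohort <- function(n_per_group, atrophy_rates_by_group, base_spec, seed = 1L) {
  if (n_per_group < 1L) stopf("n_per_group must be >= 1")
  groups <- names(atrophy_rates_by_group)
  if (is.null(groups) || anyDuplicated(groups)) {
    stopf("atrophy_rates_by_group must be a named vector with distinct groups")
  }
  n_total <- n_per_group * length(groups)
  seeds <- derive_seeds(seed, n_total)
  subjects <- vector("list", n_total)
  i <- 0L
  for (grp in groups) {
    for (k in seq_len(n_per_group)) {
      i <- i + 1L
      spec_i <- base_spec
      spec_i$atrophy_rate <- unname(atrophy_rates_by_group[[grp]])
      spec_i$seed <- seeds[i]
      pair <- generate_phantom_pair(spec_i)
      subjects[[i]] <- list(subject_id = sprintf("%s_%03d", grp, k),
                            group = grp, maps_t = pair$t, maps_tt = pair$tt,
                            truth = pair$truth, spec = spec_i)
    }
  }
  subjects
}
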