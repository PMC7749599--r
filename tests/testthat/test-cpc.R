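test_that("background closure follows the subtraction rule", {
  g <- array(c(0.6, 0.2, 0.7), c(3, 1, 1))
  w <- array(c(0.3, 0.2, 0.7), c(3, 1, 1))
  c_ <- array(c(0.1, 0.2, 0.0), c(3, 1, 1))
  maps <- close_background(g, w, c_)
  expect_equal(as.numeric(maps$b), c(0.0, 0.4, 0.0))
  expect_identical(as.logical(maps$valid), c(TRUE, TRUE, FALSE))
  expect_error(close_background(g, w, array(0, c(2, 1, 1))), "shape")
})

test_that("thresholding zeroes small components and renormalizes", {
  expect_equal(threshold_and_renormalize(c(0.1, 0.5, 0.3, 0.1), 0.2),
               c(0, 0.625, 0.375, 0))
  expect_equal(threshold_and_renormalize(rep(0.25, 4), 0.2), rep(0.25, 4))
  expect_equal(threshold_and_renormalize(c(1, 0, 0, 0), 0.2), c(1, 0, 0, 0))
  m <- rbind(c(0.1, 0.5, 0.3, 0.1), rep(0.25, 4))
  out <- threshold_and_renormalize(m, 0.2)
  expect_equal(out[1, ], c(0, 0.625, 0.375, 0))
  expect_equal(rowSums(out), c(1, 1))
  expect_error(threshold_and_renormalize(c(0, 0, 0, 0), 0.2), "sum to 1")
  expect_error(threshold_and_renormalize(c(0.3, 0.3, 0.3, 0.1), 0.5),
               "below the threshold")
  # a probability 4-vector always keeps a component at tau < 0.25
  for (i in 1:50) {
    p <- as.numeric(random_simplex_rows(1))
    expect_equal(sum(threshold_and_renormalize(p, 0.2)), 1)
  }
})

test_that("assembled systems have the stated structural dimensions", {
  set.seed(21)
  neigh_t <- random_simplex_rows(27L)
  neigh_tt <- random_simplex_rows(27L)
  total_eq <- 0L
  total_unknowns <- 0L
  for (target in c("g", "w", "c", "b")) {
    sys <- assemble_system(neigh_t, neigh_tt, target)
    expect_identical(dim(sys$design), c(27L, 4L))
    expect_length(sys$response, 27L)
    total_eq <- total_eq + length(sys$response)
    total_unknowns <- total_unknowns + ncol(sys$design)
  }
  expect_identical(total_eq, 108L)      # 3x3x3 voxels x 4 target tissues
  expect_identical(total_unknowns, 16L) # the full CPC matrix
  expect_equal(assemble_system(neigh_t, neigh_tt, "c")$response, neigh_tt[, 3])
  expect_error(assemble_system(neigh_t[1:5, ], neigh_tt, 1), "equal row")
  expect_error(assemble_system(neigh_t, neigh_tt, "x"), "unknown target")
})

test_that("solve_nnls handles exact, boundary and degenerate systems", {
  A <- rbind(diag(4), diag(4))
  b <- rep(c(0.5, 0.2, 0.2, 0.1), 2)
  fit <- solve_nnls(A, b)
  expect_equal(fit$coef, c(0.5, 0.2, 0.2, 0.1), tolerance = 1e-12)
  expect_equal(fit$residual, 0, tolerance = 1e-12)

  set.seed(31)
  A <- matrix(runif(27 * 4), 27, 4)
  fit <- solve_nnls(A, -A %*% rep(1, 4))
  expect_equal(fit$coef, rep(0, 4))

  A0 <- A
  A0[, 2] <- 0
  fit <- solve_nnls(A0, A0 %*% c(1, 0, 2, 0.5))
  expect_identical(fit$identifiable, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(fit$coef[2], 0)
  expect_error(solve_nnls(matrix(1, 3, 4), rep(1, 3)), "underdetermined")
})

test_that("solver matches the 2^4 active-set brute-force oracle", {
  set.seed(41)
  worst <- 0
  for (i in 1:120) {
    A <- matrix(runif(27 * 4), 27, 4)
    b <- runif(27)
    if (i %% 3 == 0) b <- A %*% random_simplex_rows(1)[1, ] + rnorm(27, sd = 0.05)
    fit <- solve_nnls(A, b)
    oracle <- nnls_bruteforce(A, as.numeric(b))
    expect_lt(abs(fit$residual - oracle$rss), 1e-9)
    worst <- max(worst, abs(fit$residual - oracle$rss))
    expect_true(all(fit$coef >= 0))
  }
  expect_lt(worst, 1e-9)
})

test_that("fit_voxel recovers identity, known transfer maps, and caps", {
  cfg <- cpc_config()
  neigh <- pure_mixed_neighborhood()
  fit <- fit_voxel(neigh, neigh, cfg)
  expect_equal(unname(fit$elements), diag(4), tolerance = 1e-8)
  expect_true(all(fit$identifiable))
  expect_equal(unname(fit$fit_residual), rep(0, 4), tolerance = 1e-12)

  for (phi in c(0.1, 0.3, 0.5)) {
    neigh_t <- transfer_safe_neighborhood()
    neigh_tt <- apply_gm_to_csf(neigh_t, phi)
    expect_equal(threshold_and_renormalize(neigh_tt, cfg$prob_threshold),
                 neigh_tt)  # transfer stays threshold-inactive
    fit <- fit_voxel(neigh_t, neigh_tt, cfg)
    truth <- diag(4)
    truth[1, 1] <- 1 - phi
    truth[1, 3] <- phi
    expect_equal(unname(fit$elements), truth, tolerance = 1e-6)
  }

  # elements exceeding the cap are stored at the cap
  design <- do.call(rbind, rep(list(0.1 * diag(4)), 4))
  fit <- fit_voxel(design, design * 9, cpc_config())
  expect_equal(unname(diag(fit$elements)), rep(5, 4))
  expect_error(fit_voxel(neigh[1:5, ], neigh[1:5, ], cfg), "min_valid_voxels")
})

test_that("cap equals 1/threshold by default", {
  expect_equal(cpc_config()$cpc_cap, 5)
  expect_equal(cpc_config(prob_threshold = 0.25)$cpc_cap, 4)
  expect_error(cpc_config(prob_threshold = 1.2), "prob_threshold")
})

test_that("volume sweep marks exactly the interior and is deterministic", {
  set.seed(51)
  dims <- c(7L, 7L, 7L)
  mk <- function() {
    m <- random_simplex_rows(prod(dims))
    probability_map_set(array(m[, 1], dims), array(m[, 2], dims),
                        array(m[, 3], dims), array(m[, 4], dims))
  }
  maps_t <- mk()
  maps_tt <- mk()
  cpc <- compute_cpc_volume(maps_t, maps_tt)
  interior <- array(FALSE, dims)
  interior[2:6, 2:6, 2:6] <- TRUE
  expect_identical(as.logical(cpc$validity_mask), as.logical(interior))
  expect_true(all(cpc$channels >= 0 & cpc$channels <= 5))
  cpc2 <- compute_cpc_volume(maps_t, maps_tt)
  expect_identical(cpc$channels, cpc2$channels)
  expect_error(compute_cpc_volume(maps_t, generate_phantom_pair(
    small_sphere_spec())$t), "different grids")
})

test_that("volume sweep agrees with the R-level per-voxel fit", {
  set.seed(61)
  dims <- c(6L, 6L, 6L)
  mk <- function() {
    m <- random_simplex_rows(prod(dims))
    probability_map_set(array(m[, 1], dims), array(m[, 2], dims),
                        array(m[, 3], dims), array(m[, 4], dims))
  }
  maps_t <- mk()
  maps_tt <- mk()
  cfg <- cpc_config()
  cpc <- compute_cpc_volume(maps_t, maps_tt, cfg)
  for (center in list(c(2, 2, 2), c(3, 4, 3), c(5, 5, 5))) {
    nt <- gather_neighborhood(maps_t, center, cfg$prob_threshold)
    ntt <- gather_neighborhood(maps_tt, center, cfg$prob_threshold)
    ref <- fit_voxel(nt, ntt, cfg)
    got <- matrix(cpc$channels[center[1], center[2], center[3], ], 4, 4,
                  byrow = TRUE)
    expect_equal(got, unname(ref$elements), tolerance = 1e-10)
  }
})

test_that("zero-change phantom yields identity CPC where identifiable", {
  pair <- generate_phantom_pair(small_sphere_spec())
  cpc <- compute_cpc_volume(pair$t, pair$t)
  dims <- dim(pair$t$g)
  checked <- 0L
  for (x in seq(2, dims[1] - 1)) for (y in seq(2, dims[2] - 1))
    for (z in seq(2, dims[3] - 1)) {
      if (!cpc$validity_mask[x, y, z]) next
      design <- gather_neighborhood(pair$t, c(x, y, z))
      if (!design_full_rank(design)) next
      ident <- cpc$identifiable[x, y, z, ]
      F_hat <- matrix(cpc$channels[x, y, z, ], 4, 4, byrow = TRUE)
      expect_equal(F_hat[ident, ], diag(4)[ident, ], tolerance = 1e-6)
      checked <- checked + 1L
    }
  expect_gt(checked, 100L)
})

test_that("atrophy phantom concentrates F_gc inside the true atrophy mask", {
  spec <- small_sphere_spec(atrophy_rate = 0.5)
  pair <- generate_phantom_pair(spec)
  cpc <- compute_cpc_volume(pair$t, pair$tt)
  f_gc <- cpc_channel(cpc, "F_gc")
  inside <- mean(f_gc[pair$truth$atrophy_mask & cpc$validity_mask], na.rm = TRUE)
  outside <- mean(f_gc[!pair$truth$atrophy_mask & cpc$validity_mask], na.rm = TRUE)
  expect_gt(inside, outside)
})

test_that("CPC volumes round-trip through disk", {
  pair <- generate_phantom_pair(small_sphere_spec(atrophy_rate = 0.3))
  cpc <- compute_cpc_volume(pair$t, pair$tt)
  prefix <- file.path(tempdir(), "roundtrip")
  write_cpc_volume(cpc, prefix)
  back <- read_cpc_volume(prefix)
  expect_identical(back$validity_mask, cpc$validity_mask)
  expect_equal(back$channels, cpc$channels, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(back$config_used$cpc_cap, 5)
})
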