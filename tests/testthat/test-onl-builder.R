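test_that("a single requested nucleus rasterizes as a sphere of the right size", {
  lv <- generate_packed_nuclei(1, c(64, 64, 64), 0.2, radius_mean = 2,
                               radius_sd = 0, axis_ratio_range = c(1, 1),
                               seed = 7)
  expect_identical(sort(unique(as.vector(lv$labels))), c(0L, 1L))
  v_expected <- 4 / 3 * pi * (2 / 0.2)^3  # voxels
  expect_lt(abs(sum(lv$labels == 1L) - v_expected) / v_expected, 0.05)
})

test_that("packing is deterministic and nuclei never overlap", {
  a <- generate_packed_nuclei(8, c(80, 80, 60), 0.25, 2, 0.2, seed = 3)
  b <- generate_packed_nuclei(8, c(80, 80, 60), 0.25, 2, 0.2, seed = 3)
  expect_identical(a$labels, b$labels)
  # exhaustive voxel scan: rebuild each ellipsoid from the recorded geometry
  # and verify no voxel satisfies two ellipsoid equations at once
  d <- dim(a$labels)
  idx <- which(a$labels > 0)
  ai <- arrayInd(idx, d)
  inside_count <- integer(length(idx))
  for (k in seq_len(8)) {
    ctr <- a$meta$centers[k, ]
    ax <- a$meta$semi_axes[k, ] / a$voxel_size
    q <- ((ai[, 1] - ctr[1]) / ax[1])^2 + ((ai[, 2] - ctr[2]) / ax[2])^2 +
      ((ai[, 3] - ctr[3]) / ax[3])^2
    inside_count <- inside_count + (q <= 1)
  }
  expect_true(all(inside_count <= 1L))
})

test_that("unachievable packing fails loudly, reporting progress", {
  expect_error(
    generate_packed_nuclei(50, c(40, 40, 40), 0.25, 2, 0.1, seed = 1),
    "packing")
  expect_error(
    generate_packed_nuclei(6, c(36, 36, 36), 0.25, 2, 0, max_attempts = 5L,
                           max_volume_fraction = 0.55, seed = 1),
    "placed")
})

test_that("inverted painting splits each nucleus into equal concentric halves", {
  lv <- ball_labels(radius_vox = 10, voxel = 0.2)
  pars <- chromatin_params()
  ri <- assign_inverted(lv, pars)
  idx <- which(lv$labels == 1L)
  v <- length(idx)
  frac_n2 <- mean(ri$ri[idx] == pars$n2)
  expect_lt(abs(frac_n2 - 0.5), 0.01)
  expect_lt(abs(mean(ri$ri[idx]) - (pars$n1 + pars$n2) / 2), 0.001)
  # the dense core of a digitized ball is concentric with radius R * 2^(-1/3)
  ctr <- (dim(lv$labels)[1] + 1) / 2
  ai <- arrayInd(idx, dim(lv$labels))
  r <- sqrt(rowSums((ai - ctr)^2))
  r_core_max <- max(r[ri$ri[idx] == pars$n2])
  expect_lt(abs(r_core_max - 10 * 2^(-1 / 3)), 1)
  # background is the surround index
  expect_identical(unique(as.vector(ri$ri[lv$labels == 0L])), pars$n0)
})

test_that("tiny nuclei get the uniform mean index with a warning", {
  labs <- array(0L, c(8, 8, 8)); labs[4:5, 4, 4] <- 1L
  lv <- labeled_volume(labs, 0.2)
  expect_warning(ri <- assign_inverted(lv), "voxels")
  expect_equal(unique(ri$ri[labs == 1L]), (1.357 + 1.382) / 2)
})

test_that("chromocenter painting matches the inverted phase budget exactly", {
  lv <- generate_packed_nuclei(5, c(72, 72, 60), 0.25, 2, 0.15, seed = 5)
  pars <- chromatin_params()
  inv <- assign_inverted(lv, pars)
  cc <- assign_chromocenters(lv, pars, seed = 9)
  cc2 <- assign_chromocenters(lv, pars, seed = 9)
  expect_identical(cc$ri, cc2$ri)  # determinism
  nuc <- split(which(lv$labels > 0), lv$labels[lv$labels > 0])
  for (idx in nuc) {
    expect_lt(abs(mean(cc$ri[idx] == pars$n2) - 0.5), 0.01)
    # the two architectures differ only in arrangement, not in composition
    expect_lt(abs(mean(cc$ri[idx]) - mean(inv$ri[idx])), 0.001)
  }
  expect_true(all(cc$meta$nuclei$n_cc >= 8 & cc$meta$nuclei$n_cc <= 12))
  cc1 <- assign_chromocenters(lv, pars, seed = 9, n_cc = 1)
  expect_true(all(cc1$meta$nuclei$n_cc == 1L))
})

test_that("smoothing conserves integrated optical path and acts as a Gaussian", {
  lv <- ball_labels(radius_vox = 8, voxel = 0.2)
  pars <- chromatin_params()
  ri <- assign_inverted(lv, pars)
  expect_identical(smooth_and_embed(ri, pars, sigma = 0)$ri, ri$ri)
  sm <- smooth_and_embed(ri, pars, sigma = 2)
  path0 <- sum(ri$ri - pars$n0)
  expect_lt(abs(sum(sm$ri - pars$n0) - path0) / path0, 1e-3)
  # point impulse spreads into a 3D Gaussian of conserved integral
  h <- 0.05
  imp <- ri_volume(array(1.33, c(32, 32, 32)), 0.2)
  imp$ri[16, 16, 16] <- 1.33 + h
  smi <- smooth_and_embed(imp, chromatin_params(), sigma = 2)
  expect_lt(abs(sum(smi$ri - 1.33) - h) / h, 1e-9)
  peak_expected <- h / ((2 * pi)^1.5 * 2^3)
  expect_lt(abs(max(smi$ri - 1.33) - peak_expected) / peak_expected, 0.01)
})

test_that("constructor invariants are enforced", {
  expect_error(labeled_volume(array(-1L, c(2, 2, 2)), 0.2), "non-negative")
  expect_error(labeled_volume(matrix(0L, 2, 2), 0.2), "3D")
  expect_error(chromatin_params(n1 = 1.4, n2 = 1.38), "n2 >= n1")
  expect_error(chromatin_params(n_cc_range = c(5, 2)), "n_cc_range")
  expect_error(ri_volume(array(NaN, c(2, 2, 2)), 0.2), "non-finite")
})
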