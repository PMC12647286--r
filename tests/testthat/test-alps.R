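test_that("alps_index and variant_alps follow their defining ratios", {
  reg <- list(projDxx = 1.2e-3, assocDxx = 1.0e-3,
              projDyy = 0.8e-3, assocDzz = 0.7e-3)
  expect_equal(alps_index(reg), 1.1e-3 / 0.75e-3, tolerance = 1e-12)
  expect_equal(alps_index(list(projDxx = 1e-3, assocDxx = 1e-3,
                               projDyy = 1e-3, assocDzz = 1e-3)), 1)
  expect_equal(variant_alps(list(ccbDzz = 0.9e-3, ccbDyy = 0.6e-3), "ccb"), 1.5)
  expect_equal(variant_alps(list(ccgDyy = 1e-3, ccgDzz = 1e-3), "ccg"), 1)
  expect_error(alps_index(list(projDxx = 1, assocDxx = 1,
                               projDyy = -1, assocDzz = 0)),
               "non-positive denominator")
  expect_error(variant_alps(list(ccbDzz = 1), "ccq"))
})

test_that("indices are invariant to a global diffusivity scale", {
  reg <- list(projDxx = 1.2e-3, assocDxx = 1.0e-3, projDyy = 0.8e-3,
              assocDzz = 0.7e-3, ccgDyy = 5e-4, ccgDzz = 4e-4,
              ccbDzz = 6e-4, ccbDyy = 5e-4, ccsDyy = 5e-4, ccsDzz = 5e-4)
  scaled <- lapply(reg, `*`, 3.7)
  for (f in list(alps_index,
                 function(r) variant_alps(r, "ccg"),
                 function(r) variant_alps(r, "ccb"),
                 function(r) variant_alps(r, "ccs"))) {
    expect_equal(f(reg), f(scaled), tolerance = 1e-12)
  }
})

test_that("regional means average and pool as specified", {
  ph <- build_phantom(phantom_spec())
  maps <- tensor_maps(fit_tensor(simulate_dwi(ph, snr = Inf)))
  reg <- regional_means(maps)
  # pooling: proj = proj_L + proj_R voxels
  expect_equal(unname(reg$voxels["proj"]), 16L)
  vox <- which(ph$labels %in% c(1L, 2L))
  expect_equal(reg$projDxx, mean(maps$Dxx[vox]), tolerance = 1e-12)
  # error contracts
  labs <- ph$labels
  labs[labs == 1L | labs == 2L] <- 0L
  expect_error(regional_means(maps, labs), "empty region: proj")
  expect_error(regional_means(maps, array(0L, c(2, 2, 2))), "grid")
})

test_that("isotropic phantom gives all indices exactly 1 when noiseless", {
  spec <- tiny_phantom_spec(pvs_fraction = 0, lambda_par = 0.8e-3,
                            lambda_perp = 0.8e-3)
  reg <- regional_means(tensor_maps(fit_tensor(simulate_dwi(
    build_phantom(spec), snr = Inf))))
  idx <- alps_indices(reg)
  for (v in c("alps", "ccgALPS", "ccbALPS", "ccsALPS")) {
    expect_equal(idx[[v]], 1, tolerance = 1e-9)
  }
  # and within 3 SE of 1 across noisy replicates
  n_rep <- 25L
  noisy <- vapply(seq_len(n_rep), function(i) {
    alps_index(regional_means(tensor_maps(fit_tensor(simulate_dwi(
      build_phantom(spec), snr = 20, seed = 300 + i)))))
  }, numeric(1))
  expect_lt(abs(mean(noisy) - 1), 3 * stats::sd(noisy) / sqrt(n_rep))
})

test_that("swapping genu and splenium labels swaps their indices only", {
  ph <- build_phantom(phantom_spec(pvs_fraction = c(
    proj_L = 0.1, proj_R = 0.1, assoc_L = 0.1, assoc_R = 0.1,
    ccg = 0.05, ccb = 0.1, ccs = 0.2)))
  maps <- tensor_maps(fit_tensor(simulate_dwi(ph, snr = Inf)))
  idx <- alps_indices(regional_means(maps))
  swapped <- ph$labels
  swapped[ph$labels == 5L] <- 7L
  swapped[ph$labels == 7L] <- 5L
  idx_sw <- alps_indices(regional_means(maps, swapped))
  expect_equal(idx_sw$ccgALPS, idx$ccsALPS, tolerance = 1e-12)
  expect_equal(idx_sw$ccsALPS, idx$ccgALPS, tolerance = 1e-12)
  expect_equal(idx_sw$alps, idx$alps, tolerance = 1e-12)
  expect_equal(idx_sw$ccbALPS, idx$ccbALPS, tolerance = 1e-12)
})

test_that("fitted ccb anisotropy grows with the perivascular fraction", {
  ratios <- vapply(seq(0, 0.5, by = 0.1), function(f) {
    D <- fit_phantom_region(tiny_phantom_spec(pvs_fraction = f), "ccb")
    D[["Dzz"]] / D[["Dyy"]]
  }, numeric(1))
  expect_true(all(diff(ratios) >= -1e-12))
})

test_that("delta metrics subtract evening from morning", {
  expect_equal(delta_metrics(list(alps = 1.40), list(alps = 1.45))$alps, 0.05)
  same <- list(alps = 1.2, projDxx = 5e-4)
  expect_equal(unlist(delta_metrics(same, same)), c(alps = 0, projDxx = 0))
  expect_error(delta_metrics(NULL, same), "both sessions")
})

test_that("framewise displacement follows the Power convention", {
  tr <- matrix(0, 4, 6)
  fd0 <- framewise_displacement(tr)
  expect_equal(fd0$fd, rep(0, 4))
  expect_equal(fd0$mean_fd, 0)
  # single 0.1 mm x-translation step
  tr1 <- tr; tr1[3:4, 1] <- 0.1
  expect_equal(framewise_displacement(tr1)$fd, c(0, 0, 0.1, 0))
  # single 0.002 rad rotation step with r = 50 mm -> 0.1 mm
  tr2 <- tr; tr2[2:4, 5] <- 0.002
  expect_equal(framewise_displacement(tr2)$fd[2], 0.1)
  # invariance to constant offsets
  tr3 <- matrix(rnorm(24), 4, 6)
  off <- framewise_displacement(tr3 + rep(1, 4) %o% rnorm(6))
  expect_equal(off$fd, framewise_displacement(tr3)$fd, tolerance = 1e-12)
  expect_warning(framewise_displacement(matrix(0, 1, 6)), "single-volume")
})
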