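cube_from_matrix <- function(per_pixel, n_bins = 8) {
  # each pixel's histogram is flat with the given total
  arr <- array(0, c(nrow(per_pixel), ncol(per_pixel), n_bins))
  for (b in seq_len(n_bins)) arr[, , b] <- per_pixel / n_bins
  new_decay_cube(arr, channel = "other")
}

test_that("spatial binning sums the (2b+1)^2 sliding kernel", {
  # uniform 100 photons/px: interior pixels reach 2500 at bin factor 2
  u <- cube_from_matrix(matrix(100, 11, 11), n_bins = 4)
  b2 <- bin_pixels(u, 2)
  totals <- apply(b2$counts, c(1, 2), sum)
  expect_equal(totals[6, 6], 2500)
  expect_equal(totals[3, 3], 2500)     # any interior pixel
  expect_lt(totals[1, 1], 2500)        # zero-padded corner

  # bin factor 3 sums 49 pixels
  b3 <- bin_pixels(u, 3)
  expect_equal(apply(b3$counts, c(1, 2), sum)[6, 6], 4900)

  # identity at bin factor 0
  expect_identical(bin_pixels(u, 0)$counts, u$counts)

  # a delta spreads into a (2b+1)^2 block of copies
  d <- matrix(0, 7, 7); d[4, 4] <- 13
  bd <- bin_pixels(cube_from_matrix(d, 2), 1)
  tot <- apply(bd$counts, c(1, 2), sum)
  expect_equal(tot[3:5, 3:5], matrix(13, 3, 3))
  expect_equal(sum(tot != 0), 9)

  expect_error(bin_pixels(cube_from_matrix(matrix(1, 4, 4)), 2), "kernel")
})

test_that("background thresholding is inclusive at the photon floor", {
  px <- matrix(c(2499, 2500, 2501, 0), 2, 2)
  cube <- cube_from_matrix(px, n_bins = 1)
  mask <- threshold_background(cube, 2500)
  expect_identical(as.vector(mask), c(FALSE, TRUE, TRUE, FALSE))
  expect_true(all(threshold_background(cube, 0)))
})

test_that("noiseless biexponential decays are recovered within 1%", {
  irf <- test_irf()
  mu <- decay_model_expected(400, 2500, 1750, 750, 0, irf)
  fit <- fit_biexponential(mu, irf)
  expect_true(fit$converged)
  expect_lt(abs(fit$tau1 - 400) / 400, 0.01)
  expect_lt(abs(fit$tau2 - 2500) / 2500, 0.01)
  expect_lt(abs(fit$alpha1_pct - 70), 1)
  expect_lt(abs(fit$tau_m - 1030) / 1030, 0.01)
})

test_that("single-exponential truth collapses cleanly", {
  irf <- test_irf()
  spec <- emitter_spec(1200, 1200, 1, 0, 1e4)
  y <- simulate_decay(spec, irf, rng_seed = 3)
  fit <- fit_biexponential(y, irf)
  expect_lt(abs(fit$tau_m - 1200) / 1200, 0.02)
})

test_that("fitting errors on an all-zero histogram", {
  expect_error(fit_biexponential(numeric(256), test_irf()), "all-zero")
})

test_that("the Poisson optimum conserves total intensity", {
  irf <- test_irf()
  for (s in 1:5) {
    y <- simulate_decay(ref_emitter(5000, 0.2), irf, rng_seed = s)
    fit <- fit_biexponential(y, irf)
    mu <- decay_model_expected(fit$tau1, fit$tau2, fit$alpha1_raw,
                               fit$alpha2_raw, fit$c_background, irf)
    expect_lt(abs(sum(mu) - sum(y)) / sum(y), 1e-4)
  }
})

test_that("randomised initialisation does not flip component labels", {
  irf <- test_irf()
  y <- simulate_decay(ref_emitter(10000), irf, rng_seed = 17)
  ref <- fit_biexponential(y, irf)
  set.seed(99)
  for (i in 1:5) {
    init <- c(tau1 = runif(1, 100, 900), tau2 = runif(1, 1500, 4000),
              a1 = runif(1, 1000, 9000), a2 = runif(1, 1000, 9000),
              c_bg = runif(1, 0, 1))
    fit <- fit_biexponential(y, irf, init = init)
    expect_lte(fit$tau1, fit$tau2)
    expect_lt(abs(fit$tau1 - ref$tau1), 0.02 * ref$tau1)
    expect_lt(abs(fit$tau2 - ref$tau2), 0.02 * ref$tau2)
    expect_lt(abs(fit$alpha1_pct - ref$alpha1_pct), 1)
  }
})

test_that("mean lifetime is the amplitude-weighted mean", {
  f <- list(tau1 = 400, tau2 = 2500, alpha1_raw = 70, alpha2_raw = 30)
  expect_equal(mean_lifetime(f), 1030)
  f2 <- list(tau1 = 1500, tau2 = 1500, alpha1_raw = 2, alpha2_raw = 5)
  expect_equal(mean_lifetime(f2), 1500)
  f3 <- list(tau1 = 800, tau2 = 2500, alpha1_raw = 3, alpha2_raw = 0)
  expect_equal(mean_lifetime(f3), 800)
  expect_error(mean_lifetime(list(tau1 = 1, tau2 = 2, alpha1_raw = 0,
                                  alpha2_raw = 0)), "amplitude")
})

test_that("alpha normalisation yields percentages summing to exactly 100", {
  expect_equal(unname(normalize_alpha(list(alpha1_raw = 3, alpha2_raw = 1))),
               c(75, 25))
  expect_equal(unname(normalize_alpha(list(alpha1_raw = 7.3, alpha2_raw = 7.3))),
               c(50, 50))
  expect_equal(unname(normalize_alpha(list(alpha1_raw = 2, alpha2_raw = 0))),
               c(100, 0))
  set.seed(5)
  for (i in 1:20) {
    a <- runif(2, 0, 100)
    p <- normalize_alpha(list(alpha1_raw = a[1], alpha2_raw = a[2]))
    expect_identical(sum(p), 100)   # exact, by complement construction
  }
  expect_error(normalize_alpha(list(alpha1_raw = 0, alpha2_raw = 0)),
               "amplitude")
})

test_that("whole-image fitting masks background and is deterministic", {
  profs <- two_type_profiles()
  profs[[1]]$area_px <- c(60, 0.05); profs[[2]]$area_px <- c(60, 0.05)
  scene <- build_scene(profs, field_size = c(48, 48), n_cells = 2,
                       rng_seed = 13, background_rate = 0)
  fm <- fit_image(scene$cubes$nadph, scene$irf$nadph, bin_factor = 2,
                  min_photons = 2500)
  bg <- scene$label_image == 0
  # zero-background scenes cannot pass the floor away from cells
  eroded_bg <- bg
  eroded_bg[as.vector(bin_pixels(cube_from_matrix(1 * !bg, 1), 2)$counts) > 0] <- FALSE
  expect_false(any(fm$valid_mask[eroded_bg]))
  # fitted values only where valid
  expect_true(all(is.na(fm$tau_m[!fm$valid_mask & eroded_bg])))

  fm2 <- fit_image(scene$cubes$nadph, scene$irf$nadph, bin_factor = 2,
                   min_photons = 2500)
  expect_identical(fm$tau_m, fm2$tau_m)
  expect_identical(fm$valid_mask, fm2$valid_mask)
})

test_that("a homogeneous field yields tightly clustered per-pixel lifetimes", {
  irf <- test_irf()
  spec <- ref_emitter(photons = 260, bg = 0.01)  # ~6500 per binned pixel
  nr <- 14
  arr <- array(0L, c(nr, nr, irf$n_bins))
  set.seed(23)
  for (i in seq_len(nr)) for (j in seq_len(nr)) {
    arr[i, j, ] <- simulate_decay(spec, irf)
  }
  cube <- new_decay_cube(arr, channel = "NADPH")
  fm <- fit_image(cube, irf, bin_factor = 2, min_photons = 2500)
  interior <- fm$tau_m[3:(nr - 2), 3:(nr - 2)]
  expect_true(all(is.finite(interior)))
  expect_lt(sd(interior) / mean(interior), 0.05)
  expect_lt(abs(median(interior) - 1030) / 1030, 0.05)
})
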