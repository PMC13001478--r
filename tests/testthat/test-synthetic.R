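test_that("IRF is unit-area, centred, and collapses to a delta", {
  irf <- make_irf(fwhm_ps = 220, center_ps = 1500, n_bins = 256)
  expect_equal(sum(irf$weights), 1, tolerance = 1e-9)
  expect_true(all(irf$weights >= 0))
  # mode bin is the bin containing the centre
  expect_equal(which.max(irf$weights), which.min(abs(irf$time_ps - 1500)))

  # degenerate width: one bin carries everything
  delta <- make_irf(fwhm_ps = 0, center_ps = 1500)
  expect_equal(sum(delta$weights != 0), 1)
  expect_equal(which(delta$weights == 1), which.min(abs(delta$time_ps - 1500)))

  expect_error(make_irf(220, center_ps = 2e4), "window")
  expect_error(make_irf(220, 1500, n_bins = 8))
})

test_that("simulated decays are deterministic under a seed and conserve photons", {
  irf <- test_irf()
  spec <- ref_emitter(photons = 5000, bg = 0.1)
  y1 <- simulate_decay(spec, irf, rng_seed = 42)
  y2 <- simulate_decay(spec, irf, rng_seed = 42)
  expect_identical(y1, y2)
  expect_true(all(y1 == floor(y1)) && all(y1 >= 0))

  # expectation: photons_per_pixel + n_bins * background_rate, within 3 SE
  tots <- vapply(1:200, function(i) sum(simulate_decay(spec, irf, rng_seed = i)),
                 numeric(1))
  expected <- 5000 + 256 * 0.1
  se <- sd(tots) / sqrt(length(tots))
  expect_lt(abs(mean(tots) - expected), 3 * se + 1e-9)
})

test_that("model collapses to a single exponential when tau1 = tau2", {
  irf <- test_irf()
  mu_collapsed <- decay_model_expected(1800, 1800, 700, 300, 0.5, irf)
  mu_single <- decay_model_expected(1800, 1800, 0, 1000, 0.5, irf)
  expect_equal(mu_collapsed, mu_single, tolerance = 1e-12)
})

test_that("empirical mean arrival time matches the photon-weighted tau_m", {
  # delta IRF at t = 0, no background, huge photon budget: the empirical
  # mean arrival time estimates tau_m = a1 tau1 + a2 tau2 (photon weights).
  # A doubled window and fine bins keep wrap-around and bin-quantisation
  # offsets (each ~1-2% on the default axis) out of the comparison.
  irf0 <- make_irf(fwhm_ps = 0, center_ps = 2, n_bins = 4096,
                   bin_width_ps = 25000 / 4096)
  spec <- emitter_spec(400, 2000, 0.6, background_rate = 0,
                       photons_per_pixel = 1e6)
  y <- simulate_decay(spec, irf0, rng_seed = 7)
  t <- irf0$time_ps - irf0$time_ps[1]
  tbar <- sum(y * t) / sum(y)
  tau_m_true <- emitter_tau_m(spec)  # 0.6*400 + 0.4*2000 = 1040
  expect_equal(tau_m_true, 1040)
  expect_lt(abs(tbar - tau_m_true) / tau_m_true, 0.01)
})

test_that("high-photon histogram shape converges to the analytic curve", {
  irf0 <- make_irf(fwhm_ps = 0, center_ps = 12500 / 512)
  spec <- emitter_spec(400, 2500, 0.7, 0, 1e6)
  y <- simulate_decay(spec, irf0, rng_seed = 11)
  mu <- decay_model_expected(400, 2500, 7e5, 3e5, 0, irf0)
  expect_lt(max(abs(y / sum(y) - mu / sum(mu))), 0.01)
})

test_that("scenes have disjoint labelled footprints with one truth row each", {
  profs <- two_type_profiles()
  scene <- build_scene(profs, field_size = c(150, 150), n_cells = 12,
                       rng_seed = 5)
  labs <- sort(unique(as.vector(scene$label_image)))
  expect_identical(labs, 0:12)
  expect_identical(sort(scene$truth_table$cell_id), 1:12)
  # realised areas match the footprints
  for (i in c(1, 7, 12)) {
    expect_equal(sum(scene$label_image == i), scene$truth_table$area_px[i])
  }
  # determinism
  scene2 <- build_scene(profs, field_size = c(150, 150), n_cells = 12,
                        rng_seed = 5)
  expect_identical(scene$label_image, scene2$label_image)
  expect_identical(scene$cubes$nadph$counts, scene2$cubes$nadph$counts)
  expect_equal(scene$truth_table, scene2$truth_table)
})

test_that("a single-cell scene labels exactly background and one cell", {
  scene <- build_scene(two_type_profiles(), field_size = c(64, 64),
                       n_cells = 1, rng_seed = 2)
  expect_identical(sort(unique(as.vector(scene$label_image))), 0:1)
})

test_that("abundance sampling respects binomial variation", {
  profs <- two_type_profiles()
  profs[[1]]$area_px <- c(45, 0.1)   # small footprints keep the field compact
  profs[[2]]$area_px <- c(45, 0.1)
  scene <- build_scene(profs, field_size = c(220, 220), n_cells = 200,
                       rng_seed = 9)
  counts <- table(scene$truth_table$cell_type)
  ci <- qbinom(c(0.005, 0.995), 200, 0.5)
  expect_gte(min(counts), ci[1])
  expect_lte(max(counts), ci[2])
})

test_that("cells drawn below 70 pixels are flagged small in the truth table", {
  profs <- two_type_profiles()
  small <- profs[[1]]
  small$name <- "tiny"
  small$abundance <- 1
  small$area_px <- c(40, 0.15)
  scene <- build_scene(list(small), field_size = c(100, 100), n_cells = 10,
                       rng_seed = 3)
  expect_true(any(scene$truth_table$small_mask))
  expect_identical(scene$truth_table$small_mask,
                   scene$truth_table$area_px < 70)
})

test_that("impossible placement densities error informatively", {
  profs <- two_type_profiles()
  expect_error(build_scene(profs, field_size = c(40, 40), n_cells = 30,
                           rng_seed = 1),
               "density")
})

test_that("feature tables have the documented shape and per-type means", {
  profs <- default_pbmc_profiles("quiescent")
  tab <- sample_feature_table(profs, n_per_type = 100, rng_seed = 21)
  expect_equal(nrow(tab), 100 * length(profs))
  expect_true(all(omi_variables() %in% names(tab)))
  expect_identical(tab, sample_feature_table(profs, 100, rng_seed = 21))
  # per-type empirical means track the profile means
  mono <- tab[tab$cell_type == "monocyte", ]
  expect_lt(abs(mean(mono$area_px) - 320) / 320, 0.1)
  expect_lt(abs(mean(mono$nadph_tau_m) - 1340) / 1340, 0.05)
  # tau ordering holds row-wise by construction
  expect_true(all(tab$nadph_tau1 <= tab$nadph_tau_m + 1e-9))
  expect_true(all(tab$nadph_tau_m <= tab$nadph_tau2 + 1e-9))
})

test_that("identical profiles give null effect sizes on every variable", {
  p <- default_pbmc_profiles("quiescent")[[1]]
  p1 <- p; p1$name <- "a"; p2 <- p; p2$name <- "b"
  tab <- sample_feature_table(list(p1, p2), n_per_type = 1000, rng_seed = 31)
  for (v in omi_variables()) {
    d <- cohens_d(tab[[v]][tab$cell_type == "a"],
                  tab[[v]][tab$cell_type == "b"])$d
    expect_lt(abs(d), 0.2)
  }
})

test_that("a configured tau_m contrast is recovered empirically", {
  profs <- two_type_profiles(d_tau_m = 1.0)
  tab <- sample_feature_table(profs, n_per_type = 1000, rng_seed = 41)
  d <- cohens_d(tab$nadph_tau_m[tab$cell_type == "helper_T"],
                tab$nadph_tau_m[tab$cell_type == "monocyte"])$d
  expect_lt(abs(d - 1.0), 0.1)
})
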