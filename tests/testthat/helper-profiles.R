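# Shared fixtures built in code.

# Small IRF on the default 256-bin / 12.5 ns axis.
test_irf <- function(fwhm = 220, center = 1500) make_irf(fwhm, center)

# The reference emitter used across fitting tests: the conventional NAD(P)H
# test point (tau1 = 400 ps, tau2 = 2500 ps, alpha1 = 70% photon fraction,
# tau_m = 1030 ps).
ref_emitter <- function(photons = 2500, bg = 0.02) {
  emitter_spec(400, 2500, 0.7, background_rate = bg,
               photons_per_pixel = photons)
}

# Two-type profile pair (lymphocyte-like vs monocyte-like) whose NAD(P)H
# tau_m contrast is calibrated to an exact Cohen's d, with the accompanying
# alpha1/area contrasts monocytes display.
two_type_profiles <- function(d_tau_m = 2.0) {
  q <- default_pbmc_profiles("quiescent")
  lym <- q[[which(vapply(q, `[[`, character(1), "name") == "helper_T")]]
  mono <- q[[which(vapply(q, `[[`, character(1), "name") == "monocyte")]]
  m1 <- lym$nadph_tau_m[1]; cv <- lym$nadph_tau_m[2]
  f <- function(m2) (m1 - m2) / sqrt(((cv * m1)^2 + (cv * m2)^2) / 2) - d_tau_m
  m2 <- stats::uniroot(f, c(m1 / 3, m1 - 1))$root
  mono$nadph_tau_m <- c(m2, cv)
  lym$abundance <- 0.5
  mono$abundance <- 0.5
  list(lym, mono)
}

# Minimal hand-built pixel_fit_map pair for aggregation tests: constant
# parameter values inside a mask, given intensity images.
mock_fitmaps <- function(nr, nc, intensity_n, intensity_f,
                         tau1 = 400, tau2 = 2400, alpha1 = 45,
                         chi2 = 1.0, valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, nr, nc)
  mk <- function(v) matrix(v, nr, nc)
  one <- function(intensity) {
    structure(list(tau1 = mk(tau1), tau2 = mk(tau2),
                   alpha1_pct = mk(alpha1),
                   tau_m = mk((alpha1 * tau1 + (100 - alpha1) * tau2) / 100),
                   chi2 = mk(chi2), n_photons = intensity,
                   valid_mask = valid, intensity = intensity,
                   bin_factor = 0L, min_photons = 0, n_failed = 0L),
              class = "pixel_fit_map")
  }
  list(nadph = one(intensity_n), fad = one(intensity_f))
}
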