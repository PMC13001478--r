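# Ground-truthed synthetic FLIM data: single decays, multi-cell fields of
# view, and direct feature-table sampling for fast statistical tests.

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. NULL seed runs in the ambient stream.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Stable sub-stream seed keyed by (seed, channel index, cell id); kept below
# 2^31 - 1.
.sub_seed <- function(seed, channel = 0L, cell = 0L) {
  (as.numeric(seed) + 999983 * channel + 7919 * cell) %% 2147483629
}

#' Decay cube container
#'
#' Per-pixel photon arrival-time histograms for one spectral channel of one
#' field of view.
#'
#' @param counts Non-negative integer array indexed (row, col, time_bin).
#' @param bin_width_ps TCSPC bin width, picoseconds.
#' @param channel One of "NADPH", "FAD", "other".
#' @return A `decay_cube`.
#' @export
new_decay_cube <- function(counts, bin_width_ps = 12500 / 256,
                           channel = c("NADPH", "FAD", "other")) {
  channel <- match.arg(channel)
  stopifnot(length(dim(counts)) == 3, all(counts >= 0), bin_width_ps > 0)
  structure(list(counts = counts, bin_width_ps = bin_width_ps,
                 channel = channel, bin_factor = 0L),
            class = "decay_cube")
}

#' @export
print.decay_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<decay_cube> %s: %d x %d px, %d time bins x %.3f ps, %.3g photons total\n",
              x$channel, d[1], d[2], d[3], x$bin_width_ps, sum(x$counts)))
  invisible(x)
}

#' Biexponential emitter specification
#'
#' Ground-truth generative parameters for one emitter. `alpha1_frac` is the
#' fraction of detected photons carried by the short component (component
#' curves are normalised to unit area before mixing), so the amplitude-
#' weighted mean lifetime equals the background-free mean photon arrival
#' time.
#'
#' @param tau1,tau2 Short / long lifetime, picoseconds (0 < tau1 <= tau2).
#' @param alpha1_frac Photon fraction of the short component, in \[0, 1\].
#' @param background_rate Expected background photons per time bin.
#' @param photons_per_pixel Expected total decay photons (Poisson mean).
#' @return An `emitter_spec`.
#' @export
emitter_spec <- function(tau1, tau2, alpha1_frac, background_rate = 0,
                         photons_per_pixel = 2500) {
  stopifnot(tau1 > 0, tau2 >= tau1, alpha1_frac >= 0, alpha1_frac <= 1,
            background_rate >= 0, photons_per_pixel > 0)
  structure(list(tau1 = tau1, tau2 = tau2, alpha1_frac = alpha1_frac,
                 background_rate = background_rate,
                 photons_per_pixel = photons_per_pixel),
            class = "emitter_spec")
}

#' True mean lifetime of an emitter spec
#' @param spec An [emitter_spec()].
#' @return Picoseconds.
#' @export
emitter_tau_m <- function(spec) {
  spec$alpha1_frac * spec$tau1 + (1 - spec$alpha1_frac) * spec$tau2
}

#' Simulate one TCSPC decay histogram
#'
#' Poisson-samples the reconvolution forward model: unit-area biexponential
#' (photon-fraction mixture), circularly convolved with the IRF over the
#' repetition window, scaled to the photon budget, plus flat background.
#'
#' @param spec An [emitter_spec()].
#' @param irf A [make_irf()] object.
#' @param rng_seed Integer seed for reproducibility (NULL = ambient RNG).
#' @return Integer vector of photon counts per bin.
#' @export
simulate_decay <- function(spec, irf, rng_seed = NULL) {
  stopifnot(inherits(spec, "emitter_spec"), inherits(irf, "flim_irf"))
  mu <- decay_model_expected(
    spec$tau1, spec$tau2,
    spec$photons_per_pixel * spec$alpha1_frac,
    spec$photons_per_pixel * (1 - spec$alpha1_frac),
    spec$background_rate, irf)
  .with_seed(rng_seed, stats::rpois(length(mu), pmax(mu, 0)))
}

# ---- cell-type profiles -----------------------------------------------------

#' Cell-type profile
#'
#' Distributional description of one cell type for the generator. Each OMI
#' quantity is given as `c(mean, cv)` and drawn per cell from a normal with
#' SD = cv * mean (clamped to its physical range). Lifetimes in picoseconds,
#' alpha fractions in percent, area in pixels; `nadph_photons` is the
#' expected NAD(P)H decay photons per pixel, and the per-cell FAD photon
#' budget is derived from the drawn optical redox ratio so that the cell's
#' expected ORR equals the draw. The long lifetime tau2 is derived per cell
#' from (tau1, tau_m, alpha1), which keeps tau1 <= tau_m <= tau2 by
#' construction.
#'
#' @param name Cell-type label.
#' @param abundance Expected fraction of cells of this type in a field.
#' @param nadph_tau1,nadph_tau_m,nadph_alpha1 NAD(P)H channel `c(mean, cv)`.
#' @param fad_tau1,fad_tau_m,fad_alpha1 FAD channel `c(mean, cv)`.
#' @param orr Optical redox ratio `c(mean, cv)`.
#' @param area_px Cell area in pixels `c(mean, cv)`.
#' @param nadph_photons Per-pixel NAD(P)H photon budget `c(mean, cv)`.
#' @param stain_lnorm Optional `c(meanlog, sdlog)` of a lognormal surface-
#'   stain intensity (a.u.), e.g. CD56 for NK cells; NA to omit.
#' @return A `cell_type_profile`.
#' @export
cell_type_profile <- function(name, abundance,
                              nadph_tau1, nadph_tau_m, nadph_alpha1,
                              fad_tau1, fad_tau_m, fad_alpha1,
                              orr, area_px, nadph_photons = c(170, 0.10),
                              stain_lnorm = NULL) {
  dists <- list(nadph_tau1 = nadph_tau1, nadph_tau_m = nadph_tau_m,
                nadph_alpha1 = nadph_alpha1, fad_tau1 = fad_tau1,
                fad_tau_m = fad_tau_m, fad_alpha1 = fad_alpha1,
                orr = orr, area_px = area_px, nadph_photons = nadph_photons)
  for (nm in names(dists)) {
    d <- dists[[nm]]
    if (length(d) != 2 || d[1] <= 0 || d[2] < 0)
      stop("profile '", name, "': ", nm, " must be c(mean > 0, cv >= 0)", call. = FALSE)
  }
  stopifnot(abundance >= 0)
  structure(c(list(name = name, abundance = abundance,
                   stain_lnorm = stain_lnorm), dists),
            class = "cell_type_profile")
}

# Normal draw parameterised by (mean, cv), clamped to [lo, hi].
.draw <- function(n, dist, lo = -Inf, hi = Inf) {
  pmin(pmax(stats::rnorm(n, dist[1], dist[2] * dist[1]), lo), hi)
}

# Long-lifetime component implied by (tau1, tau_m, alpha1 photon fraction),
# capped at a physiological ceiling: protein-bound NAD(P)H/FAD long
# components sit around 2-3.5 ns, and a longer tail carrying few photons is
# both unrealistic and barely identifiable within a 12.5 ns window.
.derive_tau2 <- function(tau1, tau_m, alpha1_frac, cap = 3500) {
  tau_m <- pmax(tau_m, tau1 * 1.02)
  pmin(pmax((tau_m - alpha1_frac * tau1) / (1 - alpha1_frac), tau_m), cap)
}

#' Default PBMC cell-type profiles
#'
#' Five peripheral-blood mononuclear cell types (helper T, cytotoxic T,
#' monocyte, B, NK) with OMI parameter distributions that emulate the
#' direction of the reported cell-type contrasts: monocytes with low NAD(P)H
#' tau_m, high NAD(P)H alpha1 and large cell area; B cells with slightly
#' elevated NAD(P)H alpha1; NK cells with a distinct ORR and FAD
#' short-lifetime signature. The "activated" condition shifts lymphocyte
#' NAD(P)H tau_m down and alpha1 up, monocyte tau_m up and alpha1 down,
#' raises ORR and lowers NAD(P)H tau1 for all types, and widens the more
#' heterogeneous variables. Abundances follow the relative cell counts of a
#' typical PBMC imaging cohort.
#'
#' Alpha values here are photon fractions (see [emitter_spec()]): a
#' conventional amplitude fraction of 70-80% for the free (short) component
#' corresponds to a photon fraction around 0.35-0.50, because the long
#' component integrates more photons per unit amplitude. Mean lifetimes are
#' photon-weighted accordingly.
#'
#' @param condition "quiescent" or "activated".
#' @return List of [cell_type_profile()] objects.
#' @export
default_pbmc_profiles <- function(condition = c("quiescent", "activated")) {
  condition <- match.arg(condition)
  if (condition == "quiescent") {
    list(
      cell_type_profile("helper_T", 0.23,
        nadph_tau1 = c(480, 0.08), nadph_tau_m = c(1600, 0.08),
        nadph_alpha1 = c(38.5, 0.08),
        fad_tau1 = c(330, 0.09), fad_tau_m = c(1530, 0.08),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.72, 0.06), area_px = c(150, 0.20)),
      cell_type_profile("cytotoxic_T", 0.23,
        nadph_tau1 = c(480, 0.08), nadph_tau_m = c(1580, 0.08),
        nadph_alpha1 = c(39, 0.08),
        fad_tau1 = c(330, 0.09), fad_tau_m = c(1520, 0.08),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.72, 0.06), area_px = c(150, 0.20)),
      cell_type_profile("monocyte", 0.18,
        nadph_tau1 = c(460, 0.08), nadph_tau_m = c(1340, 0.08),
        nadph_alpha1 = c(46.5, 0.07),
        fad_tau1 = c(320, 0.09), fad_tau_m = c(1500, 0.08),
        fad_alpha1 = c(30, 0.10),
        orr = c(0.69, 0.06), area_px = c(320, 0.22),
        nadph_photons = c(180, 0.10)),
      cell_type_profile("B", 0.15,
        nadph_tau1 = c(480, 0.08), nadph_tau_m = c(1520, 0.08),
        nadph_alpha1 = c(42, 0.08),
        fad_tau1 = c(330, 0.09), fad_tau_m = c(1510, 0.08),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.71, 0.06), area_px = c(140, 0.20)),
      cell_type_profile("NK", 0.21,
        nadph_tau1 = c(480, 0.08), nadph_tau_m = c(1580, 0.08),
        nadph_alpha1 = c(38.5, 0.08),
        fad_tau1 = c(290, 0.09), fad_tau_m = c(1450, 0.08),
        fad_alpha1 = c(33, 0.10),
        orr = c(0.66, 0.06), area_px = c(145, 0.20),
        stain_lnorm = c(log(55), 0.47))
    )
  } else {
    list(
      cell_type_profile("helper_T", 0.22,
        nadph_tau1 = c(410, 0.08), nadph_tau_m = c(1460, 0.09),
        nadph_alpha1 = c(41, 0.08),
        fad_tau1 = c(330, 0.12), fad_tau_m = c(1560, 0.09),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.78, 0.06), area_px = c(155, 0.25)),
      cell_type_profile("cytotoxic_T", 0.22,
        nadph_tau1 = c(410, 0.08), nadph_tau_m = c(1440, 0.09),
        nadph_alpha1 = c(41.5, 0.08),
        fad_tau1 = c(330, 0.12), fad_tau_m = c(1550, 0.09),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.78, 0.06), area_px = c(155, 0.25)),
      cell_type_profile("monocyte", 0.19,
        nadph_tau1 = c(400, 0.08), nadph_tau_m = c(1480, 0.09),
        nadph_alpha1 = c(38.5, 0.07),
        fad_tau1 = c(320, 0.12), fad_tau_m = c(1530, 0.09),
        fad_alpha1 = c(29, 0.10),
        orr = c(0.75, 0.06), area_px = c(340, 0.27),
        nadph_photons = c(180, 0.10)),
      cell_type_profile("B", 0.21,
        nadph_tau1 = c(410, 0.08), nadph_tau_m = c(1400, 0.09),
        nadph_alpha1 = c(44, 0.08),
        fad_tau1 = c(330, 0.12), fad_tau_m = c(1540, 0.09),
        fad_alpha1 = c(28, 0.10),
        orr = c(0.77, 0.06), area_px = c(145, 0.25)),
      cell_type_profile("NK", 0.16,
        nadph_tau1 = c(410, 0.08), nadph_tau_m = c(1440, 0.09),
        nadph_alpha1 = c(41, 0.08),
        fad_tau1 = c(290, 0.12), fad_tau_m = c(1480, 0.09),
        fad_alpha1 = c(33, 0.10),
        orr = c(0.72, 0.06), area_px = c(150, 0.25),
        stain_lnorm = c(log(55), 0.47))
    )
  }
}

# Draw per-cell OMI truth for one profile; returns a data.frame of n rows.
.draw_cells <- function(profile, n) {
  a1n <- .draw(n, profile$nadph_alpha1, 2, 98)
  t1n <- .draw(n, profile$nadph_tau1, 20)
  tmn <- .draw(n, profile$nadph_tau_m, 40)
  tmn <- pmax(tmn, t1n * 1.02)
  t2n <- .derive_tau2(t1n, tmn, a1n / 100)
  a1f <- .draw(n, profile$fad_alpha1, 2, 98)
  t1f <- .draw(n, profile$fad_tau1, 20)
  tmf <- .draw(n, profile$fad_tau_m, 40)
  tmf <- pmax(tmf, t1f * 1.02)
  t2f <- .derive_tau2(t1f, tmf, a1f / 100)
  orr <- .draw(n, profile$orr, 0.01, 0.99)
  area <- round(pmax(.draw(n, profile$area_px, 6), 6))
  phot <- .draw(n, profile$nadph_photons, 1)
  stain <- if (is.null(profile$stain_lnorm)) rep(NA_real_, n) else
    stats::rlnorm(n, profile$stain_lnorm[1], profile$stain_lnorm[2])
  data.frame(
    cell_type = profile$name,
    nadph_tau1 = t1n, nadph_tau2 = t2n, nadph_alpha1 = a1n,
    nadph_tau_m = (a1n * t1n + (100 - a1n) * t2n) / 100,
    fad_tau1 = t1f, fad_tau2 = t2f, fad_alpha1 = a1f,
    fad_tau_m = (a1f * t1f + (100 - a1f) * t2f) / 100,
    orr = orr, area_px = area, nadph_photons = phot,
    stain_intensity = stain,
    stringsAsFactors = FALSE)
}

#' Sample a per-cell OMI feature table directly
#'
#' Bypasses the imaging physics: draws the 10 OMI variables per cell straight
#' from the cell-type profiles, for fast statistical tests of the downstream
#' effect-size, heterogeneity and classification procedures.
#'
#' @param profiles List of [cell_type_profile()] objects.
#' @param n_per_type Cells drawn per profile.
#' @param rng_seed Integer seed.
#' @param condition Condition label stored in the table.
#' @param donors Donor labels assigned round-robin.
#' @return A data.frame with one row per cell: metadata (`cell_id`, `donor`,
#'   `condition`, `cell_type`), the 10 OMI variables (`nadph_tau_m`,
#'   `nadph_tau1`, `nadph_tau2`, `nadph_alpha1`, `fad_tau_m`, `fad_tau1`,
#'   `fad_tau2`, `fad_alpha1`, `orr`, `area_px`), `mean_nadph_intensity`,
#'   `chi2_max`, `stain_intensity`, and QC fields (`qc_pass`, `qc_reasons`).
#' @export
sample_feature_table <- function(profiles, n_per_type, rng_seed = NULL,
                                 condition = "quiescent",
                                 donors = c("A", "B", "C")) {
  stopifnot(n_per_type >= 1, length(profiles) >= 1)
  .with_seed(rng_seed, {
    rows <- lapply(profiles, .draw_cells, n = n_per_type)
    df <- do.call(rbind, rows)
    n <- nrow(df)
    df$cell_id <- seq_len(n)
    df$donor <- rep_len(donors, n)
    df$condition <- condition
    df$mean_nadph_intensity <- df$nadph_photons
    df$chi2_max <- pmax(stats::rnorm(n, 1.0, 0.08), 0.2)
    df$qc_pass <- TRUE
    df$qc_reasons <- ""
    df[, c("cell_id", "donor", "condition", "cell_type",
           omi_variables(), "mean_nadph_intensity", "chi2_max",
           "stain_intensity", "qc_pass", "qc_reasons")]
  })
}

#' The 10 OMI variables
#'
#' Canonical ordered names of the optical metabolic imaging variables used
#' throughout: NAD(P)H and FAD tau_m, tau1, tau2, alpha1, the optical redox
#' ratio, and cell area.
#' @return Character vector of length 10.
#' @export
omi_variables <- function() {
  c("nadph_tau_m", "nadph_tau1", "nadph_tau2", "nadph_alpha1",
    "fad_tau_m", "fad_tau1", "fad_tau2", "fad_alpha1",
    "orr", "area_px")
}

# ---- scene construction -----------------------------------------------------

# Place n axis-aligned ellipses of given areas without overlap by rejection.
.place_cells <- function(areas, nr, nc, max_tries = 400L) {
  label <- matrix(0L, nr, nc)
  pix <- vector("list", length(areas))
  for (i in seq_along(areas)) {
    r0 <- sqrt(areas[i] / pi)
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      e <- stats::runif(1, 0.75, 1.33)
      a <- r0 * e; b <- r0 / e
      if (2 * a + 2 >= nr || 2 * b + 2 >= nc) next
      cx <- stats::runif(1, a + 1, nr - a)
      cy <- stats::runif(1, b + 1, nc - b)
      xs <- max(1L, floor(cx - a)):min(nr, ceiling(cx + a))
      ys <- max(1L, floor(cy - b)):min(nc, ceiling(cy + b))
      inside <- outer(((xs - cx) / a)^2, ((ys - cy) / b)^2, "+") <= 1
      if (!any(inside)) next
      sub <- label[xs, ys, drop = FALSE]
      if (any(sub[inside] != 0L)) next
      sub[inside] <- i
      label[xs, ys] <- sub
      pix[[i]] <- which(label == i)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop(sprintf(
        "could not place cell %d of %d after %d tries; achieved density %.1f%% of the %d x %d field -- reduce n_cells or areas",
        i, length(areas), max_tries, 100 * mean(label != 0L), nr, nc),
        call. = FALSE)
    }
  }
  list(label = label, pixels = pix)
}

#' Build a ground-truthed synthetic FLIM scene
#'
#' Generates a multi-cell field of view: cell types sampled by profile
#' abundance, per-cell OMI truth drawn from the profiles, elliptical
#' footprints placed without overlap, and per-channel TCSPC decay cubes
#' Poisson-sampled from each cell's emitter through the IRF. Background
#' pixels carry only the flat background rate. One RNG sub-stream per
#' (seed, channel, cell) allows partial regeneration.
#'
#' @param profiles List of [cell_type_profile()] objects; abundances should
#'   sum to 1 (renormalised with a warning otherwise).
#' @param field_size `c(rows, cols)` in pixels.
#' @param n_cells Number of cells to place.
#' @param rng_seed Integer seed.
#' @param irf_nadph,irf_fad Per-channel IRFs (default 220 ps FWHM Gaussian).
#' @param background_rate Background photons per bin per pixel.
#' @param cell_types Optional explicit cell-type assignment (recycled),
#'   bypassing abundance sampling.
#' @return A `synthetic_scene`: `label_image` (0 = background),
#'   `truth_table` (one row per cell: type, realised `area_px`,
#'   `small_mask` flag for areas < 70 px, true per-channel tau1/tau2/alpha1
#'   and tau_m, true `orr`, photon budgets, stain intensity), `cubes`
#'   (list `nadph`, `fad` of `decay_cube`), `irf` (list per channel),
#'   `rng_seed`.
#' @export
build_scene <- function(profiles, field_size = c(512L, 512L), n_cells,
                        rng_seed = 1L,
                        irf_nadph = make_irf(), irf_fad = make_irf(),
                        background_rate = 0.05, cell_types = NULL) {
  stopifnot(n_cells >= 1, length(field_size) == 2)
  ab <- vapply(profiles, `[[`, numeric(1), "abundance")
  if (abs(sum(ab) - 1) > 1e-6) {
    warning("profile abundances sum to ", signif(sum(ab), 4), "; renormalising")
  }
  ab <- ab / sum(ab)
  names(profiles) <- vapply(profiles, `[[`, character(1), "name")
  nr <- as.integer(field_size[1]); nc <- as.integer(field_size[2])

  truth <- .with_seed(.sub_seed(rng_seed, 0L, 0L), {
    types <- if (is.null(cell_types)) {
      sample(names(profiles), n_cells, replace = TRUE, prob = ab)
    } else rep_len(cell_types, n_cells)
    do.call(rbind, lapply(seq_len(n_cells), function(i) {
      .draw_cells(profiles[[types[i]]], 1L)
    }))
  })
  placement <- .with_seed(.sub_seed(rng_seed, 0L, 1L),
                          .place_cells(truth$area_px, nr, nc))
  truth$cell_id <- seq_len(n_cells)
  truth$area_px <- vapply(placement$pixels, length, integer(1))
  truth$small_mask <- truth$area_px < 70
  # FAD photon budget derived from the drawn ORR so expected cell-level
  # ORR equals the truth draw.
  truth$fad_photons <- truth$nadph_photons * (1 - truth$orr) / truth$orr

  n_bins <- irf_nadph$n_bins
  cubes <- list()
  for (ch in c("nadph", "fad")) {
    ch_i <- if (ch == "nadph") 1L else 2L
    irf <- if (ch == "nadph") irf_nadph else irf_fad
    counts <- .with_seed(.sub_seed(rng_seed, ch_i, 0L),
                         stats::rpois(nr * nc * n_bins, background_rate))
    dim(counts) <- c(nr, nc, n_bins)
    pre <- if (ch == "nadph") "nadph_" else "fad_"
    for (i in seq_len(n_cells)) {
      budget <- truth[[paste0(pre, "photons")]][i]
      a1 <- truth[[paste0(pre, "alpha1")]][i] / 100
      mu <- decay_model_expected(
        truth[[paste0(pre, "tau1")]][i], truth[[paste0(pre, "tau2")]][i],
        budget * a1, budget * (1 - a1), 0, irf)
      px <- placement$pixels[[i]]
      draws <- .with_seed(.sub_seed(rng_seed, ch_i, i),
                          stats::rpois(length(px) * n_bins,
                                       rep(mu, each = length(px))))
      idx <- rep(px, n_bins) + (rep(seq_len(n_bins), each = length(px)) - 1L) * (nr * nc)
      counts[idx] <- counts[idx] + draws
    }
    storage.mode(counts) <- "integer"
    cubes[[ch]] <- new_decay_cube(counts, irf$bin_width_ps,
                                  if (ch == "nadph") "NADPH" else "FAD")
  }
  row.names(truth) <- NULL
  structure(list(label_image = placement$label, truth_table = truth,
                 cubes = cubes,
                 irf = list(nadph = irf_nadph, fad = irf_fad),
                 rng_seed = rng_seed),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %d x %d px, %d cells (%s), seed %s\n",
              nrow(x$label_image), ncol(x$label_image), nrow(x$truth_table),
              paste(names(table(x$truth_table$cell_type)), collapse = ", "),
              format(x$rng_seed)))
  invisible(x)
}
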