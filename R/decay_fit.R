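# Pixel-level FLIM processing: spatial binning, background thresholding, and
# biexponential IRF-reconvolution fitting by Poisson maximum likelihood.

# ---- spatial binning --------------------------------------------------------

# Sliding (2k+1)-wide box sum along rows of a matrix, zero padded, same size.
.box_sum_rows <- function(m, k) {
  if (k == 0L) return(m)
  n <- nrow(m)
  pad <- matrix(0, k, ncol(m))
  cs <- apply(rbind(pad, m, pad), 2, cumsum)        # (n + 2k) x p
  cs <- rbind(0, cs)
  cs[(2L * k + 2L):(n + 2L * k + 1L), , drop = FALSE] - cs[1:n, , drop = FALSE]
}

.box_sum_2d <- function(m, k) {
  t(.box_sum_rows(t(.box_sum_rows(m, k)), k))
}

#' Spatially bin a decay cube
#'
#' Applies the FLIM "bin factor" convention: each output pixel's photon
#' histogram is the element-wise sum over a sliding (2b+1) x (2b+1) kernel
#' centred on it (bin factor 2 sums 25 pixels in a 5x5 kernel; factor 3 sums
#' 49 pixels in a 7x7 kernel). The image grid is preserved; edges are zero
#' padded.
#'
#' @param cube A `decay_cube` (see [new_decay_cube()]).
#' @param bin_factor Non-negative integer b; kernel side is 2b+1.
#' @return A `decay_cube` of the same dimensions with summed histograms.
#' @export
bin_pixels <- function(cube, bin_factor) {
  stopifnot(inherits(cube, "decay_cube"), bin_factor >= 0,
            bin_factor == round(bin_factor))
  k <- as.integer(bin_factor)
  d <- dim(cube$counts)
  if (2L * k + 1L > min(d[1], d[2])) {
    stop("binning kernel (", 2L * k + 1L, " px) exceeds the image (",
         d[1], " x ", d[2], ")", call. = FALSE)
  }
  if (k == 0L) return(cube)
  out <- cube$counts
  for (b in seq_len(d[3])) {
    out[, , b] <- .box_sum_2d(cube$counts[, , b], k)
  }
  cube$counts <- out
  cube$bin_factor <- k
  cube
}

#' Photon-count background threshold
#'
#' Marks pixels whose total photon count (summed over all time bins) reaches
#' the floor required for a reliable lifetime fit. The boundary is inclusive:
#' exactly `min_photons` passes.
#'
#' @param cube A `decay_cube`.
#' @param min_photons Minimum total photons per decay (default 2500).
#' @return Logical matrix, `TRUE` where the pixel passes.
#' @export
threshold_background <- function(cube, min_photons = 2500) {
  stopifnot(inherits(cube, "decay_cube"), min_photons >= 0)
  totals <- rowSums(matrix(cube$counts, nrow = prod(dim(cube$counts)[1:2])))
  matrix(totals >= min_photons, dim(cube$counts)[1], dim(cube$counts)[2])
}

# ---- Poisson MLE biexponential fit -----------------------------------------

# Negative Poisson log-likelihood (dropping the lfactorial(y) constant) and
# its gradient for par = (tau1, tau2, a1, a2, c_bg).
.biexp_nll <- function(par, y, t, irf_fft, n) {
  f1 <- decay_shape(par[1], t); f2 <- decay_shape(par[2], t)
  g1 <- Re(stats::fft(stats::fft(f1) * irf_fft, inverse = TRUE)) / n
  g2 <- Re(stats::fft(stats::fft(f2) * irf_fft, inverse = TRUE)) / n
  mu <- pmax(par[3] * g1 + par[4] * g2 + par[5], 1e-12)
  sum(mu) - sum(y * log(mu))
}

.biexp_nll_grad <- function(par, y, t, irf_fft, n) {
  f1 <- decay_shape(par[1], t); f2 <- decay_shape(par[2], t)
  g1 <- Re(stats::fft(stats::fft(f1) * irf_fft, inverse = TRUE)) / n
  g2 <- Re(stats::fft(stats::fft(f2) * irf_fft, inverse = TRUE)) / n
  mu <- pmax(par[3] * g1 + par[4] * g2 + par[5], 1e-12)
  r <- 1 - y / mu
  d1 <- Re(stats::fft(stats::fft(decay_shape_dtau(par[1], t)) * irf_fft,
                      inverse = TRUE)) / n
  d2 <- Re(stats::fft(stats::fft(decay_shape_dtau(par[2], t)) * irf_fft,
                      inverse = TRUE)) / n
  c(par[3] * sum(r * d1), par[4] * sum(r * d2),
    sum(r * g1), sum(r * g2), sum(r))
}

# Method-of-moments initialisation: tau_m from the background-corrected mean
# arrival time (IRF centroid subtracted), components straddling it.
.biexp_init <- function(y, t, irf) {
  n <- length(y)
  tail_bins <- max(2L, ceiling(0.05 * n))
  c0 <- mean(y[(n - tail_bins + 1L):n])
  yc <- pmax(y - c0, 0)
  if (sum(yc) <= 0) yc <- y
  tbar <- sum(yc * (t - t[1])) / sum(yc)
  irf_centroid <- sum(irf$weights * (t - t[1]))
  tau_m0 <- min(max(tbar - irf_centroid, 100), 5000)
  amp <- max(sum(y) - n * c0, 1)
  c(tau1 = 0.4 * tau_m0, tau2 = 2.5 * tau_m0,
    a1 = 0.7 * amp, a2 = 0.3 * amp, c_bg = max(c0, 0))
}

#' Fit a biexponential decay by Poisson maximum likelihood
#'
#' Maximises the Poisson log-likelihood of an observed TCSPC histogram under
#' the reconvolution model: expected counts per bin are the IRF circularly
#' convolved with a two-component exponential decay, plus a flat background
#' (see [decay_model_expected()]). Optimisation uses L-BFGS-B with analytic
#' gradients; on non-convergence the fit restarts from deterministically
#' perturbed initial values (so repeated fits of the same histogram are
#' bit-identical). Lifetimes are returned sorted (tau1 <= tau2) with
#' amplitudes permuted accordingly.
#'
#' The goodness-of-fit statistic is the Pearson reduced chi-square over bins
#' with expected counts >= `chi2_min_expected`, divided by (bins used - 5)
#' for the five free parameters.
#'
#' @param decay Non-negative numeric vector of photon counts per bin.
#' @param irf A [make_irf()] object on the same time axis.
#' @param init Optional named vector `(tau1, tau2, a1, a2, c_bg)` overriding
#'   the method-of-moments start.
#' @param tau_bounds Lifetime search range in picoseconds.
#' @param chi2_min_expected Minimum expected count for a bin to enter the
#'   Pearson chi-square.
#' @param max_restarts Deterministic restarts attempted on non-convergence.
#' @return A `flim_fit` list: `tau1`, `tau2` (ps, sorted), `alpha1_raw`,
#'   `alpha2_raw` (photons per component), `alpha1_pct`, `alpha2_pct`
#'   (normalised percentages), `c_background` (photons/bin), `tau_m` (ps),
#'   `chi2_reduced`, `n_photons`, `logLik` (full Poisson log-likelihood),
#'   `converged`.
#' @export
fit_biexponential <- function(decay, irf, init = NULL,
                              tau_bounds = c(20, 6000),
                              chi2_min_expected = 5,
                              max_restarts = 3L) {
  stopifnot(inherits(irf, "flim_irf"), all(decay >= 0),
            length(decay) == irf$n_bins)
  if (sum(decay) <= 0) stop("all-zero decay histogram: nothing to fit", call. = FALSE)
  t <- irf$time_ps
  n <- irf$n_bins
  irf_fft <- stats::fft(irf$weights)
  p0 <- if (is.null(init)) .biexp_init(decay, t, irf) else
    init[c("tau1", "tau2", "a1", "a2", "c_bg")]
  lower <- c(tau_bounds[1], tau_bounds[1], 0, 0, 0)
  upper <- c(tau_bounds[2], tau_bounds[2], Inf, Inf, Inf)
  p0 <- pmin(pmax(p0, lower + c(1e-6, 1e-6, 0, 0, 0)), c(tau_bounds[2], tau_bounds[2], Inf, Inf, Inf))

  # Deterministic restart schedule: fixed multiplicative perturbations of the
  # lifetime start points, so identical inputs always give identical fits.
  perturb <- list(c(1, 1), c(0.5, 1.6), c(1.8, 0.7), c(0.25, 2.5))
  best <- NULL
  for (r in seq_len(min(max_restarts, 3L) + 1L)) {
    pr <- p0
    pr[1:2] <- pmin(pmax(p0[1:2] * perturb[[r]], lower[1:2] * 1.0001), upper[1:2])
    opt <- tryCatch(
      stats::optim(pr, .biexp_nll, gr = .biexp_nll_grad,
                   y = decay, t = t, irf_fft = irf_fft, n = n,
                   method = "L-BFGS-B", lower = lower, upper = upper,
                   control = list(maxit = 1000L, factr = 10,
                                  parscale = c(pr[1], pr[2],
                                               max(pr[3], 1), max(pr[3], 1),
                                               max(pr[5], 0.01)))),
      error = function(e) NULL)
    if (is.null(opt) || !is.finite(opt$value)) next
    if (is.null(best) || opt$value < best$value - 1e-9) best <- opt
    if (!is.null(best) && best$convergence == 0 && r >= 1L &&
        (r > 1L || opt$convergence == 0)) break
  }
  if (is.null(best)) stop("biexponential fit failed: non-finite likelihood from every start", call. = FALSE)

  par <- best$par
  if (par[1] > par[2]) par <- par[c(2, 1, 4, 3, 5)]
  names(par) <- c("tau1", "tau2", "a1", "a2", "c_bg")
  mu <- decay_model_expected(par[1], par[2], par[3], par[4], par[5], irf)
  use <- mu >= chi2_min_expected
  dof <- max(sum(use) - 5L, 1L)
  chi2 <- sum((decay[use] - mu[use])^2 / mu[use]) / dof
  alpha <- normalize_alpha_raw(par[["a1"]], par[["a2"]])
  fit <- list(
    tau1 = par[["tau1"]], tau2 = par[["tau2"]],
    alpha1_raw = par[["a1"]], alpha2_raw = par[["a2"]],
    alpha1_pct = unname(alpha[1]), alpha2_pct = unname(alpha[2]),
    c_background = par[["c_bg"]],
    tau_m = (par[["a1"]] * par[["tau1"]] + par[["a2"]] * par[["tau2"]]) /
      (par[["a1"]] + par[["a2"]]),
    chi2_reduced = chi2,
    n_photons = sum(decay),
    logLik = sum(stats::dpois(round(decay), pmax(mu, 1e-12), log = TRUE)),
    converged = best$convergence == 0
  )
  class(fit) <- "flim_fit"
  fit
}

#' @export
print.flim_fit <- function(x, ...) {
  cat(sprintf(
    "<flim_fit> tau1 %.0f ps, tau2 %.0f ps, alpha1 %.1f%%, tau_m %.0f ps, C %.3g/bin, chi2 %.3f%s\n",
    x$tau1, x$tau2, x$alpha1_pct, x$tau_m, x$c_background, x$chi2_reduced,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Amplitude-weighted mean lifetime
#'
#' tau_m = (alpha1 tau1 + alpha2 tau2) / (alpha1 + alpha2). Always lies
#' between tau1 and tau2.
#'
#' @param fit A `flim_fit`, or a list with `tau1`, `tau2`, `alpha1_raw`,
#'   `alpha2_raw`.
#' @return Mean lifetime in picoseconds.
#' @export
mean_lifetime <- function(fit) {
  a1 <- fit$alpha1_raw; a2 <- fit$alpha2_raw
  if (a1 + a2 <= 0) stop("zero total amplitude: mean lifetime undefined", call. = FALSE)
  (a1 * fit$tau1 + a2 * fit$tau2) / (a1 + a2)
}

# Raw two-amplitude normalisation; second percentage by complement so the two
# sum to exactly 100.
normalize_alpha_raw <- function(a1, a2) {
  if (a1 + a2 <= 0) stop("zero total amplitude: alpha fractions undefined", call. = FALSE)
  p1 <- 100 * a1 / (a1 + a2)
  c(alpha1_pct = p1, alpha2_pct = 100 - p1)
}

#' Normalised amplitude percentages
#'
#' Converts raw component amplitudes to the reported normalised fractions
#' alpha1/(alpha1+alpha2) and alpha2/(alpha1+alpha2), as percentages summing
#' to exactly 100.
#'
#' @param fit A `flim_fit` (or list with `alpha1_raw`, `alpha2_raw`).
#' @return Named numeric vector `c(alpha1_pct, alpha2_pct)`.
#' @export
normalize_alpha <- function(fit) {
  normalize_alpha_raw(fit$alpha1_raw, fit$alpha2_raw)
}

# ---- whole-image fitting ----------------------------------------------------

#' Fit every above-threshold pixel of a decay cube
#'
#' Composition of [bin_pixels()], [threshold_background()] and
#' [fit_biexponential()]: the cube is spatially binned, pixels below the
#' photon floor are masked out, and each remaining pixel's histogram is fit.
#' Conventional bin factors are 2 for NAD(P)H and 3 for FAD.
#'
#' @param cube A `decay_cube`.
#' @param irf A [make_irf()] object.
#' @param bin_factor Spatial bin factor (kernel side 2b+1).
#' @param min_photons Photon floor applied after binning (default 2500).
#' @param ... Passed to [fit_biexponential()].
#' @return A `pixel_fit_map`: list of per-pixel matrices `tau1`, `tau2`,
#'   `alpha1_pct`, `tau_m`, `chi2`, `n_photons` (NA where invalid), a logical
#'   `valid_mask` (above threshold AND converged), the total-intensity matrix
#'   `intensity` of the *unbinned* cube, plus `bin_factor` and `min_photons`.
#' @export
fit_image <- function(cube, irf, bin_factor = 2L, min_photons = 2500, ...) {
  stopifnot(inherits(cube, "decay_cube"))
  raw_intensity <- matrix(rowSums(matrix(cube$counts,
                                         nrow = prod(dim(cube$counts)[1:2]))),
                          dim(cube$counts)[1], dim(cube$counts)[2])
  binned <- bin_pixels(cube, bin_factor)
  mask <- threshold_background(binned, min_photons)
  d <- dim(binned$counts)
  m_na <- matrix(NA_real_, d[1], d[2])
  out <- list(tau1 = m_na, tau2 = m_na, alpha1_pct = m_na, tau_m = m_na,
              chi2 = m_na, n_photons = m_na,
              valid_mask = mask, intensity = raw_intensity,
              bin_factor = as.integer(bin_factor), min_photons = min_photons,
              n_failed = 0L)
  ymat <- matrix(binned$counts, nrow = d[1] * d[2])
  idx <- which(mask)
  for (p in idx) {
    fit <- tryCatch(fit_biexponential(ymat[p, ], irf, ...),
                    error = function(e) NULL)
    if (is.null(fit)) {
      out$valid_mask[p] <- FALSE
      out$n_failed <- out$n_failed + 1L
      next
    }
    out$tau1[p] <- fit$tau1; out$tau2[p] <- fit$tau2
    out$alpha1_pct[p] <- fit$alpha1_pct; out$tau_m[p] <- fit$tau_m
    out$chi2[p] <- fit$chi2_reduced; out$n_photons[p] <- fit$n_photons
    if (!fit$converged) out$valid_mask[p] <- FALSE
  }
  class(out) <- "pixel_fit_map"
  out
}

#' @export
print.pixel_fit_map <- function(x, ...) {
  cat(sprintf("<pixel_fit_map> %d x %d px, bin factor %d, %d valid pixels (floor %g photons)\n",
              nrow(x$tau_m), ncol(x$tau_m), x$bin_factor,
              sum(x$valid_mask), x$min_photons))
  invisible(x)
}
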