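## Bi-exponential decay fitting (Poisson MLE) and cube preprocessing.

#' Spatially bin a photon cube
#'
#' Each output pixel's histogram is the channel-wise sum over the square
#' `(2*binning+1)^2` window centred on it (49 pixels at `binning = 3`,
#' matching SPCImage's convention). Windows are truncated at the image
#' border (no padding).
#'
#' @param cube A `photon_cube`.
#' @param binning Non-negative integer half-width; `0` is the identity.
#' @return A `photon_cube` of identical dimensions with binned counts.
#' @export
spatial_bin <- function(cube, binning = 3L) {
  stopifnot(inherits(cube, "photon_cube"), binning >= 0)
  b <- as.integer(binning)
  if (b == 0L) return(cube)
  d <- dim(cube$counts)
  out <- cube
  # summed-area table per channel over the (y, x) plane
  for (ch in seq_len(d[1])) {
    plane <- cube$counts[ch, , , drop = TRUE]
    if (is.null(dim(plane))) plane <- matrix(plane, cube$ny, cube$nx)
    sat <- apply(apply(plane, 2, cumsum), 1, cumsum) # nx x ny (transposed)
    sat <- t(sat)
    satp <- matrix(0, cube$ny + 1, cube$nx + 1)
    satp[-1, -1] <- sat
    y0 <- pmax(seq_len(cube$ny) - b, 1); y1 <- pmin(seq_len(cube$ny) + b, cube$ny)
    x0 <- pmax(seq_len(cube$nx) - b, 1); x1 <- pmin(seq_len(cube$nx) + b, cube$nx)
    out$counts[ch, , ] <- satp[y1 + 1, x1 + 1, drop = FALSE] -
      satp[y0, x1 + 1, drop = FALSE] -
      satp[y1 + 1, x0, drop = FALSE] + satp[y0, x0, drop = FALSE]
  }
  out
}

#' Intensity threshold mask
#'
#' Pixels whose total (channel-summed) counts reach the threshold are
#' retained; used to exclude low signal-to-noise regions before fitting.
#'
#' @param cube A `photon_cube`.
#' @param threshold Minimum total counts per pixel (`>= 0`).
#' @return ny x nx logical matrix.
#' @export
intensity_threshold_mask <- function(cube, threshold) {
  stopifnot(threshold >= 0)
  cube_intensity(cube) >= threshold
}

#' Fit a bi-exponential decay by Poisson maximum likelihood
#'
#' Minimises the Poisson deviance between the counts and the periodic
#' bi-exponential model convolved with the Gaussian IRF, with an optional
#' temporal shift (signal vs IRF, within +-3 channels) and a constant
#' offset (ambient/dark background). Initialisation is a multi-start scan
#' over a coarse lifetime grid (`tau1` in {100, 300, 600} ps x `tau2` in
#' {1200, 2000, 3000} ps); the two best starts are refined with
#' box-constrained quasi-Newton iterations ([stats::nlminb()]).
#'
#' @param hist A `decay_histogram` with at least 1000 photons; below the
#'   5000-photon analysis floor a warning flag is set on the result.
#' @param fit_shift,fit_offset Fit the temporal shift / the constant
#'   offset (both default `TRUE`); when `FALSE` the value is held at 0.
#' @param init Optional list with starting values `tau1`, `tau2`, `a1`
#'   (canonicalised so that `tau1 <= tau2`); replaces the grid scan.
#' @return An object of class `biexp_fit`: `a1`, `a2` (unit simplex, with
#'   `tau1 <= tau2` enforced by swapping), `tau1`, `tau2`, `shift`,
#'   `offset`, `chi2_reduced` (Pearson chi-square over channels minus
#'   free parameters), `n_photons_used`, `deviance`, `converged`,
#'   `warn_low_photons`.
#' @examples
#' cell <- list(tau1 = 196, tau2 = 1698, a1 = 5 / 6)
#' h <- simulate_decay(cell, total_photons = 1e5, seed = 1)
#' fit <- fit_biexponential(h)
#' c(fit$tau1, fit$tau2, fit$a1 / fit$a2)
#' @export
fit_biexponential <- function(hist, fit_shift = TRUE, fit_offset = TRUE,
                              init = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  y <- hist$counts
  if (all(y == 0)) stop("all-zero histogram")
  if (hist$n_photons < 1000)
    stop("fewer than 1000 photons; curve cannot be fitted reliably")
  instr <- hist$instrument
  t <- hist$times; t0 <- instr$irf_t0; sigma <- instr$irf_sigma
  period <- instr$window; dt <- instr$channel_width
  npar <- 4L + as.integer(fit_shift) + as.integer(fit_offset)

  obj <- function(p) biexp_deviance_cpp(p, y, t, t0, sigma, period)

  n_tot <- sum(y)
  off0 <- if (fit_offset) max(min(y[y > 0 | TRUE]), 0.01) else 0
  scale0 <- max(n_tot - off0 * length(y), n_tot * 0.1)
  shift_cap <- if (fit_shift) 3 * dt else 0

  starts <- if (!is.null(init)) {
    tt <- sort(c(init$tau1, init$tau2))
    a1i <- if (!is.null(init$a1)) {
      if (init$tau1 <= init$tau2) init$a1 else 1 - init$a1
    } else 0.7
    list(c(tt[1], tt[2], a1i, 0, scale0, off0))
  } else {
    grid <- expand.grid(tau1 = c(100, 300, 600), tau2 = c(1200, 2000, 3000))
    lapply(seq_len(nrow(grid)), function(i)
      c(grid$tau1[i], grid$tau2[i], 0.7, 0, scale0, off0))
  }
  dev0 <- vapply(starts, obj, numeric(1))
  keep <- order(dev0)[seq_len(min(2L, length(starts)))]

  lower <- c(20, 20, 1e-4, -shift_cap, 1, 0)
  upper <- c(8000, 8000, 1 - 1e-4, shift_cap, Inf, Inf)
  if (!fit_offset) upper[6] <- 1e-12

  best <- NULL
  for (k in keep) {
    res <- tryCatch(
      stats::nlminb(starts[[k]], obj, lower = lower, upper = upper,
                    control = list(iter.max = 500, rel.tol = 1e-9)),
      error = function(e) NULL)
    if (!is.null(res) && (is.null(best) || res$objective < best$objective))
      best <- res
  }
  if (is.null(best))
    stop("bi-exponential fit failed to converge from all starts")

  p <- best$par
  # enforce tau1 <= tau2 by swapping components
  if (p[1] > p[2]) p <- c(p[2], p[1], 1 - p[3], p[4], p[5], p[6])
  mu <- biexp_expected_cpp(p, t, t0, sigma, period)
  chi2 <- sum((y - mu)^2 / pmax(mu, 1e-12)) / (length(y) - npar)

  out <- list(a1 = p[3], a2 = 1 - p[3], tau1 = p[1], tau2 = p[2],
              shift = p[4], offset = p[6], scale = p[5],
              chi2_reduced = chi2, n_photons_used = n_tot,
              deviance = best$objective,
              converged = best$convergence == 0,
              warn_low_photons = n_tot < 5000,
              degenerate = abs(p[1] - p[2]) < 1e-3 * p[2] ||
                p[3] < 1e-3 || p[3] > 1 - 1e-3)
  class(out) <- "biexp_fit"
  out
}

#' @export
print.biexp_fit <- function(x, ...) {
  cat(sprintf(
    "Bi-exponential fit: tau1 = %.0f ps, tau2 = %.0f ps, a1 = %.3f, a1/a2 = %.2f, chi2_red = %.3f%s\n",
    x$tau1, x$tau2, x$a1, x$a1 / x$a2, x$chi2_reduced,
    if (x$warn_low_photons) " [below 5000-photon floor]" else ""))
  invisible(x)
}

#' Fit every masked pixel of a (binned) photon cube
#'
#' Applies [spatial_bin()] then [fit_biexponential()] to each pixel whose
#' binned total counts pass the intensity threshold.
#'
#' @param cube A `photon_cube`.
#' @param binning Spatial binning half-width (default 3, i.e. 49 pixels).
#' @param threshold Minimum binned counts per fitted pixel.
#' @param ... Passed to [fit_biexponential()].
#' @return A list with `mask` (fitted pixels) and per-pixel parameter
#'   matrices `tau1`, `tau2`, `a1`, `a2`, `taum`, `amp_ratio`,
#'   `chi2_reduced` (`NA` outside the mask), plus `intensity` (binned
#'   totals).
#' @export
fit_cube <- function(cube, binning = 3L, threshold = 1000, ...) {
  binned <- spatial_bin(cube, binning)
  mask <- intensity_threshold_mask(binned, threshold)
  dims <- c(cube$ny, cube$nx)
  out <- list(mask = mask, intensity = cube_intensity(binned),
              tau1 = matrix(NA_real_, dims[1], dims[2]))
  for (nm in c("tau2", "a1", "a2", "taum", "amp_ratio", "chi2_reduced"))
    out[[nm]] <- out$tau1
  for (i in which(mask)) {
    yy <- ((i - 1) %% dims[1]) + 1; xx <- ((i - 1) %/% dims[1]) + 1
    h <- decay_histogram(binned$counts[, yy, xx], cube$instrument)
    f <- tryCatch(fit_biexponential(h, ...), error = function(e) NULL)
    if (is.null(f)) next
    out$tau1[yy, xx] <- f$tau1; out$tau2[yy, xx] <- f$tau2
    out$a1[yy, xx] <- f$a1; out$a2[yy, xx] <- f$a2
    out$taum[yy, xx] <- compute_tau_m(f$a1, f$a2, f$tau1, f$tau2)
    out$amp_ratio[yy, xx] <- f$a1 / f$a2
    out$chi2_reduced[yy, xx] <- f$chi2_reduced
  }
  out
}

#' Diagnostic correlations between intensity/fit quality and decay parameters
#'
#' Screens for dependence of the decay parameters on fluorescence
#' intensity and on fit quality (reduced chi-square): a sound analysis
#' expects the absence of such correlations.
#'
#' @param fits List of `biexp_fit` objects (at least 3).
#' @param intensities Numeric vector of per-cell intensities, same length.
#' @return A data.frame with one row per (predictor, parameter) pair:
#'   Pearson and Spearman correlation and p-values; `NA` with
#'   `undefined = TRUE` for constant columns.
#' @export
check_diagnostic_correlations <- function(fits, intensities) {
  if (length(fits) < 3) stop("need at least 3 fits")
  stopifnot(length(intensities) == length(fits))
  pars <- data.frame(
    tau1 = vapply(fits, `[[`, numeric(1), "tau1"),
    tau2 = vapply(fits, `[[`, numeric(1), "tau2"),
    taum = vapply(fits, function(f)
      compute_tau_m(f$a1, f$a2, f$tau1, f$tau2), numeric(1)),
    amp_ratio = vapply(fits, function(f) f$a1 / f$a2, numeric(1)))
  chi2 <- vapply(fits, `[[`, numeric(1), "chi2_reduced")
  preds <- list(intensity = intensities, chi2_reduced = chi2)
  rows <- list()
  for (pn in names(preds)) for (vn in names(pars)) {
    x <- preds[[pn]]; v <- pars[[vn]]
    if (sd(x) == 0 || sd(v) == 0) {
      rows[[length(rows) + 1]] <- data.frame(
        predictor = pn, parameter = vn, pearson_r = NA_real_,
        pearson_p = NA_real_, spearman_rho = NA_real_,
        spearman_p = NA_real_, undefined = TRUE)
      next
    }
    pe <- cor.test(x, v, method = "pearson")
    sp <- suppressWarnings(cor.test(x, v, method = "spearman"))
    rows[[length(rows) + 1]] <- data.frame(
      predictor = pn, parameter = vn,
      pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
      spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
      undefined = FALSE)
  }
  do.call(rbind, rows)
}
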