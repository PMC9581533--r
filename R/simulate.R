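## TCSPC decay and FLIM image-cube simulation.

#' Construct a decay histogram object
#'
#' Container for one TCSPC photon-count histogram: counts per time
#' channel plus the instrument description. Used both for measured and
#' for simulated curves; simulated curves carry their ground-truth
#' parameters for recovery tests.
#'
#' @param counts Non-negative counts per channel (length must equal
#'   `instrument$n_channels`). Non-integer values are allowed (noiseless
#'   expected curves).
#' @param instrument A [flim_instrument()].
#' @param truth Optional list/one-row data.frame of true parameters.
#' @param warn_low_photons Flag set when the photon budget is below the
#'   5000-photon analysis floor.
#' @return An object of class `decay_histogram` with fields `counts`,
#'   `times`, `channel_width`, `instrument`, `n_photons`, `truth`,
#'   `warn_low_photons`.
#' @export
decay_histogram <- function(counts, instrument = flim_instrument(),
                            truth = NULL, warn_low_photons = FALSE) {
  stopifnot(inherits(instrument, "flim_instrument"))
  if (length(counts) != instrument$n_channels)
    stop("counts length (", length(counts), ") does not match n_channels (",
         instrument$n_channels, ")")
  if (any(counts < 0)) stop("counts must be non-negative")
  obj <- list(counts = as.numeric(counts),
              times = instrument$times,
              channel_width = instrument$channel_width,
              instrument = instrument,
              n_photons = sum(counts),
              truth = truth,
              warn_low_photons = isTRUE(warn_low_photons))
  class(obj) <- "decay_histogram"
  obj
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("TCSPC decay histogram: %d channels, %.0f photons%s\n",
              length(x$counts), x$n_photons,
              if (x$warn_low_photons) " [below 5000-photon floor]" else ""))
  invisible(x)
}

#' Noiseless expected decay curve for a cell
#'
#' Expected counts per channel for the periodic bi-exponential model
#' convolved with the Gaussian IRF: `total_photons` times the unit-sum
#' decay shape, plus the instrument background rate. Wrap-around of
#' previous excitation periods is included analytically (geometric tail
#' sum over the repetition period).
#'
#' @param cell One-row data.frame or list with `tau1`, `tau2` (ps) and
#'   `a1` (unit-simplex amplitude of the short component).
#' @param instrument A [flim_instrument()].
#' @param total_photons Expected number of signal photons in the window.
#' @return A `decay_histogram` with non-integer expected counts.
#' @examples
#' h <- expected_decay(list(tau1 = 196, tau2 = 1698, a1 = 5/6), total_photons = 1e5)
#' @export
expected_decay <- function(cell, instrument = flim_instrument(),
                           total_photons = 1e5) {
  stopifnot(total_photons > 0)
  shape <- decay_shape_cpp(instrument$times, cell$tau1, cell$tau2, cell$a1,
                           instrument$irf_t0 + instrument$irf_shift,
                           instrument$irf_sigma, instrument$window)
  mu <- total_photons * shape / sum(shape) + instrument$background_rate
  decay_histogram(mu, instrument,
                  truth = list(tau1 = cell$tau1, tau2 = cell$tau2,
                               a1 = cell$a1, a2 = 1 - cell$a1,
                               total_photons = total_photons))
}

#' Simulate a photon-count decay histogram
#'
#' Draws independent Poisson counts per channel around the expected curve
#' of [expected_decay()]. Budgets below the 5000-photon analysis floor
#' are simulated but flagged via `warn_low_photons`.
#'
#' @inheritParams expected_decay
#' @param seed Optional integer seed (reproducible, RNG-state safe).
#' @return A `decay_histogram` with integer counts and ground truth.
#' @examples
#' cell <- sample_cells(load_reference_table()[7, ], 1, seed = 1)
#' h <- simulate_decay(cell, total_photons = 1e5, seed = 2)
#' @export
simulate_decay <- function(cell, instrument = flim_instrument(),
                           total_photons = 1e5, seed = NULL) {
  if (total_photons <= 0) stop("total_photons must be positive")
  mu <- expected_decay(cell, instrument, total_photons)
  with_local_seed(seed, {
    counts <- rpois(length(mu$counts), mu$counts)
    decay_histogram(counts, instrument, truth = mu$truth,
                    warn_low_photons = total_photons < 5000)
  })
}

#' Describe a synthetic FLIM scene
#'
#' A scene is a pixel grid with an ECM-like background (long lifetime,
#' low intensity) and non-overlapping elliptical cell regions. Pixel
#' coordinates are 0-based, row-major.
#'
#' @param ny,nx Image size in pixels.
#' @param background One-row data.frame/list with `tau1`, `tau2`, `a1`
#'   for the background field. Default emulates collagen/elastin-dominated
#'   ECM (long-lifetime, a1-poor).
#' @param background_photons Expected photons per background pixel.
#' @return An object of class `flim_scene`; add cells with
#'   [scene_add_ellipse()].
#' @export
flim_scene <- function(ny, nx,
                       background = list(tau1 = 400, tau2 = 2600, a1 = 0.35),
                       background_photons = 200) {
  stopifnot(ny >= 1, nx >= 1, background_photons >= 0)
  obj <- list(ny = as.integer(ny), nx = as.integer(nx),
              background = background,
              background_photons = background_photons, cells = list())
  class(obj) <- "flim_scene"
  obj
}

#' Add an elliptical cell region to a scene
#'
#' @param scene A [flim_scene()].
#' @param cell One-row data.frame/list with `tau1`, `tau2`, `a1` and
#'   optionally `group_label`, `class_name`.
#' @param cx,cy Ellipse centre (0-based pixel coordinates, x = column).
#' @param rx,ry Ellipse semi-axes in pixels.
#' @param photons Expected photons per cell pixel.
#' @return The scene with the cell appended. Overlap with an existing
#'   cell raises an error (ambiguous ground truth).
#' @export
scene_add_ellipse <- function(scene, cell, cx, cy, rx, ry, photons = 1e4) {
  stopifnot(inherits(scene, "flim_scene"), rx > 0, ry > 0, photons > 0)
  new_mask <- ellipse_mask(scene$ny, scene$nx, cx, cy, rx, ry)
  for (existing in scene$cells)
    if (any(new_mask & existing$mask))
      stop("cell regions overlap: ambiguous ground truth")
  scene$cells <- c(scene$cells, list(list(cell = cell, mask = new_mask,
                                          photons = photons)))
  scene
}

# Rasterize ((x-cx)/rx)^2 + ((y-cy)/ry)^2 <= 1 on the 0-based pixel grid.
ellipse_mask <- function(ny, nx, cx, cy, rx, ry) {
  x <- matrix(rep(0:(nx - 1), each = ny), ny, nx)
  y <- matrix(rep(0:(ny - 1), nx), ny, nx)
  ((x - cx) / rx)^2 + ((y - cy) / ry)^2 <= 1
}

#' Simulate a FLIM photon cube from a scene
#'
#' Every pixel gets an independent Poisson TCSPC histogram: cell pixels
#' draw from their cell's decay shape, remaining pixels from the
#' background field.
#'
#' @param scene A [flim_scene()] with cells added.
#' @param instrument A [flim_instrument()].
#' @param seed Optional integer seed.
#' @return An object of class `photon_cube`: `counts` array of dimension
#'   `(n_channels, ny, nx)`, the `instrument`, and ground truth
#'   `truth_label` (ny x nx integer matrix, `NA` for background) and
#'   `truth_class` (class names, `NA` for background).
#' @examples
#' sc <- flim_scene(16, 16)
#' cell <- sample_cells(load_reference_table()[7, ], 1, seed = 1)
#' sc <- scene_add_ellipse(sc, cell, cx = 8, cy = 8, rx = 4, ry = 3)
#' cube <- simulate_flim_cube(sc, seed = 2)
#' @export
simulate_flim_cube <- function(scene, instrument = flim_instrument(),
                               seed = NULL) {
  stopifnot(inherits(scene, "flim_scene"))
  nch <- instrument$n_channels
  with_local_seed(seed, {
    bg_mu <- expected_decay(scene$background, instrument,
                            max(scene$background_photons, 1e-9))$counts
    if (scene$background_photons == 0)
      bg_mu <- rep(instrument$background_rate, nch)
    counts <- array(rpois(nch * scene$ny * scene$nx, rep(bg_mu, scene$ny * scene$nx)),
                    dim = c(nch, scene$ny, scene$nx))
    label <- matrix(NA_integer_, scene$ny, scene$nx)
    cls <- matrix(NA_character_, scene$ny, scene$nx)
    for (cl in scene$cells) {
      mu <- expected_decay(cl$cell, instrument, cl$photons)$counts
      idx <- which(cl$mask)
      for (i in idx)
        counts[, ((i - 1) %% scene$ny) + 1, ((i - 1) %/% scene$ny) + 1] <-
          rpois(nch, mu)
      label[cl$mask] <- if (!is.null(cl$cell$group_label))
        as.integer(cl$cell$group_label) else NA_integer_
      cls[cl$mask] <- if (!is.null(cl$cell$class_name))
        as.character(cl$cell$class_name) else NA_character_
    }
    obj <- list(counts = counts, instrument = instrument,
                ny = scene$ny, nx = scene$nx,
                truth_label = label, truth_class = cls)
    class(obj) <- "photon_cube"
    obj
  })
}

#' @export
print.photon_cube <- function(x, ...) {
  cat(sprintf("FLIM photon cube: %d x %d pixels x %d channels, %.3g photons total\n",
              x$ny, x$nx, dim(x$counts)[1], sum(x$counts)))
  invisible(x)
}

#' Per-pixel total intensity image of a cube
#' @param cube A `photon_cube`.
#' @return ny x nx matrix of summed counts.
#' @export
cube_intensity <- function(cube) {
  stopifnot(inherits(cube, "photon_cube"))
  apply(cube$counts, c(2, 3), sum)
}
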