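## FLIM parameter set, feature vectors and 2D segmentation.

#' Amplitude-weighted mean fluorescence lifetime
#'
#' `taum = (a1*tau1 + a2*tau2) / (a1 + a2)`.
#'
#' @param a1,a2 Component amplitudes (any positive scale; `a1 + a2 > 0`).
#' @param tau1,tau2 Component lifetimes in ps (positive).
#' @return Mean lifetime in ps (vectorised).
#' @examples
#' compute_tau_m(2, 1, 300, 1200)  # 600
#' @export
compute_tau_m <- function(a1, a2, tau1, tau2) {
  if (any(a1 + a2 <= 0)) stop("a1 + a2 must be positive")
  if (any(tau1 <= 0) || any(tau2 <= 0)) stop("lifetimes must be positive")
  (a1 * tau1 + a2 * tau2) / (a1 + a2)
}

# canonical feature order for the classifier
flim_feature_names <- function(include_intensity = FALSE,
                               include_shape = FALSE) {
  nm <- c("tau1", "tau2", "a1", "a2", "taum", "tau_ratio", "amp_ratio",
          "amp_contrast")
  if (include_intensity) nm <- c(nm, "intensity")
  if (include_shape) nm <- c(nm, "shape")
  nm
}

#' Build the FLIM classifier feature vector
#'
#' The default 8-value vector holds the independent bi-exponential
#' parameters `tau1`, `tau2`, `a1`, `a2` and the derived variables
#' `taum`, `tau_ratio = tau2/tau1`, `amp_ratio = a1/a2` and
#' `amp_contrast = (a1 - a2)/(a1 + a2)`. Power-normalised intensity and
#' a circular/noncircular shape flag can be appended via the flags; cell
#' size is never included.
#'
#' @param fit A `biexp_fit`, or any list/one-row data.frame with `a1`,
#'   `a2`, `tau1`, `tau2`.
#' @param intensity Optional intensity (photons/mW), used when
#'   `include_intensity = TRUE`.
#' @param shape Optional shape flag (1 circular, 0 noncircular), used
#'   when `include_shape = TRUE`.
#' @param include_intensity,include_shape Feature flags (default off).
#' @return Named numeric vector in canonical feature order.
#' @examples
#' build_feature_vector(list(a1 = 5/6, a2 = 1/6, tau1 = 196, tau2 = 1698))
#' @export
build_feature_vector <- function(fit, intensity = NA_real_, shape = NA_real_,
                                 include_intensity = FALSE,
                                 include_shape = FALSE) {
  v <- c(tau1 = fit$tau1, tau2 = fit$tau2, a1 = fit$a1, a2 = fit$a2,
         taum = compute_tau_m(fit$a1, fit$a2, fit$tau1, fit$tau2),
         tau_ratio = fit$tau2 / fit$tau1,
         amp_ratio = fit$a1 / fit$a2,
         amp_contrast = (fit$a1 - fit$a2) / (fit$a1 + fit$a2))
  if (include_intensity) v <- c(v, intensity = unname(intensity))
  if (include_shape) v <- c(v, shape = unname(shape))
  v
}

#' Feature table for a set of synthetic cells
#'
#' Maps the per-cell ground-truth parameters of
#' [simulate_reference_cells()] (or fitted parameters in the same layout)
#' to the classifier feature matrix plus the label vector.
#'
#' @param cells Data.frame with `tau1`, `tau2`, `a1`, `a2`,
#'   optionally `intensity` and `group_label`.
#' @param include_intensity,include_shape Feature flags.
#' @return A list: `X` (numeric matrix, canonical feature columns),
#'   `y` (integer labels, `NA` when unknown), `feature_names`.
#' @export
cells_to_features <- function(cells, include_intensity = FALSE,
                              include_shape = FALSE) {
  X <- cbind(tau1 = cells$tau1, tau2 = cells$tau2,
             a1 = cells$a1, a2 = cells$a2,
             taum = compute_tau_m(cells$a1, cells$a2, cells$tau1, cells$tau2),
             tau_ratio = cells$tau2 / cells$tau1,
             amp_ratio = cells$a1 / cells$a2,
             amp_contrast = (cells$a1 - cells$a2) / (cells$a1 + cells$a2))
  if (include_intensity)
    X <- cbind(X, intensity = cells$intensity)
  if (include_shape)
    X <- cbind(X, shape = if (!is.null(cells$shape)) cells$shape else NA_real_)
  y <- if (!is.null(cells$group_label)) as.integer(cells$group_label)
       else rep(NA_integer_, nrow(X))
  list(X = X, y = y, feature_names = colnames(X))
}

#' Normalise fluorescence intensity by laser power
#'
#' Counts are averaged over the binning window (the pixel of interest
#' plus its 48 square neighbours by default) and divided by the optical
#' power.
#'
#' @param total_counts Total counts summed over the window.
#' @param laser_power_mW Laser power in mW (positive).
#' @param window_pixels Number of pixels in the window (default 49).
#' @return Intensity in photons/mW (vectorised).
#' @examples
#' normalize_intensity(4900, 1)  # 100
#' @export
normalize_intensity <- function(total_counts, laser_power_mW,
                                window_pixels = 49) {
  if (any(laser_power_mW <= 0)) stop("laser power must be positive")
  stopifnot(window_pixels >= 1)
  total_counts / window_pixels / laser_power_mW
}

#' Per-class parameter boxes for 2D segmentation
#'
#' Builds `mean - k*sd, mean + k*sd` intervals per class over a chosen
#' parameter pair from the reference table.
#'
#' @param table Reference table rows to build boxes for.
#' @param params Two parameter names among `"tau1"`, `"tau2"`, `"taum"`,
#'   `"amp_ratio"` (default `c("tau1", "amp_ratio")`).
#' @param k Half-width in class standard deviations (default 2).
#' @return Data.frame with `class_name`, `group_label` and
#'   `<param>_lo`/`<param>_hi` columns.
#' @export
class_boxes <- function(table = load_reference_table(),
                        params = c("tau1", "amp_ratio"), k = 2) {
  stopifnot(length(params) == 2, k > 0)
  out <- table[, c("class_name", "group_label")]
  for (p in params) {
    m <- table[[paste0(p, "_mean")]]; s <- table[[paste0(p, "_sd")]]
    if (is.null(m) || is.null(s)) stop("unknown segmentation parameter ", p)
    out[[paste0(p, "_lo")]] <- m - k * s
    out[[paste0(p, "_hi")]] <- m + k * s
  }
  attr(out, "params") <- params
  out
}

#' 2D segmentation of fitted FLIM parameter maps
#'
#' Labels each masked pixel by the unique class whose parameter box
#' contains the pixel's fitted values; `"ambiguous"` when several boxes
#' match and `"unclassified"` when none does.
#'
#' @param maps Named list of ny x nx parameter matrices (as from
#'   [fit_cube()]) containing the box parameters.
#' @param boxes Output of [class_boxes()] (must be non-empty).
#' @param mask Optional logical matrix restricting the labelling; default
#'   all pixels with non-`NA` parameters.
#' @param by Label pixels by `"group"` (M1/M2/other group label, default)
#'   or `"class"` (class name); group-level boxes are merged so that
#'   overlap between classes of the same group is not ambiguous.
#' @return ny x nx character matrix: the label, `"ambiguous"`,
#'   `"unclassified"`, or `NA` outside the mask.
#' @export
segment_pixels <- function(maps, boxes = class_boxes(), mask = NULL,
                           by = c("group", "class")) {
  by <- match.arg(by)
  if (is.null(boxes) || nrow(boxes) == 0) stop("empty class boxes")
  params <- attr(boxes, "params")
  stopifnot(all(params %in% names(maps)))
  d <- dim(maps[[params[1]]])
  if (is.null(mask)) mask <- !is.na(maps[[params[1]]])
  out <- matrix(NA_character_, d[1], d[2])
  ids <- if (by == "group") as.character(boxes$group_label)
         else as.character(boxes$class_name)
  for (i in which(mask)) {
    hit <- rep(TRUE, nrow(boxes))
    for (p in params) {
      v <- maps[[p]][i]
      if (is.na(v)) { hit[] <- FALSE; break }
      hit <- hit & v >= boxes[[paste0(p, "_lo")]] &
        v <= boxes[[paste0(p, "_hi")]]
    }
    matched <- unique(ids[hit])
    out[i] <- if (length(matched) == 0) "unclassified"
              else if (length(matched) == 1) matched else "ambiguous"
  }
  out
}
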