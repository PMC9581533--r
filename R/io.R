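## File formats: decay CSV, feature tables, photon cubes, reports.
## All writers use C-locale numeric formatting (via data.table) so a
## fixed seed reproduces byte-identical files.

#' Read / write a single decay curve as CSV
#'
#' Two-column CSV `time_ps, counts` with header. On reading, the
#' instrument geometry is reconstructed from the channel spacing.
#'
#' @param hist A `decay_histogram`.
#' @param path CSV path.
#' @param instrument Optional [flim_instrument()] overriding the
#'   reconstruction on read.
#' @return `write_decay_csv` returns `path` invisibly; `read_decay_csv`
#'   a `decay_histogram`.
#' @export
write_decay_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  data.table::fwrite(data.table::data.table(time_ps = hist$times,
                                            counts = hist$counts), path)
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path, instrument = NULL) {
  d <- data.table::fread(path)
  if (!all(c("time_ps", "counts") %in% names(d)))
    stop("decay CSV must have columns time_ps, counts")
  if (is.null(instrument)) {
    dt <- d$time_ps[2] - d$time_ps[1]
    n <- nrow(d)
    instrument <- flim_instrument(repetition_rate = 1e12 / (dt * n),
                                  n_channels = n)
  }
  decay_histogram(d$counts, instrument)
}

#' Write / read a fit-result table as CSV
#'
#' Columns: `cell_id, a1, a2, tau1_ps, tau2_ps, shift_ps, offset,
#' chi2_reduced, n_photons, warn_low_photons`.
#'
#' @param fits List of `biexp_fit` objects.
#' @param path CSV path.
#' @param cell_id Optional identifiers (default `1:length(fits)`).
#' @return `write_fits_csv` returns `path` invisibly; `read_fits_csv` a
#'   data.frame.
#' @export
write_fits_csv <- function(fits, path, cell_id = seq_along(fits)) {
  g <- function(nm) vapply(fits, `[[`, numeric(1), nm)
  d <- data.table::data.table(
    cell_id = cell_id, a1 = g("a1"), a2 = g("a2"),
    tau1_ps = g("tau1"), tau2_ps = g("tau2"), shift_ps = g("shift"),
    offset = g("offset"), chi2_reduced = g("chi2_reduced"),
    n_photons = g("n_photons_used"),
    warn_low_photons = vapply(fits, `[[`, logical(1), "warn_low_photons"))
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_fits_csv
#' @export
read_fits_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read a cell feature table as CSV
#'
#' @param cells Data.frame of cells (as from
#'   [simulate_reference_cells()] or assembled from fits).
#' @param path CSV path.
#' @return `write_features_csv` returns `path` invisibly;
#'   `read_features_csv` a data.frame.
#' @export
write_features_csv <- function(cells, path) {
  d <- as.data.frame(cells)
  d$tau_ratio <- d$tau2 / d$tau1
  if (is.null(d$amp_ratio)) d$amp_ratio <- d$a1 / d$a2
  d$amp_contrast <- (d$a1 - d$a2) / (d$a1 + d$a2)
  data.table::fwrite(d, path)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  as.data.frame(data.table::fread(path))
}

#' Write / read a photon cube as a plain-text container
#'
#' Header lines (`# key value`) carry the instrument metadata
#' (`time_resolution_ps`, `repetition_rate_hz`, `irf_fwhm_ps`, image
#' size) followed by the counts as a channels x (ny*nx) CSV matrix in
#' column-major pixel order, and an optional ground-truth label block.
#'
#' @param cube A `photon_cube`.
#' @param path Output path.
#' @return `write_cube_text` returns `path` invisibly; `read_cube_text`
#'   a `photon_cube`.
#' @export
write_cube_text <- function(cube, path) {
  stopifnot(inherits(cube, "photon_cube"))
  instr <- cube$instrument
  hdr <- c("# macroflim_cube_v1",
           sprintf("# ny %d", cube$ny),
           sprintf("# nx %d", cube$nx),
           sprintf("# n_channels %d", instr$n_channels),
           sprintf("# time_resolution_ps %.10g", instr$channel_width),
           sprintf("# repetition_rate_hz %.10g", instr$repetition_rate),
           sprintf("# irf_fwhm_ps %.10g", instr$irf_fwhm),
           sprintf("# irf_t0_ps %.10g", instr$irf_t0),
           sprintf("# background_rate %.10g", instr$background_rate),
           sprintf("# has_truth %d", as.integer(!all(is.na(cube$truth_label)))))
  writeLines(hdr, path)
  m <- matrix(cube$counts, dim(cube$counts)[1], cube$ny * cube$nx)
  data.table::fwrite(data.table::as.data.table(m), path, append = TRUE,
                     col.names = FALSE)
  if (!all(is.na(cube$truth_label))) {
    lab <- as.integer(cube$truth_label)
    lab[is.na(lab)] <- -1L
    cat("# truth_label\n", file = path, append = TRUE)
    cat(paste(lab, collapse = ","), "\n", sep = "", file = path,
        append = TRUE)
  }
  invisible(path)
}

#' @rdname write_cube_text
#' @export
read_cube_text <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "# macroflim_cube_v1"))
    stop("not a macroflim cube file")
  hdr <- grep("^# ", lines, value = TRUE)
  getv <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  ny <- as.integer(getv("ny")); nx <- as.integer(getv("nx"))
  nch <- as.integer(getv("n_channels"))
  instrument <- flim_instrument(repetition_rate = getv("repetition_rate_hz"),
                                n_channels = nch,
                                irf_fwhm = getv("irf_fwhm_ps"),
                                irf_t0 = getv("irf_t0_ps"),
                                background_rate = getv("background_rate"))
  body <- lines[!startsWith(lines, "#")]
  counts_lines <- body[seq_len(nch)]
  m <- as.matrix(data.table::fread(text = counts_lines, header = FALSE))
  label <- matrix(NA_integer_, ny, nx)
  if (getv("has_truth") == 1) {
    lab <- as.integer(strsplit(body[nch + 1], ",")[[1]])
    lab[lab < 0] <- NA_integer_
    label <- matrix(lab, ny, nx)
  }
  obj <- list(counts = array(m, dim = c(nch, ny, nx)),
              instrument = instrument, ny = ny, nx = nx,
              truth_label = label,
              truth_class = matrix(NA_character_, ny, nx))
  class(obj) <- "photon_cube"
  obj
}

#' Write phasor coordinates as CSV
#'
#' @param points List of `phasor_point`s.
#' @param path CSV path.
#' @param cell_id Optional identifiers.
#' @return `path`, invisibly.
#' @export
write_phasor_csv <- function(points, path, cell_id = seq_along(points)) {
  d <- data.table::data.table(
    cell_id = cell_id,
    g = vapply(points, `[[`, numeric(1), "g"),
    s = vapply(points, `[[`, numeric(1), "s"),
    harmonic = vapply(points, `[[`, integer(1), "harmonic"))
  data.table::fwrite(d, path)
  invisible(path)
}

#' Write an evaluation report as JSON
#'
#' Serialises an `eval_report` (plus optional CV results and run
#' metadata) with full numeric precision.
#'
#' @param report An `eval_report` from [repeated_split_eval()].
#' @param path JSON path.
#' @param cv Optional [kfold_cv()] result.
#' @param meta Optional named list of run metadata (seed, config hash).
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path, cv = NULL, meta = NULL) {
  stopifnot(inherits(report, "eval_report"))
  obj <- list(schema = "macroflim_report_v1",
              n_repeats = report$n_repeats,
              n_redraws = report$n_redraws,
              metrics = report$metrics,
              confusion = unname(apply(report$confusion, 1, as.list)),
              classes = report$classes)
  if (!is.null(cv)) obj$cv <- list(scores = cv$scores, mean = cv$mean)
  if (!is.null(meta)) obj$meta <- meta
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
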