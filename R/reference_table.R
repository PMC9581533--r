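## Reference class table and per-class cell sampling.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Load the bundled TPE-FLIM reference class table
#'
#' The bundled table lists, for each dermal/epidermal cell class, the
#' mean and standard deviation of the bi-exponential decay parameters
#' (short lifetime `tau1`, long lifetime `tau2`, mean lifetime `taum`,
#' amplitude ratio `a1/a2`) and of the power-normalised autofluorescence
#' intensity, together with the per-class cell counts used for dataset
#' assembly (399 cells in total) and the three-way phenotype label
#' (0 = M1 macrophage, 1 = M2 macrophage, 2 = other dermal cell).
#'
#' The ex vivo and in vivo mast-cell rows are synthetic stand-ins that
#' reuse the in vitro resting-mast-cell distributions (`standin = TRUE`);
#' the monocyte row is a reference distribution that is not part of the
#' 399-cell model input (`in_model = FALSE`).
#'
#' @param include_all If `TRUE`, also return rows not used for dataset
#'   assembly (the monocyte reference row). Default `FALSE`: only the
#'   model rows, whose counts sum to 399.
#' @param path Path to an alternative reference CSV with the same columns.
#'
#' @return A data.frame with one row per cell class; columns
#'   `class_name`, `group_label`, `environment`, `n_cells`,
#'   `{tau1,tau2,taum,amp_ratio,intensity}_{mean,sd}`, `in_model`,
#'   `standin`.
#' @examples
#' tab <- load_reference_table()
#' sum(tab$n_cells)  # 399
#' @export
load_reference_table <- function(include_all = FALSE, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_table.csv",
                        package = "macroflim", mustWork = TRUE)
  tab <- tryCatch(
    suppressWarnings(utils::read.csv(path, comment.char = "#",
                                     stringsAsFactors = FALSE)),
    error = function(e) stop("failed to read reference table '", path,
                             "': ", conditionMessage(e)))
  needed <- c("class_name", "group_label", "environment", "n_cells",
              "tau1_mean", "tau1_sd", "tau2_mean", "tau2_sd",
              "taum_mean", "taum_sd", "amp_ratio_mean", "amp_ratio_sd",
              "intensity_mean", "intensity_sd", "in_model", "standin")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("reference table is corrupted: missing column(s) ",
         paste(missing, collapse = ", "))
  if (!include_all) tab <- tab[tab$in_model, , drop = FALSE]
  bad <- with(tab, tau1_mean >= tau2_mean | n_cells <= 0 |
                tau1_mean <= 0 | tau2_mean <= 0 | tau1_sd <= 0 |
                tau2_sd <= 0 | amp_ratio_mean <= 0 | amp_ratio_sd <= 0)
  if (any(bad))
    stop("reference table is corrupted: invalid row(s) ",
         paste(tab$class_name[bad], collapse = ", "))
  rownames(tab) <- NULL
  tab
}

# Gaussian truncated at > lower by resampling.
rnorm_trunc <- function(n, mean, sd, lower = 0) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Sample synthetic cells from one reference class
#'
#' Draws per-cell ground-truth decay parameters from the class's Gaussian
#' distributions: `tau1` and `tau2` truncated at zero and jointly
#' resampled until `tau1 < tau2`; the amplitude ratio a1/a2 truncated at
#' zero and converted to unit-simplex amplitudes `a1 = ratio/(1+ratio)`,
#' `a2 = 1/(1+ratio)`; intensity truncated at zero. The mean
#' lifetime is derived as `taum = a1*tau1 + a2*tau2` (amplitudes already
#' normalised), never sampled independently.
#'
#' @param row A single-row data.frame from [load_reference_table()].
#' @param n Number of cells to draw (`n >= 0`).
#' @param seed Optional integer seed; sampling is reproducible under a
#'   fixed seed and leaves the caller's RNG state untouched.
#' @return A data.frame of `n` cells: `class_name`, `environment`,
#'   `group_label`, `tau1`, `tau2`, `a1`, `a2`, `amp_ratio`, `taum`,
#'   `intensity`.
#' @examples
#' m1 <- load_reference_table()[7, ]  # in vivo M1 row
#' cells <- sample_cells(m1, 5, seed = 1)
#' @export
sample_cells <- function(row, n, seed = NULL) {
  if (!is.data.frame(row) || nrow(row) != 1L)
    stop("row must be a single reference-table row")
  if (length(n) != 1L || is.na(n) || n < 0)
    stop("n must be a non-negative integer")
  n <- as.integer(n)
  with_local_seed(seed, {
    tau1 <- numeric(n); tau2 <- numeric(n)
    if (n > 0) {
      tau1 <- rnorm_trunc(n, row$tau1_mean, row$tau1_sd)
      tau2 <- rnorm_trunc(n, row$tau2_mean, row$tau2_sd)
      bad <- which(tau1 >= tau2)
      while (length(bad)) {
        tau1[bad] <- rnorm_trunc(length(bad), row$tau1_mean, row$tau1_sd)
        tau2[bad] <- rnorm_trunc(length(bad), row$tau2_mean, row$tau2_sd)
        bad <- bad[tau1[bad] >= tau2[bad]]
      }
    }
    r <- if (n > 0) rnorm_trunc(n, row$amp_ratio_mean, row$amp_ratio_sd)
         else numeric(0)
    intensity <- if (n > 0)
      rnorm_trunc(n, row$intensity_mean, row$intensity_sd) else numeric(0)
    a1 <- r / (1 + r)
    a2 <- 1 / (1 + r)
    data.frame(
      class_name = rep(row$class_name, n),
      environment = rep(row$environment, n),
      group_label = rep(as.integer(row$group_label), n),
      tau1 = tau1, tau2 = tau2, a1 = a1, a2 = a2,
      amp_ratio = r, taum = a1 * tau1 + a2 * tau2,
      intensity = intensity,
      stringsAsFactors = FALSE
    )
  })
}

#' Assemble the full synthetic reference cell set
#'
#' Draws every class of the reference table with its per-class count
#' (399 cells by default), emulating the study's model-input dataset.
#'
#' @param table Reference table, default [load_reference_table()].
#' @param seed Integer seed for reproducible assembly.
#' @param counts Optional per-row override of the number of cells.
#' @return A data.frame of cells (see [sample_cells()]), rows in table
#'   order.
#' @examples
#' cells <- simulate_reference_cells(seed = 1)
#' nrow(cells)  # 399
#' table(cells$group_label)
#' @export
simulate_reference_cells <- function(table = load_reference_table(),
                                     seed = NULL, counts = table$n_cells) {
  stopifnot(length(counts) == nrow(table), all(counts >= 0))
  with_local_seed(seed, {
    out <- lapply(seq_len(nrow(table)), function(i)
      sample_cells(table[i, ], counts[i], seed = NULL))
    do.call(rbind, out)
  })
}
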