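## Pipeline configuration and the end-to-end classification protocol.

#' Load and validate a pipeline configuration
#'
#' Reads a YAML config and validates every field against the module
#' preconditions; explicit arguments in `...` override file values.
#'
#' @param path Optional YAML file path.
#' @param ... Named overrides of individual fields.
#' @return A validated list of class `flim_config` with fields `seed`,
#'   `photons_per_cell`, `binning`, `include_intensity`, `include_shape`,
#'   `max_depth`, `min_samples_split`, `n_repeats`, `k_folds`,
#'   `phasor_threshold`, and instrument overrides `repetition_rate`,
#'   `n_channels`, `irf_fwhm`, `background_rate`.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- list(seed = 1L, photons_per_cell = 1e5, binning = 3L,
              include_intensity = FALSE, include_shape = FALSE,
              max_depth = 9L, min_samples_split = 2L,
              n_repeats = 1000L, k_folds = 5L, phasor_threshold = 0.7,
              repetition_rate = 8e7, n_channels = 256L, irf_fwhm = 80,
              background_rate = 1)
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown config field(s): ", paste(unknown, collapse = ", "))
    cfg[names(file_cfg)] <- file_cfg
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (cfg$photons_per_cell <= 0) stop("photons_per_cell must be positive")
  if (cfg$binning < 0) stop("binning must be >= 0")
  if (cfg$max_depth < 1) stop("max_depth must be >= 1")
  if (cfg$min_samples_split < 2) stop("min_samples_split must be >= 2")
  if (cfg$n_repeats < 1) stop("n_repeats must be >= 1")
  if (cfg$k_folds < 2) stop("k_folds must be >= 2")
  if (cfg$phasor_threshold < 0 || cfg$phasor_threshold > 1)
    stop("phasor_threshold must be in [0, 1]")
  flim_instrument(cfg$repetition_rate, cfg$n_channels, cfg$irf_fwhm,
                  background_rate = cfg$background_rate) # validates
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("flim_config", "list")
  cfg
}

#' Relabel cells for the classification tasks
#'
#' `"three_class"` keeps the 0/1/2 labels (M1, M2, other);
#' `"binary_mphi"` pools M1 and M2 into one macrophage class (0) against
#' other dermal cells (1); `"ground_truth"` restricts to the in vitro and
#' ex vivo macrophages with known phenotype and labels M1 vs M2 (0/1).
#'
#' @param cells Data.frame from [simulate_reference_cells()].
#' @param task One of `"three_class"`, `"binary_mphi"`, `"ground_truth"`.
#' @return `cells` (possibly subset) with a `label` column.
#' @export
task_labels <- function(cells, task = c("three_class", "binary_mphi",
                                        "ground_truth")) {
  task <- match.arg(task)
  if (task == "three_class") {
    cells$label <- as.integer(cells$group_label)
  } else if (task == "binary_mphi") {
    cells$label <- ifelse(cells$group_label %in% c(0L, 1L), 0L, 1L)
  } else {
    cells <- cells[cells$environment %in% c("in_vitro", "ex_vivo") &
                     cells$group_label %in% c(0L, 1L), , drop = FALSE]
    cells$label <- as.integer(cells$group_label)
  }
  cells
}

#' Run the full classification protocol on the synthetic reference set
#'
#' Generates the 399-cell synthetic dataset, then runs the repeated
#' 50/50-split evaluation for the three-class, pooled-macrophage binary,
#' and ground-truth (M1 vs M2, in vitro + ex vivo) tasks, plus shuffled
#' fivefold cross-validation and per-class ROC curves on one held-out
#' split of the three-class task.
#'
#' @param config A [pipeline_config()] (or arguments to build one).
#' @param table Reference table.
#' @return A list with `cells`, per-task `eval_report`s
#'   (`three_class`, `binary_mphi`, `ground_truth`), `cv` and `roc`
#'   (per-class list with `auc`).
#' @examples
#' \donttest{
#' res <- run_classification_protocol(pipeline_config(n_repeats = 100))
#' res$three_class$metrics
#' }
#' @export
run_classification_protocol <- function(config = pipeline_config(),
                                        table = load_reference_table()) {
  hp <- tree_hyperparams(config$max_depth, config$min_samples_split)
  seed <- config$seed
  cells <- simulate_reference_cells(table, seed = seed)
  out <- list(cells = cells, config = config)
  for (task in c("three_class", "binary_mphi", "ground_truth")) {
    tc <- task_labels(cells, task)
    feats <- cells_to_features(tc, config$include_intensity,
                               config$include_shape)
    out[[task]] <- repeated_split_eval(feats$X, tc$label, hp,
                                       n_repeats = config$n_repeats,
                                       seed = seed + match(task, c(
                                         "three_class", "binary_mphi",
                                         "ground_truth")) * 1000L)
  }
  feats <- cells_to_features(task_labels(cells, "three_class"),
                             config$include_intensity, config$include_shape)
  out$cv <- kfold_cv(feats$X, feats$y, hp, k = config$k_folds,
                     seed = seed + 4000L)
  # ROC on one fixed 50/50 split of the three-class task
  out$roc <- with_local_seed(seed + 5000L, {
    n <- length(feats$y)
    idx <- sample.int(n, floor(n / 2))
    tree <- fit_tree(feats$X[idx, , drop = FALSE], feats$y[idx], hp)
    sc <- predict_scores(tree, feats$X[-idx, , drop = FALSE])
    lapply(setNames(as.list(tree$classes), paste0("class_", tree$classes)),
           function(k) roc_curve(sc[, as.character(k)], feats$y[-idx], k))
  })
  out
}
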