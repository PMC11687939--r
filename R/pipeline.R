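#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's settings; a serialized copy is written with each
#' run's outputs so results are reproducible from the manifest alone.
#'
#' @param out_dir output directory.
#' @param cohort a [cohort_config()] (simulated input) or `NULL` when
#'   `input_dir` holds beat CSVs.
#' @param input_dir directory of beat CSV + sidecar records (ignored when
#'   `cohort` is given).
#' @param preprocess a [preprocess_config()].
#' @param registry a [feature_registry()].
#' @param train_fraction,threshold split and operating-point settings.
#' @param grid list of [classifier_spec()]s; `NULL` skips the grid search
#'   and trains the default random forest (50 trees, depth 6).
#' @param seed integer seed governing split, SMOTE and training.
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir, cohort = NULL, input_dir = NULL,
                       preprocess = preprocess_config(),
                       registry = feature_registry(),
                       train_fraction = 0.70, threshold = 0.5,
                       grid = NULL, seed = 1) {
  if (is.null(cohort) && is.null(input_dir))
    stop("run_config needs a cohort config or an input directory", call. = FALSE)
  if (is.null(registry)) stop("run_config needs a feature registry", call. = FALSE)
  structure(list(out_dir = out_dir, cohort = cohort, input_dir = input_dir,
                 preprocess = preprocess, registry = registry,
                 train_fraction = train_fraction, threshold = threshold,
                 grid = grid, seed = seed),
            class = "run_config")
}

#' Run the full pipeline
#'
#' Simulates (or reads) a cohort, preprocesses and featurizes every record,
#' derives labels (consensus of simulated expert votes for synthetic
#' cohorts), splits 70/30 with stratification, scales to \[0, 1\],
#' SMOTE-balances the training set, trains the classifier (grid search when
#' a grid is configured, otherwise the default random forest), evaluates on
#' the held-out set, and compares against the threshold-based PIH
#' definitions. All outputs plus a manifest are written under `out_dir`.
#'
#' @param cfg a [run_config()].
#' @return The manifest list (also written as `manifest.json`): counts of
#'   records in/excluded, eliminated-beat fractions, the selected
#'   classifier, evaluation metrics, and PIH overlap fractions.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(cfg$cohort)) {
    sim <- generate_cohort(cfg$cohort)
    records <- sim$records
    labels_truth <- sim$truth$class
  } else {
    paths <- list.files(cfg$input_dir, pattern = "\\.csv$", full.names = TRUE)
    if (length(paths) == 0) stop("no beat CSVs in ", cfg$input_dir, call. = FALSE)
    records <- lapply(paths, read_record)
    labels_truth <- vapply(records, function(r)
      if (is.null(r$ground_truth)) NA_character_ else r$ground_truth, "")
  }

  fc <- featurize_cohort(records, cfg$preprocess, cfg$registry)
  feats <- fc$features
  write_feature_table(feats, file.path(cfg$out_dir, "features.csv"))
  y <- factor(labels_truth[fc$included], levels = c("stable", "unstable"))
  if (anyNA(y)) stop("records without labels; cannot train", call. = FALSE)

  X <- as.matrix(feats[, -1, drop = FALSE])
  sp <- split_data(X, y, cfg$train_fraction, seed = cfg$seed)
  scaler <- fit_scaler(sp$train$X)
  Xtr <- apply_scaler(scaler, sp$train$X)
  Xte <- apply_scaler(scaler, sp$test$X)

  if (!is.null(cfg$grid)) {
    gs <- grid_search(Xtr, sp$train$y, cfg$grid, seed = cfg$seed)
    spec <- gs$best
  } else {
    gs <- NULL
    spec <- classifier_spec("random_forest", seed = cfg$seed)
  }
  aug <- smote(Xtr, sp$train$y, seed = cfg$seed)
  model <- train_classifier(spec, aug$X, aug$y)
  report <- evaluate_classifier(model, Xte, sp$test$y, cfg$threshold)

  pih65 <- vapply(fc$signals, pih_classify, logical(1), rule = "map_lt_65")
  pih20 <- vapply(fc$signals, pih_classify, logical(1), rule = "sap_drop_gt_20pct")
  model_unstable <- y == "unstable"

  manifest <- list(
    n_records = length(records),
    n_included = sum(fc$included),
    n_excluded = sum(!fc$included),
    median_frac_eliminated = stats::median(
      vapply(fc$reports, `[[`, numeric(1), "frac_eliminated"), na.rm = TRUE),
    n_unstable = sum(model_unstable),
    classifier = list(family = spec$family,
                      hyperparameters = spec$hyperparameters),
    cv_auroc = if (is.null(gs)) NULL else gs$cv_auroc,
    evaluation = report[c("tn", "fp", "fn", "tp", "sensitivity",
                          "specificity", "accuracy", "auroc", "threshold")],
    pih = list(map_lt_65 = overlap_report(model_unstable, pih65),
               sap_drop_gt_20pct = overlap_report(model_unstable, pih20)),
    seed = cfg$seed)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  utils::write.csv(roc_points(report$scores, sp$test$y),
                   file.path(cfg$out_dir, "roc.csv"), row.names = FALSE)
  invisible(manifest)
}
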