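## End-to-end orchestration: simulate (or read) a plate, segment,
## featurize, compute the roundness Z-score read-out, the PCA fingerprint,
## the linear-classifier scores and the CNN ratios, and join everything
## into one per-well report. One seed in the config; stage seeds are
## derived by stable hashing of stage names.

#' Run configuration
#'
#' @param out_dir Output directory for all stage artifacts.
#' @param seed Single integer seed propagated (by stable stage hashing) to
#'   every stochastic stage.
#' @param platemap A [plate_map()] or path to a plate map JSON.
#' @param simulate `NULL` to read images from `image_dir`, otherwise a
#'   list of [simulation_config()] override arguments (e.g. `image_size`,
#'   `cells_per_field`, `mixtures`).
#' @param image_dir Directory with plate TIFFs when `simulate` is `NULL`.
#' @param feature_args List of [feature_config()] override arguments.
#' @param linear_source Named list mapping `M0`/`M1like`/`M2like` to
#'   training well addresses (enables the linear-classifier stage).
#' @param cnn_source Named list mapping all four classes (incl. `dead`)
#'   to training well addresses (enables the CNN stage).
#' @param cells_per_class Training cells per class for the linear model.
#' @param cnn_epochs,crop_size CNN training epochs and crop edge length.
#' @param toxicity_fraction Toxicity flag threshold (default 0.5).
#' @param confidence_threshold CNN confidence gate (default 0.40).
#' @return An object of class `RunConfig`.
#' @export
run_config <- function(out_dir, seed = 1L, platemap = NULL, simulate = NULL,
                       image_dir = NULL, feature_args = list(),
                       linear_source = NULL, cnn_source = NULL,
                       cells_per_class = 100L, cnn_epochs = 12L,
                       crop_size = 64L, toxicity_fraction = 0.5,
                       confidence_threshold = 0.40) {
  if (is.null(platemap) && is.null(image_dir))
    stop("config needs a platemap (for simulation) or an image_dir")
  if (is.character(platemap)) {
    if (!file.exists(platemap)) stop("plate map file not found: ", platemap)
    platemap <- read_plate_map(platemap)
  }
  if (is.null(simulate) && is.null(image_dir))
    stop("either simulate settings or an image_dir must be given")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 platemap = platemap, simulate = simulate,
                 image_dir = image_dir, feature_args = feature_args,
                 linear_source = linear_source, cnn_source = cnn_source,
                 cells_per_class = as.integer(cells_per_class),
                 cnn_epochs = as.integer(cnn_epochs),
                 crop_size = as.integer(crop_size),
                 toxicity_fraction = toxicity_fraction,
                 confidence_threshold = confidence_threshold),
            class = "RunConfig")
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage and writes per-stage CSV outputs plus a
#' joined per-well report (`report.csv`) and a machine-readable JSON
#' summary into `out_dir`. Reruns with the same config are bit-identical.
#'
#' @param config A [run_config()].
#' @return List with the report `data.frame` and the per-stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  t_all <- as.numeric(Sys.time())

  ## stage: images
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- derive_seed(config$seed, "simulate")
    simcfg <- do.call(simulation_config, sim_args)
    sim <- simulate_plate(simcfg, config$platemap)
    bundle <- sim$bundle
    truth <- sim$truth
    write_table_file(truth$cells, file.path(config$out_dir, "ground_truth.csv"))
  } else {
    bundle <- read_plate(config$image_dir)
    config$platemap <- bundle$platemap
    truth <- NULL
  }
  platemap <- config$platemap

  ## stage: features (includes flatfield + segmentation)
  fconfig <- do.call(feature_config, config$feature_args)
  cells <- extract_features(bundle, fconfig)
  if (!nrow(cells)) stop("stage features: no cells found on the plate")
  write_table_file(cells, file.path(config$out_dir, "cell_features.csv"))

  ## stage: roundness Z-score + toxicity
  zres <- roundness_zscore(well_mean_roundness(cells), platemap,
                           config$toxicity_fraction)
  write_table_file(zres, file.path(config$out_dir, "roundness_zscore.csv"))

  ## stage: PCA fingerprint
  pca <- NULL
  if (nrow(zres) >= 3L) {
    pca <- tryCatch(profile_pca(cells, platemap = platemap),
                    error = function(e) {
                      cp_log("profile", "skipped: ", conditionMessage(e))
                      NULL
                    })
    if (!is.null(pca))
      write_table_file(data.frame(well = rownames(pca$coords),
                                  PC1 = pca$coords[, 1], PC2 = pca$coords[, 2]),
                       file.path(config$out_dir, "pca_coords.csv"))
  }

  ## stage: linear classifier
  linear <- NULL
  if (!is.null(config$linear_source)) {
    spec <- training_spec(config$linear_source,
                          cells_per_class = config$cells_per_class,
                          seed = derive_seed(config$seed, "train"))
    catalog <- enumerate_catalog(fconfig)
    training <- sample_training_cells(cells, spec)
    model <- train_linear_classifier(training, spec, catalog)
    write_linear_model(model, file.path(config$out_dir, "linear_model.json"))
    labels <- data.frame(well = cells$well,
                         class = predict_cells(model, cells))
    scores <- normalize_to_dmso(well_class_fractions(labels), platemap)
    write_table_file(scores, file.path(config$out_dir, "linear_scores.csv"))
    linear <- list(model = model, scores = scores)
  }

  ## stage: CNN
  cnn <- NULL
  if (!is.null(config$cnn_source)) {
    if (is.null(truth))
      stop("stage cnn: training labels require simulated ground truth")
    crops <- make_crops(bundle, size = config$crop_size)
    src <- config$cnn_source
    lab <- rep(NA_character_, nrow(crops$meta))
    for (cls in names(src))
      lab[crops$meta$well %in% src[[cls]]] <- cls
    train_sel <- !is.na(lab)
    model <- train_cnn(crops$crops[, , , train_sel, drop = FALSE],
                       lab[train_sel],
                       seed = derive_seed(config$seed, "cnn"),
                       epochs = config$cnn_epochs)
    pred <- predict_with_confidence(model, crops,
                                    threshold = config$confidence_threshold)
    write_table_file(pred$predictions,
                     file.path(config$out_dir, "cnn_predictions.csv"))
    ratios <- well_ratios(pred$predictions, platemap)
    write_table_file(ratios$wells, file.path(config$out_dir, "cnn_wells.csv"))
    if (!is.null(ratios$conditions))
      write_table_file(ratios$conditions,
                       file.path(config$out_dir, "cnn_conditions.csv"))
    cnn <- list(model = model, predictions = pred, ratios = ratios)
  }

  ## joined per-well report
  report <- zres
  if (!is.null(linear))
    report <- merge(report, linear$scores[, c("well", "pct_M0", "pct_M1like",
                                              "pct_M2like", "normalized_score")],
                    by = "well", all.x = TRUE)
  if (!is.null(cnn))
    report <- merge(report, cnn$ratios$wells[, c("well",
                                                 paste0("ratio_", CP_CLASSES))],
                    by = "well", all.x = TRUE)
  report <- report[order(report$well), , drop = FALSE]
  rownames(report) <- NULL
  write_table_file(report, file.path(config$out_dir, "report.csv"))
  jsonlite::write_json(list(plate = platemap$plate_id, seed = config$seed,
                            n_wells = nrow(report),
                            n_cells = nrow(cells),
                            stages = c("features", "zscore",
                                       if (!is.null(pca)) "pca",
                                       if (!is.null(linear)) "linear",
                                       if (!is.null(cnn)) "cnn")),
                      file.path(config$out_dir, "summary.json"),
                      auto_unbox = TRUE, digits = NA)
  cp_log("pipeline", "complete: ", nrow(report), " wells", t0 = t_all)
  list(report = report, cells = cells, zscore = zres, pca = pca,
       linear = linear, cnn = cnn, truth = truth)
}
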