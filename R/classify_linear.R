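## The trained linear classifier: seeded sampling of training cells per
## polarization state, one-vs-one L1-regularized linear discriminants on
## standardized features (a sparse surrogate for the proprietary
## PhenoLOGIC linear classifier that reproduces its observable outputs:
## per-cell class, per-pair relevant features with coefficients), per-well
## class fractions and the DMSO-normalized %M2(-like)-%M1(-like) score.

#' Training specification for the linear classifier
#'
#' @param class_source Named list mapping each class (`M0`, `M1like`,
#'   `M2like`) to the well addresses its training cells come from.
#' @param cells_per_class Cells sampled per class (default 100).
#' @param seed Integer seed for the sampling.
#' @param feature_mask `"all"`, `"no_standard_morphology"`,
#'   `"no_roundness"`, or an explicit character vector of feature names to
#'   drop.
#' @param lambda Fixed L1 regularization strength on standardized
#'   features (default 0.02).
#' @return An object of class `TrainingSpec`.
#' @export
training_spec <- function(class_source, cells_per_class = 100L, seed = 1L,
                          feature_mask = "all", lambda = 0.02) {
  classes <- c("M0", "M1like", "M2like")
  if (!setequal(names(class_source), classes))
    stop("class_source must name exactly: ", paste(classes, collapse = ", "))
  if (any(!vapply(class_source, length, integer(1))))
    stop("every class needs a nonempty source well list")
  stopifnot(cells_per_class >= 2L, lambda > 0)
  structure(list(classes = classes, class_source = class_source,
                 cells_per_class = as.integer(cells_per_class),
                 seed = as.integer(seed), feature_mask = feature_mask,
                 lambda = lambda),
            class = "TrainingSpec")
}

#' Sample training cells
#'
#' Draws exactly `cells_per_class` cells per class without replacement,
#' stratified as evenly as possible across the source wells (round-robin
#' over seeded per-well permutations).
#'
#' @param cell_table Single-cell feature table.
#' @param spec A [training_spec()].
#' @return The sampled subset of `cell_table` with an extra `class`
#'   column.
#' @export
sample_training_cells <- function(cell_table, spec) {
  stopifnot(inherits(spec, "TrainingSpec"))
  picks <- list()
  for (cls in spec$classes) {
    wells <- spec$class_source[[cls]]
    pool_n <- sum(cell_table$well %in% wells)
    if (pool_n < spec$cells_per_class)
      stop("class ", cls, ": only ", pool_n, " cells available in source ",
           "wells but ", spec$cells_per_class, " requested")
    idx_by_well <- lapply(sort(wells), function(w)
      with_seed(derive_seed(spec$seed, paste("train", cls, w)),
                sample(which(cell_table$well == w))))
    ## round-robin across wells
    maxlen <- max(vapply(idx_by_well, length, integer(1)))
    order_idx <- unlist(lapply(seq_len(maxlen), function(k)
      vapply(idx_by_well, function(v)
        if (k <= length(v)) v[k] else NA_integer_, integer(1))))
    order_idx <- order_idx[!is.na(order_idx)]
    sel <- order_idx[seq_len(spec$cells_per_class)]
    sub <- cell_table[sel, , drop = FALSE]
    sub$class <- cls
    picks[[cls]] <- sub
  }
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Train the pairwise sparse linear classifier
#'
#' Standardizes the masked feature columns on the training cells, then
#' fits one L1-regularized logistic discriminant per class pair
#' (M0|M1like, M0|M2like, M1like|M2like) at the fixed regularization
#' strength of the spec. Nonzero coefficients are the model's "relevant
#' features".
#'
#' @param training Labeled training subset from [sample_training_cells()]
#'   (needs a `class` column).
#' @param spec A [training_spec()].
#' @param catalog Feature catalog (default [enumerate_catalog()]).
#' @return An object of class `LinearModel`.
#' @export
train_linear_classifier <- function(training, spec,
                                    catalog = enumerate_catalog()) {
  stopifnot(inherits(spec, "TrainingSpec"), "class" %in% names(training))
  feats <- mask_feature_names(spec$feature_mask, catalog)
  feats <- intersect(feats, names(training))
  if (length(feats) < 2L) stop("fewer than 2 usable features after masking")
  X <- as.matrix(training[, feats, drop = FALSE])
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  keep <- which(scl > 0 & is.finite(scl))
  if (length(keep) < 2L)
    stop("degenerate training set: (almost) all features have zero variance")
  feats <- feats[keep]
  ctr <- ctr[keep]; scl <- scl[keep]
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2, ctr), 2, scl, "/")
  pairs <- utils::combn(spec$classes, 2, simplify = FALSE)
  fits <- list()
  for (pr in pairs) {
    sel <- training$class %in% pr
    if (sum(training$class == pr[1]) < 2L || sum(training$class == pr[2]) < 2L)
      stop("need >= 2 training cells per class for pair ",
           paste(pr, collapse = "|"))
    y <- factor(training$class[sel], levels = pr)
    ## decreasing lambda path ending at the fixed strength keeps glmnet's
    ## coordinate descent warm-started and deterministic
    lam <- spec$lambda * c(8, 4, 2, 1)
    fit <- glmnet::glmnet(Z[sel, , drop = FALSE], y, family = "binomial",
                          alpha = 1, lambda = lam, standardize = FALSE)
    beta <- as.numeric(fit$beta[, length(lam)])
    names(beta) <- feats
    fits[[paste(pr, collapse = "|")]] <-
      list(a = pr[1], b = pr[2], coef = beta,
           intercept = as.numeric(fit$a0[length(lam)]))
  }
  model <- structure(list(classes = spec$classes, pairs = fits,
                          center = ctr, scale = scl, features = feats,
                          feature_mask = spec$feature_mask,
                          lambda = spec$lambda, seed = spec$seed,
                          cells_per_class = spec$cells_per_class),
                     class = "LinearModel")
  model$training_accuracy <-
    mean(predict_cells(model, training) == training$class)
  model
}

#' @export
print.LinearModel <- function(x, ...) {
  cat(sprintf("LinearModel: %s; %d features (mask: %s), lambda %.3g\n",
              paste(x$classes, collapse = "/"), length(x$features),
              paste(x$feature_mask, collapse = ","), x$lambda))
  for (nm in names(x$pairs))
    cat(sprintf("  %s: %d relevant feature(s)\n", nm,
                sum(x$pairs[[nm]]$coef != 0)))
  if (!is.null(x$training_accuracy))
    cat(sprintf("  training accuracy: %.3f\n", x$training_accuracy))
  invisible(x)
}

#' Classify cells with a trained linear model
#'
#' Pairwise votes; the majority class wins, ties are broken by summed
#' signed margins, then by the fixed class order M0 < M1like < M2like.
#'
#' @param model A [train_linear_classifier()] model.
#' @param cell_table Feature table covering the model's retained features.
#' @return Character vector of class labels, one per row.
#' @export
predict_cells <- function(model, cell_table) {
  stopifnot(inherits(model, "LinearModel"))
  miss <- setdiff(model$features, names(cell_table))
  if (length(miss))
    stop("cell table lacks model feature(s): ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  X <- as.matrix(cell_table[, model$features, drop = FALSE])
  Z <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  n <- nrow(Z)
  votes <- matrix(0L, n, length(model$classes),
                  dimnames = list(NULL, model$classes))
  margin <- matrix(0, n, length(model$classes),
                   dimnames = list(NULL, model$classes))
  for (pr in model$pairs) {
    m <- drop(Z %*% pr$coef) + pr$intercept  # > 0 favours class b
    bwin <- m > 0
    votes[, pr$b] <- votes[, pr$b] + bwin
    votes[, pr$a] <- votes[, pr$a] + !bwin
    margin[, pr$b] <- margin[, pr$b] + m
    margin[, pr$a] <- margin[, pr$a] - m
  }
  vapply(seq_len(n), function(i) {
    v <- votes[i, ]
    top <- which(v == max(v))
    if (length(top) > 1L) {
      mg <- margin[i, top]
      top <- top[mg == max(mg)]
    }
    model$classes[top[1]]
  }, character(1))
}

#' Per-well class fractions
#'
#' @param labels `data.frame` with columns `well` and `class` (labels from
#'   [predict_cells()]).
#' @return `data.frame` with columns `well`, `n`, `pct_M0`, `pct_M1like`,
#'   `pct_M2like`; percentages sum to 100 over classified cells.
#' @export
well_class_fractions <- function(labels) {
  stopifnot(all(c("well", "class") %in% names(labels)))
  wells <- unique(labels$well)
  rows <- lapply(wells, function(w) {
    cl <- labels$class[labels$well == w]
    n <- length(cl)
    data.frame(well = w, n = n,
               pct_M0 = 100 * mean(cl == "M0"),
               pct_M1like = 100 * mean(cl == "M1like"),
               pct_M2like = 100 * mean(cl == "M2like"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' DMSO-normalize per-well polarization scores
#'
#' normalized_score = (%M2like - mean %M2like over vehicle wells) -
#' (%M1like - mean %M1like over vehicle wells). By construction the
#' vehicle wells average exactly 0.
#'
#' @param scores Output of [well_class_fractions()].
#' @param platemap A [plate_map()] with at least one vehicle well present
#'   in `scores`.
#' @return `scores` with an extra `normalized_score` column.
#' @export
normalize_to_dmso <- function(scores, platemap) {
  stopifnot(inherits(platemap, "PlateMap"))
  veh <- intersect(vehicle_wells(platemap), scores$well)
  if (!length(veh))
    stop("plate ", platemap$plate_id, ": no vehicle wells among the scores")
  m2v <- mean(scores$pct_M2like[scores$well %in% veh])
  m1v <- mean(scores$pct_M1like[scores$well %in% veh])
  scores$normalized_score <- (scores$pct_M2like - m2v) -
    (scores$pct_M1like - m1v)
  scores
}

#' Relevant features of a linear model
#'
#' Per class pair, the nonzero coefficients on the standardized scale,
#' sorted by decreasing magnitude — the model's feature-relevance report.
#'
#' @param model A [train_linear_classifier()] model.
#' @return Named list (by pair) of `data.frame`s with columns `feature`,
#'   `coefficient`.
#' @export
relevant_features <- function(model) {
  stopifnot(inherits(model, "LinearModel"))
  lapply(model$pairs, function(pr) {
    nz <- which(pr$coef != 0)
    df <- data.frame(feature = names(pr$coef)[nz],
                     coefficient = unname(pr$coef[nz]),
                     stringsAsFactors = FALSE)
    df[order(-abs(df$coefficient)), , drop = FALSE]
  })
}

#' Morphology-ablation comparison
#'
#' Trains three models on the identical sampled training cells — all
#' features, without the 15 standard morphology features, and without the
#' cell roundness feature — scores every well with each, and reports the
#' DMSO-normalized scores side by side with their pairwise Pearson
#' correlations.
#'
#' @param cell_table Single-cell feature table.
#' @param spec A [training_spec()] (its `feature_mask` is ignored).
#' @param platemap A [plate_map()] for DMSO normalization.
#' @param catalog Feature catalog.
#' @return List with `scores` (well x mask table of normalized scores),
#'   `correlations` (3x3 Pearson matrix), `models` (the three models).
#' @export
ablation_compare <- function(cell_table, spec, platemap,
                             catalog = enumerate_catalog()) {
  training <- sample_training_cells(cell_table, spec)
  masks <- c("all", "no_standard_morphology", "no_roundness")
  models <- list()
  score_cols <- list()
  for (mk in masks) {
    sp <- spec
    sp$feature_mask <- mk
    mod <- train_linear_classifier(training, sp, catalog)
    labels <- data.frame(well = cell_table$well,
                         class = predict_cells(mod, cell_table))
    sc <- normalize_to_dmso(well_class_fractions(labels), platemap)
    models[[mk]] <- mod
    score_cols[[mk]] <- sc[, c("well", "normalized_score")]
    names(score_cols[[mk]])[2] <- mk
  }
  scores <- Reduce(function(a, b) merge(a, b, by = "well"), score_cols)
  M <- as.matrix(scores[, masks])
  correlations <- stats::cor(M)
  list(scores = scores, correlations = correlations, models = models)
}

#' Save / load a linear model as JSON
#'
#' @param model A [train_linear_classifier()] model.
#' @param path JSON file path.
#' @return `read_linear_model` returns the model; predictions after a
#'   round trip are identical.
#' @export
write_linear_model <- function(model, path) {
  stopifnot(inherits(model, "LinearModel"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_linear_model
#' @export
read_linear_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$classes <- as.character(obj$classes)
  obj$center <- unlist(obj$center)
  obj$scale <- unlist(obj$scale)
  obj$features <- as.character(obj$features)
  obj$pairs <- lapply(obj$pairs, function(pr)
    list(a = pr$a, b = pr$b, coef = unlist(pr$coef),
         intercept = pr$intercept))
  structure(obj, class = "LinearModel")
}
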