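## Per-well phenotypic fingerprints: mean feature vector per well,
## column standardization (center, scale by sample sd), and the first two
## principal components of the well x feature matrix.

#' Aggregate a single-cell feature table to well profiles
#'
#' Arithmetic mean of every feature column per well. Wells with zero cells
#' simply do not occur in the input and are therefore absent.
#'
#' @param cell_table Feature table from [extract_features()].
#' @param feature_cols Feature column names (default: every numeric column
#'   after the key columns `plate`, `well`, `field`, `cell_id`, `cy`, `cx`).
#' @param platemap Optional [plate_map()] used to attach treatment labels.
#' @return `data.frame` with `well` (+ `treatment` if a plate map is
#'   given) and one mean column per feature.
#' @export
aggregate_wells <- function(cell_table, feature_cols = NULL, platemap = NULL) {
  stopifnot(is.data.frame(cell_table), nrow(cell_table) > 0)
  if (is.null(feature_cols))
    feature_cols <- setdiff(names(cell_table),
                            c("plate", "well", "field", "cell_id", "cy", "cx"))
  wells <- unique(cell_table$well)
  mat <- matrix(0, length(wells), length(feature_cols),
                dimnames = list(NULL, feature_cols))
  for (i in seq_along(wells)) {
    sel <- cell_table$well == wells[i]
    mat[i, ] <- colMeans(as.matrix(cell_table[sel, feature_cols, drop = FALSE]))
  }
  out <- cbind(data.frame(well = wells, stringsAsFactors = FALSE),
               as.data.frame(mat))
  if (!is.null(platemap))
    out <- cbind(out[, "well", drop = FALSE],
                 treatment = platemap$wells$treatment[
                   match(out$well, platemap$wells$well)],
                 out[, feature_cols, drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Standardize well profiles
#'
#' Centers each feature column by its mean and scales by its sample
#' (n-1) standard deviation. Zero-variance columns cannot be scaled and
#' are dropped (their names are logged and returned).
#'
#' @param profiles Output of [aggregate_wells()] or a plain numeric
#'   matrix/data.frame of profiles (non-numeric columns are carried
#'   through as row metadata).
#' @return List with `matrix` (standardized wells x features), `center`,
#'   `scale` (named vectors over retained columns), `dropped` (names of
#'   zero-variance columns), and `meta` (the non-numeric columns).
#' @export
standardize <- function(profiles) {
  df <- as.data.frame(profiles)
  num <- vapply(df, is.numeric, logical(1))
  meta <- df[, !num, drop = FALSE]
  X <- as.matrix(df[, num, drop = FALSE])
  if (nrow(X) < 2L) stop("standardization needs >= 2 profiles")
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  dropped <- colnames(X)[scl == 0 | !is.finite(scl)]
  if (length(dropped))
    cp_log("standardize", "dropping ", length(dropped),
           " zero-variance column(s): ",
           paste(utils::head(dropped, 5), collapse = ", "),
           if (length(dropped) > 5) ", ...")
  keep <- setdiff(colnames(X), dropped)
  X <- X[, keep, drop = FALSE]
  Z <- sweep(sweep(X, 2, ctr[keep]), 2, scl[keep], "/")
  list(matrix = Z, center = ctr[keep], scale = scl[keep],
       dropped = dropped, meta = meta)
}

#' Two-component PCA fingerprint
#'
#' First two principal components (by descending eigenvalue) of an
#' already standardized wells x features matrix, with a deterministic
#' sign convention: in each loading vector the largest-magnitude entry is
#' made positive.
#'
#' @param Z Standardized numeric matrix (>= 3 rows, >= 2 columns), e.g.
#'   `standardize(profiles)$matrix`.
#' @return An object of class `PCAResult`: list with `coords` (wells x 2),
#'   `explained_variance_ratio` (length 2, descending), `loadings`
#'   (features x 2).
#' @export
pca2 <- function(Z) {
  Z <- as.matrix(Z)
  if (nrow(Z) < 3L) stop("PCA needs >= 3 wells")
  if (ncol(Z) < 2L) stop("PCA needs >= 2 retained feature columns")
  total_var <- sum(apply(Z, 2, stats::var))
  if (total_var == 0)
    stop("profile matrix has rank 0: no variance to decompose")
  pr <- stats::prcomp(Z, center = FALSE, scale. = FALSE)
  if (length(pr$sdev) < 2L)
    stop("profile matrix has rank < 2")
  load <- pr$rotation[, 1:2, drop = FALSE]
  coords <- pr$x[, 1:2, drop = FALSE]
  for (k in 1:2) {
    j <- which.max(abs(load[, k]))
    if (load[j, k] < 0) {
      load[, k] <- -load[, k]
      coords[, k] <- -coords[, k]
    }
  }
  evr <- pr$sdev[1:2]^2 / total_var
  structure(list(coords = coords, explained_variance_ratio = evr,
                 loadings = load), class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat(sprintf("PCAResult: %d wells, PC1/PC2 explain %.1f%% / %.1f%%\n",
              nrow(x$coords), 100 * x$explained_variance_ratio[1],
              100 * x$explained_variance_ratio[2]))
  invisible(x)
}

#' Well-profile PCA in one call
#'
#' Convenience wrapper: [aggregate_wells()] -> [standardize()] -> [pca2()].
#'
#' @inheritParams aggregate_wells
#' @return The [pca2()] result with an extra element `wells`.
#' @export
profile_pca <- function(cell_table, feature_cols = NULL, platemap = NULL) {
  prof <- aggregate_wells(cell_table, feature_cols, platemap)
  st <- standardize(prof)
  res <- pca2(st$matrix)
  res$wells <- prof$well
  rownames(res$coords) <- prof$well
  res
}
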