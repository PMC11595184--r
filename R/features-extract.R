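## Per-cell feature extraction. Response maps (SER, Gabor, sliding-parabola
## top-hat) are computed once per field and channel, then averaged over each
## cell's region pixels; all texture features are divided by the region mean
## intensity ("kernel normalization"), making them invariant to positive
## rescaling of the whole image.

## edge-replicating shift of a matrix by (dr, dc)
shift_mat <- function(m, dr, dc) {
  H <- nrow(m); W <- ncol(m)
  ri <- pmin(pmax(seq_len(H) + dr, 1L), H)
  ci <- pmin(pmax(seq_len(W) + dc, 1L), W)
  m[ri, ci, drop = FALSE]
}

## Gaussian-derivative / Hessian-eigenvalue response maps at one scale.
## All eight responses are linear in image intensity and vanish on a
## constant image.
ser_response_maps <- function(img, scale) {
  sm <- EBImage::filter2(img, gaussian_kernel(scale), boundary = "replicate")
  Lx <- (shift_mat(sm, 0L, 1L) - shift_mat(sm, 0L, -1L)) / 2 * scale
  Ly <- (shift_mat(sm, 1L, 0L) - shift_mat(sm, -1L, 0L)) / 2 * scale
  Lxx <- (shift_mat(sm, 0L, 1L) - 2 * sm + shift_mat(sm, 0L, -1L)) * scale^2
  Lyy <- (shift_mat(sm, 1L, 0L) - 2 * sm + shift_mat(sm, -1L, 0L)) * scale^2
  Lxy <- (shift_mat(sm, 1L, 1L) - shift_mat(sm, 1L, -1L) -
            shift_mat(sm, -1L, 1L) + shift_mat(sm, -1L, -1L)) / 4 * scale^2
  tr2 <- (Lxx + Lyy) / 2
  disc <- sqrt(((Lxx - Lyy) / 2)^2 + Lxy^2)
  l1 <- tr2 - disc  # smaller eigenvalue
  l2 <- tr2 + disc  # larger eigenvalue
  list(spot = pos_part(-(l1 + l2)),   # scale-normalized Laplacian, bright
       hole = pos_part(l1 + l2),      # and dark blob responses

       edge = sqrt(Lx^2 + Ly^2),
       ridge = pos_part(-l1),
       valley = pos_part(l2),
       saddle = sqrt(pos_part(-l1) * pos_part(l2)),
       bright = pos_part(img - sm),
       dark = pos_part(sm - img))
}

## Quadrature Gabor kernel pair (even kernel mean-subtracted so a constant
## image yields zero response).
gabor_kernel_pair <- function(period, theta_deg, max_radius = Inf) {
  freq <- 1 / period
  sigma <- 0.56 / freq
  radius <- min(ceiling(2.5 * sigma), max_radius)
  x <- (-radius):radius
  X <- matrix(x, length(x), length(x), byrow = TRUE)
  Y <- matrix(x, length(x), length(x))
  th <- theta_deg * pi / 180
  xr <- cos(th) * X + sin(th) * Y
  env <- exp(-(X^2 + Y^2) / (2 * sigma^2))
  env <- env / sum(env)
  even <- env * cos(2 * pi * freq * xr)
  odd <- env * sin(2 * pi * freq * xr)
  list(even = even - mean(even), odd = odd - mean(odd))
}

gabor_magnitude_map <- function(img, period, theta_deg) {
  max_r <- floor((min(dim(img)) - 1) / 2)
  k <- gabor_kernel_pair(period, theta_deg, max_radius = max_r)
  re <- EBImage::filter2(img, k$even, boundary = "replicate")
  im <- EBImage::filter2(img, k$odd, boundary = "replicate")
  sqrt(re^2 + im^2)
}

## Sliding-parabola background removal: grayscale opening with a parabolic
## structuring element (separable 1D min/max sweeps), subtracted from the
## image. The parabola depth at the radius equals the image's robust
## dynamic range, so structures wider than ~2*radius survive into the
## background.
parabola_tophat <- function(img, radius = 10) {
  rng <- stats::quantile(img, c(0.01, 0.99), names = FALSE)
  amp <- max(rng[2] - rng[1], 1e-9)
  cpar <- amp / radius^2
  sweep1 <- function(m, op) {
    out <- m
    for (k in seq(-radius, radius)) {
      if (k == 0) next
      pen <- cpar * k^2
      out <- if (op == "erode") pmin(out, shift_mat(m, 0L, k) + pen)
             else pmax(out, shift_mat(m, 0L, k) - pen)
    }
    out
  }
  sweep2 <- function(m, op) {
    out <- m
    for (k in seq(-radius, radius)) {
      if (k == 0) next
      pen <- cpar * k^2
      out <- if (op == "erode") pmin(out, shift_mat(m, k, 0L) + pen)
             else pmax(out, shift_mat(m, k, 0L) - pen)
    }
    out
  }
  eroded <- sweep2(sweep1(img, "erode"), "erode")
  opened <- sweep1(sweep2(eroded, "dilate"), "dilate")
  pos_part(img - opened)
}

#' Standard intensity statistics of a region
#'
#' The 13 standard intensity properties of one region in one channel:
#' mean, sd, CV, median, MAD (median absolute deviation, unscaled), min,
#' max, sum, 5 and 95 percent quantiles, skewness, kurtosis (excess), and
#' the background-subtracted integrated intensity (sum minus field
#' background median times area).
#'
#' @param values Numeric vector of region pixel intensities.
#' @param bg_median Field background median (pixels outside all cells).
#' @return Named numeric vector of length 13. An empty region yields all
#'   zeros (the documented sentinel).
#' @export
extract_intensity <- function(values, bg_median = 0) {
  out <- stats::setNames(numeric(length(INTENSITY_STATS)), INTENSITY_STATS)
  n <- length(values)
  if (n == 0L) return(out)
  m <- mean(values)
  s <- if (n > 1L) stats::sd(values) else 0
  md <- stats::median(values)
  m2 <- mean((values - m)^2)
  out[["mean"]] <- m
  out[["sd"]] <- s
  out[["cv"]] <- if (m != 0) s / m else 0
  out[["median"]] <- md
  out[["mad"]] <- stats::median(abs(values - md))
  out[["min"]] <- min(values)
  out[["max"]] <- max(values)
  out[["sum"]] <- sum(values)
  qs <- stats::quantile(values, c(0.05, 0.95), names = FALSE)
  out[["q05"]] <- qs[1]; out[["q95"]] <- qs[2]
  out[["skewness"]] <- if (m2 > 0) mean((values - m)^3) / m2^1.5 else 0
  out[["kurtosis"]] <- if (m2 > 0) mean((values - m)^4) / m2^2 - 3 else 0
  out[["sumbg"]] <- sum(values) - bg_median * n
  out
}

## Crofton 4-direction perimeter of a logical mask matrix (zero-padded).
crofton_perimeter <- function(mask) {
  A <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  A[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask * 1L
  nh <- sum(A[, -1] != A[, -ncol(A)])
  nv <- sum(A[-1, ] != A[-nrow(A), ])
  nd1 <- sum(A[-1, -1] != A[-nrow(A), -ncol(A)])
  nd2 <- sum(A[-1, -ncol(A)] != A[-nrow(A), -1])
  pi / 8 * (nh + nv + (nd1 + nd2) / sqrt(2))
}

## idx -> 0-based (row, col) coordinates in an H-row grid
idx_coords <- function(idx, H) {
  cbind(y = (idx - 1L) %% H, x = (idx - 1L) %/% H)
}

## Mask morphology from a pixel index set: area, Crofton roundness, axis
## lengths of the second-moment equivalent ellipse.
mask_morphology <- function(idx, H, pixel_size_um = 1) {
  n <- length(idx)
  if (n == 0L)
    return(c(area = 0, roundness = 0, width = 0, length = 0,
             width_to_length = 1, area_px = 0, perimeter_px = 0))
  co <- idx_coords(idx, H)
  if (n == 1L)
    return(c(area = pixel_size_um^2, roundness = 1, width = 1 * pixel_size_um,
             length = 1 * pixel_size_um, width_to_length = 1, area_px = 1,
             perimeter_px = 4))
  y0 <- co[, 1] - min(co[, 1]); x0 <- co[, 2] - min(co[, 2])
  mask <- matrix(FALSE, max(y0) + 1L, max(x0) + 1L)
  mask[cbind(y0 + 1L, x0 + 1L)] <- TRUE
  P <- crofton_perimeter(mask)
  roundness <- min(1, 4 * pi * n / P^2)
  muy <- mean(co[, 1]); mux <- mean(co[, 2])
  vy <- mean((co[, 1] - muy)^2); vx <- mean((co[, 2] - mux)^2)
  vxy <- mean((co[, 1] - muy) * (co[, 2] - mux))
  disc <- sqrt(((vx - vy) / 2)^2 + vxy^2)
  lmax <- (vx + vy) / 2 + disc
  lmin <- pos_part((vx + vy) / 2 - disc)
  len <- 4 * sqrt(lmax); wid <- 4 * sqrt(lmin)
  c(area = n * pixel_size_um^2, roundness = roundness,
    width = wid * pixel_size_um, length = len * pixel_size_um,
    width_to_length = if (len > 0) min(1, wid / len) else 1,
    area_px = n, perimeter_px = P)
}

#' Standard morphology properties per region
#'
#' Area (um^2), roundness (4 pi area / perimeter^2, Crofton perimeter,
#' clamped to \[0, 1\]), width and length (minor/major axis lengths of the
#' second-moment equivalent ellipse, um) and their ratio, for each of the
#' three regions of a cell.
#'
#' @param regions A single cell's region list (`nucleus`, `cytoplasm`,
#'   `cell` pixel index vectors).
#' @param H Number of grid rows.
#' @param pixel_size_um Pixel size.
#' @return Named numeric vector `morph_<region>_<prop>`; an empty
#'   cytoplasm falls back to the nucleus values.
#' @export
extract_morph_standard <- function(regions, H, pixel_size_um = 1) {
  vals <- list()
  nucleus_m <- mask_morphology(regions$nucleus, H, pixel_size_um)
  for (rg in CP_REGIONS) {
    idx <- regions[[rg]]
    m <- if (length(idx) == 0L && rg == "cytoplasm") nucleus_m
         else mask_morphology(idx, H, pixel_size_um)
    for (p in MORPH_PROPS)
      vals[[sprintf("morph_%s_%s", rg, p)]] <- unname(m[[p]])
  }
  unlist(vals)
}

#' SER texture features of a region
#'
#' Spot, hole, edge, ridge, valley, saddle, bright and dark responses from
#' scale-normalized Gaussian-derivative / Hessian-eigenvalue maps,
#' rectified, averaged over the region and divided by the region mean
#' intensity, at each requested scale. Invariant to multiplying the image
#' by a positive constant; zero on constant images.
#'
#' @param img Channel intensity matrix.
#' @param idx Region pixel indices.
#' @param scales Scales in px.
#' @param maps Optional precomputed [ser_response_maps] per scale.
#' @return Named numeric vector `<prop>_s<scale>` of length
#'   `8 * length(scales)`.
#' @export
extract_ser <- function(img, idx, scales = c(1, 2, 4, 8), maps = NULL) {
  out <- numeric(0)
  mi <- if (length(idx)) mean(img[idx]) else 0
  for (si in seq_along(scales)) {
    sc <- scales[si]
    mp <- if (is.null(maps)) ser_response_maps(img, sc) else maps[[si]]
    for (p in SER_PROPS) {
      v <- if (mi > 0) mean(mp[[p]][idx]) / mi else 0
      out[sprintf("%s_s%g", p, sc)] <- v
    }
  }
  out
}

#' Gabor texture features of a region
#'
#' Mean magnitude and energy of a quadrature Gabor filter bank over the
#' region, kernel-normalized: magnitude is divided by the region mean
#' intensity and energy by its square, so both are invariant to positive
#' intensity scaling. With orientations at multiples of 45 degrees, a
#' 90-degree image rotation permutes the orientation-indexed features.
#'
#' @param img Channel intensity matrix.
#' @param idx Region pixel indices.
#' @param periods Carrier periods (px).
#' @param orientations Orientations (degrees).
#' @param maps Optional precomputed magnitude maps, list indexed
#'   `[[period]][[orientation]]` by position.
#' @return Named numeric vector `p<period>_o<deg>_<mag|energy>`.
#' @export
extract_gabor <- function(img, idx, periods = c(16, 8, 4),
                          orientations = c(0, 45, 90, 135), maps = NULL) {
  out <- numeric(0)
  mi <- if (length(idx)) mean(img[idx]) else 0
  for (pi_ in seq_along(periods)) for (oi in seq_along(orientations)) {
    mag <- if (is.null(maps))
      gabor_magnitude_map(img, periods[pi_], orientations[oi])
    else maps[[pi_]][[oi]]
    pref <- sprintf("p%g_o%g", periods[pi_], orientations[oi])
    if (mi > 0 && length(idx)) {
      out[paste0(pref, "_mag")] <- mean(mag[idx]) / mi
      out[paste0(pref, "_energy")] <- mean(mag[idx]^2) / mi^2
    } else {
      out[paste0(pref, "_mag")] <- 0
      out[paste0(pref, "_energy")] <- 0
    }
  }
  out
}

## STAR descriptors on a background-removed (top-hat) intensity patch:
## 12 reflection-odd moment symmetry scores, 12 threshold-compactness
## features (3 at each of 4 quantile thresholds), 4 axial, 4 radial and
## 4 radial-profile features; intensity-weighted throughout.
star_descriptors <- function(tophat_vals, idx, H) {
  tags <- star_tags()
  out <- stats::setNames(numeric(length(tags)), tags)
  n <- length(idx)
  tot <- sum(tophat_vals)
  if (n == 0L || tot <= 0) {
    out[grepl("^sym", names(out))] <- 1
    return(out)
  }
  w <- tophat_vals / tot
  co <- idx_coords(idx, H)
  muy <- sum(w * co[, 1]); mux <- sum(w * co[, 2])
  dy <- co[, 1] - muy; dx <- co[, 2] - mux
  vy <- sum(w * dy^2); vx <- sum(w * dx^2); vxy <- sum(w * dx * dy)
  disc <- sqrt(((vx - vy) / 2)^2 + vxy^2)
  la <- (vx + vy) / 2 + disc; lb <- pos_part((vx + vy) / 2 - disc)
  ## near-isotropic regions have no defined principal axis: snap to the
  ## grid frame so the features stay translation-stable
  phi <- if (disc <= 1e-8 * (vx + vy)) 0 else
    0.5 * atan2(2 * vxy, vx - vy)
  u <- cos(phi) * dx + sin(phi) * dy      # principal (major) axis
  v <- -sin(phi) * dx + cos(phi) * dy
  sig <- sqrt(sqrt(max(la, 1e-12)) * sqrt(max(lb, 1e-12)))
  un <- u / sig; vn <- v / sig
  ## 12 reflection-odd normalized moments -> symmetry scores in (0, 1]
  for (k in seq_along(STAR_SYM_ORDERS)) {
    pq <- STAR_SYM_ORDERS[[k]]
    m <- sum(w * un^pq[1] * vn^pq[2])
    out[sprintf("sym%d%d", pq[1], pq[2])] <- 1 / (1 + abs(m))
  }
  ## threshold compactness at quantile thresholds (q = fraction kept)
  for (q in STAR_TC_QUANTILES) {
    thr <- stats::quantile(tophat_vals, 1 - q, names = FALSE)
    keep <- tophat_vals >= thr
    tag <- sprintf("tc%02d", q * 100)
    if (!any(keep)) {
      out[paste0(tag, "_compact")] <- 0
      out[paste0(tag, "_areafrac")] <- 0
      out[paste0(tag, "_intfrac")] <- 0
    } else {
      mm <- mask_morphology(idx[keep], H)
      out[paste0(tag, "_compact")] <- unname(mm["roundness"])
      out[paste0(tag, "_areafrac")] <- mean(keep)
      out[paste0(tag, "_intfrac")] <- sum(tophat_vals[keep]) / tot
    }
  }
  ## axial: all near zero for radially symmetric signal
  sa <- sqrt(max(la, 1e-12)); sb <- sqrt(max(lb, 1e-12))
  m30 <- sum(w * (u / sa)^3); m03 <- sum(w * (v / sb)^3)
  out["axial_elongation"] <- 1 - sb / sa
  out["axial_skewmajor"] <- abs(m30)
  out["axial_skewminor"] <- abs(m03)
  out["axial_corr"] <- abs(vxy) / (sqrt(max(vx, 1e-12)) * sqrt(max(vy, 1e-12)))
  ## radial distribution
  r <- sqrt(dx^2 + dy^2)
  rmax <- max(r, 1e-9)
  mr <- sum(w * r)
  sr <- sqrt(pos_part(sum(w * r^2) - mr^2))
  out["radial_meanr"] <- mr / rmax
  out["radial_sdr"] <- sr / rmax
  out["radial_halfmass"] <- sum(w[r <= rmax / 2])
  m3r <- sum(w * (r - mr)^3)
  out["radial_skewr"] <- if (sr > 0) m3r / sr^3 else 0
  ## radial profile over 4 shells
  ## snap values numerically on a shell boundary before binning
  shell <- pmin(floor(round(r / rmax * 4, 9)) + 1, 4)
  pmeans <- vapply(1:4, function(s) {
    sel <- shell == s
    if (any(sel)) mean(tophat_vals[sel]) else 0
  }, numeric(1))
  mu_all <- mean(tophat_vals)
  xs <- 1:4
  out["profile_slope"] <- sum((xs - mean(xs)) * (pmeans - mean(pmeans))) /
    sum((xs - mean(xs))^2) / max(mu_all, 1e-12)
  out["profile_c2e"] <- (pmeans[1] - pmeans[4]) /
    (pmeans[1] + pmeans[4] + 1e-12)
  ord <- order(r)
  cum <- cumsum(w[ord])
  out["profile_halfrad"] <- r[ord][which(cum >= 0.5)[1]] / rmax
  out["profile_var"] <- stats::var(pmeans) / max(mu_all, 1e-12)^2
  out
}

#' STAR intensity-weighted shape features of a region
#'
#' Removes background with a sliding parabola (grayscale opening with a
#' parabolic structuring element), then computes 36 intensity-weighted
#' descriptors: 12 moment-based symmetry scores, threshold compactness at
#' 4 quantile thresholds (3 features each), 4 axial, 4 radial and 4
#' radial-profile features. Translation invariant.
#'
#' @param img Channel intensity matrix.
#' @param idx Region pixel indices.
#' @param radius Sliding-parabola radius (px).
#' @param tophat Optional precomputed top-hat map.
#' @return Named numeric vector of length 36.
#' @export
extract_star <- function(img, idx, radius = 10, tophat = NULL) {
  if (is.null(tophat)) tophat <- parabola_tophat(img, radius)
  star_descriptors(tophat[idx], idx, nrow(img))
}

## Precompute all response maps for one channel grid.
channel_maps <- function(img, config) {
  list(ser = if ("ser" %in% config$families)
         lapply(config$ser_scales, function(s) ser_response_maps(img, s)),
       gabor = if ("gabor" %in% config$families)
         lapply(config$gabor_periods, function(p)
           lapply(config$gabor_orientations, function(o)
             gabor_magnitude_map(img, p, o))),
       tophat = if ("star" %in% config$families)
         parabola_tophat(img, config$star_radius))
}

#' Extract all features for one segmented field
#'
#' One row per retained cell with the key columns (`plate`, `well`,
#' `field`, `cell_id`, nucleus centroid `cy`/`cx`) followed by exactly the
#' catalog columns of `config`.
#'
#' @param seg A [cell_segmentation()].
#' @param channels Named list of the four channel matrices for the field.
#' @param config A [feature_config()].
#' @param plate_id Plate identifier for the key columns.
#' @return `data.frame` feature table chunk.
#' @export
extract_all <- function(seg, channels, config = feature_config(),
                        plate_id = "plate") {
  stopifnot(inherits(seg, "CellSegmentation"))
  miss <- setdiff(config$channels, names(channels))
  if (length(miss)) stop("missing channel(s): ", paste(miss, collapse = ", "))
  catalog <- enumerate_catalog(config)
  regions <- derive_regions(seg)
  H <- nrow(seg$cell_mask)
  summ <- seg_cell_summary(seg)
  n <- length(seg$cell_ids)
  if (n == 0L) {
    empty <- as.data.frame(matrix(numeric(0), 0, nrow(catalog)))
    names(empty) <- catalog$name
    return(cbind(data.frame(plate = character(0), well = character(0),
                            field = integer(0), cell_id = integer(0),
                            cy = numeric(0), cx = numeric(0)), empty))
  }
  maps <- lapply(config$channels, function(ch)
    channel_maps(channels[[ch]], config))
  names(maps) <- config$channels
  bg_median <- lapply(config$channels, function(ch) {
    bg <- channels[[ch]][seg$cell_mask == 0L]
    if (length(bg)) stats::median(bg) else 0
  })
  names(bg_median) <- config$channels
  px <- seg$pixel_size_um
  feat <- matrix(0, n, nrow(catalog), dimnames = list(NULL, catalog$name))
  for (i in seq_len(n)) {
    rg_set <- regions[[as.character(seg$cell_ids[i])]]
    row <- numeric(0)
    for (ch in config$channels) {
      img <- channels[[ch]]
      for (rg in config$regions) {
        idx <- rg_set[[rg]]
        pref <- sprintf("_%s_%s", ch, rg)
        if ("intensity" %in% config$families) {
          v <- extract_intensity(img[idx], bg_median[[ch]])
          names(v) <- paste0("int", pref, "_", names(v))
          row <- c(row, v)
        }
        if ("ser" %in% config$families) {
          v <- extract_ser(img, idx, config$ser_scales, maps[[ch]]$ser)
          names(v) <- paste0("ser", pref, "_", names(v))
          row <- c(row, v)
        }
        if ("gabor" %in% config$families) {
          v <- extract_gabor(img, idx, config$gabor_periods,
                             config$gabor_orientations, maps[[ch]]$gabor)
          names(v) <- paste0("gabor", pref, "_", names(v))
          row <- c(row, v)
        }
        if ("star" %in% config$families) {
          v <- extract_star(img, idx, config$star_radius, maps[[ch]]$tophat)
          names(v) <- paste0("star", pref, "_", names(v))
          row <- c(row, v)
        }
      }
    }
    if ("morph" %in% config$families)
      row <- c(row, extract_morph_standard(rg_set, H, px))
    if ("context" %in% config$families) {
      dcc <- sqrt((summ$cell_cy - summ$cell_cy[i])^2 +
                    (summ$cell_cx - summ$cell_cx[i])^2) * px
      row <- c(row, c(
        context_nucleus_cell_area_fraction =
          summ$nucleus_area_px[i] / max(summ$cell_area_px[i], 1),
        context_nucleus_displacement =
          sqrt((summ$cy[i] - summ$cell_cy[i])^2 +
                 (summ$cx[i] - summ$cell_cx[i])^2) * px,
        context_neighbor_count_30um =
          sum(dcc <= config$neighbor_radius_um) - 1,
        context_border_distance =
          min(summ$cell_cy[i], summ$cell_cx[i],
              (H - 1) - summ$cell_cy[i],
              (ncol(seg$cell_mask) - 1) - summ$cell_cx[i]) * px))
    }
    feat[i, ] <- row[catalog$name]
  }
  cbind(data.frame(plate = plate_id, well = seg$well, field = seg$field,
                   cell_id = seg$cell_ids, cy = summ$cy, cx = summ$cx,
                   stringsAsFactors = FALSE),
        as.data.frame(feat))
}

#' Segment and featurize a whole plate
#'
#' Runs flatfield correction (optional), segmentation and feature
#' extraction over every field of a plate bundle and returns the single-
#' cell feature table.
#'
#' @param bundle A [plate_bundle()].
#' @param config A [feature_config()].
#' @param flatfield Apply per-field flatfield correction first.
#' @param min_area_px,exclude_border Passed to [find_nuclei()].
#' @return `data.frame`: key columns + one column per catalog entry.
#' @export
extract_features <- function(bundle, config = feature_config(),
                             flatfield = TRUE, min_area_px = 50L,
                             exclude_border = TRUE) {
  stopifnot(inherits(bundle, "PlateBundle"))
  t0 <- as.numeric(Sys.time())
  if (flatfield) bundle <- flatfield_correct_bundle(bundle)
  fl <- bundle_fields(bundle)
  chunks <- vector("list", nrow(fl))
  for (i in seq_len(nrow(fl))) {
    seg <- segment_field(bundle, fl$well[i], fl$field[i],
                         min_area_px = min_area_px,
                         exclude_border = exclude_border)
    chunks[[i]] <- extract_all(seg, bundle$images[[fl$key[i]]], config,
                               plate_id = bundle$platemap$plate_id)
  }
  out <- do.call(rbind, chunks)
  rownames(out) <- NULL
  cp_log("features", sprintf("%d cells x %d features from %d fields",
                             nrow(out), nrow(enumerate_catalog(config)),
                             nrow(fl)), t0 = t0)
  out
}
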