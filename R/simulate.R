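## Seeded synthetic cell painting plates. Cells are rotated super-ellipses
## with low-order boundary jitter, rasterized and lightly blurred; channel
## intensities follow the organelle logic of the assay (Hoechst in the
## nucleus, concanavalin-A-like Alexa488 filling the cell body, textured
## Alexa568/Alexa647 within the cell). Class mixtures per well are realized
## with exact largest-remainder allocation so mixture-recovery tests are
## exact. Everything is a pure function of (seed, config, platemap).

default_class_params <- function() {
  ## Aspect-ratio regime: M1-like round (~1.1), M0 intermediate (~2.0),
  ## M2-like elongated (~3.0); dead cells are small with condensed bright
  ## nuclei and dim cytoplasm (area x0.35, nucleus intensity x2, cytoplasm
  ## x0.3 relative to M0).
  int <- function(h, a488, a568, a647)
    list(Hoechst33342 = h, Alexa488 = a488, Alexa568 = a568, Alexa647 = a647)
  list(
    M0 = list(aspect = c(mean = 2.0, sd = 0.20),
              area_um2 = c(mean = 450, sd = 70),
              nucleus_fraction = 0.25,
              intensity = int(c(3000, 400), c(1500, 200),
                              c(800, 120), c(800, 120))),
    M1like = list(aspect = c(mean = 1.1, sd = 0.08),
                  area_um2 = c(mean = 420, sd = 65),
                  nucleus_fraction = 0.25,
                  intensity = int(c(3000, 400), c(1500, 200),
                                  c(2200, 300), c(600, 100))),
    M2like = list(aspect = c(mean = 3.0, sd = 0.30),
                  area_um2 = c(mean = 480, sd = 75),
                  nucleus_fraction = 0.25,
                  intensity = int(c(3000, 400), c(1500, 200),
                                  c(600, 100), c(2200, 300))),
    dead = list(aspect = c(mean = 1.1, sd = 0.08),
                area_um2 = c(mean = 450 * 0.35, sd = 25),
                nucleus_fraction = 0.5,
                intensity = int(c(6000, 700), c(450, 80),
                                c(240, 50), c(240, 50))))
}

#' Simulation configuration
#'
#' Parameters of the synthetic plate generator. The defaults emulate a
#' 384-well macrophage cell painting plate imaged at 20x with camera
#' binning (1080 x 1080 grid, 0.6 um pixels) and the three polarization
#' regimes the analysis assumes: round M1-like cells (aspect ratio ~1.1),
#' intermediate M0 (~2.0), elongated M2-like (~3.0), plus a small
#' bright-nucleus dead phenotype. Tests and examples typically shrink
#' `image_size` and `cells_per_field`.
#'
#' @param seed Integer seed; together with the config and plate map it
#'   fully determines the output bits.
#' @param image_size Integer pair (height, width) of each field grid.
#' @param cells_per_field Cells rendered per field.
#' @param mixtures Named list mapping a treatment label (or well address)
#'   to a named fraction vector over [cp_classes()] summing to 1. Wells
#'   with role vehicle/untreated default to pure M0.
#' @param class_params Per-class shape and intensity parameters; see
#'   the package source for the default structure (aspect mean/sd,
#'   area mean/sd in um^2, nucleus fraction, per-channel intensity mean/sd).
#' @param baseline Background intensity in camera counts.
#' @param noise_sd Additive Gaussian noise sd (counts); 0 disables.
#' @param poisson If `TRUE`, pixel values are Poisson-resampled.
#' @param illumination_amplitude Amplitude in \[0, 1) of the multiplicative
#'   second-order (radial quadratic) illumination surface; 0 disables.
#' @param pixel_size_um Pixel edge length in micrometres.
#' @param boundary_jitter Relative amplitude of the low-order radial
#'   perturbation of each cell outline.
#' @param blur_sigma Gaussian blur sigma (px) applied after rasterization.
#' @param place_border_cell If `TRUE`, the first cell of field 0 of each
#'   well is centred on the top image edge (for border-exclusion tests).
#' @param cell_count_overrides Named list (by well address or treatment
#'   label) of per-field cell counts overriding `cells_per_field`, e.g. to
#'   emulate the reduced cell number of cytotoxic conditions.
#' @param keep_masks If `TRUE`, the ground truth also records each cell's
#'   rasterized pixel index set (for segmentation-overlap checks).
#' @return An object of class `SimulationConfig`.
#' @export
simulation_config <- function(seed = 1L, image_size = c(1080L, 1080L),
                              cells_per_field = 50L, mixtures = list(),
                              class_params = default_class_params(),
                              baseline = 100, noise_sd = 15, poisson = FALSE,
                              illumination_amplitude = 0.15,
                              pixel_size_um = 0.6, boundary_jitter = 0.06,
                              blur_sigma = 1, place_border_cell = FALSE,
                              cell_count_overrides = list(),
                              keep_masks = FALSE) {
  stopifnot(length(image_size) == 2L, all(image_size >= 32),
            cells_per_field >= 0, baseline >= 0, noise_sd >= 0,
            illumination_amplitude >= 0, illumination_amplitude < 1,
            pixel_size_um > 0, boundary_jitter >= 0)
  for (cls in names(class_params)) {
    p <- class_params[[cls]]
    if (p$aspect[["mean"]] < 1) stop("aspect-ratio mean must be >= 1 (", cls, ")")
    if (p$aspect[["sd"]] < 0 || p$area_um2[["sd"]] < 0)
      stop("sds must be nonnegative (", cls, ")")
  }
  for (nm in names(mixtures)) check_mixture(mixtures[[nm]], nm)
  structure(list(seed = as.integer(seed), image_size = as.integer(image_size),
                 cells_per_field = as.integer(cells_per_field),
                 mixtures = mixtures, class_params = class_params,
                 baseline = baseline, noise_sd = noise_sd, poisson = poisson,
                 illumination_amplitude = illumination_amplitude,
                 pixel_size_um = pixel_size_um,
                 boundary_jitter = boundary_jitter, blur_sigma = blur_sigma,
                 place_border_cell = place_border_cell,
                 cell_count_overrides = cell_count_overrides,
                 keep_masks = keep_masks),
            class = "SimulationConfig")
}

check_mixture <- function(mix, label) {
  if (is.null(names(mix)) || !all(names(mix) %in% CP_CLASSES))
    stop("mixture '", label, "' must be named over ",
         paste(CP_CLASSES, collapse = "/"))
  if (any(mix < 0)) stop("mixture '", label, "' has negative fractions")
  if (abs(sum(mix) - 1) > 1e-9)
    stop("mixture '", label, "' must sum to 1 (got ", sum(mix), ")")
  invisible(mix)
}

## Mixture lookup for a well row: explicit well address beats treatment
## label; vehicle/untreated default to pure M0.
well_mixture <- function(config, wellrow) {
  m <- config$mixtures[[wellrow$well]]
  if (is.null(m)) m <- config$mixtures[[wellrow$treatment]]
  if (is.null(m)) {
    if (wellrow$role %in% c("vehicle", "untreated"))
      m <- c(M0 = 1)
    else
      stop("no class mixture configured for treatment well ", wellrow$well,
           " (treatment '", wellrow$treatment, "')")
  }
  full <- stats::setNames(numeric(length(CP_CLASSES)), CP_CLASSES)
  full[names(m)] <- m
  full
}

## Exact largest-remainder apportionment of n cells to class fractions.
allocate_counts <- function(fractions, n) {
  raw <- fractions * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- raw - base
    ## ties broken by fixed class order for determinism
    ord <- order(-frac, match(names(fractions), CP_CLASSES))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  stats::setNames(as.integer(base), names(fractions))
}

## Super-ellipse area factor: area = f(n) * a * b.
superellipse_area_factor <- function(n) {
  4 * gamma(1 + 1 / n)^2 / gamma(1 + 2 / n)
}

## Rasterize one jittered, rotated super-ellipse; returns linear pixel
## indices into an H x W grid (or NULL if empty).
rasterize_cell <- function(cy, cx, area_px, aspect, phi, jitter_amp,
                           jitter_k, jitter_phase, H, W, exponent = 2.5) {
  fac <- superellipse_area_factor(exponent)
  b <- sqrt(area_px / (fac * aspect))
  a <- aspect * b
  rmax <- max(a, b) * (1 + jitter_amp) + 1
  r0 <- max(1L, floor(cy - rmax) + 1L); r1 <- min(H, ceiling(cy + rmax) + 1L)
  c0 <- max(1L, floor(cx - rmax) + 1L); c1 <- min(W, ceiling(cx + rmax) + 1L)
  if (r0 > r1 || c0 > c1) return(NULL)
  rr <- r0:r1; cc <- c0:c1
  dy <- (rr - 1) - cy; dx <- (cc - 1) - cx
  DY <- matrix(dy, length(rr), length(cc))
  DX <- matrix(dx, length(rr), length(cc), byrow = TRUE)
  u <- (cos(phi) * DX + sin(phi) * DY) / a
  v <- (-sin(phi) * DX + cos(phi) * DY) / b
  rho <- (abs(u)^exponent + abs(v)^exponent)^(1 / exponent)
  theta <- atan2(v, u)
  lim <- 1 + jitter_amp * sin(jitter_k * theta + jitter_phase)
  inside <- rho <= lim
  if (!any(inside)) return(NULL)
  idx_r <- row(inside)[inside] + r0 - 1L
  idx_c <- col(inside)[inside] + c0 - 1L
  (idx_c - 1L) * H + idx_r
}

## Smooth unit-mean texture field (granularity for Alexa568/647).
texture_field <- function(H, W, sigma = 2, rel_sd = 0.35) {
  n <- matrix(stats::rnorm(H * W), H, W)
  k <- gaussian_kernel(sigma)
  sm <- EBImage::filter2(n, k)
  sm <- sm / stats::sd(sm)
  pmax(1 + rel_sd * sm, 0.2)
}

gaussian_kernel <- function(sigma, radius = max(1L, ceiling(3 * sigma))) {
  x <- (-radius):radius
  k <- exp(-x^2 / (2 * sigma^2))
  k2 <- outer(k, k)
  k2 / sum(k2)
}

## Render one field; returns list(channels = named list of matrices,
## cells = data.frame ground truth).
render_field <- function(config, wellrow, field_idx, labels, plate_id) {
  H <- config$image_size[1]; W <- config$image_size[2]
  px_area <- config$pixel_size_um^2
  seed <- derive_seed(config$seed, paste(plate_id, wellrow$well, field_idx))
  with_seed(seed, {
    chans <- lapply(CP_CHANNELS, function(ch) matrix(0, H, W))
    names(chans) <- CP_CHANNELS
    occupied <- matrix(FALSE, H, W)
    labels <- sample(labels)
    n <- length(labels)
    truth <- vector("list", n)
    masks <- if (config$keep_masks) vector("list", n)
    margin <- 3
    for (i in seq_len(n)) {
      cls <- labels[i]
      p <- config$class_params[[cls]]
      placed <- FALSE
      for (try in seq_len(400L)) {
        aspect <- max(1, stats::rnorm(1, p$aspect[["mean"]], p$aspect[["sd"]]))
        area_um2 <- max(p$area_um2[["mean"]] * 0.3,
                        stats::rnorm(1, p$area_um2[["mean"]], p$area_um2[["sd"]]))
        area_px <- area_um2 / px_area
        phi <- stats::runif(1, 0, pi)
        jk <- sample(3:6, 1)
        jphase <- stats::runif(1, 0, 2 * pi)
        fac <- superellipse_area_factor(2.5)
        b <- sqrt(area_px / (fac * aspect)); a <- aspect * b
        rmax <- max(a, b) * (1 + config$boundary_jitter) + 1
        if (config$place_border_cell && i == 1L && field_idx == 0L) {
          cy <- 0; cx <- stats::runif(1, rmax + margin, W - 1 - rmax - margin)
        } else {
          if (2 * (rmax + margin) >= min(H, W) - 2)
            stop("cell too large for field; lower density or area")
          cy <- stats::runif(1, rmax + margin, H - 1 - rmax - margin)
          cx <- stats::runif(1, rmax + margin, W - 1 - rmax - margin)
        }
        idx <- rasterize_cell(cy, cx, area_px, aspect, phi,
                              config$boundary_jitter, jk, jphase, H, W)
        if (is.null(idx) || any(occupied[idx])) next
        ## nucleus: rounder concentric ellipse, slightly offset
        nuc_aspect <- sqrt(aspect)
        off <- stats::runif(2, -0.1, 0.1) * b
        nidx <- rasterize_cell(cy + off[1], cx + off[2],
                               area_px * p$nucleus_fraction, nuc_aspect, phi,
                               0, 3, 0, H, W, exponent = 2)
        nidx <- intersect(nidx, idx)
        if (!length(nidx)) next
        occupied[idx] <- TRUE
        draw <- function(ms) max(0.1 * ms[1], stats::rnorm(1, ms[1], ms[2]))
        chans$Hoechst33342[nidx] <- chans$Hoechst33342[nidx] +
          draw(p$intensity$Hoechst33342)
        chans$Alexa488[idx] <- chans$Alexa488[idx] + draw(p$intensity$Alexa488)
        chans$Alexa568[idx] <- chans$Alexa568[idx] + draw(p$intensity$Alexa568)
        chans$Alexa647[idx] <- chans$Alexa647[idx] + draw(p$intensity$Alexa647)
        truth[[i]] <- data.frame(
          plate = plate_id, well = wellrow$well, field = field_idx,
          cell_id = i, class = cls, aspect = aspect, area_um2 = area_um2,
          area_px = length(idx), cy = cy, cx = cx,
          stringsAsFactors = FALSE)
        if (config$keep_masks) masks[[i]] <- idx
        placed <- TRUE
        break
      }
      if (!placed && !(config$place_border_cell && i == 1L && field_idx == 0L)) {
        ## crowded field: systematic scan of candidate centres (shuffled
        ## 4 px grid) with a fresh median-sized shape draw
        aspect <- p$aspect[["mean"]]
        area_um2 <- p$area_um2[["mean"]] * 0.85
        area_px <- area_um2 / px_area
        phi <- stats::runif(1, 0, pi)
        jk <- sample(3:6, 1)
        jphase <- stats::runif(1, 0, 2 * pi)
        fac <- superellipse_area_factor(2.5)
        b <- sqrt(area_px / (fac * aspect)); a <- aspect * b
        rmax <- max(a, b) * (1 + config$boundary_jitter) + 1
        lo <- rmax + margin
        cys <- seq(lo, H - 1 - lo, by = 4)
        cxs <- seq(lo, W - 1 - lo, by = 4)
        cand <- expand.grid(cy = cys, cx = cxs)
        cand <- cand[sample(nrow(cand)), , drop = FALSE]
        for (ci in seq_len(nrow(cand))) {
          cy <- cand$cy[ci]; cx <- cand$cx[ci]
          idx <- rasterize_cell(cy, cx, area_px, aspect, phi,
                                config$boundary_jitter, jk, jphase, H, W)
          if (is.null(idx) || any(occupied[idx])) next
          nidx <- rasterize_cell(cy, cx, area_px * p$nucleus_fraction,
                                 sqrt(aspect), phi, 0, 3, 0, H, W,
                                 exponent = 2)
          nidx <- intersect(nidx, idx)
          if (!length(nidx)) next
          occupied[idx] <- TRUE
          draw <- function(ms) max(0.1 * ms[1], stats::rnorm(1, ms[1], ms[2]))
          chans$Hoechst33342[nidx] <- chans$Hoechst33342[nidx] +
            draw(p$intensity$Hoechst33342)
          chans$Alexa488[idx] <- chans$Alexa488[idx] + draw(p$intensity$Alexa488)
          chans$Alexa568[idx] <- chans$Alexa568[idx] + draw(p$intensity$Alexa568)
          chans$Alexa647[idx] <- chans$Alexa647[idx] + draw(p$intensity$Alexa647)
          truth[[i]] <- data.frame(
            plate = plate_id, well = wellrow$well, field = field_idx,
            cell_id = i, class = cls, aspect = aspect, area_um2 = area_um2,
            area_px = length(idx), cy = cy, cx = cx,
            stringsAsFactors = FALSE)
          if (config$keep_masks) masks[[i]] <- idx
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("could not place cell ", i, " in well ", wellrow$well,
             " field ", field_idx,
             " without overlap after 400 retries and a grid scan; ",
             "lower cells_per_field or area")
    }
    ## texture for the two stain channels, inside cells only
    any_cell <- occupied
    for (ch in c("Alexa568", "Alexa647")) {
      tex <- texture_field(H, W)
      chans[[ch]][any_cell] <- chans[[ch]][any_cell] * tex[any_cell]
    }
    ## blur, illumination, baseline, noise, quantize
    illum <- 1
    if (config$illumination_amplitude > 0) {
      yy <- ((seq_len(H) - 1) - (H - 1) / 2)
      xx <- ((seq_len(W) - 1) - (W - 1) / 2)
      q <- outer(yy^2, rep(1, W)) + outer(rep(1, H), xx^2)
      illum <- 1 - config$illumination_amplitude * q / max(q)
    }
    k <- if (config$blur_sigma > 0) gaussian_kernel(config$blur_sigma) else NULL
    for (ch in CP_CHANNELS) {
      img <- chans[[ch]]
      ## replicate boundary: no wrap-around ghosts from edge-touching cells
      if (!is.null(k)) img <- EBImage::filter2(img, k, boundary = "replicate")
      img <- (img + config$baseline) * illum
      if (config$noise_sd > 0)
        img <- img + stats::rnorm(length(img), 0, config$noise_sd)
      if (config$poisson)
        img <- stats::rpois(length(img), pmax(img, 0))
      chans[[ch]] <- matrix(round(pmin(pmax(img, 0), 65535)), H, W)
    }
    cells <- if (n > 0) do.call(rbind, truth) else
      data.frame(plate = character(), well = character(), field = integer(),
                 cell_id = integer(), class = character(), aspect = numeric(),
                 area_um2 = numeric(), area_px = integer(), cy = numeric(),
                 cx = numeric())
    if (config$keep_masks && n > 0)
      names(masks) <- sprintf("%s_f%02d_c%d", wellrow$well, field_idx,
                              seq_len(n))
    list(channels = chans, cells = cells,
         masks = if (config$keep_masks) masks)
  })
}

#' Simulate a synthetic cell painting plate
#'
#' Renders every well of `platemap` with the class mixture configured for
#' it (vehicle and untreated wells default to pure M0) and returns the
#' plate bundle together with the per-cell ground truth. Class counts per
#' well are allocated exactly (largest-remainder rounding) and spread
#' round-robin over the well's fields; identical seeds give bit-identical
#' output.
#'
#' @param config A [simulation_config()].
#' @param platemap A [plate_map()].
#' @return A list with elements `bundle` (a [plate_bundle()]) and `truth`
#'   (list of `cells` — one row per rendered cell with class, true aspect,
#'   area and centre — and `well_counts` with requested vs realized counts).
#' @examples
#' pm <- plate_map("SIM", data.frame(row = "A", col = 1, treatment = "DMSO",
#'                                   role = "vehicle"), fields_per_well = 1)
#' cfg <- simulation_config(seed = 1, image_size = c(96, 96),
#'                          cells_per_field = 3, illumination_amplitude = 0)
#' sim <- simulate_plate(cfg, pm)
#' @export
simulate_plate <- function(config, platemap) {
  stopifnot(inherits(config, "SimulationConfig"), inherits(platemap, "PlateMap"))
  if (nrow(platemap$wells) == 0L) stop("plate map has no wells")
  t0 <- as.numeric(Sys.time())
  images <- list()
  cell_rows <- list()
  count_rows <- list()
  nf <- platemap$fields_per_well
  masks <- list()
  for (i in seq_len(nrow(platemap$wells))) {
    wellrow <- platemap$wells[i, ]
    mix <- well_mixture(config, wellrow)
    cpf <- config$cell_count_overrides[[wellrow$well]]
    if (is.null(cpf)) cpf <- config$cell_count_overrides[[wellrow$treatment]]
    if (is.null(cpf)) cpf <- config$cells_per_field
    n_total <- as.integer(cpf) * nf
    counts <- allocate_counts(mix, n_total)
    label_pool <- rep(names(counts), counts)
    realized <- stats::setNames(integer(length(CP_CLASSES)), CP_CLASSES)
    for (f in seq_len(nf) - 1L) {
      lab_f <- label_pool[((seq_along(label_pool) - 1L) %% nf) == f]
      fr <- render_field(config, wellrow, f, lab_f, platemap$plate_id)
      images[[field_key(wellrow$well, f)]] <- fr$channels
      cell_rows[[length(cell_rows) + 1L]] <- fr$cells
      if (config$keep_masks) masks <- c(masks, fr$masks)
      tb <- table(factor(fr$cells$class, levels = CP_CLASSES))
      realized <- realized + as.integer(tb)
    }
    count_rows[[length(count_rows) + 1L]] <- data.frame(
      well = wellrow$well, class = CP_CLASSES,
      requested = as.integer(counts[CP_CLASSES]),
      realized = as.integer(realized), stringsAsFactors = FALSE)
  }
  bundle <- plate_bundle(platemap, images, config$pixel_size_um)
  truth <- list(cells = do.call(rbind, cell_rows),
                well_counts = do.call(rbind, count_rows),
                masks = if (config$keep_masks) masks)
  rownames(truth$cells) <- NULL
  cp_log("simulate", sprintf("plate %s: %d wells, %d fields",
                             platemap$plate_id, nrow(platemap$wells),
                             length(images)), t0 = t0)
  list(bundle = bundle, truth = truth)
}

#' Render only the vehicle/untreated wells of a plate
#'
#' Convenience wrapper fixing mixtures by role: vehicle and untreated wells
#' are drawn from the M0 distributions; treatment wells must already have a
#' mixture configured, otherwise this errors.
#'
#' @inheritParams simulate_plate
#' @return A [plate_bundle()].
#' @export
render_vehicle_plate <- function(config, platemap) {
  stopifnot(inherits(platemap, "PlateMap"))
  if (!length(vehicle_wells(platemap)))
    stop("plate map has no vehicle wells")
  simulate_plate(config, platemap)$bundle
}

#' Attach ground-truth class labels to segmented cells
#'
#' Matches segmented cells to simulator ground truth by nearest nucleus
#' centroid within `max_dist_um`.
#'
#' @param cells `data.frame` with columns `well`, `field`, `cell_id`,
#'   `cy`, `cx` (pixel centroids), e.g. a feature table's key columns.
#' @param truth The `truth` element returned by [simulate_plate()].
#' @param pixel_size_um Pixel size used to convert the distance cap.
#' @param max_dist_um Maximum accepted centroid distance (default 15 um).
#' @return Character vector of class labels (NA where unmatched).
#' @export
match_ground_truth <- function(cells, truth, pixel_size_um = 1,
                               max_dist_um = 15) {
  out <- rep(NA_character_, nrow(cells))
  tr <- truth$cells
  max_px <- max_dist_um / pixel_size_um
  for (i in seq_len(nrow(cells))) {
    cand <- tr[tr$well == cells$well[i] & tr$field == cells$field[i], ]
    if (!nrow(cand)) next
    d <- sqrt((cand$cy - cells$cy[i])^2 + (cand$cx - cells$cx[i])^2)
    j <- which.min(d)
    if (d[j] <= max_px) out[i] <- cand$class[j]
  }
  out
}
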