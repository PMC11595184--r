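## Shared simulated fixtures, built once per test run and cached.
.fixture_env <- new.env(parent = emptyenv())

fixture_cached <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

## Small mixed plate: 2 vehicle wells, pure-class wells, two mixtures and a
## dead-heavy well; 1 field/well, 256 px fields, 14 cells/field.
fixture_plate <- function() {
  fixture_cached("plate", function() {
    pm <- plate_map("FIX", data.frame(
      row = rep("A", 8), col = 1:8,
      treatment = c("DMSO", "DMSO", "m0", "m1", "m2", "mixA", "mixB", "deadw"),
      role = c("vehicle", "vehicle", rep("treatment", 6))),
      fields_per_well = 1)
    cfg <- simulation_config(
      seed = 3, image_size = c(256L, 256L), cells_per_field = 14L,
      mixtures = list(m0 = c(M0 = 1), m1 = c(M1like = 1), m2 = c(M2like = 1),
                      mixA = c(M0 = 0.5, M1like = 0.5),
                      mixB = c(M0 = 0.3, M2like = 0.7),
                      deadw = c(dead = 0.8, M0 = 0.2)),
      keep_masks = TRUE)
    sim <- simulate_plate(cfg, pm)
    list(pm = pm, cfg = cfg, sim = sim)
  })
}

## Full 1279-entry feature table of the fixture plate (most expensive
## shared object; reused across feature/classifier/profiling tests).
fixture_features <- function() {
  fixture_cached("features", function() {
    fx <- fixture_plate()
    cells <- extract_features(fx$sim$bundle)
    truth_class <- match_ground_truth(cells, fx$sim$truth,
                                      pixel_size_um = fx$cfg$pixel_size_um)
    list(cells = cells, truth_class = truth_class)
  })
}

## Class parameters with scaled-down cell areas, for tests that render
## tiny fields where the default macrophage footprint would not fit.
small_class_params <- function(scale = 0.35) {
  p <- cellpaintr:::default_class_params()
  for (cls in names(p)) p[[cls]]$area_um2 <- p[[cls]]$area_um2 * scale
  p
}

## A deterministic toy field image wrapper.
toy_field <- function(pixels, channel = "Hoechst33342", well = "A01",
                      field = 0L, pixel_size_um = 1) {
  field_image(well, field, channel, pixels, pixel_size_um)
}

## Brute-force reference moments for oracle tests.
brute_moments <- function(x) {
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n
  list(mean = m, m2 = m2,
       skew = if (m2 > 0) (sum((x - m)^3) / n) / m2^1.5 else 0,
       kurt = if (m2 > 0) (sum((x - m)^4) / n) / m2^2 - 3 else 0)
}

## Independent transition-count Crofton perimeter (loop implementation,
## kept deliberately naive as an oracle).
oracle_crofton <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask * 1L
  nh <- nv <- nd1 <- nd2 <- 0L
  for (i in seq_len(H + 2)) for (j in seq_len(W + 1))
    if (pad[i, j] != pad[i, j + 1]) nh <- nh + 1L
  for (j in seq_len(W + 2)) for (i in seq_len(H + 1))
    if (pad[i, j] != pad[i + 1, j]) nv <- nv + 1L
  for (i in seq_len(H + 1)) for (j in seq_len(W + 1)) {
    if (pad[i, j] != pad[i + 1, j + 1]) nd1 <- nd1 + 1L
    if (pad[i, j + 1] != pad[i + 1, j]) nd2 <- nd2 + 1L
  }
  pi / 8 * (nh + nv + (nd1 + nd2) / sqrt(2))
}

## Rendered 2D Gaussian spot image.
gaussian_spot <- function(n = 65, sigma = 5, amp = 100, cy = NULL, cx = NULL) {
  if (is.null(cy)) cy <- (n + 1) / 2
  if (is.null(cx)) cx <- (n + 1) / 2
  y <- matrix(seq_len(n), n, n); x <- t(y)
  amp * exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2))
}
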