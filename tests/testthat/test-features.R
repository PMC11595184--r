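test_that("default catalog has exactly 1279 uniquely named entries", {
  catalog <- enumerate_catalog()
  expect_equal(nrow(catalog), 1279L)
  expect_false(anyDuplicated(catalog$name) > 0)
  ## documented decomposition
  expect_equal(sum(catalog$family == "intensity"), 13L * 12L)
  expect_equal(sum(catalog$family == "ser"), 32L * 12L)
  expect_equal(sum(catalog$family == "gabor"), 24L * 12L)
  expect_equal(sum(catalog$family == "star"), 36L * 12L)
  expect_equal(sum(catalog$family == "morph"), 15L)
  expect_equal(sum(catalog$family == "context"), 4L)
})

test_that("catalog is a pure, stable function of its configuration", {
  expect_identical(enumerate_catalog(), enumerate_catalog())
  ## 1 channel x 1 region -> 105 + 5 morphology + 4 context = 114
  one <- enumerate_catalog(feature_config(channels = "Alexa488",
                                          regions = "cell"))
  expect_equal(nrow(one), 114L)
  expect_error(feature_config(channels = c("Alexa488", "Alexa488")),
               "duplicate")
  expect_error(feature_config(channels = character(0)), "channel")
  expect_error(feature_config(regions = character(0)), "region")
})

test_that("intensity statistics match brute-force pixel loops", {
  ## constant region
  v <- extract_intensity(rep(5, 4))
  expect_equal(unname(v[c("mean", "sd", "sum", "min", "max")]),
               c(5, 0, 20, 5, 5))
  v2 <- extract_intensity(c(1, 2, 3, 4))
  expect_equal(unname(v2[c("mean", "median", "sum")]), c(2.5, 2.5, 10))
  ## moments against direct formulas on random values
  set.seed(11)
  x <- rnorm(20, 50, 12)
  ref <- brute_moments(x)
  got <- extract_intensity(x)
  expect_equal(unname(got["skewness"]), ref$skew, tolerance = 1e-10)
  expect_equal(unname(got["kurtosis"]), ref$kurt, tolerance = 1e-10)
  expect_equal(unname(got["mad"]), median(abs(x - median(x))),
               tolerance = 1e-12)
  expect_equal(unname(got["sumbg"]), sum(x), tolerance = 1e-9)
  expect_equal(unname(extract_intensity(x, bg_median = 3)["sumbg"]),
               sum(x) - 3 * 20, tolerance = 1e-9)
  ## empty region sentinel
  expect_true(all(extract_intensity(numeric(0)) == 0))
})

test_that("mask morphology matches independent loops on tiny masks", {
  H <- 7L
  ## hand-made <= 7x7 masks
  masks <- list(
    square3 = {m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE; m},
    lshape = {m <- matrix(FALSE, 7, 7); m[2:6, 3] <- TRUE; m[6, 3:6] <- TRUE; m},
    bar = {m <- matrix(FALSE, 7, 7); m[4, 2:6] <- TRUE; m})
  for (nm in names(masks)) {
    m <- masks[[nm]]
    idx <- which(m)
    got <- cellpaintr:::mask_morphology(idx, H)
    ## area
    expect_equal(unname(got["area_px"]), sum(m))
    ## perimeter against the naive transition-count oracle
    sub <- m[range(which(rowSums(m) > 0))[1]:range(which(rowSums(m) > 0))[2],
             range(which(colSums(m) > 0))[1]:range(which(colSums(m) > 0))[2],
             drop = FALSE]
    expect_equal(unname(got["perimeter_px"]), oracle_crofton(sub),
                 tolerance = 1e-10)
    ## axis lengths against brute-force second moments
    co <- which(m, arr.ind = TRUE) - 1
    vy <- mean((co[, 1] - mean(co[, 1]))^2)
    vx <- mean((co[, 2] - mean(co[, 2]))^2)
    vxy <- mean((co[, 1] - mean(co[, 1])) * (co[, 2] - mean(co[, 2])))
    ev <- eigen(matrix(c(vy, vxy, vxy, vx), 2))$values
    expect_equal(unname(got["length"]), 4 * sqrt(max(ev)), tolerance = 1e-10)
    expect_equal(unname(got["width"]), 4 * sqrt(max(0, min(ev))),
                 tolerance = 1e-10)
  }
  ## 3x3 square: area 9 px
  expect_equal(unname(cellpaintr:::mask_morphology(which(masks$square3), H)["area_px"]),
               9)
  ## single pixel: roundness 1, unit axes
  one <- cellpaintr:::mask_morphology(which(masks$square3)[1], H)
  expect_equal(unname(one[c("roundness", "width", "length")]), c(1, 1, 1))
})

test_that("roundness behaves like 4*pi*A/P^2 on reference shapes", {
  ## filled disk radius 20 -> roundness >= 0.95
  n <- 51
  y <- matrix(1:n, n, n); x <- t(y)
  disk <- (y - 26)^2 + (x - 26)^2 <= 20^2
  gd <- cellpaintr:::mask_morphology(which(disk), n)
  expect_gte(unname(gd["roundness"]), 0.95)
  ## rasterized 10x40 rectangle: equals the formula with the package's own
  ## perimeter estimator, and is far less round than the disk
  rect <- matrix(FALSE, 20, 50); rect[6:15, 6:45] <- TRUE
  gr <- cellpaintr:::mask_morphology(which(rect), 20)
  P <- oracle_crofton(rect[6:15, 6:45])
  expect_equal(unname(gr["roundness"]), min(1, 4 * pi * 400 / P^2),
               tolerance = 1e-10)
  expect_lt(unname(gr["roundness"]), unname(gd["roundness"]))
  ## elongation ordering: the analytic 4*pi*A/P^2 with ideal perimeters
  ## gives 0.503 for 10x40; the estimator agrees within rasterization bias
  expect_lt(abs(unname(gr["roundness"]) - 0.503), 0.12)
})

test_that("SER features vanish on constant images and are scale invariant", {
  const <- matrix(7, 64, 64)
  idx <- which(matrix(TRUE, 64, 64))
  v <- extract_ser(const, idx, scales = c(1, 2))
  expect_true(all(abs(v) < 1e-10))
  ## positive scaling invariance through kernel normalization
  fx <- fixture_plate()
  img <- fx$sim$bundle$images$A01_f00$Alexa568
  region <- which(img > quantile(img, 0.8))
  a <- extract_ser(img, region, scales = c(2, 4))
  b <- extract_ser(img * 3.7, region, scales = c(2, 4))
  expect_equal(a, b, tolerance = 1e-9)
  ## zero-intensity region convention
  expect_true(all(extract_ser(matrix(0, 32, 32), 1:10, scales = 2) == 0))
})

test_that("a bright spot drives the spot response above the edge response", {
  img <- gaussian_spot(65, sigma = 4, amp = 100) + 10
  ## spot support region: disk of 1.5 sigma around the centred spot
  y <- matrix(1:65, 65, 65); x <- t(y)
  region <- which((y - 33)^2 + (x - 33)^2 <= 6^2)
  v <- extract_ser(img, region, scales = 4)
  expect_gt(v[["spot_s4"]], v[["edge_s4"]])
  expect_gt(v[["spot_s4"]], v[["hole_s4"]])
})

test_that("Gabor features vanish on constants and normalize away scaling", {
  idx <- which(matrix(TRUE, 64, 64))
  v <- extract_gabor(matrix(3, 64, 64), idx, periods = c(8), orientations = c(0, 90))
  expect_true(all(abs(v) < 1e-8))
  fx <- fixture_plate()
  img <- fx$sim$bundle$images$A03_f00$Alexa647
  region <- which(img > quantile(img, 0.8))
  a <- extract_gabor(img, region)
  b <- extract_gabor(img * 2.4, region)
  expect_equal(a, b, tolerance = 1e-9)
})

test_that("gratings excite the matching Gabor orientation most", {
  n <- 64
  x <- matrix(rep(1:n, each = n), n, n)   # varies along columns
  grating <- 100 + 50 * sin(2 * pi * x / 8)
  idx <- which(matrix(TRUE, n, n))
  v <- extract_gabor(grating, idx, periods = 8,
                     orientations = c(0, 45, 90, 135))
  mags <- v[grepl("_mag$", names(v))]
  expect_equal(names(which.max(mags)), "p8_o0_mag")
})

test_that("rotating the image by 90 degrees permutes Gabor orientations", {
  fx <- fixture_plate()
  img <- fx$sim$bundle$images$A04_f00$Alexa568[1:128, 1:128]
  rot <- t(img)[ncol(img):1, ]           # 90 degree rotation
  idx <- which(matrix(TRUE, 128, 128))
  a <- extract_gabor(img, idx, periods = 8, orientations = c(0, 45, 90, 135))
  b <- extract_gabor(rot, idx, periods = 8, orientations = c(0, 45, 90, 135))
  ## orientation o in the original matches (o + 90) mod 180 in the rotation
  expect_equal(a[["p8_o0_mag"]], b[["p8_o90_mag"]], tolerance = 1e-6)
  expect_equal(a[["p8_o90_mag"]], b[["p8_o0_mag"]], tolerance = 1e-6)
  expect_equal(a[["p8_o45_mag"]], b[["p8_o135_mag"]], tolerance = 1e-6)
  expect_equal(a[["p8_o135_energy"]], b[["p8_o45_energy"]], tolerance = 1e-6)
})

test_that("STAR features reward radial symmetry and ignore translation", {
  img <- gaussian_spot(65, sigma = 6, amp = 200, cy = 33, cx = 33) + 5
  y <- matrix(1:65, 65, 65); x <- t(y)
  region <- which((y - 33)^2 + (x - 33)^2 <= 20^2)
  v <- extract_star(img, region, radius = 10)
  sym <- v[grepl("^sym", names(v))]
  expect_true(all(sym > 0.9))
  expect_lt(v[["axial_skewmajor"]], 0.1)
  expect_lt(v[["axial_elongation"]], 0.1)
  ## an asymmetric blob scores lower symmetry
  img2 <- img + 3 * gaussian_spot(65, sigma = 3, amp = 60, cy = 25, cx = 40)
  v2 <- extract_star(img2, region, radius = 10)
  expect_lt(min(v2[grepl("^sym", names(v2))]), min(sym))
  ## integer translation invariance: the same spot rendered at two offsets
  ## (image and region shifted together) gives identical features
  imgA <- gaussian_spot(81, sigma = 6, amp = 200, cy = 30, cx = 28) + 5
  imgB <- gaussian_spot(81, sigma = 6, amp = 200, cy = 41, cx = 46) + 5
  yy <- matrix(1:81, 81, 81); xx <- t(yy)
  regA <- which((yy - 30)^2 + (xx - 28)^2 <= 18^2)
  regB <- which((yy - 41)^2 + (xx - 46)^2 <= 18^2)
  expect_equal(imgA[regA], imgB[regB])  # exact translation by construction
  vA <- extract_star(imgA, regA, radius = 10)
  vB <- extract_star(imgB, regB, radius = 10)
  expect_equal(vA, vB, tolerance = 1e-9)
})

test_that("threshold compactness at full quantile equals support roundness", {
  fx <- fixture_plate()
  img <- fx$sim$bundle$images$A05_f00$Alexa488
  seg <- segment_field(flatfield_correct_bundle(fx$sim$bundle), "A05", 0)
  rs <- derive_regions(seg)
  idx <- rs[[1]]$cell
  v <- extract_star(img, idx, radius = 10)
  support <- cellpaintr:::mask_morphology(idx, nrow(img))
  expect_equal(v[["tc100_compact"]], unname(support["roundness"]),
               tolerance = 1e-10)
  expect_equal(v[["tc100_areafrac"]], 1)
  expect_equal(v[["tc100_intfrac"]], 1)
})

test_that("extract_all yields one catalog-complete row per retained cell", {
  fx <- fixture_plate()
  ft <- fixture_features()$cells
  catalog <- enumerate_catalog()
  expect_identical(setdiff(names(ft), c("plate", "well", "field", "cell_id",
                                        "cy", "cx")), catalog$name)
  ## one row per simulated (non-border) cell
  expect_equal(nrow(ft), nrow(fx$sim$truth$cells))
  expect_false(any(is.na(ft)))
  ## rerun on the same field is identical
  bundle <- flatfield_correct_bundle(fx$sim$bundle)
  seg <- segment_field(bundle, "A06", 0)
  a <- extract_all(seg, bundle$images$A06_f00, plate_id = "FIX")
  b <- extract_all(seg, bundle$images$A06_f00, plate_id = "FIX")
  expect_identical(a, b)
  ## missing channel is an error
  expect_error(extract_all(seg, bundle$images$A06_f00[1:3], plate_id = "FIX"),
               "missing channel")
})

test_that("border-excluded cells never reach the feature table", {
  pm <- plate_map("BD2", data.frame(row = "A", col = 1, treatment = "DMSO",
                                    role = "vehicle"), fields_per_well = 1)
  cfg <- simulation_config(seed = 13, image_size = c(256L, 256L),
                           cells_per_field = 8L, place_border_cell = TRUE)
  sim <- simulate_plate(cfg, pm)
  ft <- extract_features(sim$bundle,
                         feature_config(families = c("morph", "context")))
  expect_equal(nrow(ft), 7L)
  ## the border cell (cy ~ 0) has no feature row
  expect_true(all(ft$cy > 10))
})
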