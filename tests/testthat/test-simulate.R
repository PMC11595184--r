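test_that("identical seeds give bit-identical plates and ground truth", {
  pm <- plate_map("DET", data.frame(row = "A", col = 1:2,
                                    treatment = c("DMSO", "mx"),
                                    role = c("vehicle", "treatment")),
                  fields_per_well = 1)
  cfg <- simulation_config(seed = 7, image_size = c(96L, 96L),
                           cells_per_field = 4L,
                           class_params = small_class_params(),
                           mixtures = list(mx = c(M1like = 0.5, dead = 0.5)))
  s1 <- simulate_plate(cfg, pm)
  s2 <- simulate_plate(cfg, pm)
  expect_identical(s1$bundle$images, s2$bundle$images)
  expect_identical(s1$truth, s2$truth)
  ## different seed changes the bits
  s3 <- simulate_plate(simulation_config(seed = 8, image_size = c(96L, 96L),
                                         cells_per_field = 4L,
                                         class_params = small_class_params(),
                                         mixtures = cfg$mixtures), pm)
  expect_false(identical(s1$bundle$images, s3$bundle$images))
})

test_that("class mixtures are realized with exact counts", {
  pm <- plate_map("MIX", data.frame(row = "A", col = 1:2,
                                    treatment = c("pure", "half"),
                                    role = "treatment"),
                  fields_per_well = 1)
  ## 50 cells, all M1like -> all 50 labels M1like
  cfg <- simulation_config(seed = 1, image_size = c(512L, 512L),
                           cells_per_field = 50L,
                           mixtures = list(pure = c(M1like = 1),
                                           half = c(M0 = 0.5, M2like = 0.5)))
  sim <- simulate_plate(cfg, pm)
  pure_labels <- sim$truth$cells$class[sim$truth$cells$well == "A01"]
  expect_length(pure_labels, 50L)
  expect_true(all(pure_labels == "M1like"))
  ## {M0: .5, M2like: .5} x 50 -> 25/25 exactly
  wc <- sim$truth$well_counts
  expect_equal(wc$realized[wc$well == "A02" & wc$class == "M0"], 25L)
  expect_equal(wc$realized[wc$well == "A02" & wc$class == "M2like"], 25L)
  expect_equal(wc$requested, wc$realized)
})

test_that("largest-remainder allocation is exact for uneven mixtures", {
  f <- cellpaintr:::allocate_counts
  expect_equal(unname(f(c(M0 = 0.5, M2like = 0.5), 40)), c(20L, 20L))
  x <- f(c(M0 = 1 / 3, M1like = 1 / 3, M2like = 1 / 3), 40)
  expect_equal(sum(x), 40L)
  expect_true(max(x) - min(x) <= 1L)
  expect_equal(sum(f(c(M0 = 0.21, M1like = 0.37, M2like = 0.42), 17)), 17L)
})

test_that("realized shape statistics match the configured distributions", {
  pm <- plate_map("SH", data.frame(row = "A", col = 1, treatment = "m2",
                                   role = "treatment"), fields_per_well = 3)
  cfg <- simulation_config(seed = 21, image_size = c(512L, 512L),
                           cells_per_field = 40L,
                           mixtures = list(m2 = c(M2like = 1)))
  sim <- simulate_plate(cfg, pm)
  asp <- sim$truth$cells$aspect
  expect_gte(length(asp), 100L)
  p <- cfg$class_params$M2like$aspect
  se <- p[["sd"]] / sqrt(length(asp))
  expect_lt(abs(mean(asp) - p[["mean"]]), 3 * se + 1e-9)
})

test_that("clean background equals the configured baseline exactly", {
  pm <- plate_map("BG", data.frame(row = "A", col = 1, treatment = "DMSO",
                                   role = "vehicle"), fields_per_well = 1)
  cfg <- simulation_config(seed = 5, image_size = c(128L, 128L),
                           cells_per_field = 2L, noise_sd = 0,
                           illumination_amplitude = 0, baseline = 100)
  sim <- simulate_plate(cfg, pm)
  img <- sim$bundle$images$A01_f00$Alexa568
  ## pixels far from any cell are exactly baseline
  tr <- sim$truth$cells
  H <- nrow(img)
  yy <- matrix(0:(H - 1), H, H); xx <- t(yy)
  dmin <- Reduce(pmin, lapply(seq_len(nrow(tr)), function(i)
    sqrt((yy - tr$cy[i])^2 + (xx - tr$cx[i])^2)))
  far <- dmin > 60
  expect_true(any(far))
  expect_true(all(img[far] == 100))
})

test_that("mixture and well validation contract holds", {
  expect_error(simulation_config(mixtures = list(a = c(M0 = 0.6, M1like = 0.3))),
               "sum to 1")
  expect_error(simulation_config(mixtures = list(a = c(bad = 1))), "named")
  pm <- plate_map("V", data.frame(row = "A", col = 1:3,
                                  treatment = c("DMSO", "none", "drug"),
                                  role = c("vehicle", "untreated", "treatment")),
                  fields_per_well = 1)
  cfg <- simulation_config(seed = 2, image_size = c(96L, 96L),
                           cells_per_field = 2L,
                           class_params = small_class_params())
  ## treatment well without a mixture -> error naming the well
  expect_error(simulate_plate(cfg, pm), "A03")
  expect_error(render_vehicle_plate(cfg, pm), "A03")
  ## vehicle + untreated default to pure M0
  pm2 <- plate_map("V2", data.frame(row = "A", col = 1:2,
                                    treatment = c("DMSO", "none"),
                                    role = c("vehicle", "untreated")),
                   fields_per_well = 1)
  sim <- simulate_plate(cfg, pm2)
  expect_true(all(sim$truth$cells$class == "M0"))
  ## no vehicle wells -> render_vehicle_plate refuses
  pm3 <- plate_map("V3", data.frame(row = "A", col = 1, treatment = "none",
                                    role = "untreated"), fields_per_well = 1)
  expect_error(render_vehicle_plate(cfg, pm3), "vehicle")
})

test_that("impossible densities fail with a clear message", {
  pm <- plate_map("D", data.frame(row = "A", col = 1, treatment = "DMSO",
                                  role = "vehicle"), fields_per_well = 1)
  cfg <- simulation_config(seed = 1, image_size = c(96L, 96L),
                           cells_per_field = 60L)
  expect_error(simulate_plate(cfg, pm), "lower")
})
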