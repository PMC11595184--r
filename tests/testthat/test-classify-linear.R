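toy_catalog <- function(names) {
  data.frame(name = names, family = "intensity", channel = "Alexa488",
             region = "cell", tag = names, stringsAsFactors = FALSE)
}

## separable 2-feature toy set: f1 separates the classes, f2 is noise
toy_training <- function(n = 20, seed = 1) {
  set.seed(seed)
  data.frame(
    well = rep(c("W0", "W1", "W2"), each = n),
    class = rep(c("M0", "M1like", "M2like"), each = n),
    f1 = c(rnorm(n, 0, 0.3), rnorm(n, 5, 0.3), rnorm(n, 10, 0.3)),
    f2 = rnorm(3 * n))
}

test_that("training-cell sampling is exact, stratified and seeded", {
  cells <- fixture_features()$cells
  spec <- training_spec(list(M0 = "A03", M1like = "A04", M2like = "A05"),
                        cells_per_class = 10, seed = 11)
  tr <- sample_training_cells(cells, spec)
  expect_equal(nrow(tr), 30L)
  expect_equal(as.integer(table(tr$class)), rep(10L, 3))
  expect_false(anyDuplicated(tr$cell_id[tr$class == "M0"]) > 0)
  ## seeded: identical across reruns
  expect_identical(sample_training_cells(cells, spec), tr)
  ## different seed draws a different subset
  spec2 <- training_spec(spec$class_source, cells_per_class = 10, seed = 12)
  expect_false(identical(sample_training_cells(cells, spec2), tr))
  ## insufficient pool
  spec3 <- training_spec(spec$class_source, cells_per_class = 100)
  expect_error(sample_training_cells(cells, spec3), "only .* available")
  ## stratification: cells drawn evenly across two source wells
  spec4 <- training_spec(list(M0 = c("A01", "A02"), M1like = "A04",
                              M2like = "A05"), cells_per_class = 10, seed = 1)
  tr4 <- sample_training_cells(cells, spec4)
  m0_wells <- table(tr4$well[tr4$class == "M0"])
  expect_equal(as.integer(m0_wells), c(5L, 5L))
})

test_that("a separable toy problem is fit perfectly and sparsely", {
  tr <- toy_training()
  spec <- training_spec(list(M0 = "W0", M1like = "W1", M2like = "W2"),
                        cells_per_class = 20, seed = 1)
  mod <- train_linear_classifier(tr, spec, toy_catalog(c("f1", "f2")))
  expect_equal(mod$training_accuracy, 1)
  ## the informative feature carries the weight in every pair
  rel <- relevant_features(mod)
  for (pair in rel) expect_true("f1" %in% pair$feature)
  ## predictions are invariant to row order
  p1 <- predict_cells(mod, tr)
  perm <- sample(nrow(tr))
  expect_identical(predict_cells(mod, tr[perm, ])[order(perm)], p1)
  ## a cell at a class centroid is assigned that class
  centro <- data.frame(f1 = 5, f2 = 0)
  expect_equal(predict_cells(mod, centro), "M1like")
  ## missing feature column errors by name
  expect_error(predict_cells(mod, tr[, c("well", "f1")]), "f2")
})

test_that("feature masks remove morphology from model and report", {
  cells <- fixture_features()$cells
  spec <- training_spec(list(M0 = "A03", M1like = "A04", M2like = "A05"),
                        cells_per_class = 12, seed = 5,
                        feature_mask = "no_roundness")
  tr <- sample_training_cells(cells, spec)
  mod <- train_linear_classifier(tr, spec)
  expect_false("morph_cell_roundness" %in% mod$features)
  rel <- relevant_features(mod)
  expect_false(any(vapply(rel, function(df)
    "morph_cell_roundness" %in% df$feature, logical(1))))
  spec$feature_mask <- "no_standard_morphology"
  mod2 <- train_linear_classifier(tr, spec)
  expect_length(grep("^morph_", mod2$features), 0L)
  ## explicit unknown mask names are rejected
  spec$feature_mask <- c("not_a_feature")
  expect_error(train_linear_classifier(tr, spec), "not in catalog")
})

test_that("degenerate training input fails loudly", {
  tr <- toy_training()
  tr$f1 <- 1; tr$f2 <- 2  # zero variance everywhere
  spec <- training_spec(list(M0 = "W0", M1like = "W1", M2like = "W2"),
                        cells_per_class = 20)
  expect_error(train_linear_classifier(tr, spec, toy_catalog(c("f1", "f2"))),
               "degenerate|zero variance")
})

test_that("well class fractions count correctly and sum to 100", {
  lab <- data.frame(well = rep("A01", 10),
                    class = c(rep("M1like", 6), rep("M0", 4)))
  fr <- well_class_fractions(lab)
  expect_equal(fr$pct_M0, 40)
  expect_equal(fr$pct_M1like, 60)
  expect_equal(fr$pct_M2like, 0)
  all2 <- well_class_fractions(data.frame(well = "B02",
                                          class = rep("M2like", 7)))
  expect_equal(all2$pct_M2like, 100)
  ## brute-force on random labels
  set.seed(31)
  lab2 <- data.frame(well = sample(c("C01", "C02"), 50, TRUE),
                     class = sample(c("M0", "M1like", "M2like"), 50, TRUE))
  fr2 <- well_class_fractions(lab2)
  for (i in seq_len(nrow(fr2))) {
    sel <- lab2$well == fr2$well[i]
    expect_equal(fr2$pct_M1like[i], 100 * sum(lab2$class[sel] == "M1like") /
                   sum(sel))
    expect_equal(fr2$pct_M0[i] + fr2$pct_M1like[i] + fr2$pct_M2like[i], 100,
                 tolerance = 1e-9)
  }
})

test_that("DMSO normalization matches the stated arithmetic", {
  pm <- plate_map("N", data.frame(
    row = "A", col = 1:3, treatment = c("DMSO", "DMSO", "drug"),
    role = c("vehicle", "vehicle", "treatment")), fields_per_well = 1)
  sc <- data.frame(well = c("A01", "A02", "A03"), n = 10L,
                   pct_M0 = c(78, 78, 55), pct_M1like = c(12, 12, 5),
                   pct_M2like = c(10, 10, 40))
  out <- normalize_to_dmso(sc, pm)
  ## (40 - 10) - (5 - 12) = 37
  expect_equal(out$normalized_score[out$well == "A03"], 37)
  ## vehicle wells at the vehicle averages -> 0; mean over vehicles is 0
  expect_equal(out$normalized_score[out$well %in% c("A01", "A02")], c(0, 0))
  expect_equal(mean(out$normalized_score[out$well %in% c("A01", "A02")]), 0)
  expect_error(normalize_to_dmso(sc[3, ], pm), "no vehicle")
})

test_that("model serialization round-trips predictions bit-exactly", {
  cells <- fixture_features()$cells
  spec <- training_spec(list(M0 = "A03", M1like = "A04", M2like = "A05"),
                        cells_per_class = 12, seed = 5)
  mod <- train_linear_classifier(sample_training_cells(cells, spec), spec)
  path <- tempfile(fileext = ".json")
  write_linear_model(mod, path)
  back <- read_linear_model(path)
  expect_identical(predict_cells(back, cells), predict_cells(mod, cells))
})

test_that("identical seeds make the ablation's 'all' column reproducible", {
  cells <- fixture_features()$cells
  fx <- fixture_plate()
  spec <- training_spec(list(M0 = "A03", M1like = "A04", M2like = "A05"),
                        cells_per_class = 12, seed = 5)
  ab1 <- ablation_compare(cells, spec, fx$pm)
  ab2 <- ablation_compare(cells, spec, fx$pm)
  expect_identical(ab1$scores, ab2$scores)
  expect_equal(dim(ab1$correlations), c(3L, 3L))
  ## the all-features scores equal a directly trained all-features model
  tr <- sample_training_cells(cells, spec)
  mod <- train_linear_classifier(tr, spec)
  lab <- data.frame(well = cells$well, class = predict_cells(mod, cells))
  sc <- normalize_to_dmso(well_class_fractions(lab), fx$pm)
  expect_equal(ab1$scores$all,
               sc$normalized_score[match(ab1$scores$well, sc$well)])
})
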