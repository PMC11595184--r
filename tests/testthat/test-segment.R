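test_that("flatfield correction is the identity on flat inputs", {
  const <- toy_field(matrix(50, 64, 64))
  out <- flatfield_correct(const)
  expect_equal(out$pixels, const$pixels, tolerance = 1e-6)
  zero <- toy_field(matrix(0, 64, 64))
  expect_equal(flatfield_correct(zero)$pixels, zero$pixels)
  ## mean preservation
  fx <- fixture_plate()
  img <- get_field_image(fx$sim$bundle, "A01", 0, "Alexa488")
  corr <- flatfield_correct(img)
  expect_lt(abs(mean(corr$pixels) - mean(img$pixels)) / mean(img$pixels), 1e-6)
  expect_error(flatfield_correct(img, matrix(0, 256, 256)), "positive")
  expect_error(flatfield_correct(img, matrix(1, 5, 5)), "shape")
})

test_that("flatfield correction removes a known quadratic shading surface", {
  pm <- plate_map("FF", data.frame(row = "A", col = 1, treatment = "DMSO",
                                   role = "vehicle"), fields_per_well = 1)
  base_args <- list(seed = 9, image_size = c(256L, 256L),
                    cells_per_field = 10L, noise_sd = 0)
  flat <- simulate_plate(do.call(simulation_config,
                                 c(base_args, illumination_amplitude = 0)), pm)
  shaded <- simulate_plate(do.call(simulation_config,
                                   c(base_args, illumination_amplitude = 0.3)),
                           pm)
  a <- flat$bundle$images$A01_f00$Alexa488
  b <- shaded$bundle$images$A01_f00$Alexa488
  corr <- flatfield_correct(
    field_image("A01", 0, "Alexa488", b, 0.6))$pixels
  ## correction preserves the (shaded) input mean by contract, so compare
  ## shading removal after matching overall brightness
  cs <- corr * mean(a) / mean(corr)
  bs <- b * mean(a) / mean(b)
  expect_lt(mean(abs(cs - a)) / mean(a), 0.02)
  expect_gt(mean(abs(bs - a)) / mean(a), 0.04)  # shading was material
})

test_that("nucleus detection recovers the simulated count and contract", {
  fx <- fixture_plate()
  bundle <- flatfield_correct_bundle(fx$sim$bundle)
  hoechst <- get_field_image(bundle, "A01", 0, "Hoechst33342")
  nuclei <- find_nuclei(hoechst)
  expect_equal(max(nuclei), 14L)  # all simulated nuclei, none at border
  expect_equal(sort(unique(as.vector(nuclei[nuclei > 0]))), 1:14)
  ## empty field -> 0 labels
  empty <- toy_field(matrix(100, 128, 128))
  expect_equal(max(find_nuclei(empty)), 0L)
  ## wrong channel is rejected
  a488 <- get_field_image(bundle, "A01", 0, "Alexa488")
  expect_error(find_nuclei(a488), "Hoechst")
})

test_that("border-touching objects are excluded when requested", {
  pm <- plate_map("BD", data.frame(row = "A", col = 1, treatment = "DMSO",
                                   role = "vehicle"), fields_per_well = 1)
  cfg <- simulation_config(seed = 13, image_size = c(256L, 256L),
                           cells_per_field = 10L, place_border_cell = TRUE)
  sim <- simulate_plate(cfg, pm)
  hoechst <- get_field_image(sim$bundle, "A01", 0, "Hoechst33342")
  with_border <- find_nuclei(hoechst, exclude_border = FALSE)
  without <- find_nuclei(hoechst, exclude_border = TRUE)
  expect_equal(max(with_border), 10L)
  expect_equal(max(without), 9L)
  expect_gte(attr(without, "n_border_excluded"), 1L)
})

test_that("cell bodies overlap the simulated cells (IoU >= 0.7)", {
  fx <- fixture_plate()
  bundle <- flatfield_correct_bundle(fx$sim$bundle)
  ious <- c()
  for (w in c("A01", "A04", "A05")) {
    seg <- segment_field(bundle, w, 0)
    summ <- cellpaintr:::seg_cell_summary(seg)
    tr <- fx$sim$truth$cells
    tr <- tr[tr$well == w, ]
    for (i in seq_len(nrow(summ))) {
      d <- sqrt((tr$cy - summ$cy[i])^2 + (tr$cx - summ$cx[i])^2)
      j <- which.min(d)
      key <- sprintf("%s_f%02d_c%d", w, 0, tr$cell_id[j])
      truth_idx <- fx$sim$truth$masks[[key]]
      seg_idx <- which(seg$cell_mask == summ$cell_id[i])
      ious <- c(ious, length(intersect(truth_idx, seg_idx)) /
                  length(union(truth_idx, seg_idx)))
    }
  }
  expect_gte(length(ious), 30L)
  expect_gte(mean(ious >= 0.7), 0.95)
})

test_that("cell segmentation keeps nuclei inside matching cells", {
  fx <- fixture_plate()
  bundle <- flatfield_correct_bundle(fx$sim$bundle)
  seg <- segment_field(bundle, "A03", 0)
  nm <- seg$nucleus_mask; cm <- seg$cell_mask
  expect_setequal(unique(nm[nm > 0]), unique(cm[cm > 0]))
  expect_true(all(cm[nm > 0] == nm[nm > 0]))
  ## zero nuclei -> zero cells
  empty <- matrix(0L, 64, 64)
  a488 <- toy_field(matrix(100, 64, 64), channel = "Alexa488")
  expect_equal(max(find_cells(a488, empty)), 0L)
  expect_error(find_cells(a488, matrix(0L, 8, 8)), "mismatch")
  expect_error(find_cells(toy_field(matrix(1, 64, 64)), empty), "Alexa488")
})

test_that("a nucleus with no surrounding signal degenerates to cell = nucleus", {
  nuc <- matrix(0L, 64, 64)
  nuc[30:34, 30:34] <- 1L
  a488 <- toy_field(matrix(100, 64, 64), channel = "Alexa488")  # featureless
  cells <- find_cells(a488, nuc)
  seg <- cell_segmentation("A01", 0, nuc, cells)
  expect_true(all(cells[nuc > 0] == 1L))
  expect_true(all(nuc[cells > 0] == cells[cells > 0]) ||
                sum(cells > 0) >= sum(nuc > 0))
})

test_that("region derivation obeys exact set algebra", {
  ## toy: 3x3 nucleus inside 5x5 cell -> 16 cytoplasm pixels
  nm <- matrix(0L, 9, 9); cm <- matrix(0L, 9, 9)
  cm[3:7, 3:7] <- 1L
  nm[4:6, 4:6] <- 1L
  seg <- cell_segmentation("A01", 0, nm, cm)
  rs <- derive_regions(seg)
  expect_length(rs[["1"]]$cytoplasm, 16L)
  expect_length(rs[["1"]]$cell, 25L)
  expect_setequal(c(rs[["1"]]$nucleus, rs[["1"]]$cytoplasm), rs[["1"]]$cell)
  expect_length(intersect(rs[["1"]]$nucleus, rs[["1"]]$cytoplasm), 0L)
  ## nucleus = cell -> empty cytoplasm, no error
  seg2 <- cell_segmentation("A01", 0, cm, cm)
  expect_length(derive_regions(seg2)[["1"]]$cytoplasm, 0L)
  ## two cells -> two disjoint triples
  cm2 <- cm; cm2[1:2, 1:2] <- 2L
  nm2 <- nm; nm2[1, 1] <- 2L
  rs2 <- derive_regions(cell_segmentation("A01", 0, nm2, cm2))
  expect_length(rs2, 2L)
  expect_length(intersect(rs2[["1"]]$cell, rs2[["2"]]$cell), 0L)
  ## orphan labels are rejected
  expect_error(cell_segmentation("A01", 0, nm * 0L, cm), "orphan")
  ## region algebra on a real segmentation
  fx <- fixture_plate()
  seg3 <- segment_field(flatfield_correct_bundle(fx$sim$bundle), "A05", 0)
  rs3 <- derive_regions(seg3)
  for (cell in rs3) {
    expect_setequal(c(cell$nucleus, cell$cytoplasm), cell$cell)
    expect_length(intersect(cell$nucleus, cell$cytoplasm), 0L)
  }
})
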