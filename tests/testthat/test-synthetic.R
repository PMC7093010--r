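test_that("rendering an empty plant yields an empty mask and zero PLA", {
  g <- genotype_presets()$wildtype
  r <- render_rosette(g, 0, canvas_size = 64, rng_seed = 7)
  expect_true(all(r$plant_mask == 0L))
  expect_identical(compute_pla(r$plant_mask), 0)
  expect_equal(dim(r$pixels), c(64, 64, 3))
  expect_true(all(r$pixels >= 0 & r$pixels <= 255))
})

test_that("rendering is bit-identical for a fixed seed", {
  g <- genotype_presets()$elongata
  r1 <- render_rosette(g, 5, canvas_size = 64, rng_seed = 123)
  r2 <- render_rosette(g, 5, canvas_size = 64, rng_seed = 123)
  expect_identical(r1$pixels, r2$pixels)
  expect_identical(r1$plant_mask, r2$plant_mask)
  r3 <- render_rosette(g, 5, canvas_size = 64, rng_seed = 124)
  expect_false(identical(r1$pixels, r3$pixels))
})

test_that("mask components stay below the leaf count and area grows with it", {
  g <- genotype_presets()$wildtype
  r12 <- render_rosette(g, 12, canvas_size = 96, rng_seed = 5)
  r6 <- render_rosette(g, 6, canvas_size = 96, rng_seed = 5)
  comps <- max(EBImage::bwlabel(r12$plant_mask))
  expect_lte(comps, 12)
  expect_gt(sum(r12$plant_mask), sum(r6$plant_mask))
})

test_that("compute_pla is the plant-pixel fraction", {
  expect_identical(compute_pla(matrix(0L, 10, 10)), 0)
  expect_identical(compute_pla(matrix(1L, 10, 10)), 1)
  m <- matrix(0L, 320, 320)
  m[seq_len(10240)] <- 1L
  expect_identical(compute_pla(m), 0.1)
  expect_error(compute_pla(matrix(c(0, 2), 2, 2)))
})

test_that("generated datasets have the promised size and full annotations", {
  ds <- generate_dataset(24, 52, canvas_size = 64, seed = 1)
  expect_equal(nrow(ds$annotations), 1248)
  ds2 <- generate_dataset(2, 1, canvas_size = 64, seed = 1)
  expect_equal(length(ds2$images), 2)
  expect_true(all(vapply(ds2$images, `[[`, TRUE, "has_count")))
  expect_true(all(vapply(ds2$images, `[[`, TRUE, "has_pla")))
})

test_that("stored PLA matches the mask and counts grow monotonically", {
  ds <- tiny_dataset()
  for (im in ds$images) {
    expect_lt(abs(im$pla - compute_pla(im$plant_mask)), 0.01)
    expect_true(im$leaf_count == 0 || sum(im$plant_mask) > 0)
  }
  ann <- ds$annotations
  for (pid in unique(ann$plant_id)) {
    counts <- ann$leaf_count[ann$plant_id == pid][order(ann$timepoint[ann$plant_id == pid])]
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("dataset generation is seeded-reproducible and balanced", {
  d1 <- generate_dataset(5, 2, canvas_size = 64, seed = 9, mutant_fraction = 0.4)
  d2 <- generate_dataset(5, 2, canvas_size = 64, seed = 9, mutant_fraction = 0.4)
  expect_identical(d1, d2)
  per_plant <- tapply(d1$annotations$genotype, d1$annotations$plant_id, `[`, 1)
  expect_lte(abs(sum(per_plant) - round(0.4 * 5)), 1)
})

test_that("invalid generator arguments are rejected", {
  expect_error(generate_dataset(4, 2, mutant_fraction = 0), "mutant_fraction")
  expect_error(generate_dataset(4, 2, mutant_fraction = 1), "mutant_fraction")
  only_wt <- genotype_presets()["wildtype"]
  expect_error(generate_dataset(4, 2, genotype_pool = only_wt), "mutant")
  expect_error(render_rosette(genotype_presets()$wildtype, 3, canvas_size = 32))
})

test_that("genotype classes are separable by mean plant hue", {
  ds <- generate_dataset(8, 6, canvas_size = 64, seed = 17)
  hue_of <- function(im) {
    px <- im$pixels / 255
    sel <- im$plant_mask == 1
    h <- grDevices::rgb2hsv(rbind(px[, , 1][sel], px[, , 2][sel],
                                  px[, , 3][sel]))[1, ]
    mean(h) * 360
  }
  hues <- vapply(ds$images, hue_of, numeric(1))
  labs <- vapply(ds$images, `[[`, integer(1), "genotype")
  # threshold fixed a priori between the two presets' hue ranges
  acc <- 100 * mean(as.integer(hues < 105) == labs)
  expect_gt(acc, 70)
})
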