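test_that("write_dataset / load_dataset round-trips images and annotations", {
  ds <- generate_dataset(2, 2, canvas_size = 64, seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir, masks = TRUE)
  back <- load_dataset(dir, file.path(dir, "annotations.csv"))
  expect_equal(length(back$images), 4)
  expect_identical(back$images[[1]]$pixels, ds$images[[1]]$pixels)
  expect_identical(back$images[[1]]$plant_mask, ds$images[[1]]$plant_mask)
  expect_equal(back$images[[3]]$leaf_count, ds$images[[3]]$leaf_count)
  expect_equal(back$images[[2]]$pla, ds$images[[2]]$pla, tolerance = 1e-6)
})

test_that("loading rejects missing files and out-of-range PLA, keeps empty cells absent", {
  ds <- generate_dataset(2, 2, canvas_size = 64, seed = 3)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ann <- utils::read.csv(file.path(dir, "annotations.csv"))

  bad <- ann
  bad$image[2] <- "nope.png"
  utils::write.csv(bad, file.path(dir, "bad1.csv"), row.names = FALSE)
  expect_error(load_dataset(dir, file.path(dir, "bad1.csv")), "row 2")

  bad <- ann
  bad$pla[3] <- 1.5
  utils::write.csv(bad, file.path(dir, "bad2.csv"), row.names = FALSE)
  expect_error(load_dataset(dir, file.path(dir, "bad2.csv")), "row 3")

  part <- ann
  part$leaf_count[1] <- NA
  utils::write.csv(part, file.path(dir, "part.csv"), row.names = FALSE)
  got <- load_dataset(dir, file.path(dir, "part.csv"))
  expect_false(got$images[[1]]$has_count)
  expect_true(got$images[[1]]$has_pla)
  expect_true(got$images[[2]]$has_count)
})

test_that("preprocess resizes arbitrary inputs to the square model size", {
  img <- array(runif(317 * 309 * 3), c(317, 309, 3))
  out <- preprocess(img, 320)
  expect_equal(dim(out), c(320, 320, 3))
  out96 <- preprocess(array(as.integer(round(runif(500 * 530 * 3) * 255)),
                            c(500, 530, 3)), 96)
  expect_equal(dim(out96), c(96, 96, 3))
  expect_true(all(out96 >= 0 & out96 <= 1))
  same <- array(runif(96 * 96 * 3), c(96, 96, 3))
  expect_equal(preprocess(same, 96), same)
  expect_error(preprocess(matrix(0, 10, 10), 96), "RGB")
})

test_that("augmentation transforms behave as involutions/identities", {
  img <- preprocess(tiny_dataset()$images[[5]]$pixels, 64)
  expect_equal(augment(img, list(kind = "rotate", angle = 0)), img,
               tolerance = 1e-6)
  expect_identical(augment(augment(img, list(kind = "hflip")),
                           list(kind = "hflip")), img)
  expect_identical(augment(augment(img, list(kind = "vflip")),
                           list(kind = "vflip")), img)
  expect_identical(augment(img, list(kind = "shift", dx = 0, dy = 0)), img)
  shifted <- augment(img, list(kind = "shift", dx = 5, dy = -3))
  expect_equal(shifted[10, 10, ], img[13, 5, ])
})

test_that("rotation keeps the mask-derived PLA of a centred rosette", {
  rec <- tiny_dataset()$images[[20]]
  rot <- augment(rec, list(kind = "rotate", angle = 90))
  expect_lt(abs(compute_pla(rot$plant_mask) - compute_pla(rec$plant_mask)),
            0.01)
  # count/genotype annotations ride along unchanged
  expect_identical(rot$leaf_count, rec$leaf_count)
  expect_identical(rot$genotype, rec$genotype)
})

test_that("cross-validation folds partition plants without leakage", {
  plants <- sprintf("p%02d", 1:24)
  splits <- make_cv_splits(plants, 4, seed = 2)
  test_sets <- lapply(splits, `[[`, "test_plant_ids")
  expect_true(all(lengths(test_sets) == 6))
  expect_setequal(unlist(test_sets), plants)
  expect_equal(anyDuplicated(unlist(test_sets)), 0)
  for (sp in splits) {
    expect_length(intersect(sp$train_plant_ids, sp$test_plant_ids), 0)
    expect_length(intersect(sp$val_plant_ids, sp$test_plant_ids), 0)
    expect_length(intersect(sp$train_plant_ids, sp$val_plant_ids), 0)
  }
  two <- make_cv_splits(c("a", "b"), 2, seed = 1)
  expect_true(all(lengths(lapply(two, `[[`, "test_plant_ids")) == 1))
})

test_that("genotype-stratified folds cover every genotype when possible", {
  plants <- sprintf("p%02d", 1:20)
  geno <- setNames(rep(c("g1", "g2", "g3", "g4", "g5"), each = 4), plants)
  splits <- make_cv_splits(plants, 4, genotypes = geno, seed = 3)
  for (sp in splits)
    expect_setequal(unique(geno[sp$test_plant_ids]), unique(geno))
  # 3 plants of one genotype cannot stratify into 4 folds
  geno2 <- setNames(c(rep("g1", 3), rep("g2", 17)), plants)
  expect_warning(make_cv_splits(plants, 4, genotypes = geno2, seed = 3),
                 "stratification")
})

test_that("uniform label reduction removes every 4th (keep 0.75) or keeps every 4th (keep 0.25)", {
  ds <- fake_dataset(3, 8)
  red <- reduce_count_labels(ds, reduction_plan("uniform", 0.75))
  for (pid in unique(red$annotations$plant_id)) {
    idx <- which(vapply(red$images, `[[`, character(1), "plant_id") == pid)
    has <- vapply(red$images[idx], `[[`, TRUE, "has_count")
    tp <- vapply(red$images[idx], `[[`, integer(1), "timepoint")
    expect_identical(tp[!has], c(1L, 5L))
    expect_equal(sum(has), 6)
  }
  red25 <- reduce_count_labels(ds, reduction_plan("uniform", 0.25))
  has <- vapply(red25$images, `[[`, TRUE, "has_count")
  tp <- vapply(red25$images, `[[`, integer(1), "timepoint")
  expect_true(all(tp[has] %in% c(4L, 8L)))
})

test_that("juvenile/mature/random strategies mask the right timepoints", {
  ds <- fake_dataset(2, 8)
  juv <- reduce_count_labels(ds, reduction_plan("juvenile_first", 0.5))
  tp <- vapply(juv$images, `[[`, integer(1), "timepoint")
  has <- vapply(juv$images, `[[`, TRUE, "has_count")
  expect_true(all(tp[has] >= 5))
  expect_true(all(tp[!has] <= 4))

  mat <- reduce_count_labels(ds, reduction_plan("mature_first", 0.5))
  has <- vapply(mat$images, `[[`, TRUE, "has_count")
  expect_true(all(tp[has] <= 4))

  r1 <- reduce_count_labels(ds, reduction_plan("random", 0.5, seed = 4))
  r2 <- reduce_count_labels(ds, reduction_plan("random", 0.5, seed = 4))
  expect_identical(vapply(r1$images, `[[`, TRUE, "has_count"),
                   vapply(r2$images, `[[`, TRUE, "has_count"))
  expect_equal(sum(vapply(r1$images, `[[`, TRUE, "has_count")), 8)
})

test_that("label reduction never touches PLA/genotype and keeps the fraction", {
  ds <- fake_dataset(3, 7)
  for (strat in c("uniform", "juvenile_first", "mature_first", "random")) {
    for (f in c(0.75, 0.5, 0.25)) {
      red <- reduce_count_labels(ds, reduction_plan(strat, f, seed = 1))
      expect_true(all(vapply(red$images, `[[`, TRUE, "has_pla")))
      expect_true(all(vapply(red$images, `[[`, TRUE, "has_genotype")))
      realized <- mean(vapply(red$images, `[[`, TRUE, "has_count"))
      expect_lte(abs(realized - f), 1 / 7 + 1e-9)
    }
  }
  same <- reduce_count_labels(ds, reduction_plan("uniform", 1.0))
  expect_identical(same, ds)
  expect_error(reduction_plan("uniform", 0.6), "keep_fraction")
})
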