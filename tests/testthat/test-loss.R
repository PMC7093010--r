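make_batch <- function(pred_count, gt_count, pred_pla = NULL, gt_pla = NULL,
                       pred_prob = NULL, gt_geno = NULL,
                       has_count = TRUE, has_pla = TRUE, has_genotype = TRUE) {
  n <- length(pred_count)
  rep_n <- function(x, d) if (is.null(x)) rep(d, n) else rep(x, length.out = n)
  list(predictions = list(count = pred_count,
                          pla = rep_n(pred_pla, 0.1),
                          genotype_prob = rep_n(pred_prob, 0.5)),
       targets = list(count = gt_count,
                      pla = rep_n(gt_pla, 0.1),
                      genotype = rep_n(gt_geno, 1L)),
       masks = list(has_count = rep(has_count, length.out = n),
                    has_pla = rep(has_pla, length.out = n),
                    has_genotype = rep(has_genotype, length.out = n)))
}

test_that("a perfect prediction has zero data loss", {
  b <- make_batch(pred_count = c(3, 5), gt_count = c(3, 5),
                  pred_prob = c(1 - 1e-12, 1 - 1e-12), gt_geno = c(1, 1))
  l <- multitask_loss(b$predictions, b$targets, b$masks)
  expect_equal(l$total, 0, tolerance = 1e-9)
  expect_equal(unname(l$per_task), c(0, 0, 0), tolerance = 1e-9)
})

test_that("the count mask annihilates the count term", {
  b <- make_batch(pred_count = 5, gt_count = 4, has_count = FALSE,
                  pred_prob = 1 - 1e-12, gt_geno = 1)
  l <- multitask_loss(b$predictions, b$targets, b$masks)
  expect_equal(l$total, 0, tolerance = 1e-9)
})

test_that("the count term is 10 x masked mean squared error", {
  b <- make_batch(pred_count = c(5, 8), gt_count = c(4, 5),
                  pred_prob = c(1 - 1e-12, 1 - 1e-12), gt_geno = c(1, 1))
  l <- multitask_loss(b$predictions, b$targets, b$masks)
  expect_equal(l$per_task[["count"]], 10 * mean(c(1, 9)))
  expect_equal(l$total, sum(l$per_task))
})

test_that("genotype cross-entropy applies per-class weights", {
  b <- make_batch(pred_count = 3, gt_count = 3,
                  pred_prob = 0.8, gt_geno = 1)
  cfg <- loss_config(genotype_class_weights = c(1, 2))
  l <- multitask_loss(b$predictions, b$targets, b$masks, cfg)
  expect_equal(l$per_task[["genotype"]], -2 * log(0.8))
  # wild-type sample is scored on 1 - p with the wild weight
  b2 <- make_batch(pred_count = 3, gt_count = 3,
                   pred_prob = 0.25, gt_geno = 0)
  l2 <- multitask_loss(b2$predictions, b2$targets, b2$masks, cfg)
  expect_equal(l2$per_task[["genotype"]], -1 * log(0.75))
})

test_that("a batch with every task masked everywhere is rejected", {
  b <- make_batch(pred_count = c(1, 2), gt_count = c(1, 2),
                  has_count = FALSE, has_pla = FALSE, has_genotype = FALSE)
  expect_error(multitask_loss(b$predictions, b$targets, b$masks),
               "unlearnable")
})

test_that("finite differences confirm zero gradient for masked count samples", {
  b <- make_batch(pred_count = c(5, 2, 7), gt_count = c(4, 2, 6),
                  has_count = c(TRUE, FALSE, FALSE),
                  pred_prob = rep(0.7, 3), gt_geno = c(1, 1, 0))
  base <- multitask_loss(b$predictions, b$targets, b$masks)$total
  for (i in 2:3) {
    pert <- b$predictions
    pert$count[i] <- pert$count[i] + 1e-4
    expect_identical(multitask_loss(pert, b$targets, b$masks)$total, base)
  }
  pert <- b$predictions
  pert$count[1] <- pert$count[1] + 1e-4
  expect_gt(multitask_loss(pert, b$targets, b$masks)$total, base)
})

test_that("class weights follow the balanced heuristic", {
  expect_equal(unname(class_weights(c(rep(1, 10), rep(0, 10)))), c(1, 1))
  w <- class_weights(c(rep(1, 15), rep(0, 5)))
  expect_equal(unname(w["wild"]), 2.0)
  expect_equal(unname(w["mutant"]), 2 / 3, tolerance = 1e-9)
  # identity sum_c w_c * N_c = N on random label sets
  for (seed in 1:5) {
    set.seed(seed)
    labs <- c(0, 1, sample(0:1, 20, replace = TRUE))
    w <- class_weights(labs)
    expect_equal(w[["wild"]] * sum(labs == 0) + w[["mutant"]] * sum(labs == 1),
                 length(labs))
  }
  expect_error(class_weights(rep(1, 5)), "both")
})
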