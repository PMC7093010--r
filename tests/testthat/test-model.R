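test_that("build_model validates its configuration", {
  expect_error(build_model(model_config(backbone = "resnet50_pretrained")),
               "small_cnn")
  expect_error(build_model(model_config(backbone = "nonsense")), "small_cnn")
  expect_error(build_model(model_config(input_size = 100)), "multiple of 16")
  m <- build_model(model_config(input_size = 64))
  expect_s3_class(m, "phenomtl_model")
  expect_equal(dim(m$params[["shared.W"]]), c(1536, 128))
  expect_equal(dim(m$params[["genotype3.W"]]), c(2, 256))
})

test_that("single-task model keeps an architecturally identical count branch", {
  set.seed(1)
  mtl <- build_model(model_config(input_size = 64))
  set.seed(1)
  single <- build_model(model_config(input_size = 64,
                                     enabled_tasks = "count"))
  expect_identical(dim(mtl$params[["count1.W"]]),
                   dim(single$params[["count1.W"]]))
  expect_identical(dim(mtl$params[["count2.W"]]),
                   dim(single$params[["count2.W"]]))
  expect_null(single$params[["pla1.W"]])
  expect_null(single$params[["genotype1.W"]])
})

test_that("predictions have the contracted shapes, ranges and determinism", {
  set.seed(2)
  m <- build_model(model_config(input_size = 64))
  ds <- tiny_dataset()
  imgs <- ds$images[1:4]
  p1 <- predict(m, imgs)
  expect_equal(nrow(p1), 4)
  expect_true(all(c("count", "pla", "genotype_prob") %in% names(p1)))
  expect_true(all(is.finite(unlist(p1))))
  expect_true(all(p1$count >= 0))
  expect_true(all(p1$pla >= 0 & p1$pla <= 1))
  expect_equal(p1$genotype_prob + p1$genotype_prob_wild, rep(1, 4),
               tolerance = 1e-12)
  p2 <- predict(m, imgs)
  expect_identical(p1, p2)
  expect_error(predict(m, matrix(0, 10, 2)), "expects")
})

test_that("a forward pass on the small backbone is fast on CPU", {
  set.seed(3)
  m <- build_model(model_config(input_size = 96))
  X <- matrix(runif(3 * 96 * 96 * 8), ncol = 8)
  elapsed <- system.time(predict(m, X))["elapsed"]
  expect_lt(elapsed, 1)
})

test_that("training and inference forward paths agree (single vs double precision)", {
  set.seed(4)
  m <- build_model(model_config(input_size = 64))
  X <- matrix(runif(3 * 64 * 64 * 3), ncol = 3)
  inf <- phenomtl:::model_forward(m, X, cache = FALSE)$tasks
  tr <- phenomtl:::model_forward(m, X, cache = TRUE)$tasks
  expect_equal(inf$count, tr$count, tolerance = 1e-4)
  expect_equal(inf$genotype, tr$genotype, tolerance = 1e-4)
})

test_that("all task losses backpropagate into the shared trunk (hard sharing)", {
  set.seed(5)
  m <- build_model(model_config(input_size = 64))
  X <- matrix(runif(3 * 64 * 64 * 4), ncol = 4)
  tg <- list(count = rep(5, 4), pla = rep(0.2, 4), genotype = c(0, 1, 0, 1),
             has_count = rep(FALSE, 4), has_pla = rep(TRUE, 4),
             has_genotype = rep(FALSE, 4))
  fwd <- phenomtl:::model_forward(m, X, cache = TRUE)
  bl <- phenomtl:::batch_loss_and_grads(m, fwd, tg, 1:4, loss_config())
  g <- phenomtl:::model_backward(m, fwd$cache, bl$dz)
  # a PLA-only batch still updates the shared conv trunk and representation
  expect_gt(sum(abs(g[["conv1.W"]])), 0)
  expect_gt(sum(abs(g[["shared.W"]])), 0)
  # but leaves the masked count branch output layer untouched
  expect_equal(sum(abs(g[["count2.W"]])), 0)
})

test_that("models round-trip through save/load with identical predictions", {
  fit <- tiny_fit()
  path <- withr::local_tempfile(fileext = ".json")
  save_model(fit$model, path)
  back <- load_model(path)
  imgs <- tiny_dataset()$images[1:3]
  expect_equal(predict(fit$model, imgs), predict(back, imgs),
               tolerance = 1e-12)
})

test_that("the sigmoid genotype head yields normalised mutant probabilities", {
  set.seed(6)
  m <- build_model(model_config(input_size = 64, genotype_head = "sigmoid"))
  p <- predict(m, tiny_dataset()$images[1:3])
  expect_true(all(p$genotype_prob >= 0 & p$genotype_prob <= 1))
  expect_equal(p$genotype_prob + p$genotype_prob_wild, rep(1, 3))
})
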