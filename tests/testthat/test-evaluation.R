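test_that("count metrics match hand-computed values", {
  m <- count_metrics(c(3, 4, 5), c(3, 3, 5))
  expect_equal(m$dic_mean, 1 / 3)
  expect_equal(m$abs_dic_mean, 1 / 3)
  expect_equal(m$agreement, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(m$mse, 1 / 3)

  exact <- count_metrics(c(2.2, 3.6, 5.4), c(2, 4, 5))
  expect_equal(exact$dic_mean, 0)
  expect_equal(exact$agreement, 100)
  expect_equal(exact$r_squared, 1)

  gt <- c(2, 4, 6, 8)
  flat <- count_metrics(rep(mean(gt), 4), gt)
  expect_lte(flat$r_squared, 0)
  expect_error(count_metrics(1:3, 1:4), "length")
  expect_error(count_metrics(1, 1), "at least 2")
  expect_warning(count_metrics(c(3, 4), c(3, 3)), "constant")
})

test_that("rounding is half away from zero", {
  expect_equal(round_half_up(c(2.5, 3.5, -2.5, 0.49, -0.5)),
               c(3, 4, -3, 0, -1))
})

test_that("metrics agree with brute-force oracles on random instances", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(2:50, 1)
    gt <- sample(0:12, n, replace = TRUE)
    if (length(unique(gt)) == 1) gt[1] <- gt[1] + 1L
    pred <- gt + rnorm(n, 0, 1.5)
    a <- count_metrics(pred, gt)
    b <- oracle_count(pred, gt)
    for (f in names(b)) expect_equal(a[[f]], b[[f]], tolerance = 1e-9)
    expect_equal(within_one_accuracy(pred, gt)$percent,
                 oracle_within_one(pred, gt), tolerance = 1e-9)
    prob <- runif(n)
    labs <- sample(0:1, n, replace = TRUE)
    g1 <- genotype_metrics(prob, labs)
    g2 <- oracle_genotype(prob, labs)
    expect_equal(g1$accuracy, g2$accuracy, tolerance = 1e-9)
    expect_equal(unname(unclass(g1$confusion)), g2$confusion)
    expect_gte(a$mse, a$dic_mean^2 - 1e-12)
    expect_gte(a$abs_dic_mean, abs(a$dic_mean) - 1e-12)
  }
})

test_that("within-one accuracy and its histogram are consistent", {
  pred <- c(1, 2, 4, 6, 9)
  gt <- c(3, 3, 4, 5, 7)        # diffs -2, -1, 0, 1, 2
  w <- within_one_accuracy(pred, gt)
  expect_equal(w$percent, 60)
  expect_equal(sum(w$histogram), length(gt))
  expect_equal(within_one_accuracy(gt, gt)$percent, 100)
})

test_that("genotype metrics handle edge cases and normalise rows", {
  g <- genotype_metrics(c(0.9, 0.2), c(1, 1))
  expect_equal(g$accuracy, 50)
  all_right <- genotype_metrics(c(0.1, 0.95, 0.2), c(0, 1, 0))
  expect_equal(all_right$accuracy, 100)
  expect_equal(sum(all_right$confusion[1, 2], all_right$confusion[2, 1]), 0)
  both <- genotype_metrics(c(0.9, 0.2, 0.7, 0.1), c(1, 1, 0, 0))
  expect_equal(unname(rowSums(both$confusion_percent)), c(100, 100))
  # a class absent from the truth yields an all-zero (not NaN) row
  expect_equal(unname(rowSums(g$confusion_percent)), c(0, 100))
  expect_error(genotype_metrics(numeric(0), numeric(0)), "empty")
})

test_that("bootstrap test is exact on degenerate input and detects big shifts", {
  e <- c(1, 2, 3, 2, 1)
  expect_identical(bootstrap_paired_ttest(e, e, n_boot = 100), 1.0)
  set.seed(1)
  a <- rnorm(50, 0, 0.1)
  b <- a + 5 + rnorm(50, 0, 0.01)
  expect_lt(bootstrap_paired_ttest(a, b, n_boot = 2e4, seed = 1), 0.001)
  # two-tailed symmetry under swapping the samples
  set.seed(2)
  x <- rnorm(20)
  y <- x + rnorm(20, 0.3, 0.5)
  expect_equal(bootstrap_paired_ttest(x, y, n_boot = 5e3, seed = 9),
               bootstrap_paired_ttest(y, x, n_boot = 5e3, seed = 9))
  expect_error(bootstrap_paired_ttest(1:3, 1:4), "length")
  expect_error(bootstrap_paired_ttest(1:2, 2:3), "3 pairs")
})

test_that("vectorised bootstrap matches a plain-loop implementation", {
  set.seed(5)
  a <- rnorm(12)
  b <- a + rnorm(12, 0.4, 0.6)
  p_fast <- bootstrap_paired_ttest(a, b, n_boot = 3000, seed = 17)
  p_slow <- oracle_boot_p(a, b, 3000, seed = 31)
  expect_lt(abs(p_fast - p_slow), 0.03)
})

test_that("evaluation reports assemble all task metrics", {
  df <- data.frame(gt_count = c(3, 4, 5, 6), count = c(3.2, 3.9, 6.1, 5.8),
                   gt_pla = c(0.1, 0.2, 0.3, 0.4),
                   pla = c(0.12, 0.18, 0.33, 0.41),
                   gt_genotype = c(0, 0, 1, 1),
                   genotype_prob = c(0.2, 0.6, 0.8, 0.4))
  rep <- evaluation_report(df)
  expect_equal(rep$n, 4)
  expect_equal(rep$mse, mean((round_half_up(df$count) - df$gt_count)^2))
  expect_equal(rep$pla_mse, mean((df$pla - df$gt_pla)^2))
  expect_equal(rep$genotype_accuracy, 50)
  expect_equal(sum(rep$confusion), 4)
})
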