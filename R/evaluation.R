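#' Round half away from zero
#'
#' Converts raw count regressions to integer counts using the CVPPP
#' convention (2.5 -> 3, -2.5 -> -3), unlike R's banker's rounding.
#'
#' @param x Numeric vector.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' CVPPP leaf-count metrics
#'
#' Computes the standard leaf-counting metric suite on a test set:
#' difference in count `DiC = mean(round(pred) - gt)` with its population
#' standard deviation, absolute DiC, percentage agreement (exact match of
#' the rounded prediction), MSE of the rounded predictions and the
#' coefficient of determination R^2. Predictions are rounded half away
#' from zero before all metrics unless `raw = TRUE`.
#'
#' @param pred Numeric predictions.
#' @param gt Integer ground-truth counts (same length, >= 2 for R^2).
#' @param raw Skip rounding?
#' @return List with `dic_mean`, `dic_std`, `abs_dic_mean`, `abs_dic_std`,
#'   `agreement`, `mse`, `r_squared` (NA with a warning when the ground
#'   truth is constant).
#' @export
count_metrics <- function(pred, gt, raw = FALSE) {
  if (length(pred) != length(gt))
    stop("pred and gt must have the same length")
  if (length(gt) < 2) stop("count metrics need at least 2 observations")
  r <- if (raw) pred else round_half_up(pred)
  d <- r - gt
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  ss_tot <- sum((gt - mean(gt))^2)
  r2 <- if (ss_tot == 0) {
    warning("constant ground truth: R^2 undefined, returning NA")
    NA_real_
  } else 1 - sum(d^2) / ss_tot
  list(dic_mean = mean(d), dic_std = pop_sd(d),
       abs_dic_mean = mean(abs(d)), abs_dic_std = pop_sd(abs(d)),
       agreement = 100 * mean(d == 0),
       mse = mean(d^2),
       r_squared = r2)
}

#' Percentage of predictions within one leaf of the truth
#'
#' Also returns the signed difference-in-count histogram used to inspect
#' the spread of counting errors around zero.
#'
#' @param pred Numeric predictions.
#' @param gt Integer ground truth.
#' @return List with `percent` and `histogram` (named table of signed
#'   rounded differences; bin counts sum to `length(gt)`).
#' @export
within_one_accuracy <- function(pred, gt) {
  if (length(pred) != length(gt))
    stop("pred and gt must have the same length")
  d <- round_half_up(pred) - gt
  list(percent = 100 * mean(abs(d) <= 1),
       histogram = table(factor(d, levels = seq(min(d), max(d)))))
}

#' Genotype classification metrics
#'
#' Hard calls at the given probability threshold; returns overall accuracy
#' and the 2x2 confusion matrix in counts and row-normalised percentages
#' (rows are the true class, columns the predicted class).
#'
#' @param prob Predicted probability of the mutant class.
#' @param labels True 0/1 labels.
#' @param threshold Decision threshold (default 0.5).
#' @return List with `accuracy` (percent), `confusion` (counts) and
#'   `confusion_percent` (each row sums to 100).
#' @export
genotype_metrics <- function(prob, labels, threshold = 0.5) {
  if (length(prob) == 0) stop("empty input")
  if (length(prob) != length(labels))
    stop("prob and labels must have the same length")
  call <- as.integer(prob >= threshold)
  lev <- c("wild-type", "mutant")
  conf <- table(factor(lev[labels + 1], levels = lev),
                factor(lev[call + 1], levels = lev))
  rs <- rowSums(conf)
  confp <- sweep(conf, 1, ifelse(rs == 0, 1, rs), "/") * 100
  list(accuracy = 100 * mean(call == labels),
       confusion = unclass(conf),
       confusion_percent = unclass(confp))
}

#' Bootstrapped paired t-test
#'
#' A bootstrap-t test on paired differences for settings where the error
#' distribution is non-Gaussian: the observed paired t statistic is
#' compared against the distribution of t statistics computed on
#' `n_boot` resamples (with replacement) of the mean-centred differences
#' (the null of equal means imposed). The two-tailed p-value is the
#' fraction of resampled `|t*|` at or above the observed `|t|`.
#'
#' @param errors_a,errors_b Paired samples (equal length, n >= 3).
#' @param n_boot Number of bootstrap resamples (default 1e5).
#' @param seed Seed for the resampling.
#' @return Two-tailed p-value; exactly 1 when all paired differences are
#'   zero.
#' @export
bootstrap_paired_ttest <- function(errors_a, errors_b, n_boot = 1e5,
                                   seed = 1L) {
  if (length(errors_a) != length(errors_b))
    stop("paired samples must have the same length")
  n <- length(errors_a)
  if (n < 3) stop("need at least 3 pairs")
  d <- errors_a - errors_b
  if (all(d == 0)) return(1.0)
  t_obs <- mean(d) / (stats::sd(d) / sqrt(n))
  d0 <- d - mean(d)
  with_rng(seed, {
    exceed <- 0
    chunk <- 20000L
    done <- 0L
    while (done < n_boot) {
      m <- min(chunk, n_boot - done)
      X <- matrix(sample(d0, n * m, replace = TRUE), n, m)
      mu <- colMeans(X)
      v <- (colMeans(X^2) - mu^2) * n / (n - 1)
      tstar <- ifelse(v > 0, mu / sqrt(v / n),
                      ifelse(mu == 0, 0, Inf))
      exceed <- exceed + sum(abs(tstar) >= abs(t_obs))
      done <- done + m
    }
    exceed / n_boot
  })
}

#' Build an evaluation report from pooled test predictions
#'
#' Combines the count metric suite, the within-one accuracy, the PLA MSE
#' and the genotype metrics into one report, for whichever tasks are
#' present.
#'
#' @param predictions Data frame with ground-truth columns `gt_count`,
#'   `gt_pla`, `gt_genotype` and prediction columns `count`, `pla`,
#'   `genotype_prob` (as produced by [cross_validate()]).
#' @param tasks Tasks to report on.
#' @return Object of class `evaluation_report` (a list of metric fields).
#' @export
evaluation_report <- function(predictions,
                              tasks = c("count", "pla", "genotype")) {
  rep <- list(n = nrow(predictions))
  if ("count" %in% tasks && !is.null(predictions$count)) {
    cm <- count_metrics(predictions$count, predictions$gt_count)
    w1 <- within_one_accuracy(predictions$count, predictions$gt_count)
    rep <- c(rep, cm, list(within_one = w1$percent,
                           dic_histogram = w1$histogram))
  }
  if ("pla" %in% tasks && !is.null(predictions$pla))
    rep$pla_mse <- mean((predictions$pla - predictions$gt_pla)^2)
  if ("genotype" %in% tasks && !is.null(predictions$genotype_prob)) {
    gm <- genotype_metrics(predictions$genotype_prob,
                           predictions$gt_genotype)
    rep$genotype_accuracy <- gm$accuracy
    rep$confusion <- gm$confusion
    rep$confusion_percent <- gm$confusion_percent
  }
  structure(rep, class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation report (n = %d)\n", x$n))
  if (!is.null(x$dic_mean)) {
    cat(sprintf("  DiC %.2f (%.2f)  |DiC| %.2f (%.2f)\n",
                x$dic_mean, x$dic_std, x$abs_dic_mean, x$abs_dic_std))
    cat(sprintf("  agreement %.1f%%  MSE %.3f  R^2 %s  within-1 %.1f%%\n",
                x$agreement, x$mse,
                ifelse(is.na(x$r_squared), "N/A", sprintf("%.3f", x$r_squared)),
                x$within_one))
  }
  if (!is.null(x$pla_mse)) cat(sprintf("  PLA MSE %.4f\n", x$pla_mse))
  if (!is.null(x$genotype_accuracy))
    cat(sprintf("  genotype accuracy %.1f%%\n", x$genotype_accuracy))
  invisible(x)
}
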