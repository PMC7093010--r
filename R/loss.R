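#' Loss configuration for multitask training
#'
#' The count and PLA tasks use mean squared error; because PLA fractions
#' and (relative to the cross-entropy term) count errors produce small
#' values, both MSE terms are multiplied by 10 to keep the three task
#' losses comparable. The genotype task uses two-class cross-entropy with
#' optional per-class weights to counter class imbalance.
#'
#' @param count_scale Multiplier on the count MSE (default 10).
#' @param pla_scale Multiplier on the PLA MSE (default 10).
#' @param genotype_class_weights Two positive weights `c(wild, mutant)`
#'   applied to the cross-entropy of samples of each true class.
#' @return Object of class `loss_config`.
#' @export
loss_config <- function(count_scale = 10, pla_scale = 10,
                        genotype_class_weights = c(1, 1)) {
  stopifnot(count_scale > 0, pla_scale > 0,
            length(genotype_class_weights) == 2,
            all(genotype_class_weights > 0))
  structure(list(count_scale = count_scale, pla_scale = pla_scale,
                 genotype_class_weights = genotype_class_weights),
            class = "loss_config")
}

#' Balanced class weights from training genotype labels
#'
#' Uses the balanced heuristic `w_c = N_total / (2 * N_c)`, which satisfies
#' `sum_c w_c * N_c = N_total`: the majority class gets weight below 1 and
#' the minority class above 1, making per-class training importance
#' proportional to the inverse class frequency.
#'
#' @param train_labels Vector of 0 (wild-type) / 1 (mutant) labels.
#' @return Named numeric vector `c(wild = ..., mutant = ...)`.
#' @export
class_weights <- function(train_labels) {
  train_labels <- train_labels[!is.na(train_labels)]
  n0 <- sum(train_labels == 0)
  n1 <- sum(train_labels == 1)
  if (n0 == 0 || n1 == 0)
    stop("both genotype classes must be present in the training labels")
  n <- n0 + n1
  c(wild = n / (2 * n0), mutant = n / (2 * n1))
}

#' Label-masked multitask loss
#'
#' The total loss is
#' `count_scale * MSE_count + pla_scale * MSE_pla + weighted CE_genotype`,
#' where each task's term averages only over the images whose availability
#' flag for that task is `TRUE`. A task with no unmasked image in the
#' batch contributes exactly zero (and, in training, propagates no
#' gradient to that branch for those samples) — this is what lets
#' partially annotated datasets train all tasks jointly.
#'
#' @param predictions List or data frame with elements among `count`,
#'   `pla`, `genotype_prob` (probability of the mutant class).
#' @param targets List or data frame with elements `count`, `pla`,
#'   `genotype` (0/1), aligned with the predictions.
#' @param masks List or data frame with logical vectors `has_count`,
#'   `has_pla`, `has_genotype`.
#' @param config A [loss_config()].
#' @return List with `total` and `per_task` (named numeric vector with
#'   entries count, pla, genotype).
#' @export
multitask_loss <- function(predictions, targets, masks,
                           config = loss_config()) {
  n <- length(masks$has_count %||% masks$has_pla %||% masks$has_genotype)
  mc <- as.logical(masks$has_count %||% rep(FALSE, n))
  mp <- as.logical(masks$has_pla %||% rep(FALSE, n))
  mg <- as.logical(masks$has_genotype %||% rep(FALSE, n))
  if (all(!mc & !mp & !mg))
    stop("unlearnable batch: every sample has all three task masks FALSE")
  per <- c(count = 0, pla = 0, genotype = 0)
  if (any(mc)) {
    e <- predictions$count[mc] - targets$count[mc]
    per[["count"]] <- config$count_scale * mean(e^2)
  }
  if (any(mp)) {
    e <- predictions$pla[mp] - targets$pla[mp]
    per[["pla"]] <- config$pla_scale * mean(e^2)
  }
  if (any(mg)) {
    y <- targets$genotype[mg]
    p <- pmin(pmax(predictions$genotype_prob[mg], 1e-12), 1 - 1e-12)
    w <- config$genotype_class_weights[y + 1]
    per[["genotype"]] <- mean(w * ifelse(y == 1, -log(p), -log(1 - p)))
  }
  list(total = sum(per), per_task = per)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
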