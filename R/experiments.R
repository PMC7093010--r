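#' Desk-scale experiment configuration
#'
#' The default regime used by the experiment drivers: a synthetic dataset
#' of 20 plants x 12 timepoints rendered at 96 pixels, the small CNN
#' backbone with a 768-unit shared representation, two-fold plant-level
#' cross-validation with two validation plants per fold, and Adam at 1e-3
#' (a standard rate for a small network trained from scratch) for up to
#' 48 epochs with patience 10 after a 22-epoch warm-up during which early
#' stopping is not armed. The warm-up matters: with sparse count labels,
#' count-bearing batches are rare and the count task converges several
#' times later than with full labels, so early stopping must not fire
#' against the pre-convergence plateau. Data augmentation is off in this
#' regime: the synthetic generator already randomises leaf placement and
#' orientation, so augmentation buys no generalisation here and only
#' slows convergence (it remains the default for training on real
#' images). Swapping in a larger backbone, 320-pixel inputs, the full
#' 1536-unit shared layer, augmentation and fourfold cross-validation
#' recovers the full-scale configuration when the hardware allows it.
#'
#' @param n_plants,n_timepoints,canvas_size Synthetic dataset dimensions.
#' @param k Cross-validation folds.
#' @param n_val Validation plants held out per fold.
#' @param seeds Integer vector of experiment seeds.
#' @param input_size Model input side in pixels.
#' @param shared_dim Shared representation width for the desk-scale model.
#' @param max_epochs,patience,min_epochs,batch_size,learning_rate
#'   Optimisation settings.
#' @param augment Per-epoch data augmentation (off by default here).
#' @return Named list of configuration pieces consumed by the
#'   `run_*` experiment drivers.
#' @export
desk_spec <- function(n_plants = 20, n_timepoints = 12, canvas_size = 96,
                      k = 2, n_val = 2, seeds = 1:5, input_size = 96,
                      shared_dim = 768,
                      max_epochs = 48, patience = 10, min_epochs = 22,
                      batch_size = 8, learning_rate = 1e-3,
                      augment = FALSE) {
  list(n_plants = n_plants, n_timepoints = n_timepoints,
       canvas_size = canvas_size, k = k, n_val = n_val, seeds = seeds,
       model = function(tasks = c("count", "pla", "genotype"))
         model_config(input_size = input_size, shared_dim = shared_dim,
                      enabled_tasks = tasks),
       train = function(seed = 1L)
         train_config(learning_rate = learning_rate, batch_size = batch_size,
                      max_epochs = max_epochs, early_stop_patience = patience,
                      min_epochs = min_epochs, seed = seed,
                      augment = augment),
       loss = loss_config())
}

seed_dataset <- function(spec, seed) {
  generate_dataset(spec$n_plants, spec$n_timepoints,
                   canvas_size = spec$canvas_size,
                   seed = derive_seed(seed, 1))
}

run_one_cv <- function(spec, ds, seed, tasks, reduction = NULL) {
  cross_validate(ds, k = spec$k, model_cfg = spec$model(tasks),
                 loss_cfg = spec$loss, train_cfg = spec$train(),
                 reduction = reduction, seed = derive_seed(seed, 2),
                 n_val = spec$n_val %||% 1L)
}

#' Multitask versus single-task leaf counting
#'
#' For each seed, trains the full multitask model and a single-task count
#' model on identical data and identical plant-level splits, reports the
#' pooled count metrics of both, and tests the per-image absolute count
#' errors of the two models against each other with the bootstrapped
#' paired t-test.
#'
#' @param spec A [desk_spec()].
#' @param n_boot Bootstrap resamples for the paired test.
#' @return List with `table` (one row per seed x model with the count
#'   metric suite and the paired p-value), `reports` (the full pooled
#'   evaluation reports) and `p_values`.
#' @export
run_mtl_vs_single <- function(spec = desk_spec(), n_boot = 1e4) {
  rows <- list()
  reports <- list()
  p_values <- numeric(0)
  for (seed in spec$seeds) {
    ds <- seed_dataset(spec, seed)
    mtl <- run_one_cv(spec, ds, seed, c("count", "pla", "genotype"))
    single <- run_one_cv(spec, ds, seed, "count")
    stopifnot(identical(sort(mtl$predictions$image),
                        sort(single$predictions$image)))
    m <- mtl$predictions[order(mtl$predictions$image), ]
    s <- single$predictions[order(single$predictions$image), ]
    err_m <- abs(round_half_up(m$count) - m$gt_count)
    err_s <- abs(round_half_up(s$count) - s$gt_count)
    p <- bootstrap_paired_ttest(err_m, err_s, n_boot = n_boot,
                                seed = derive_seed(seed, 99))
    p_values <- c(p_values, p)
    reports[[paste0("seed", seed)]] <- list(mtl = mtl$pooled,
                                            single = single$pooled)
    for (nm in c("mtl", "single")) {
      rp <- if (nm == "mtl") mtl$pooled else single$pooled
      rows[[length(rows) + 1L]] <-
        data.frame(seed = seed, model = nm, dic = rp$dic_mean,
                   dic_std = rp$dic_std, abs_dic = rp$abs_dic_mean,
                   agreement = rp$agreement, mse = rp$mse,
                   r_squared = rp$r_squared, p_value = p)
    }
  }
  list(table = do.call(rbind, rows), reports = reports, p_values = p_values)
}

#' Count-annotation reduction grid
#'
#' Trains the multitask and single-task models at each count-label keep
#' fraction (uniform removal along every plant's time axis; PLA and
#' genotype labels always complete) and reports the count metric suite per
#' cell, one grid per seed.
#'
#' @param spec A [desk_spec()].
#' @param keep_fractions Subset of `c(1, 0.75, 0.5, 0.25)`.
#' @param models Which of `c("mtl", "single")` to run.
#' @return List with `table` (seed x model x fraction rows) and `reports`.
#' @export
run_label_reduction <- function(spec = desk_spec(),
                                keep_fractions = c(1, 0.75, 0.5, 0.25),
                                models = c("mtl", "single")) {
  rows <- list()
  reports <- list()
  for (seed in spec$seeds) {
    ds <- seed_dataset(spec, seed)
    for (model in models) {
      tasks <- if (model == "mtl") c("count", "pla", "genotype") else "count"
      for (f in keep_fractions) {
        red <- if (f < 1) reduction_plan("uniform", f, seed = seed) else NULL
        cv <- run_one_cv(spec, ds, seed, tasks, reduction = red)
        key <- sprintf("seed%d_%s_keep%g", seed, model, f)
        reports[[key]] <- cv$pooled
        rp <- cv$pooled
        rows[[length(rows) + 1L]] <-
          data.frame(seed = seed, model = model, keep_fraction = f,
                     dic = rp$dic_mean, dic_std = rp$dic_std,
                     abs_dic = rp$abs_dic_mean, agreement = rp$agreement,
                     mse = rp$mse, r_squared = rp$r_squared,
                     within_one = rp$within_one)
      }
    }
  }
  list(table = do.call(rbind, rows), reports = reports)
}

#' Annotation strategy comparison
#'
#' Runs the multitask model under different count-label removal
#' strategies (juvenile-first, mature-first, random) at the given keep
#' fractions and reports count, PLA and genotype metrics per cell.
#'
#' @param spec A [desk_spec()].
#' @param strategies Subset of
#'   `c("juvenile_first", "mature_first", "random")`.
#' @param keep_fractions Subset of `c(0.75, 0.5, 0.25)` (1.0 is allowed
#'   and reduces to the unreduced baseline for every strategy).
#' @return List with `table` and `reports`.
#' @export
run_strategy_comparison <- function(spec = desk_spec(),
                                    strategies = c("juvenile_first",
                                                   "mature_first", "random"),
                                    keep_fractions = c(0.75, 0.5, 0.25)) {
  rows <- list()
  reports <- list()
  for (seed in spec$seeds) {
    ds <- seed_dataset(spec, seed)
    for (strat in strategies) {
      for (f in keep_fractions) {
        red <- if (f < 1) reduction_plan(strat, f, seed = seed) else NULL
        cv <- run_one_cv(spec, ds, seed, c("count", "pla", "genotype"),
                         reduction = red)
        key <- sprintf("seed%d_%s_keep%g", seed, strat, f)
        reports[[key]] <- cv$pooled
        rp <- cv$pooled
        rows[[length(rows) + 1L]] <-
          data.frame(seed = seed, strategy = strat, keep_fraction = f,
                     abs_dic = rp$abs_dic_mean, agreement = rp$agreement,
                     mse = rp$mse, r_squared = rp$r_squared,
                     pla_mse = rp$pla_mse,
                     genotype_accuracy = rp$genotype_accuracy)
      }
    }
  }
  list(table = do.call(rbind, rows), reports = reports)
}
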