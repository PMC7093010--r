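#' Optimisation configuration
#'
#' @param learning_rate Adam learning rate (default 1e-4, the full-scale
#'   setting; the desk-scale experiment drivers use 1e-3, a standard Adam
#'   rate for small networks trained from scratch).
#' @param batch_size Mini-batch size (default 16 for the small backbone).
#' @param max_epochs Upper bound on training epochs.
#' @param early_stop_patience Epochs without validation-loss improvement
#'   before stopping (>= 1).
#' @param min_epochs Warm-up epochs before early stopping is armed; small
#'   networks trained from scratch spend their first epochs near the
#'   mean predictor and must not be stopped against a lucky early
#'   validation value.
#' @param seed Seed for shuffling, augmentation and any other training
#'   randomness.
#' @param augment Apply one random augmentation per training image per
#'   epoch?
#' @return Object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 16,
                         max_epochs = 50, early_stop_patience = 10,
                         min_epochs = 1, seed = 1L, augment = TRUE) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stop_patience >= 1, min_epochs >= 1)
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 max_epochs = max_epochs,
                 early_stop_patience = early_stop_patience,
                 min_epochs = min_epochs,
                 seed = as.integer(seed), augment = isTRUE(augment)),
            class = "train_config")
}

# Extract aligned target/mask vectors from a dataset's image records.
dataset_targets <- function(dataset) {
  imgs <- dataset$images
  list(count = vapply(imgs, function(i) as.numeric(i$leaf_count %||% NA), 1),
       pla = vapply(imgs, function(i) as.numeric(i$pla %||% NA), 1),
       genotype = vapply(imgs, function(i) as.numeric(i$genotype %||% NA), 1),
       has_count = vapply(imgs, function(i) isTRUE(i$has_count), TRUE),
       has_pla = vapply(imgs, function(i) isTRUE(i$has_pla), TRUE),
       has_genotype = vapply(imgs, function(i) isTRUE(i$has_genotype), TRUE))
}

# Per-task loss terms and final-layer pre-activation gradients for one
# batch. Masked samples contribute exactly zero gradient.
batch_loss_and_grads <- function(model, fwd, tg, idx, loss_cfg) {
  cfg <- model$config
  out <- fwd$tasks
  n <- length(idx)
  per <- c(count = 0, pla = 0, genotype = 0)
  dz <- list()
  if ("count" %in% cfg$enabled_tasks) {
    m <- tg$has_count[idx]
    pred <- as.numeric(out$count)
    d <- numeric(n)
    if (any(m)) {
      e <- pred[m] - tg$count[idx][m]
      per[["count"]] <- loss_cfg$count_scale * mean(e^2)
      d[m] <- loss_cfg$count_scale * 2 * e / sum(m)
    }
    zf <- fwd$cache$branches$count$zs[[length(cfg$branches$count)]]
    dz$count <- matrix(d * (as.numeric(zf) > 0), 1, n)
  }
  if ("pla" %in% cfg$enabled_tasks) {
    m <- tg$has_pla[idx]
    pred <- as.numeric(out$pla)
    d <- numeric(n)
    if (any(m)) {
      e <- pred[m] - tg$pla[idx][m]
      per[["pla"]] <- loss_cfg$pla_scale * mean(e^2)
      d[m] <- loss_cfg$pla_scale * 2 * e / sum(m)
    }
    zf <- fwd$cache$branches$pla$zs[[length(cfg$branches$pla)]]
    slope <- ifelse(as.numeric(zf) > 0, 1, cfg$leaky_slope)
    dz$pla <- matrix(d * slope, 1, n)
  }
  if ("genotype" %in% cfg$enabled_tasks) {
    m <- tg$has_genotype[idx]
    pr <- out$genotype                     # 2 x n (softmax) or sigmoids
    d <- matrix(0, 2, n)
    if (any(m)) {
      y <- tg$genotype[idx][m]
      w <- loss_cfg$genotype_class_weights[y + 1]
      pmut <- pmin(pmax(pr[2, m], 1e-12), 1 - 1e-12)
      if (cfg$genotype_head == "softmax") {
        per[["genotype"]] <- mean(w * ifelse(y == 1, -log(pmut),
                                             -log(1 - pmut)))
        onehot <- rbind(1 - y, y)
        d[, m] <- sweep(pr[, m, drop = FALSE] - onehot, 2, w / sum(m), "*")
      } else {
        pw <- pmin(pmax(pr[1, m], 1e-12), 1 - 1e-12)
        onehot <- rbind(1 - y, y)
        pc <- rbind(pw, pmut)
        per[["genotype"]] <- mean(w * colSums(-onehot * log(pc) -
                                              (1 - onehot) * log(1 - pc)) / 2)
        d[, m] <- sweep(pr[, m, drop = FALSE] - onehot, 2, w / (2 * sum(m)), "*")
      }
    }
    dz$genotype <- d
  }
  list(per_task = per, dz = dz)
}

#' Train a multitask model
#'
#' Mini-batch Adam optimisation of the label-masked multitask loss with
#' per-epoch data augmentation, validation-loss early stopping and
#' best-validation model selection. The validation set must be fully
#' annotated for the model's enabled tasks. Runs are reproducible given
#' the seed.
#'
#' @param model A freshly built [build_model()] model.
#' @param train_set,val_set `rosette_dataset` objects.
#' @param loss_cfg A [loss_config()].
#' @param train_cfg A [train_config()].
#' @return List with `model` (the best-validation checkpoint) and
#'   `history` (data frame of per-epoch per-task train/validation losses).
#' @export
train_model <- function(model, train_set, val_set,
                        loss_cfg = loss_config(),
                        train_cfg = train_config()) {
  stopifnot(inherits(model, "phenomtl_model"),
            length(train_set$images) > 0, length(val_set$images) > 0)
  cfg <- model$config
  S <- cfg$input_size
  tg <- dataset_targets(train_set)
  vg <- dataset_targets(val_set)
  if (!all(tg$has_count | tg$has_pla | tg$has_genotype))
    stop("some training image has no annotation for any task")

  base_cols <- vapply(train_set$images,
                      function(im) image_to_column(preprocess(im$pixels, S)),
                      numeric(3 * S * S))
  val_X <- vapply(val_set$images,
                  function(im) image_to_column(preprocess(im$pixels, S)),
                  numeric(3 * S * S))
  n <- ncol(base_cols)

  # detach parameter storage: the Adam step updates arrays in place
  model$params <- lapply(model$params, function(x) x + 0)

  # initialise regression output biases at the training-set target means so
  # optimisation starts at the mean predictor instead of spending epochs
  # getting there (standard output-prior initialisation)
  cfg_m <- model$config
  if ("count" %in% cfg_m$enabled_tasks && any(tg$has_count)) {
    nm <- paste0("count", length(cfg_m$branches$count), ".b")
    model$params[[nm]][] <- mean(tg$count[tg$has_count])
  }
  if ("pla" %in% cfg_m$enabled_tasks && any(tg$has_pla)) {
    nm <- paste0("pla", length(cfg_m$branches$pla), ".b")
    model$params[[nm]][] <- mean(tg$pla[tg$has_pla])
  }
  adam_m <- lapply(model$params, function(x) x * 0)
  adam_v <- lapply(model$params, function(x) x * 0)
  step <- 0L
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- train_cfg$learning_rate

  best_val <- Inf
  best_params <- lapply(model$params, function(x) x + 0)
  patience_left <- train_cfg$early_stop_patience
  hist <- list()

  set.seed(train_cfg$seed)
  for (epoch in seq_len(train_cfg$max_epochs)) {
    ord <- sample(n)
    ep_loss <- c(count = 0, pla = 0, genotype = 0)
    ep_n <- 0L
    for (start in seq(1, n, by = train_cfg$batch_size)) {
      idx <- ord[start:min(start + train_cfg$batch_size - 1, n)]
      Xb <- base_cols[, idx, drop = FALSE]
      if (train_cfg$augment) {
        for (j in seq_along(idx)) {
          img <- array(Xb[, j], c(S, S, 3))           # transposed layout
          img <- aperm(img, c(2, 1, 3))
          Xb[, j] <- image_to_column(augment(img))
        }
      }
      fwd <- model_forward(model, Xb, cache = TRUE)
      bl <- batch_loss_and_grads(model, fwd, tg, idx, loss_cfg)
      if (!all(is.finite(bl$per_task))) {
        bad <- names(bl$per_task)[!is.finite(bl$per_task)]
        stop("non-finite training loss in task term(s): ",
             paste(bad, collapse = ", "))
      }
      grads <- model_backward(model, fwd$cache, bl$dz)
      step <- step + 1L
      corr <- sqrt(1 - b2^step) / (1 - b1^step)
      for (nm in names(model$params))
        adam_step_cpp(model$params[[nm]], adam_m[[nm]], adam_v[[nm]],
                      grads[[nm]], lr, b1, b2, eps, corr)
      ep_loss <- ep_loss + bl$per_task * length(idx)
      ep_n <- ep_n + length(idx)
    }
    ep_loss <- ep_loss / ep_n

    vl <- validation_loss(model, val_X, vg, loss_cfg)
    hist[[epoch]] <- data.frame(epoch = epoch,
                                train_total = sum(ep_loss),
                                train_count = ep_loss[["count"]],
                                train_pla = ep_loss[["pla"]],
                                train_genotype = ep_loss[["genotype"]],
                                val_total = vl$total,
                                val_count = vl$per_task[["count"]],
                                val_pla = vl$per_task[["pla"]],
                                val_genotype = vl$per_task[["genotype"]])
    if (vl$total < best_val - 1e-12) {
      best_val <- vl$total
      best_params <- lapply(model$params, function(x) x + 0)
      patience_left <- train_cfg$early_stop_patience
    } else if (epoch >= (train_cfg$min_epochs %||% 1)) {
      patience_left <- patience_left - 1L
      if (patience_left <= 0L) break
    }
  }
  model$params <- best_params
  list(model = model, history = do.call(rbind, hist), best_val = best_val)
}

# Total masked loss on a precomputed validation batch (no augmentation).
validation_loss <- function(model, val_X, vg, loss_cfg, batch_size = 64) {
  cfg <- model$config
  n <- ncol(val_X)
  per <- c(count = 0, pla = 0, genotype = 0)
  wsum <- c(count = 0, pla = 0, genotype = 0)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fwd <- model_forward(model, val_X[, idx, drop = FALSE], cache = TRUE)
    bl <- batch_loss_and_grads(model, fwd, vg, idx, loss_cfg)
    live <- c(count = sum(vg$has_count[idx]), pla = sum(vg$has_pla[idx]),
              genotype = sum(vg$has_genotype[idx]))
    per <- per + bl$per_task * live
    wsum <- wsum + live
  }
  per <- ifelse(wsum > 0, per / wsum, 0)
  names(per) <- c("count", "pla", "genotype")
  list(total = sum(per[model$config$enabled_tasks]), per_task = per)
}

#' Cross-validated training and evaluation
#'
#' Builds plant-level, genotype-stratified folds, optionally reduces count
#' labels on each fold's training portion, trains one model per fold and
#' pools the held-out predictions so that every image appears in the test
#' set exactly once.
#'
#' @param dataset A fully annotated `rosette_dataset`.
#' @param k Number of folds.
#' @param model_cfg,loss_cfg,train_cfg Configuration objects; when
#'   `loss_cfg` has unit class weights and the genotype task is enabled,
#'   balanced class weights are computed from each fold's training labels.
#' @param reduction Optional [reduction_plan()] applied to each fold's
#'   training set.
#' @param n_val Validation plants held out per fold for early stopping.
#' @param seed Seed controlling splits, weight initialisation and
#'   training randomness.
#' @return List with `pooled` (an evaluation report over all pooled test
#'   predictions), `folds` (per-fold reports), `predictions` (pooled
#'   data frame with image ids, ground truth and predictions) and
#'   `splits`.
#' @export
cross_validate <- function(dataset, k = 4, model_cfg = model_config(),
                           loss_cfg = loss_config(),
                           train_cfg = train_config(),
                           reduction = NULL, seed = 1L, n_val = 1L) {
  pids <- vapply(dataset$images, `[[`, character(1), "plant_id")
  geno <- vapply(dataset$images, function(i) i$genotype_name %||%
                   as.character(i$genotype), character(1))
  gmap <- tapply(geno, pids, `[`, 1)
  splits <- make_cv_splits(unique(pids), k, genotypes = gmap, seed = seed,
                           n_val = n_val)

  fold_reports <- list()
  pred_rows <- list()
  for (f in seq_len(k)) {
    sp <- splits[[f]]
    train_ds <- subset_plants(dataset, sp$train_plant_ids)
    if (!is.null(reduction)) train_ds <- reduce_count_labels(train_ds, reduction)
    val_ds <- subset_plants(dataset, sp$val_plant_ids)
    test_ds <- subset_plants(dataset, sp$test_plant_ids)

    lcfg <- loss_cfg
    if ("genotype" %in% model_cfg$enabled_tasks &&
        all(lcfg$genotype_class_weights == 1)) {
      labs <- vapply(train_ds$images, function(i) as.numeric(i$genotype), 1)
      if (length(unique(stats::na.omit(labs))) == 2) {
        lcfg$genotype_class_weights <- unname(class_weights(labs))
      } else {
        warning("fold ", f, ": only one genotype class in the training ",
                "plants; using unit class weights")
      }
    }
    tcfg <- train_cfg
    tcfg$seed <- derive_seed(seed, 31, f)
    model <- with_rng(derive_seed(seed, 17, f), build_model(model_cfg))
    fit <- train_model(model, train_ds, val_ds, lcfg, tcfg)

    pred <- predict(fit$model, test_ds)
    tt <- dataset_targets(test_ds)
    df <- data.frame(image = test_ds$annotations$image,
                     plant_id = test_ds$annotations$plant_id,
                     fold = f,
                     gt_count = tt$count, gt_pla = tt$pla,
                     gt_genotype = tt$genotype)
    for (nm in names(pred)) df[[nm]] <- pred[[nm]]
    pred_rows[[f]] <- df
    fold_reports[[f]] <- evaluation_report(df,
                                           tasks = model_cfg$enabled_tasks)
  }
  pooled_df <- do.call(rbind, pred_rows)
  list(pooled = evaluation_report(pooled_df, tasks = model_cfg$enabled_tasks),
       folds = fold_reports, predictions = pooled_df, splits = splits)
}
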