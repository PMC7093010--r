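#' Load an image dataset from a directory and annotation CSV
#'
#' The CSV must have columns `image,plant_id,timepoint,leaf_count,pla,genotype`
#' (genotype 0 = wild-type, 1 = mutant). Empty annotation cells yield
#' records with the corresponding availability flag set to `FALSE`; missing
#' image files and PLA values outside `[0, 1]` are hard errors naming the
#' offending row.
#'
#' @param image_dir Directory holding the PNG images.
#' @param annotations Path to the annotation CSV.
#' @return A `rosette_dataset` (plant masks are `NULL` for loaded images
#'   unless a `masks/` subdirectory with matching filenames exists).
#' @export
load_dataset <- function(image_dir, annotations) {
  ann <- utils::read.csv(annotations, stringsAsFactors = FALSE)
  need <- c("image", "plant_id", "timepoint", "leaf_count", "pla", "genotype")
  if (!all(need %in% names(ann)))
    stop("annotation CSV must have columns: ", paste(need, collapse = ","))
  images <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    path <- file.path(image_dir, ann$image[i])
    if (!file.exists(path))
      stop(sprintf("row %d: image file '%s' not found", i, ann$image[i]))
    px <- png::readPNG(path)
    if (length(dim(px)) == 2L) px <- array(rep(px, 3), c(dim(px), 3))
    px <- array(as.integer(round(px[, , 1:3] * 255)),
                c(dim(px)[1], dim(px)[2], 3))
    mask_path <- file.path(image_dir, "masks", ann$image[i])
    mask <- if (file.exists(mask_path)) {
      m <- png::readPNG(mask_path)
      if (length(dim(m)) == 3L) m <- m[, , 1]
      matrix(as.integer(m > 0.5), nrow(m), ncol(m))
    } else NULL
    pla <- suppressWarnings(as.numeric(ann$pla[i]))
    has_pla <- !is.na(pla)
    if (has_pla && (pla < 0 || pla > 1))
      stop(sprintf("row %d: pla %.3f outside [0, 1]", i, pla))
    count <- suppressWarnings(as.integer(ann$leaf_count[i]))
    geno <- suppressWarnings(as.integer(ann$genotype[i]))
    images[[i]] <- list(pixels = px, plant_mask = mask,
                        plant_id = as.character(ann$plant_id[i]),
                        timepoint = as.integer(ann$timepoint[i]),
                        leaf_count = count, pla = pla, genotype = geno,
                        has_count = !is.na(count), has_pla = has_pla,
                        has_genotype = !is.na(geno))
  }
  structure(list(images = images, annotations = ann),
            class = "rosette_dataset")
}

#' Preprocess an image for the network
#'
#' Resizes any H x W x 3 image to the model's square input size (bilinear)
#' and scales intensities to `[0, 1]`.
#'
#' @param image H x W x 3 array, either integer 0-255 or double `[0, 1]`.
#' @param size Target side in pixels (default 320, the full-scale input;
#'   desk-scale runs use 96).
#' @return size x size x 3 double array in `[0, 1]`.
#' @export
preprocess <- function(image, size = 320) {
  if (length(dim(image)) != 3L || dim(image)[3] != 3L)
    stop("preprocess() expects an H x W x 3 RGB array")
  img <- if (is.integer(image) || max(image) > 1) image / 255 else image
  if (!all(dim(img)[1:2] == size)) {
    ebi <- EBImage::Image(aperm(img, c(2, 1, 3)), colormode = "Color")
    out <- EBImage::resize(ebi, w = size, h = size)
    img <- aperm(EBImage::imageData(out), c(2, 1, 3))
  }
  pmin(pmax(img, 0), 1)
}

# Resize a binary mask with nearest-neighbour sampling.
resize_mask <- function(mask, size) {
  if (all(dim(mask) == size)) return(mask)
  out <- EBImage::resize(EBImage::Image(mask), w = size, h = size,
                         filter = "none")
  matrix(as.integer(EBImage::imageData(out) > 0.5), size, size)
}

#' Randomly augment an image (and its mask)
#'
#' Samples one transform from the pool {rotation by U(0, 180) degrees,
#' axis shifts each U(0, 10%) of the image side, horizontal flip, vertical
#' flip} and applies it. Count and genotype annotations are unaffected by
#' construction; PLA is preserved up to the small fraction of plant pixels
#' a transform may push over the border. A specific transform can be
#' forced through `transform` for testing.
#'
#' @param image H x W x 3 double array in `[0, 1]` (a preprocessed image),
#'   or a list with `pixels` and `plant_mask` to transform jointly.
#' @param transform Optional list, e.g. `list(kind = "rotate", angle = 90)`,
#'   `list(kind = "shift", dx = 3, dy = -2)`, `list(kind = "hflip")`,
#'   `list(kind = "vflip")`. When `NULL` one transform is drawn from the
#'   current RNG stream.
#' @return Object of the same shape as the input.
#' @export
augment <- function(image, transform = NULL) {
  is_rec <- is.list(image) && !is.null(image$pixels)
  px <- if (is_rec) image$pixels else image
  if (is.integer(px) || max(px) > 1) px <- px / 255
  S <- dim(px)[1]
  if (is.null(transform)) {
    kind <- sample(c("rotate", "shift", "hflip", "vflip"), 1)
    transform <- switch(kind,
      rotate = list(kind = "rotate", angle = runif(1, 0, 180)),
      shift = list(kind = "shift",
                   dx = round(runif(1, -0.1, 0.1) * S),
                   dy = round(runif(1, -0.1, 0.1) * S)),
      hflip = list(kind = "hflip"),
      vflip = list(kind = "vflip"))
  }
  # flips and integer shifts are exact index operations; only rotation
  # needs resampling (EBImage, bilinear for pixels / nearest for masks)
  shift_2d <- function(m, dx, dy) {
    out <- m * 0
    nr <- nrow(m); nc <- ncol(m)
    sr <- seq_len(nr) - dy; sc <- seq_len(nc) - dx
    ok_r <- sr >= 1 & sr <= nr; ok_c <- sc >= 1 & sc <= nc
    out[which(ok_r), which(ok_c)] <- m[sr[ok_r], sc[ok_c]]
    out
  }
  apply_px <- function(a, filter) {
    is3 <- length(dim(a)) == 3L
    if (transform$kind == "hflip")
      return(if (is3) a[, dim(a)[2]:1, , drop = FALSE] else a[, ncol(a):1])
    if (transform$kind == "vflip")
      return(if (is3) a[dim(a)[1]:1, , , drop = FALSE] else a[nrow(a):1, ])
    if (transform$kind == "shift") {
      dx <- round(transform$dx); dy <- round(transform$dy)
      if (is3) {
        for (ch in 1:3) a[, , ch] <- shift_2d(a[, , ch], dx, dy)
        return(a)
      }
      return(shift_2d(a, dx, dy))
    }
    if (transform$kind != "rotate")
      stop("unknown transform kind: ", transform$kind)
    ebi <- if (is3) EBImage::Image(aperm(a, c(2, 1, 3)), colormode = "Color")
           else EBImage::Image(a)
    out <- EBImage::rotate(ebi, transform$angle, filter = filter,
                           output.dim = dim(ebi)[1:2], bg.col = 0)
    d <- EBImage::imageData(out)
    if (is3) aperm(d, c(2, 1, 3)) else d
  }
  new_px <- pmin(pmax(apply_px(px, "bilinear"), 0), 1)
  if (!is_rec) return(new_px)
  out <- image
  out$pixels <- new_px
  if (!is.null(image$plant_mask)) {
    m <- apply_px(matrix(as.numeric(image$plant_mask),
                         nrow(image$plant_mask)), "none")
    out$plant_mask <- matrix(as.integer(m > 0.5), nrow(m), ncol(m))
  }
  out
}

#' Plant-level cross-validation splits
#'
#' Partitions plants (never individual images) into `k` folds. Test folds
#' are genotype-stratified when every genotype has at least `k` plants;
#' otherwise a warning is issued and an unstratified partition is used.
#' One training plant per fold is held out for validation-loss early
#' stopping, which avoids time-series leakage between the train and
#' validation sets.
#'
#' @param plants Character vector of plant ids.
#' @param k Number of folds (>= 2).
#' @param genotypes Optional named vector mapping plant id to genotype
#'   label, enabling stratification.
#' @param seed Seed controlling the shuffling.
#' @param n_val Validation plants held out from each fold's training set.
#' @return List of `k` split plans, each with `fold_index`,
#'   `train_plant_ids`, `val_plant_ids`, `test_plant_ids`.
#' @export
make_cv_splits <- function(plants, k, genotypes = NULL, seed = 1L,
                           n_val = 1L) {
  stopifnot(k >= 2, length(plants) >= k)
  plants <- as.character(plants)
  with_rng(derive_seed(seed, 101), {
    fold_of <- integer(length(plants))
    names(fold_of) <- plants
    stratify <- !is.null(genotypes)
    if (stratify) {
      tab <- table(genotypes[plants])
      if (any(tab < k)) {
        warning("genotype stratification impossible (some genotype has ",
                "fewer than k plants); falling back to unstratified folds")
        stratify <- FALSE
      }
    }
    if (stratify) {
      for (g in unique(genotypes[plants])) {
        ids <- sample(plants[genotypes[plants] == g])
        fold_of[ids] <- (seq_along(ids) - 1L) %% k + 1L
      }
    } else {
      ids <- sample(plants)
      fold_of[ids] <- (seq_along(ids) - 1L) %% k + 1L
    }
    lapply(seq_len(k), function(f) {
      test <- plants[fold_of[plants] == f]
      rest <- plants[fold_of[plants] != f]
      val <- sample(rest, min(n_val, length(rest) - 1L))
      list(fold_index = f,
           train_plant_ids = setdiff(rest, val),
           val_plant_ids = val,
           test_plant_ids = test)
    })
  })
}

#' Plan for reducing leaf-count annotations
#'
#' @param strategy One of `"uniform"`, `"juvenile_first"`, `"mature_first"`,
#'   `"random"`.
#' @param keep_fraction One of 1.0, 0.75, 0.5, 0.25.
#' @param seed Seed, required only for the random strategy.
#' @return Object of class `reduction_plan`.
#' @export
reduction_plan <- function(strategy = c("uniform", "juvenile_first",
                                        "mature_first", "random"),
                           keep_fraction = 1.0, seed = 1L) {
  strategy <- match.arg(strategy)
  if (!keep_fraction %in% c(1.0, 0.75, 0.5, 0.25))
    stop("keep_fraction must be one of 1.0, 0.75, 0.5, 0.25")
  structure(list(strategy = strategy, keep_fraction = keep_fraction,
                 seed = seed), class = "reduction_plan")
}

#' Remove leaf-count labels according to a reduction plan
#'
#' Only count availability changes; PLA and genotype annotations are never
#' touched. Within each plant's time series ordered by timepoint:
#' `uniform` removes evenly spaced labels (for keep 0.75, every 4th label
#' starting with the first; for keep 0.5, every 2nd; for keep 0.25 only
#' every 4th label is retained); `juvenile_first` removes labels from the
#' earliest timepoints upward; `mature_first` from the latest downward;
#' `random` removes a seeded uniform sample per plant. When the kept count
#' is fractional the larger (more conservative) count is kept.
#'
#' @param dataset A `rosette_dataset`.
#' @param plan A [reduction_plan()].
#' @return The dataset with updated `has_count` flags.
#' @export
reduce_count_labels <- function(dataset, plan) {
  stopifnot(inherits(dataset, "rosette_dataset"),
            inherits(plan, "reduction_plan"))
  f <- plan$keep_fraction
  if (f == 1.0) return(dataset)
  pids <- vapply(dataset$images, `[[`, character(1), "plant_id")
  tps <- vapply(dataset$images, `[[`, integer(1), "timepoint")
  for (pid in unique(pids)) {
    idx <- which(pids == pid)
    idx <- idx[order(tps[idx])]
    T_len <- length(idx)
    n_keep <- ceiling(f * T_len)
    drop_pos <- switch(plan$strategy,
      uniform = {
        if (f >= 0.5) {
          m <- round(1 / (1 - f))              # drop every m-th, from the first
          seq(1L, T_len, by = m)
        } else {
          m <- round(1 / f)                     # keep only every m-th
          setdiff(seq_len(T_len), seq(m, T_len, by = m))
        }
      },
      juvenile_first = seq_len(T_len - n_keep),
      mature_first = if (n_keep < T_len) (n_keep + 1L):T_len else integer(0),
      random = with_rng(derive_seed(plan$seed, match(pid, unique(pids))),
                        sample(T_len, T_len - n_keep)))
    for (j in drop_pos) dataset$images[[idx[j]]]$has_count <- FALSE
  }
  dataset
}

#' Subset a dataset by plant ids
#'
#' @param dataset A `rosette_dataset`.
#' @param plant_ids Plants to keep.
#' @return A `rosette_dataset` restricted to those plants.
#' @export
subset_plants <- function(dataset, plant_ids) {
  pids <- vapply(dataset$images, `[[`, character(1), "plant_id")
  keep <- pids %in% plant_ids
  structure(list(images = dataset$images[keep],
                 annotations = dataset$annotations[keep, , drop = FALSE]),
            class = "rosette_dataset")
}
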