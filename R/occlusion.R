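#' Sliding black-window occlusion scan
#'
#' Slides a black (zero-intensity) square window across a preprocessed
#' image and records each enabled task's prediction at every window
#' position, producing one sensitivity grid per task. Grid positions run
#' over top-left corners `0, stride, 2*stride, ...` along each axis, so
#' the grid has `floor((S - window) / stride) + 1` cells per side. Window
#' and stride default to 60 and 20 pixels at a 320-pixel input and are
#' scaled proportionally for other input sizes.
#'
#' @param model A `phenomtl_model`.
#' @param image H x W x 3 image (preprocessed or raw; it is resized to the
#'   model input size).
#' @param window Window side in pixels; must be smaller than the input.
#' @param stride Step between window positions in pixels.
#' @param batch_size Occluded images per forward batch.
#' @return Object of class `occlusion_map`: list with `window`, `stride`,
#'   `grid_dim`, `baseline` (unoccluded prediction per task), `delta`
#'   (per-task grid of prediction minus baseline) and `prediction`
#'   (per-task grid of absolute predictions). For the genotype task the
#'   scanned quantity is the mutant-class probability.
#' @export
occlusion_scan <- function(model, image, window = NULL, stride = NULL,
                           batch_size = 64) {
  S <- model$config$input_size
  if (is.null(window)) window <- max(1L, round(60 * S / 320))
  if (is.null(stride)) stride <- max(1L, round(20 * S / 320))
  if (window >= S)
    stop("occlusion window (", window, ") must be smaller than the input size (",
         S, ")")
  img <- preprocess(if (is.list(image)) image$pixels else image, S)
  base_col <- image_to_column(img)
  g <- floor((S - window) / stride) + 1L
  offsets <- (seq_len(g) - 1L) * stride

  # linear indices (within one channel, transposed layout: x fastest) of a
  # window at top-left (row0, col0), precomputed per axis offset
  occlude_col <- function(row0, col0) {
    v <- base_col
    xs <- (col0 + 1):(col0 + window)          # image columns -> layout rows
    ys <- (row0 + 1):(row0 + window)
    idx <- as.vector(outer(xs, (ys - 1) * S, "+"))
    v[c(idx, idx + S * S, idx + 2 * S * S)] <- 0
    v
  }

  cols <- matrix(0, 3 * S * S, g * g)
  pos <- 1L
  for (gy in seq_len(g)) {
    for (gx in seq_len(g)) {
      cols[, pos] <- occlude_col(offsets[gy], offsets[gx])
      pos <- pos + 1L
    }
  }
  base_pred <- predict(model, matrix(base_col, ncol = 1))
  preds <- predict(model, cols, batch_size = batch_size)

  tasks <- intersect(model$config$enabled_tasks, c("count", "pla", "genotype"))
  getter <- c(count = "count", pla = "pla", genotype = "genotype_prob")
  baseline <- delta <- prediction <- list()
  for (task in tasks) {
    v <- preds[[getter[[task]]]]
    b <- base_pred[[getter[[task]]]]
    baseline[[task]] <- b
    prediction[[task]] <- matrix(v, g, g, byrow = TRUE)   # rows = y positions
    delta[[task]] <- prediction[[task]] - b
  }
  structure(list(window = window, stride = stride, grid_dim = c(g, g),
                 baseline = baseline, delta = delta, prediction = prediction),
            class = "occlusion_map")
}

#' Fraction of occlusion sensitivity attributable to the plant
#'
#' Scores how much of the total absolute prediction change across window
#' positions comes from windows overlapping the plant mask. A model that
#' reacts only when the plant itself is occluded scores 1; one equally
#' sensitive to background occlusion scores near the plant's share of
#' window positions.
#'
#' @param map An [occlusion_scan()] result.
#' @param plant_mask Binary plant mask (resized to the scan geometry as
#'   needed).
#' @param task Which task's delta grid to score (default `"count"`).
#' @param input_size Model input size the scan was run at; inferred from
#'   the map geometry when omitted.
#' @return Fraction in `[0, 1]`; `NA` (with a warning) when the scan
#'   produced no sensitivity at all.
#' @export
focus_score <- function(map, plant_mask, task = "count",
                        input_size = NULL) {
  stopifnot(inherits(map, "occlusion_map"))
  if (is.null(map$delta[[task]])) stop("task '", task, "' not in the map")
  if (sum(plant_mask) == 0) stop("empty plant mask: focus score undefined")
  g <- map$grid_dim[1]
  S <- if (!is.null(input_size)) input_size
       else (g - 1L) * map$stride + map$window
  mask <- resize_mask(plant_mask, S)
  offsets <- (seq_len(g) - 1L) * map$stride
  on_plant <- matrix(FALSE, g, g)
  for (gy in seq_len(g)) {
    for (gx in seq_len(g)) {
      rows <- (offsets[gy] + 1):(offsets[gy] + map$window)
      cls <- (offsets[gx] + 1):(offsets[gx] + map$window)
      on_plant[gy, gx] <- any(mask[rows, cls] > 0)
    }
  }
  dmag <- abs(map$delta[[task]])
  tot <- sum(dmag)
  if (tot == 0) {
    warning("zero total occlusion sensitivity; focus score undefined")
    return(NA_real_)
  }
  sum(dmag[on_plant]) / tot
}

#' Export an occlusion map as CSV grids and a PNG overlay
#'
#' @param map An [occlusion_scan()] result.
#' @param dir Output directory.
#' @param image Optional source image for the overlay.
#' @return Invisibly, the directory.
#' @export
export_occlusion_map <- function(map, dir, image = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (task in names(map$delta)) {
    utils::write.csv(map$delta[[task]],
                     file.path(dir, paste0("delta_", task, ".csv")),
                     row.names = FALSE)
    utils::write.csv(map$prediction[[task]],
                     file.path(dir, paste0("prediction_", task, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(image)) {
    px <- if (is.list(image)) image$pixels else image
    if (is.integer(px) || max(px) > 1) px <- px / 255
    S <- dim(px)[1]
    d <- abs(map$delta[[names(map$delta)[1]]])
    heat <- d / max(d, 1e-12)
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(heat),
                                             w = S, h = S))
    over <- px
    over[, , 1] <- pmin(1, px[, , 1] * 0.5 + t(up) * 0.8)
    png::writePNG(over, file.path(dir, "overlay.png"))
  }
  invisible(dir)
}
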