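#' Genotype appearance and growth parameters for synthetic rosettes
#'
#' Describes how one accession looks and grows in the synthetic renderer:
#' leaf shape (aspect ratio of the leaf ellipse), hue range, growth rate in
#' leaves per timepoint, overall leaf size and how tightly leaves pack
#' around the rosette centre.
#'
#' @param name Short accession label.
#' @param class Either `"wild-type"` or `"mutant"`; determines the binary
#'   classification target.
#' @param leaf_aspect_ratio Major/minor axis ratio of the leaf ellipse
#'   (> 0; elongated mutants use larger values).
#' @param hue_range Ordered pair of hue angles in degrees, each in
#'   `[0, 360)`, from which leaf hues are drawn.
#' @param growth_rate Leaves gained per timepoint (> 0).
#' @param leaf_size_scale Unitless leaf size multiplier (> 0).
#' @param compactness Radial spread control in `(0, 1]`; smaller values
#'   place leaves closer to the centre.
#' @return An object of class `genotype_params`.
#' @export
genotype_params <- function(name,
                            class = c("wild-type", "mutant"),
                            leaf_aspect_ratio = 1.6,
                            hue_range = c(115, 135),
                            growth_rate = 0.45,
                            leaf_size_scale = 1.0,
                            compactness = 0.85) {
  class <- match.arg(class)
  stopifnot(is.character(name), length(name) == 1L,
            leaf_aspect_ratio > 0, growth_rate > 0, leaf_size_scale > 0,
            compactness > 0, compactness <= 1,
            length(hue_range) == 2L, all(hue_range >= 0),
            all(hue_range < 360), hue_range[1] <= hue_range[2])
  structure(list(name = name, class = class,
                 leaf_aspect_ratio = leaf_aspect_ratio,
                 hue_range = hue_range,
                 growth_rate = growth_rate,
                 leaf_size_scale = leaf_size_scale,
                 compactness = compactness),
            class = "genotype_params")
}

#' Built-in genotype presets
#'
#' Three accessions: a round, dark-green wild type; an elongated,
#' yellow-green mutant with slower leaf initiation; and a second mutant
#' whose shape and hue sit close to the wild type, mimicking accessions
#' that are hard to tell apart visually.
#'
#' @return Named list of [genotype_params()] objects.
#' @export
genotype_presets <- function() {
  list(
    wildtype = genotype_params("wildtype", "wild-type",
                               leaf_aspect_ratio = 1.6, hue_range = c(115, 135),
                               growth_rate = 0.45, leaf_size_scale = 1.0,
                               compactness = 0.85),
    elongata = genotype_params("elongata", "mutant",
                               leaf_aspect_ratio = 2.8, hue_range = c(70, 95),
                               growth_rate = 0.35, leaf_size_scale = 1.15,
                               compactness = 0.70),
    subtilis = genotype_params("subtilis", "mutant",
                               leaf_aspect_ratio = 1.9, hue_range = c(103, 124),
                               growth_rate = 0.42, leaf_size_scale = 0.95,
                               compactness = 0.85)
  )
}

#' Render one synthetic rosette image
#'
#' Places `leaf_count` filled ellipses on a phyllotactic spiral (successive
#' angular offsets of 137.5 degrees plus uniform jitter of up to 10
#' degrees), with leaf length growing as the square root of the leaf index
#' scaled by the genotype's size parameter. The background is low-frequency
#' brown/grey noise with a darker pot disc; leaf hue, saturation and value
#' are drawn from genotype-dependent ranges. Fully deterministic for a
#' fixed seed.
#'
#' @param genotype A [genotype_params()] object.
#' @param leaf_count Number of leaves to draw (>= 0; 0 yields an empty
#'   plant mask).
#' @param canvas_size Side of the square canvas in pixels (>= 64).
#' @param rng_seed Integer seed controlling all randomness in the render.
#' @return List with `pixels` (canvas x canvas x 3 integer array, values
#'   0-255) and `plant_mask` (canvas x canvas integer 0/1 matrix, the union
#'   of the drawn leaf ellipses).
#' @export
render_rosette <- function(genotype, leaf_count, canvas_size = 96,
                           rng_seed = 1L) {
  stopifnot(inherits(genotype, "genotype_params"),
            leaf_count >= 0, canvas_size >= 64)
  S <- as.integer(canvas_size)
  with_rng(rng_seed, {
    px <- render_background(S)
    mask <- matrix(0L, S, S)
    ctr <- (S + 1) / 2
    if (leaf_count > 0) {
      for (i in seq_len(leaf_count)) {
        ang <- (i - 1) * 137.5 + runif(1, -10, 10)
        th <- ang * pi / 180
        len <- min(0.055 * S * sqrt(i) * genotype$leaf_size_scale, 0.46 * S)
        a <- len / 2
        b <- max(len / (2 * genotype$leaf_aspect_ratio), 1)
        rad <- genotype$compactness * 0.55 * len
        cy <- ctr + rad * sin(th)
        cx <- ctr + rad * cos(th)
        hue <- runif(1, genotype$hue_range[1], genotype$hue_range[2])
        col <- grDevices::col2rgb(
          grDevices::hsv(hue / 360, runif(1, 0.55, 0.80),
                         runif(1, 0.38, 0.62)))[, 1] / 255
        ext <- ceiling(a) + 1
        ys <- max(1, floor(cy - ext)):min(S, ceiling(cy + ext))
        xs <- max(1, floor(cx - ext)):min(S, ceiling(cx + ext))
        yy <- matrix(ys, length(ys), length(xs)) - cy
        xx <- matrix(xs, length(ys), length(xs), byrow = TRUE) - cx
        u <- xx * cos(th) + yy * sin(th)
        v <- -xx * sin(th) + yy * cos(th)
        inside <- (u / a)^2 + (v / b)^2 <= 1
        if (!any(inside)) next
        hit <- which(inside, arr.ind = TRUE)
        lin <- cbind(ys[hit[, 1]], xs[hit[, 2]])
        mask[lin] <- 1L
        shade <- 1 - 0.25 * (v[inside] / b)^2  # darker towards the midrib edge
        for (ch in 1:3) {
          m <- px[, , ch]
          m[lin] <- col[ch] * shade
          px[, , ch] <- m
        }
      }
    }
    px <- pmin(pmax(px, 0), 1)
    list(pixels = array(as.integer(round(px * 255)), dim = c(S, S, 3)),
         plant_mask = mask)
  })
}

# Low-frequency brown/grey soil noise plus a darker pot disc; consumes a
# fixed number of RNG draws so leaf placement is reproducible per seed.
render_background <- function(S) {
  base <- c(0.38, 0.31, 0.24)
  coarse <- 8L
  px <- array(0, c(S, S, 3))
  for (ch in 1:3) {
    g <- matrix(rnorm(coarse^2, base[ch], 0.06), coarse, coarse)
    up <- EBImage::imageData(EBImage::resize(EBImage::Image(g), w = S, h = S))
    px[, , ch] <- up
  }
  px <- px + array(rnorm(S * S * 3, 0, 0.02), c(S, S, 3))
  ctr <- (S + 1) / 2
  d2 <- outer((seq_len(S) - ctr)^2, (seq_len(S) - ctr)^2, "+")
  pot <- d2 <= (0.46 * S)^2
  for (ch in 1:3) {
    m <- px[, , ch]
    m[pot] <- m[pot] * 0.72 + 0.04
    px[, , ch] <- m
  }
  px
}

#' Projected leaf area of a plant mask
#'
#' PLA is the fraction of image pixels covered by the plant: the count of
#' set mask pixels divided by the total pixel count, in `[0, 1]`.
#'
#' @param plant_mask Binary matrix (0/1 or logical).
#' @return Plant-pixel fraction.
#' @export
compute_pla <- function(plant_mask) {
  stopifnot(is.matrix(plant_mask) || is.logical(plant_mask))
  m <- as.numeric(plant_mask)
  stopifnot(all(m %in% c(0, 1)))
  sum(m) / length(m)
}

#' Generate a complete synthetic rosette dataset
#'
#' Builds a growth time series for each plant: the leaf count at timepoint
#' `t` (1-based) is `2 + floor(growth_rate * (t - 1))`, so every plant
#' starts with two leaves and counts are non-decreasing. Each image is
#' rendered with [render_rosette()] under a seed derived from the master
#' seed, so regeneration with the same arguments is byte-identical. All
#' three annotations (count, PLA, genotype) are present for every image;
#' PLA is recomputed from the rendered mask.
#'
#' @param n_plants Number of plants (>= 2).
#' @param n_timepoints Images per plant (>= 1).
#' @param genotype_pool List of [genotype_params()] containing at least one
#'   wild-type and one mutant entry. Defaults to the wild type and the
#'   elongated mutant from [genotype_presets()].
#' @param mutant_fraction Fraction of plants assigned a mutant genotype,
#'   strictly inside `(0, 1)`; realised counts match within one plant.
#' @param canvas_size Image side in pixels.
#' @param seed Master seed.
#' @return Object of class `rosette_dataset`: a list with `images` (list of
#'   annotated image records: `pixels`, `plant_mask`, `plant_id`,
#'   `timepoint`, `leaf_count`, `pla`, `genotype`, and `has_count` /
#'   `has_pla` / `has_genotype` availability flags) and `annotations`
#'   (data frame with columns image, plant_id, timepoint, leaf_count, pla,
#'   genotype).
#' @export
generate_dataset <- function(n_plants = 24, n_timepoints = 20,
                             genotype_pool = genotype_presets()[c("wildtype", "elongata")],
                             mutant_fraction = 0.5,
                             canvas_size = 96, seed = 1L) {
  stopifnot(n_plants >= 2, n_timepoints >= 1)
  if (!(mutant_fraction > 0 && mutant_fraction < 1))
    stop("mutant_fraction must be strictly inside (0, 1)")
  classes <- vapply(genotype_pool, function(g) g$class, character(1))
  if (!any(classes == "wild-type") || !any(classes == "mutant"))
    stop("genotype_pool needs at least one wild-type and one mutant entry")

  n_mut <- round(mutant_fraction * n_plants)
  n_mut <- min(max(n_mut, 1L), n_plants - 1L)
  assignment <- with_rng(derive_seed(seed, 0),
                         sample(c(rep(1L, n_mut), rep(0L, n_plants - n_mut))))
  wt_pool <- genotype_pool[classes == "wild-type"]
  mut_pool <- genotype_pool[classes == "mutant"]
  wi <- mi <- 0L

  images <- vector("list", n_plants * n_timepoints)
  rows <- vector("list", n_plants * n_timepoints)
  k <- 0L
  for (p in seq_len(n_plants)) {
    is_mut <- assignment[p] == 1L
    if (is_mut) {
      mi <- mi + 1L
      g <- mut_pool[[(mi - 1L) %% length(mut_pool) + 1L]]
    } else {
      wi <- wi + 1L
      g <- wt_pool[[(wi - 1L) %% length(wt_pool) + 1L]]
    }
    pid <- sprintf("plant_%02d", p)
    for (t in seq_len(n_timepoints)) {
      count <- 2L + as.integer(floor(g$growth_rate * (t - 1)))
      r <- render_rosette(g, count, canvas_size,
                          rng_seed = derive_seed(seed, p, t))
      pla <- compute_pla(r$plant_mask)
      k <- k + 1L
      images[[k]] <- list(pixels = r$pixels, plant_mask = r$plant_mask,
                          plant_id = pid, timepoint = t,
                          leaf_count = count, pla = pla,
                          genotype = assignment[p],
                          genotype_name = g$name,
                          has_count = TRUE, has_pla = TRUE,
                          has_genotype = TRUE)
      rows[[k]] <- data.frame(image = sprintf("%s_t%02d.png", pid, t),
                              plant_id = pid, timepoint = t,
                              leaf_count = count, pla = pla,
                              genotype = assignment[p],
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(images = images, annotations = do.call(rbind, rows)),
            class = "rosette_dataset")
}

#' @export
print.rosette_dataset <- function(x, ...) {
  ann <- x$annotations
  cat(sprintf("rosette_dataset: %d images, %d plants, %d timepoints\n",
              nrow(ann), length(unique(ann$plant_id)),
              max(ann$timepoint)))
  cat(sprintf("  labels present: count %d, pla %d, genotype %d\n",
              sum(vapply(x$images, `[[`, TRUE, "has_count")),
              sum(vapply(x$images, `[[`, TRUE, "has_pla")),
              sum(vapply(x$images, `[[`, TRUE, "has_genotype"))))
  invisible(x)
}

#' Write a dataset to disk as PNG images and an annotation CSV
#'
#' Writes one 8-bit RGB PNG per image plus `annotations.csv` with columns
#' `image,plant_id,timepoint,leaf_count,pla,genotype` (genotype coded
#' 0 = wild-type, 1 = mutant). Plant masks are optionally written as
#' single-channel PNGs under `masks/`.
#'
#' @param dataset A `rosette_dataset`.
#' @param dir Output directory (created if missing).
#' @param masks Write plant masks too?
#' @return The annotation CSV path, invisibly.
#' @export
write_dataset <- function(dataset, dir, masks = FALSE) {
  stopifnot(inherits(dataset, "rosette_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (masks) dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  ann <- dataset$annotations
  for (i in seq_along(dataset$images)) {
    im <- dataset$images[[i]]
    png::writePNG(im$pixels / 255, file.path(dir, ann$image[i]))
    if (masks && !is.null(im$plant_mask))
      png::writePNG(im$plant_mask + 0, file.path(dir, "masks", ann$image[i]))
  }
  path <- file.path(dir, "annotations.csv")
  utils::write.csv(ann, path, row.names = FALSE)
  invisible(path)
}
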