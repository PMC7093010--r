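#' Multitask model configuration
#'
#' Declarative description of the architecture: a convolutional backbone
#' whose classification head is replaced by a shared fully connected
#' representation (default 1536 nodes) from which the task branches split
#' off. Branch hidden layers use ReLU; the final activations are ReLU for
#' the count (counts are non-negative), LeakyReLU for PLA and a softmax
#' over two nodes for the genotype. An L2 activity penalty (default 0.04)
#' is applied to the output of the layer immediately before each final
#' prediction layer, discouraging large pre-output activations without
#' shrinking the branch weights themselves. All layers up to and including
#' the shared representation are hard-shared between tasks.
#'
#' @param backbone `"small_cnn"`, a four-block strided convolutional
#'   feature extractor (16/32/64/128 filters, 3x3 kernels, stride 2)
#'   designed to train on a CPU in minutes. The `"resnet50_scratch"` and
#'   `"resnet50_pretrained"` names are recognised but not runnable in this
#'   implementation (see Details).
#' @param input_size Square input side in pixels; must be divisible by 16
#'   for the small backbone. 320 matches full-scale preprocessing; 96 is
#'   the desk-scale setting.
#' @param shared_dim Width of the shared representation (default 1536).
#' @param count_branch,pla_branch Layer widths of the regression branches
#'   (defaults `c(512, 1)`).
#' @param genotype_branch Layer widths of the classification branch
#'   (default `c(512, 256, 2)`).
#' @param l2_penalty Activity-L2 coefficient on the pre-output layers
#'   (default 0.04): the training loss adds `l2_penalty` times the batch
#'   mean of the summed squared activations of each branch's pre-output
#'   layer.
#' @param enabled_tasks Non-empty subset of `c("count", "pla", "genotype")`;
#'   a single-task count model (`enabled_tasks = "count"`) keeps a count
#'   branch architecturally identical to the multitask one.
#' @param genotype_head `"softmax"` (default; two-class cross-entropy) or
#'   `"sigmoid"` (independent per-node sigmoids with binary cross-entropy,
#'   normalised at prediction time). The two are equivalent
#'   parameterisations of a binary classifier.
#' @param leaky_slope Negative-side slope of the PLA output LeakyReLU.
#' @param input_center Constant subtracted from the `[0, 1]` intensities at
#'   the network entry (default 0.5), centring the inputs; occlusion
#'   windows are black (0) on the `[0, 1]` scale, i.e. before this
#'   normalisation.
#'
#' @details A ResNet50 backbone (optionally ImageNet-pretrained) is the
#'   full-scale configuration of this architecture; running it requires a
#'   GPU deep-learning runtime and is outside what this package executes,
#'   so `build_model()` rejects those backbone names with an informative
#'   error. The small backbone preserves the multitask structure —
#'   shared features, shared dense representation, identical branches —
#'   at CPU scale.
#' @return Object of class `model_config`.
#' @export
model_config <- function(backbone = "small_cnn",
                         input_size = 96,
                         shared_dim = 1536,
                         count_branch = c(512, 1),
                         pla_branch = c(512, 1),
                         genotype_branch = c(512, 256, 2),
                         l2_penalty = 0.04,
                         enabled_tasks = c("count", "pla", "genotype"),
                         genotype_head = c("softmax", "sigmoid"),
                         leaky_slope = 0.01,
                         input_center = 0.5) {
  genotype_head <- match.arg(genotype_head)
  enabled_tasks <- match.arg(enabled_tasks,
                             c("count", "pla", "genotype"), several.ok = TRUE)
  stopifnot(shared_dim > 0, length(enabled_tasks) >= 1,
            utils::tail(count_branch, 1) == 1,
            utils::tail(pla_branch, 1) == 1,
            utils::tail(genotype_branch, 1) == 2)
  structure(list(backbone = backbone, input_size = as.integer(input_size),
                 conv_filters = c(16L, 32L, 64L, 128L),
                 shared_dim = as.integer(shared_dim),
                 branches = list(count = count_branch, pla = pla_branch,
                                 genotype = genotype_branch),
                 l2_penalty = l2_penalty,
                 enabled_tasks = enabled_tasks,
                 genotype_head = genotype_head,
                 leaky_slope = leaky_slope,
                 input_center = input_center),
            class = "model_config")
}

#' Build a multitask phenotyping model
#'
#' Initialises all parameters (He-normal weights, zero biases; the count
#' output bias starts at 1 so its ReLU output unit is active at
#' initialisation). Weights are drawn from the current RNG stream, so
#' seed the RNG for reproducible initialisation.
#'
#' @param config A [model_config()].
#' @return Object of class `phenomtl_model` with elements `config` and
#'   `params` (a flat named list of weight matrices and bias vectors;
#'   every branch reads the same shared parameter objects — hard
#'   parameter sharing).
#' @export
build_model <- function(config = model_config()) {
  stopifnot(inherits(config, "model_config"))
  if (config$backbone != "small_cnn")
    stop("backbone '", config$backbone, "' is not runnable here; ",
         "available backbones: small_cnn")
  if (config$input_size %% 16 != 0 || config$input_size < 16)
    stop("input_size must be a positive multiple of 16")
  p <- list()
  dense <- function(n_out, n_in, bias = 0) {
    list(W = matrix(rnorm(n_out * n_in, 0, sqrt(2 / n_in)), n_out, n_in),
         b = rep(bias, n_out))
  }
  in_ch <- 3L
  for (l in seq_along(config$conv_filters)) {
    f <- config$conv_filters[l]
    d <- dense(f, in_ch * 9L)
    p[[paste0("conv", l, ".W")]] <- d$W
    p[[paste0("conv", l, ".b")]] <- d$b
    in_ch <- f
  }
  d <- dense(config$shared_dim, in_ch)
  p[["shared.W"]] <- d$W
  p[["shared.b"]] <- d$b
  for (task in config$enabled_tasks) {
    widths <- config$branches[[task]]
    n_in <- config$shared_dim
    for (j in seq_along(widths)) {
      bias <- if (task == "count" && j == length(widths)) 1 else 0
      d <- dense(widths[j], n_in, bias)
      p[[paste0(task, j, ".W")]] <- d$W
      p[[paste0(task, j, ".b")]] <- d$b
      n_in <- widths[j]
    }
  }
  structure(list(config = config, params = p), class = "phenomtl_model")
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

leaky_relu <- function(x, slope) ifelse(x > 0, x, slope * x)

softmax_cols <- function(z) {
  z <- sweep(z, 2, apply(z, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# Flatten an H x W x 3 image (double [0,1] or integer 0-255) to the
# channel-major column layout the conv kernels expect.
image_to_column <- function(image) {
  if (is.integer(image) || max(image) > 1) image <- image / 255
  as.vector(aperm(image, c(2, 1, 3)))
}

# Full forward pass on a (3*S*S) x N batch matrix. With cache = TRUE the
# intermediate activations needed by the backward pass are returned.
model_forward <- function(model, X, cache = FALSE) {
  cfg <- model$config
  p <- model$params
  S <- cfg$input_size
  H <- W <- S
  C <- 3L
  if (!is.null(cfg$input_center) && cfg$input_center != 0)
    X <- X - cfg$input_center
  A <- X
  conv_stack <- NULL
  if (cache) {
    # training path: fused single-precision conv stack with a C++-side cache
    L <- length(cfg$conv_filters)
    r <- conv_stack_forward_cpp(X,
                                lapply(seq_len(L),
                                       function(l) p[[paste0("conv", l, ".W")]]),
                                lapply(seq_len(L),
                                       function(l) p[[paste0("conv", l, ".b")]]),
                                S)
    A <- r$out
    conv_stack <- r$cache
    H <- W <- S %/% 2L^L
    C <- cfg$conv_filters[L]
  } else {
    for (l in seq_along(cfg$conv_filters)) {
      A <- conv2d_forward_cpp(A, p[[paste0("conv", l, ".W")]],
                              p[[paste0("conv", l, ".b")]],
                              C, H, W, 3L, 2L, 1L, TRUE)
      H <- H %/% 2L
      W <- W %/% 2L
      C <- cfg$conv_filters[l]
    }
  }
  P <- H * W
  N <- ncol(A)
  gap <- colMeans(array(A, c(P, C, N)), dims = 1)      # C x N
  if (N == 1L) gap <- matrix(gap, C, 1)
  Zs <- p[["shared.W"]] %*% gap + p[["shared.b"]]
  Hs <- relu(Zs)
  out <- list()
  br <- list()
  for (task in cfg$enabled_tasks) {
    widths <- cfg$branches[[task]]
    hs <- list(Hs)
    zs <- list()
    h <- Hs
    for (j in seq_along(widths)) {
      z <- p[[paste0(task, j, ".W")]] %*% h + p[[paste0(task, j, ".b")]]
      zs[[j]] <- z
      if (j < length(widths)) {
        h <- relu(z)
        hs[[j + 1]] <- h
      }
    }
    zf <- zs[[length(widths)]]
    out[[task]] <- switch(task,
      count = relu(zf),
      pla = leaky_relu(zf, cfg$leaky_slope),
      genotype = if (cfg$genotype_head == "softmax") softmax_cols(zf)
                 else 1 / (1 + exp(-zf)))
    if (cache) br[[task]] <- list(hs = hs, zs = zs)
  }
  res <- list(tasks = out)
  if (cache)
    res$cache <- list(conv_stack = conv_stack, gap = gap,
                      Zs = Zs, Hs = Hs, branches = br,
                      last_dims = c(P = P, C = C))
  res
}

# Backward pass. dz_final: named list of gradients w.r.t. each enabled
# task's final pre-activation (already combining loss, mask and output
# activation derivatives). Returns a flat named gradient list aligned
# with model$params; includes the L2 term on the pre-output layers.
model_backward <- function(model, cache, dz_final) {
  cfg <- model$config
  p <- model$params
  g <- list()
  dHs <- matrix(0, nrow(cache$Hs), ncol(cache$Hs))
  for (task in cfg$enabled_tasks) {
    widths <- cfg$branches[[task]]
    bc <- cache$branches[[task]]
    dz <- dz_final[[task]]
    for (j in rev(seq_along(widths))) {
      g[[paste0(task, j, ".W")]] <- tcrossprod(dz, bc$hs[[j]])
      g[[paste0(task, j, ".b")]] <- rowSums(dz)
      dh <- crossprod(p[[paste0(task, j, ".W")]], dz)
      # activity penalty on the layer feeding the final prediction layer
      if (j == length(widths) && cfg$l2_penalty > 0 && length(widths) >= 2)
        dh <- dh + 2 * cfg$l2_penalty * bc$hs[[j]] / ncol(dh)
      if (j > 1) dz <- dh * (bc$zs[[j - 1]] > 0)
      else dHs <- dHs + dh
    }
  }
  dZs <- dHs * (cache$Zs > 0)
  g[["shared.W"]] <- tcrossprod(dZs, cache$gap)
  g[["shared.b"]] <- rowSums(dZs)
  dgap <- crossprod(p[["shared.W"]], dZs)      # C x N
  P <- cache$last_dims[["P"]]
  C <- cache$last_dims[["C"]]
  dA <- dgap[rep(seq_len(C), each = P), , drop = FALSE] / P
  L <- length(cfg$conv_filters)
  res <- conv_stack_backward_cpp(cache$conv_stack,
                                 lapply(seq_len(L),
                                        function(l) p[[paste0("conv", l, ".W")]]),
                                 dA)
  for (l in seq_len(L)) {
    g[[paste0("conv", l, ".W")]] <- res$dW[[l]]
    g[[paste0("conv", l, ".b")]] <- as.numeric(res$db[[l]])
  }
  g
}

# Value of the activity penalty terms on the pre-output layers: for each
# branch, the batch mean of the summed squared activations of the layer
# feeding the final prediction layer, scaled by the penalty coefficient.
activity_penalty_value <- function(model, cache) {
  cfg <- model$config
  if (cfg$l2_penalty <= 0) return(0)
  tot <- 0
  for (task in cfg$enabled_tasks) {
    widths <- cfg$branches[[task]]
    if (length(widths) >= 2) {
      h <- cache$branches[[task]]$hs[[length(widths)]]
      tot <- tot + cfg$l2_penalty * mean(colSums(h^2))
    }
  }
  tot
}

#' Predict phenotyping traits for images
#'
#' Runs the network in inference mode (deterministic). The PLA output is
#' clamped to `[0, 1]`; `genotype_prob` is the probability of the mutant
#' class (the two class probabilities sum to one under the softmax head).
#'
#' @param object A `phenomtl_model`.
#' @param newdata A `rosette_dataset`, a list of image records/arrays, a
#'   single H x W x 3 array, or a precomputed `(3*S*S) x N` batch matrix.
#' @param batch_size Images per forward batch.
#' @param ... Unused.
#' @return Data frame with one row per image and columns among `count`,
#'   `pla`, `genotype_prob`, `genotype_prob_wild`.
#' @export
predict.phenomtl_model <- function(object, newdata, batch_size = 64, ...) {
  X <- as_batch_matrix(newdata, object$config$input_size)
  n <- ncol(X)
  cfg <- object$config
  acc <- list(count = numeric(0), pla = numeric(0),
              genotype = matrix(0, 2, 0))
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    out <- model_forward(object, X[, idx, drop = FALSE])$tasks
    if ("count" %in% cfg$enabled_tasks)
      acc$count <- c(acc$count, as.numeric(out$count))
    if ("pla" %in% cfg$enabled_tasks)
      acc$pla <- c(acc$pla, as.numeric(out$pla))
    if ("genotype" %in% cfg$enabled_tasks)
      acc$genotype <- cbind(acc$genotype, out$genotype)
  }
  res <- data.frame(row.names = seq_len(n))
  if ("count" %in% cfg$enabled_tasks) res$count <- acc$count
  if ("pla" %in% cfg$enabled_tasks) res$pla <- pmin(pmax(acc$pla, 0), 1)
  if ("genotype" %in% cfg$enabled_tasks) {
    pr <- acc$genotype
    if (cfg$genotype_head == "sigmoid")
      pr <- sweep(pr, 2, colSums(pr), "/")
    res$genotype_prob <- pr[2, ]
    res$genotype_prob_wild <- pr[1, ]
  }
  res
}

# Coerce the accepted input shapes to a (3*S*S) x N batch matrix.
as_batch_matrix <- function(newdata, size) {
  if (is.matrix(newdata)) {
    if (nrow(newdata) != 3 * size * size)
      stop("batch matrix has ", nrow(newdata), " rows; the model expects ",
           3 * size * size, " (input size ", size, ")")
    return(newdata)
  }
  imgs <- if (inherits(newdata, "rosette_dataset")) newdata$images
          else if (is.list(newdata) && !is.null(newdata$pixels)) list(newdata)
          else if (is.array(newdata) && length(dim(newdata)) == 3L) list(newdata)
          else newdata
  cols <- vapply(imgs, function(im) {
    px <- if (is.list(im)) im$pixels else im
    image_to_column(preprocess(px, size))
  }, numeric(3 * size * size))
  matrix(cols, nrow = 3 * size * size)
}

#' @export
print.phenomtl_model <- function(x, ...) {
  cfg <- x$config
  n_par <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("phenomtl_model: %s backbone, input %dx%d, shared dim %d\n",
              cfg$backbone, cfg$input_size, cfg$input_size, cfg$shared_dim))
  cat(sprintf("  tasks: %s | parameters: %s\n",
              paste(cfg$enabled_tasks, collapse = ", "),
              format(n_par, big.mark = ",")))
  invisible(x)
}

#' Save / load a model
#'
#' Parameters are written as a flat JSON archive with a config sidecar, a
#' text-only serialization that round-trips exactly at double precision.
#'
#' @param model A `phenomtl_model`.
#' @param path Output file path.
#' @return `save_model` the path, invisibly; `load_model` the model.
#' @export
save_model <- function(model, path) {
  obj <- list(config = unclass(model$config),
              params = lapply(model$params, function(m) {
                if (is.matrix(m)) list(dim = dim(m), data = as.numeric(m))
                else list(dim = NULL, data = as.numeric(m))
              }))
  writeLines(jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(readLines(path), simplifyVector = TRUE)
  cfg <- obj$config
  cfg$conv_filters <- as.integer(cfg$conv_filters)
  cfg$branches <- lapply(cfg$branches, as.numeric)
  class(cfg) <- "model_config"
  params <- lapply(obj$params, function(e) {
    d <- unlist(e$dim)
    if (length(d) == 2) matrix(as.numeric(e$data), d[1], d[2])
    else as.numeric(e$data)
  })
  structure(list(config = cfg, params = params), class = "phenomtl_model")
}
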