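# Brute-force reference implementations of the evaluation metrics, written
# as plain loops so they are independent of the package's vectorised code.

oracle_count <- function(pred, gt) {
  r <- numeric(length(pred))
  for (i in seq_along(pred))
    r[i] <- if (pred[i] >= 0) floor(pred[i] + 0.5) else -floor(-pred[i] + 0.5)
  d <- r - gt
  n <- length(d)
  psd <- function(x) sqrt(sum((x - sum(x) / n)^2) / n)
  list(dic_mean = sum(d) / n, dic_std = psd(d),
       abs_dic_mean = sum(abs(d)) / n, abs_dic_std = psd(abs(d)),
       agreement = 100 * sum(d == 0) / n,
       mse = sum(d^2) / n,
       r_squared = 1 - sum(d^2) / sum((gt - sum(gt) / n)^2))
}

oracle_within_one <- function(pred, gt) {
  r <- ifelse(pred >= 0, floor(pred + 0.5), -floor(-pred + 0.5))
  100 * sum(abs(r - gt) <= 1) / length(gt)
}

oracle_genotype <- function(prob, labels) {
  correct <- 0
  conf <- matrix(0, 2, 2)
  for (i in seq_along(prob)) {
    call <- if (prob[i] >= 0.5) 1 else 0
    if (call == labels[i]) correct <- correct + 1
    conf[labels[i] + 1, call + 1] <- conf[labels[i] + 1, call + 1] + 1
  }
  list(accuracy = 100 * correct / length(prob), confusion = conf)
}

oracle_boot_p <- function(a, b, n_boot, seed) {
  d <- a - b
  if (all(d == 0)) return(1)
  n <- length(d)
  t_obs <- mean(d) / (sd(d) / sqrt(n))
  d0 <- d - mean(d)
  set.seed(seed)
  hits <- 0
  for (i in seq_len(n_boot)) {
    x <- sample(d0, n, replace = TRUE)
    s <- sd(x)
    t <- if (s > 0) mean(x) / (s / sqrt(n)) else if (mean(x) == 0) 0 else Inf
    if (abs(t) >= abs(t_obs)) hits <- hits + 1
  }
  hits / n_boot
}
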