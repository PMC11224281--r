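# Independent oracles used across the test files. Each is written directly
# from the defining formula, separate from the package implementation.

# One-line benchmark formula oracles (hand-coded from the definitions).
benchmark_oracles <- list(
  sphere = function(x) sum(x * x),
  schwefel222 = function(x) sum(abs(x)) + prod(abs(x)),
  schwefel12 = function(x) {
    tot <- 0
    for (i in seq_along(x)) tot <- tot + sum(x[1:i])^2
    tot
  },
  schwefel221 = function(x) max(abs(x)),
  rosenbrock = function(x) {
    tot <- 0
    for (i in seq_len(length(x) - 1)) {
      tot <- tot + 100 * (x[i + 1] - x[i]^2)^2 + (x[i] - 1)^2
    }
    tot
  },
  ackley = function(x) {
    n <- length(x)
    -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
      20 + exp(1)
  },
  griewank = function(x) {
    p <- 1
    for (i in seq_along(x)) p <- p * cos(x[i] / sqrt(i))
    sum(x^2) / 4000 - p + 1
  },
  alpine1 = function(x) sum(abs(x * sin(x) + 0.1 * x)),
  alpine2 = function(x) prod(abs(sin(x)) * sqrt(abs(x))),
  trid = function(x) {
    tot <- sum((x - 1)^2)
    for (i in 2:length(x)) tot <- tot + x[i] * x[i - 1]
    tot
  }
)

# Reference capsule-network forward pass composed step by step in R,
# independent of the compiled path. Returns per-class output lengths.
ref_capsnet_lengths <- function(img_mat, params, arch) {
  p <- capsnet_unpack(params, arch)
  K <- arch$conv_kernel
  OH <- arch$conv_out_height
  OW <- arch$conv_out_width
  stride <- arch$conv_stride
  conv <- array(0, c(OH, OW, arch$conv_filters))
  for (f in seq_len(arch$conv_filters)) {
    for (ho in seq_len(OH)) {
      for (wo in seq_len(OW)) {
        r0 <- (ho - 1) * stride
        c0 <- (wo - 1) * stride
        patch <- img_mat[(r0 + 1):(r0 + K), (c0 + 1):(c0 + K)]
        conv[ho, wo, f] <- tanh(sum(patch * p$conv_w[, , f]) + p$conv_b[f])
      }
    }
  }
  cpl <- arch$conv_filters / arch$primary_dim
  n_i <- arch$primary_caps
  prim <- matrix(0, n_i, arch$primary_dim)
  for (wo in seq_len(OW)) {
    for (ho in seq_len(OH)) {
      loc <- (ho - 1) + OH * (wo - 1)
      for (cb in seq_len(cpl)) {
        i <- loc * cpl + cb
        fidx <- (cb - 1) * arch$primary_dim + seq_len(arch$primary_dim)
        prim[i, ] <- squash(conv[ho, wo, fidx])
      }
    }
  }
  u_hat <- array(0, c(n_i, arch$class_caps, arch$class_dim))
  for (j in seq_len(arch$class_caps)) {
    for (i in seq_len(n_i)) {
      u_hat[i, j, ] <- p$caps_w[, , i, j] %*% prim[i, ]
    }
  }
  v <- dynamic_routing(u_hat, arch$routing_iterations, bias = p$caps_b)$v
  sqrt(rowSums(v^2))
}

# Brute-force metric recomputation from raw (label, prediction) pairs.
brute_force_metrics <- function(truth, predicted, positive) {
  tp <- sum(truth == positive & predicted == positive)
  fp <- sum(truth != positive & predicted == positive)
  fn <- sum(truth == positive & predicted != positive)
  tn <- sum(truth != positive & predicted != positive)
  list(
    tp = tp, fp = fp, fn = fn, tn = tn,
    precision = 100 * tp / (tp + fp),
    recall = 100 * tp / (tp + fn),
    accuracy = 100 * (tp + tn) / (tp + tn + fp + fn),
    specificity = 100 * tn / (tn + fp),
    f1 = 100 * 2 * tp / (2 * tp + fp + fn),
    fbeta2 = 5 * tp / (5 * tp + 4 * fn + fp)
  )
}

# Pairwise brute-force AUC with 0.5 tie credit.
brute_force_auc <- function(scores, labels, positive) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Small deterministic labeled dataset for quick model tests.
tiny_smear_data <- function(n_per_class = 10, seed = 42, size = 32) {
  generate_synthetic_smears(n_per_class, smear_config(image_size = size),
                            seed = seed)
}
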