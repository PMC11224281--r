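#' Capsule-network architecture
#'
#' Describes a small capsule network: a single valid-padding convolutional
#' layer with tanh nonlinearity, primary capsules formed by grouping the
#' convolutional feature maps at each spatial location, and one class-capsule
#' layer connected by per-pair linear maps and dynamic routing. The default
#' is deliberately tiny (a few thousand parameters) so that its flat
#' parameter vector is a tractable search space for a derivative-free
#' optimizer.
#'
#' @param input_height,input_width Input image size. Default 16 x 16.
#' @param input_channels Image channels; only grayscale (1) is supported —
#'   images are luminance-converted before the network.
#' @param conv_filters Number of convolution filters. Default 4.
#' @param conv_kernel Square kernel size. Default 3.
#' @param conv_stride Stride. Default 2.
#' @param primary_dim Dimension of each primary capsule; must divide
#'   `conv_filters`. Default 4.
#' @param class_caps Number of class capsules (= classes). Default 2.
#' @param class_dim Dimension of each class capsule. Default 8.
#' @param routing_iterations Dynamic-routing rounds (>= 1). Default 3.
#' @param max_params Hard cap on the total parameter count; exceeding it is
#'   an error advising a smaller architecture. Default 20000.
#' @return Object of class `capsnet_arch`; a list of the fields above plus
#'   derived counts `conv_out_height`, `conv_out_width`, `primary_caps` and
#'   `n_params`.
#' @examples
#' arch <- capsnet_architecture()
#' arch$n_params
#' @export
capsnet_architecture <- function(input_height = 16, input_width = 16,
                                 input_channels = 1, conv_filters = 4,
                                 conv_kernel = 3, conv_stride = 2,
                                 primary_dim = 4, class_caps = 2,
                                 class_dim = 8, routing_iterations = 3,
                                 max_params = 20000) {
  vals <- c(input_height, input_width, input_channels, conv_filters,
            conv_kernel, conv_stride, primary_dim, class_caps, class_dim,
            routing_iterations)
  stopifnot(all(vals == as.integer(vals)), all(vals >= 1))
  if (input_channels != 1) {
    stop("only grayscale input (input_channels = 1) is supported; ",
         "convert images to luminance first")
  }
  if (conv_filters %% primary_dim != 0) {
    stop("`primary_dim` must divide `conv_filters`")
  }
  out_h <- (input_height - conv_kernel) %/% conv_stride + 1
  out_w <- (input_width - conv_kernel) %/% conv_stride + 1
  if (out_h < 1 || out_w < 1) stop("kernel larger than input")
  n_primary <- out_h * out_w * (conv_filters %/% primary_dim)
  arch <- list(
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    input_channels = 1L,
    conv_filters = as.integer(conv_filters),
    conv_kernel = as.integer(conv_kernel),
    conv_stride = as.integer(conv_stride),
    primary_dim = as.integer(primary_dim),
    class_caps = as.integer(class_caps),
    class_dim = as.integer(class_dim),
    routing_iterations = as.integer(routing_iterations),
    conv_out_height = as.integer(out_h),
    conv_out_width = as.integer(out_w),
    primary_caps = as.integer(n_primary)
  )
  arch$n_params <- sum(vapply(.capsnet_segments(arch), function(s) prod(s$dim),
                              numeric(1)))
  if (arch$n_params > max_params) {
    stop("architecture has ", arch$n_params, " parameters, above the cap of ",
         max_params, "; use a smaller architecture")
  }
  structure(arch, class = "capsnet_arch")
}

#' @export
print.capsnet_arch <- function(x, ...) {
  cat(sprintf(
    paste0("<capsnet_arch> %dx%d input, %d conv filters (%dx%d stride %d),\n",
           "  %d primary capsules (dim %d), %d class capsules (dim %d),\n",
           "  %d routing iterations, %d parameters\n"),
    x$input_height, x$input_width, x$conv_filters, x$conv_kernel,
    x$conv_kernel, x$conv_stride, x$primary_caps, x$primary_dim,
    x$class_caps, x$class_dim, x$routing_iterations, x$n_params
  ))
  invisible(x)
}

# Ordered parameter segments: name and array dimension of each.
.capsnet_segments <- function(arch) {
  list(
    conv_w = list(dim = c(arch$conv_kernel, arch$conv_kernel, arch$conv_filters)),
    conv_b = list(dim = arch$conv_filters),
    caps_w = list(dim = c(arch$class_dim, arch$primary_dim,
                          arch$primary_caps, arch$class_caps)),
    caps_b = list(dim = c(arch$class_dim, arch$class_caps))
  )
}

#' Parameter-vector layout of an architecture
#'
#' @param arch A [capsnet_architecture()].
#' @return Tibble with one row per segment: `segment`, `length`, `offset`
#'   (0-based start within the flat vector) and a `dim` list-column.
#' @export
capsnet_layout <- function(arch) {
  segs <- .capsnet_segments(arch)
  lens <- vapply(segs, function(s) prod(s$dim), numeric(1))
  tibble::tibble(
    segment = names(segs),
    length = as.integer(lens),
    offset = as.integer(cumsum(c(0, lens[-length(lens)]))),
    dim = lapply(segs, function(s) as.integer(s$dim))
  )
}

#' Unpack a flat parameter vector into weight/bias arrays
#'
#' @param values Numeric vector of length `arch$n_params`.
#' @param arch A [capsnet_architecture()].
#' @return Named list of arrays: `conv_w` (kernel x kernel x filters),
#'   `conv_b`, `caps_w` (class_dim x primary_dim x primary_caps x
#'   class_caps), `caps_b` (class_dim x class_caps).
#' @export
capsnet_unpack <- function(values, arch) {
  stopifnot(inherits(arch, "capsnet_arch"))
  if (length(values) != arch$n_params) {
    stop("parameter vector has length ", length(values), ", expected ",
         arch$n_params)
  }
  segs <- .capsnet_segments(arch)
  out <- list()
  at <- 0L
  for (nm in names(segs)) {
    d <- segs[[nm]]$dim
    len <- prod(d)
    x <- values[(at + 1):(at + len)]
    out[[nm]] <- if (length(d) > 1) array(x, dim = d) else as.numeric(x)
    at <- at + len
  }
  out
}

#' Pack weight/bias arrays into a flat parameter vector
#'
#' Inverse of [capsnet_unpack()]; `capsnet_pack(capsnet_unpack(v, a), a)`
#' is the identity.
#'
#' @param params Named list as returned by [capsnet_unpack()].
#' @param arch A [capsnet_architecture()].
#' @return Numeric vector of length `arch$n_params`.
#' @export
capsnet_pack <- function(params, arch) {
  stopifnot(inherits(arch, "capsnet_arch"))
  segs <- .capsnet_segments(arch)
  stopifnot(all(names(segs) %in% names(params)))
  out <- unlist(lapply(names(segs), function(nm) {
    x <- params[[nm]]
    d <- segs[[nm]]$dim
    if (prod(d) != length(x)) stop("segment '", nm, "' has the wrong length")
    as.vector(x)
  }), use.names = FALSE)
  as.numeric(out)
}

#' Squash nonlinearity
#'
#' Maps a vector to the same direction with length
#' `||s||^2 / (1 + ||s||^2)`, so output lengths lie in \[0, 1). The zero
#' vector maps to the zero vector.
#'
#' @param s Numeric vector.
#' @return Squashed vector.
#' @examples
#' sqrt(sum(squash(c(3, 0))^2)) # 0.9
#' @export
squash <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s * 0)
  s * (n2 / ((1 + n2) * sqrt(n2)))
}

#' Coupling coefficients from routing logits
#'
#' Row-wise softmax over the class index: each primary capsule's couplings
#' across class capsules sum to 1.
#'
#' @param b Logit matrix, primary capsules in rows, class capsules in
#'   columns.
#' @return Matrix of the same shape with rows summing to 1.
#' @export
coupling_coefficients <- function(b) {
  b <- as.matrix(b)
  e <- exp(b - apply(b, 1, max))
  e / rowSums(e)
}

#' Dynamic routing by agreement
#'
#' Iterates: softmax couplings from the log priors (initially zero), weighted
#' sum of prediction vectors plus the class-capsule bias, squash, then a
#' dot-product agreement update of the log priors. The agreement update is
#' skipped after the final round.
#'
#' @param u_hat Prediction vectors as an array of dimension
#'   `(primary_caps, class_caps, class_dim)`.
#' @param iterations Routing rounds (>= 1). Default 3.
#' @param bias Optional `class_dim x class_caps` matrix added to each
#'   pre-squash sum; default zero.
#' @return List with `v` (class_caps x class_dim matrix of output vectors)
#'   and `state` (final `b`, `c`, `s` matrices).
#' @export
dynamic_routing <- function(u_hat, iterations = 3, bias = NULL) {
  stopifnot(length(dim(u_hat)) == 3, iterations >= 1)
  n_i <- dim(u_hat)[1]
  n_j <- dim(u_hat)[2]
  d <- dim(u_hat)[3]
  if (is.null(bias)) bias <- matrix(0, d, n_j)
  stopifnot(nrow(bias) == d, ncol(bias) == n_j)
  b <- matrix(0, n_i, n_j)
  v <- matrix(0, n_j, d)
  s <- matrix(0, n_j, d)
  cc <- NULL
  for (it in seq_len(iterations)) {
    cc <- coupling_coefficients(b)
    for (j in seq_len(n_j)) {
      uh <- matrix(u_hat[, j, ], nrow = n_i, ncol = d)
      s[j, ] <- colSums(cc[, j] * uh) + bias[, j]
      v[j, ] <- squash(s[j, ])
    }
    if (it < iterations) {
      for (j in seq_len(n_j)) {
        uh <- matrix(u_hat[, j, ], nrow = n_i, ncol = d)
        b[, j] <- b[, j] + as.numeric(uh %*% v[j, ])
      }
    }
  }
  list(v = v, state = list(b = b, c = cc, s = s))
}

#' Margin loss
#'
#' Per-class hinge-squared loss: present classes are penalized for output
#' lengths below `m_plus`, absent classes (down-weighted by `lambda`) for
#' lengths above `m_minus`; the per-sample loss is the sum over classes.
#'
#' @param lengths Class-capsule output lengths: a vector (one sample) or an
#'   `n x k` matrix (one row per sample).
#' @param target True classes: a one-hot vector/matrix matching `lengths`,
#'   or an integer vector of 1-based class indices when `lengths` is a
#'   matrix.
#' @param m_plus,m_minus,lambda Margin parameters; defaults 0.9, 0.1, 0.5.
#' @return Mean per-sample margin loss (a scalar >= 0).
#' @examples
#' margin_loss(c(0.9, 0.1), c(1, 0)) # 0
#' margin_loss(c(0.4, 0.1), c(1, 0)) # 0.25
#' @export
margin_loss <- function(lengths, target, m_plus = 0.9, m_minus = 0.1,
                        lambda = 0.5) {
  stopifnot(0 < m_minus, m_minus < m_plus, m_plus < 1, lambda >= 0)
  if (is.vector(lengths)) lengths <- matrix(lengths, nrow = 1)
  k <- ncol(lengths)
  if (is.vector(target) && length(target) == nrow(lengths) && k > 1 &&
      all(target == as.integer(target)) && all(target >= 1 & target <= k) &&
      !(nrow(lengths) == 1 && length(target) == k)) {
    tc <- matrix(0, nrow(lengths), k)
    tc[cbind(seq_len(nrow(lengths)), as.integer(target))] <- 1
  } else {
    tc <- matrix(target, nrow = nrow(lengths), ncol = k)
  }
  stopifnot(all(tc %in% c(0, 1)), all(lengths >= 0), all(lengths <= 1))
  per_class <- tc * pmax(0, m_plus - lengths)^2 +
    lambda * (1 - tc) * pmax(0, lengths - m_minus)^2
  mean(rowSums(per_class))
}

#' Forward pass: class-capsule output lengths
#'
#' Runs the convolution, primary-capsule squash, per-pair linear maps and
#' dynamic routing, returning the length of each class capsule's output
#' vector — the class existence probabilities.
#'
#' @param images An `n x (H*W)` matrix of flattened grayscale images in
#'   \[0, 1\] (see [as_capsnet_input()]), or a single `H x W` matrix.
#' @param params Flat parameter vector of length `arch$n_params`.
#' @param arch A [capsnet_architecture()].
#' @return `n x class_caps` matrix of output-vector lengths in \[0, 1).
#' @export
capsnet_forward <- function(images, params, arch) {
  stopifnot(inherits(arch, "capsnet_arch"))
  images <- .as_image_matrix(images, arch)
  cpp_capsnet_lengths(images, as.numeric(params), unclass(arch))
}

.as_image_matrix <- function(images, arch) {
  px <- arch$input_height * arch$input_width
  if (is.matrix(images) && nrow(images) == arch$input_height &&
      ncol(images) == arch$input_width) {
    images <- matrix(as.vector(images), nrow = 1)
  }
  if (!is.matrix(images) || ncol(images) != px) {
    stop("`images` must be an n x ", px, " matrix of flattened ",
         arch$input_height, "x", arch$input_width, " images")
  }
  images
}

#' Mean margin loss of a parameter vector on a dataset
#'
#' Full-batch and deterministic: the mean margin loss over every image, with
#' no sampling, so greedy acceptance during optimization is well defined.
#'
#' @param params Flat parameter vector.
#' @param images `n x (H*W)` image matrix (see [as_capsnet_input()]).
#' @param labels Integer vector of 1-based class indices (length `n`).
#' @param arch A [capsnet_architecture()].
#' @param m_plus,m_minus,lambda Margin parameters; defaults 0.9, 0.1, 0.5.
#' @return Scalar mean margin loss (>= 0).
#' @export
capsnet_fitness <- function(params, images, labels, arch, m_plus = 0.9,
                            m_minus = 0.1, lambda = 0.5) {
  stopifnot(inherits(arch, "capsnet_arch"))
  if (nrow(images) == 0) stop("empty dataset")
  labels <- as.integer(labels)
  stopifnot(length(labels) == nrow(images),
            all(labels >= 1), all(labels <= arch$class_caps))
  cpp_capsnet_fitness(images, labels - 1L, as.numeric(params),
                      unclass(arch), m_plus, m_minus, lambda)
}

#' Predicted class from output lengths
#'
#' Argmax of the class-capsule lengths; ties go to the lowest index.
#'
#' @param lengths Vector of per-class lengths, or an `n x k` matrix.
#' @return Integer class index (or vector of them, 1-based).
#' @export
predict_class <- function(lengths) {
  if (is.matrix(lengths)) return(apply(lengths, 1, which.max))
  which.max(lengths)
}

#' Train a capsule network with the osprey optimizer
#'
#' Minimizes the full-batch margin loss over the network's flat parameter
#' vector with [osprey_optimize()], searching the box `[-bound, bound]` per
#' coordinate.
#'
#' @param data A labeled image tibble (columns `image`, `label`) such as
#'   produced by [generate_synthetic_smears()], or a list with elements
#'   `images` (matrix) and `labels` (integer indices).
#' @param arch A [capsnet_architecture()]. Default tiny architecture.
#' @param options An [osprey_options()]; default MOP with `pop_size = 30`,
#'   `iterations = 100`.
#' @param bound Half-width of the symmetric search box for every weight and
#'   bias. Default 1.
#' @param m_plus,m_minus,lambda Margin parameters; defaults 0.9, 0.1, 0.5.
#' @param seed Optional integer seed for reproducible training.
#' @return Object of class `capsnet_model`: list with `params`, `arch`,
#'   `classes`, `result` (the `osprey_result`), `loss` (final training
#'   margin loss) and the margin parameters.
#' @export
train_capsnet <- function(data, arch = capsnet_architecture(),
                          options = osprey_options(pop_size = 30, iterations = 100),
                          bound = 1, m_plus = 0.9, m_minus = 0.1,
                          lambda = 0.5, seed = NULL) {
  stopifnot(inherits(arch, "capsnet_arch"))
  prep <- .prepare_training_data(data, arch)
  objective <- function(p) {
    capsnet_fitness(p, prep$images, prep$labels, arch, m_plus, m_minus, lambda)
  }
  space <- search_space(-abs(bound), abs(bound), arch$n_params)
  result <- osprey_optimize(objective, space, options, seed = seed)
  structure(
    list(
      params = result$best_position,
      arch = arch,
      classes = prep$classes,
      result = result,
      loss = result$best_value,
      m_plus = m_plus, m_minus = m_minus, lambda = lambda
    ),
    class = "capsnet_model"
  )
}

.prepare_training_data <- function(data, arch) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("images", "labels") %in% names(data))) {
    labels <- data$labels
    classes <- attr(data, "classes")
    if (is.null(classes)) classes <- as.character(sort(unique(labels)))
    return(list(images = data$images, labels = as.integer(labels),
                classes = classes))
  }
  stopifnot(is.data.frame(data), all(c("image", "label") %in% names(data)))
  lab <- as.factor(data$label)
  if (nlevels(lab) != arch$class_caps) {
    stop("dataset has ", nlevels(lab), " classes but the architecture has ",
         arch$class_caps, " class capsules")
  }
  list(images = as_capsnet_input(data, arch), labels = as.integer(lab),
       classes = levels(lab))
}

#' @export
print.capsnet_model <- function(x, ...) {
  cat(sprintf(
    "<capsnet_model> %d parameters, classes: %s\n  trained by %s, final margin loss %.4g\n",
    x$arch$n_params, paste(x$classes, collapse = ", "),
    x$result$variant, x$loss
  ))
  invisible(x)
}

#' Predict from a trained capsule network
#'
#' @param object A `capsnet_model`.
#' @param newdata Labeled image tibble or `n x (H*W)` image matrix.
#' @param type `"class"` for predicted labels (factor), `"prob"` for the
#'   positive-class (last level) capsule length, `"lengths"` for the full
#'   length matrix.
#' @param ... Unused.
#' @return Factor, numeric vector, or matrix according to `type`.
#' @export
predict.capsnet_model <- function(object, newdata,
                                  type = c("class", "prob", "lengths"), ...) {
  type <- match.arg(type)
  images <- if (is.matrix(newdata)) newdata
            else as_capsnet_input(newdata, object$arch)
  lengths <- capsnet_forward(images, object$params, object$arch)
  colnames(lengths) <- object$classes
  switch(type,
    lengths = lengths,
    prob = lengths[, length(object$classes)],
    class = factor(object$classes[predict_class(lengths)],
                   levels = object$classes)
  )
}

#' @export
tidy.capsnet_model <- function(x, ...) tidy(x$result, ...)

#' @export
glance.capsnet_model <- function(x, ...) {
  tibble::tibble(
    variant = x$result$variant,
    n_params = x$arch$n_params,
    evaluations = x$result$evaluations,
    margin_loss = x$loss
  )
}
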