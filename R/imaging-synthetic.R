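#' Synthetic blood-smear generator settings
#'
#' Parameters of the synthetic two-class smear images: leukemic images carry
#' one large, irregular dark nucleus (a blast analogue with scanty
#' cytoplasm), normal images one smaller, round dark nucleus (a lymphocyte
#' analogue); both lie over a light background scattered with pale disc
#' distractors standing in for red blood cells, plus Gaussian pixel noise.
#' The blast nucleus-radius interval must lie strictly above the lymphocyte
#' interval, so the two classes are separable by construction.
#'
#' @param image_size Side length in pixels. Default 32.
#' @param blast_radius Blast nucleus radius interval, as a fraction of the
#'   image size. Default \[0.26, 0.36\].
#' @param lymph_radius Lymphocyte nucleus radius interval. Default
#'   \[0.10, 0.16\].
#' @param irregularity Radial perturbation amplitude of the blast nucleus
#'   boundary (fraction of its radius). Default 0.35; lymphocyte nuclei use
#'   a near-zero 0.04.
#' @param n_red_cells Integer range of pale distractor discs per image.
#'   Default 3 to 8.
#' @param noise_sigma Gaussian pixel-noise standard deviation. Default 0.02.
#' @return List of class `smear_config`.
#' @export
smear_config <- function(image_size = 32, blast_radius = c(0.26, 0.36),
                         lymph_radius = c(0.10, 0.16), irregularity = 0.35,
                         n_red_cells = c(3, 8), noise_sigma = 0.02) {
  stopifnot(image_size >= 8, length(blast_radius) == 2,
            length(lymph_radius) == 2, blast_radius[1] <= blast_radius[2],
            lymph_radius[1] <= lymph_radius[2],
            irregularity >= 0, length(n_red_cells) == 2,
            n_red_cells[1] <= n_red_cells[2], noise_sigma >= 0)
  if (lymph_radius[2] >= blast_radius[1]) {
    stop("blast radius interval must lie strictly above the lymphocyte ",
         "interval (class separability by construction)")
  }
  structure(
    list(image_size = as.integer(image_size), blast_radius = blast_radius,
         lymph_radius = lymph_radius, irregularity = irregularity,
         n_red_cells = as.integer(n_red_cells), noise_sigma = noise_sigma),
    class = "smear_config"
  )
}

# Distances/angles of every pixel center from a given point.
.pixel_polar <- function(size, center) {
  r <- matrix(seq_len(size), size, size)
  c <- matrix(seq_len(size), size, size, byrow = TRUE)
  dy <- r - center[1]
  dx <- c - center[2]
  list(dist = sqrt(dx^2 + dy^2), angle = atan2(dy, dx))
}

# Soft-edged disc overlay: pulls pixels inside `radius` toward `intensity`.
.draw_disc <- function(img, center, radius, intensity, edge = 1) {
  p <- .pixel_polar(nrow(img), center)
  wgt <- stats::plogis((radius - p$dist) / edge)
  img + wgt * (intensity - img)
}

# Nucleus with a radially perturbed boundary r(theta) = r0 (1 + irr * f),
# f a normalized sum of low-order harmonics in [-1, 1].
.draw_nucleus <- function(img, center, radius, irregularity, intensity) {
  p <- .pixel_polar(nrow(img), center)
  amp <- stats::rnorm(3)
  phase <- stats::runif(3, 0, 2 * pi)
  f <- amp[1] * cos(2 * p$angle + phase[1]) +
    amp[2] * cos(3 * p$angle + phase[2]) +
    amp[3] * cos(4 * p$angle + phase[3])
  f <- f / (sum(abs(amp)) + 1e-12)
  rb <- radius * (1 + irregularity * f)
  wgt <- stats::plogis((rb - p$dist) / 0.8)
  img + wgt * (intensity - img)
}

.generate_one_smear <- function(config, class) {
  s <- config$image_size
  img <- matrix(0.92, s, s)
  # pale red-cell distractors
  k <- sample(config$n_red_cells[1]:config$n_red_cells[2], 1)
  for (j in seq_len(k)) {
    img <- .draw_disc(
      img,
      center = stats::runif(2, 1, s),
      radius = stats::runif(1, 0.08, 0.14) * s,
      intensity = stats::runif(1, 0.72, 0.82)
    )
  }
  # central white-cell nucleus
  jitter <- stats::runif(2, -0.08, 0.08) * s
  center <- (s + 1) / 2 + jitter
  if (class == "leukemic") {
    radius <- stats::runif(1, config$blast_radius[1], config$blast_radius[2]) * s
    irr <- config$irregularity
    intensity <- stats::runif(1, 0.12, 0.22)
  } else {
    radius <- stats::runif(1, config$lymph_radius[1], config$lymph_radius[2]) * s
    irr <- 0.04
    intensity <- stats::runif(1, 0.20, 0.30)
  }
  img <- .draw_nucleus(img, center, radius, irr, intensity)
  img <- img + stats::rnorm(s * s, 0, config$noise_sigma)
  pmin(pmax(img, 0), 1)
}

#' Generate a balanced synthetic blood-smear dataset
#'
#' @param n_per_class Images per class (>= 1).
#' @param config A [smear_config()].
#' @param seed Optional integer seed; the same seed yields a pixel-identical
#'   dataset.
#' @return Tibble with `n_per_class * 2` rows: `image` (list of
#'   `image_size` x `image_size` matrices in \[0, 1\]), `label` (factor,
#'   levels `normal`, `leukemic`) and `provenance = "synthetic"`.
#' @examples
#' d <- generate_synthetic_smears(5, seed = 1)
#' table(d$label)
#' @export
generate_synthetic_smears <- function(n_per_class, config = smear_config(),
                                      seed = NULL) {
  stopifnot(n_per_class >= 1, inherits(config, "smear_config"))
  if (!is.null(seed)) set.seed(seed)
  labels <- rep(c("normal", "leukemic"), each = n_per_class)
  images <- lapply(labels, function(cls) .generate_one_smear(config, cls))
  tibble::tibble(
    image = images,
    label = factor(labels, levels = c("normal", "leukemic")),
    provenance = "synthetic"
  )
}

#' Dark-area fraction of an image
#'
#' Fraction of pixels below `threshold` — a crude nucleus-area measurement
#' used by the baseline classifier.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param threshold Darkness cut-off. Default 0.5.
#' @return Scalar in \[0, 1\].
#' @export
nucleus_area_fraction <- function(img, threshold = 0.5) {
  mean(img < threshold)
}

#' Baseline nucleus-area threshold classifier
#'
#' One-feature classifier: the dark-area fraction of the image. The training
#' step picks the midpoint cut between the two classes' feature values that
#' maximizes training accuracy. Serves as a sanity baseline showing the
#' synthetic classes are separable.
#'
#' @param data Labeled image tibble with columns `image` and `label` (two
#'   classes).
#' @return Object of class `area_classifier` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
train_area_classifier <- function(data) {
  stopifnot(is.data.frame(data), all(c("image", "label") %in% names(data)))
  lab <- as.factor(data$label)
  stopifnot(nlevels(lab) == 2)
  feat <- vapply(data$image, nucleus_area_fraction, numeric(1))
  ord <- order(feat)
  cuts <- (feat[ord][-1] + feat[ord][-length(feat)]) / 2
  means <- tapply(feat, lab, mean)
  upper_class <- names(which.max(means))
  acc <- vapply(cuts, function(ct) {
    pred <- ifelse(feat > ct, upper_class, setdiff(levels(lab), upper_class))
    mean(pred == as.character(lab))
  }, numeric(1))
  structure(
    list(cut = cuts[which.max(acc)], upper_class = upper_class,
         classes = levels(lab), train_accuracy = max(acc)),
    class = "area_classifier"
  )
}

#' @export
predict.area_classifier <- function(object, newdata,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  feat <- vapply(newdata$image, nucleus_area_fraction, numeric(1))
  if (type == "prob") {
    # monotone score for the upper (larger-area) class
    p <- stats::plogis(50 * (feat - object$cut))
    if (object$upper_class == object$classes[2]) return(p)
    return(1 - p)
  }
  lower_class <- setdiff(object$classes, object$upper_class)
  factor(ifelse(feat > object$cut, object$upper_class, lower_class),
         levels = object$classes)
}

#' @export
print.area_classifier <- function(x, ...) {
  cat(sprintf(
    "<area_classifier> cut %.4f (class '%s' above), training accuracy %.3f\n",
    x$cut, x$upper_class, x$train_accuracy
  ))
  invisible(x)
}
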