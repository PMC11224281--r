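#' Geometric image transforms for augmentation
#'
#' Center-based geometric transforms on grayscale images (numeric matrices
#' in \[0, 1\]): rotation, shear, translation, rescale and axis reflection.
#' The output is resampled (bilinear) to the input shape; pixels mapped from
#' outside the frame are filled with the median border intensity, the
#' image's background estimate. Reflections and axis-aligned rotations are
#' exact index permutations.
#'
#' @param img Numeric matrix (rows = y, columns = x), values in \[0, 1\].
#' @param angle_deg Rotation angle in degrees, positive counterclockwise in
#'   the displayed image.
#' @param sx,sy Shear factors along the x and y axis.
#' @param axis `"x"` mirrors horizontally (columns reversed), `"y"`
#'   vertically (rows reversed).
#' @param dx,dy Translation in pixels along x (columns) and y (rows); may be
#'   fractional.
#' @param factor Scale factor about the image center (> 0); values below 1
#'   shrink the content into the frame.
#' @param fill Fill intensity for out-of-frame pixels; default the median of
#'   the image border.
#' @return Transformed matrix of the same dimension.
#' @examples
#' m <- matrix(runif(64), 8, 8)
#' identical(img_reflect(img_reflect(m, "x"), "x"), m)
#' @name image-transforms
NULL

# Median of the border pixels: background estimate used as fill.
.border_median <- function(img) {
  h <- nrow(img); w <- ncol(img)
  stats::median(c(img[1, ], img[h, ], img[, 1], img[, w]))
}

# Backward-mapping bilinear sampler. `inv` maps an n x 2 matrix of output
# (row, col) coordinates to input coordinates; out-of-frame samples get
# `fill`.
.warp_bilinear <- function(img, inv, out_dim = dim(img), fill = NULL) {
  if (is.null(fill)) fill <- .border_median(img)
  h <- nrow(img); w <- ncol(img)
  oh <- out_dim[1]; ow <- out_dim[2]
  grid <- cbind(rep(seq_len(oh), times = ow), rep(seq_len(ow), each = oh))
  src <- inv(grid)
  r <- src[, 1]; c <- src[, 2]
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  # gather with fill for out-of-range indices
  gather <- function(ri, ci) {
    ok <- ri >= 1 & ri <= h & ci >= 1 & ci <= w
    v <- rep(fill, length(ri))
    v[ok] <- img[cbind(ri[ok], ci[ok])]
    v
  }
  v <- (1 - fr) * (1 - fc) * gather(r0, c0) +
    (1 - fr) * fc * gather(r0, c0 + 1) +
    fr * (1 - fc) * gather(r0 + 1, c0) +
    fr * fc * gather(r0 + 1, c0 + 1)
  matrix(v, oh, ow)
}

# Warp by the inverse of a forward affine map about the image center:
# forward (x', y') = M %*% (x, y); sampler needs input = M^{-1} (output).
.warp_center_affine <- function(img, M_inv, shift = c(0, 0), fill = NULL) {
  cy <- (nrow(img) + 1) / 2
  cx <- (ncol(img) + 1) / 2
  inv <- function(grid) {
    x <- grid[, 2] - cx - shift[1]
    y <- grid[, 1] - cy - shift[2]
    sx <- M_inv[1, 1] * x + M_inv[1, 2] * y
    sy <- M_inv[2, 1] * x + M_inv[2, 2] * y
    cbind(sy + cy, sx + cx)
  }
  .warp_bilinear(img, inv, fill = fill)
}

#' @rdname image-transforms
#' @export
img_rotate <- function(img, angle_deg, fill = NULL) {
  th <- angle_deg * pi / 180
  # y axis points down; sampling uses the inverse map, which for a
  # displayed-counterclockwise rotation by th is the matrix below.
  M_inv <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
  .warp_center_affine(img, M_inv, fill = fill)
}

#' @rdname image-transforms
#' @export
img_shear <- function(img, sx = 0, sy = 0, fill = NULL) {
  det <- 1 - sx * sy
  if (abs(det) < 1e-8) stop("degenerate shear")
  M_inv <- matrix(c(1, -sx, -sy, 1), 2, 2, byrow = TRUE) / det
  .warp_center_affine(img, M_inv, fill = fill)
}

#' @rdname image-transforms
#' @export
img_reflect <- function(img, axis = c("x", "y")) {
  axis <- match.arg(axis)
  if (axis == "x") img[, rev(seq_len(ncol(img))), drop = FALSE]
  else img[rev(seq_len(nrow(img))), , drop = FALSE]
}

#' @rdname image-transforms
#' @export
img_translate <- function(img, dx = 0, dy = 0, fill = NULL) {
  .warp_center_affine(img, diag(2), shift = c(dx, dy), fill = fill)
}

#' @rdname image-transforms
#' @export
img_rescale <- function(img, factor, fill = NULL) {
  stopifnot(factor > 0)
  .warp_center_affine(img, diag(2) / factor, fill = fill)
}

#' Salt-and-pepper impulse noise
#'
#' Sets exactly `round(density * n_pixels)` uniformly chosen pixels to 0 or
#' 1 with equal probability.
#'
#' @param img Numeric matrix in \[0, 1\].
#' @param density Fraction of corrupted pixels, in \[0, 1\].
#' @return The noised matrix.
#' @export
salt_pepper <- function(img, density) {
  stopifnot(is.numeric(density), length(density) == 1,
            density >= 0, density <= 1)
  n <- round(density * length(img))
  if (n == 0) return(img)
  idx <- sample.int(length(img), n)
  img[idx] <- sample(c(0, 1), n, replace = TRUE)
  img
}

#' Resize labeled images to the network input
#'
#' Bilinear resize of each image to the architecture's input size (with
#' pixel-center alignment) followed by row-wise flattening, producing the
#' matrix form consumed by [capsnet_forward()] and [capsnet_fitness()].
#'
#' @param data Labeled image tibble (column `image`), a list of matrices, or
#'   a single matrix.
#' @param arch A [capsnet_architecture()].
#' @return `n x (input_height * input_width)` numeric matrix.
#' @export
as_capsnet_input <- function(data, arch = capsnet_architecture()) {
  stopifnot(inherits(arch, "capsnet_arch"))
  imgs <- if (is.data.frame(data)) data$image
          else if (is.matrix(data)) list(data)
          else data
  th <- arch$input_height; tw <- arch$input_width
  rows <- vapply(imgs, function(im) {
    stopifnot(is.matrix(im))
    if (nrow(im) != th || ncol(im) != tw) {
      sr <- nrow(im) / th; sc <- ncol(im) / tw
      inv <- function(grid) {
        cbind((grid[, 1] - 0.5) * sr + 0.5, (grid[, 2] - 0.5) * sc + 0.5)
      }
      im <- .warp_bilinear(im, inv, out_dim = c(th, tw))
    }
    as.vector(im)
  }, numeric(th * tw))
  t(rows)
}

#' Augmentation settings
#'
#' Parameter ranges for the five augmentation operators. Defaults follow the
#' standard smear-augmentation recipe: rotation in \[-50, 50\] degrees and
#' shear factors in \[-0.1, 0.1\], with mild translation (up to 10% of the
#' image size per axis), scaling in \[0.9, 1.1\] and independent x/y
#' reflections with probability 0.5.
#'
#' @param rotation Rotation interval in degrees.
#' @param shear Shear-factor interval (applied independently to x and y).
#' @param reflect_x,reflect_y Reflection probabilities per axis.
#' @param translate_frac Translation interval as a fraction of image size.
#' @param scale Scale-factor interval.
#' @return List of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation = c(-50, 50), shear = c(-0.1, 0.1),
                                reflect_x = 0.5, reflect_y = 0.5,
                                translate_frac = c(-0.1, 0.1),
                                scale = c(0.9, 1.1)) {
  chk <- function(x) length(x) == 2 && x[1] <= x[2]
  stopifnot(chk(rotation), chk(shear), chk(translate_frac), chk(scale),
            reflect_x >= 0, reflect_x <= 1, reflect_y >= 0, reflect_y <= 1,
            all(scale > 0))
  structure(
    list(rotation = rotation, shear = shear, reflect_x = reflect_x,
         reflect_y = reflect_y, translate_frac = translate_frac,
         scale = scale),
    class = "augmentation_config"
  )
}

# One random composition of the five operators.
.augment_one <- function(img, config) {
  img <- img_rotate(img, stats::runif(1, config$rotation[1], config$rotation[2]))
  img <- img_shear(img, stats::runif(1, config$shear[1], config$shear[2]),
                   stats::runif(1, config$shear[1], config$shear[2]))
  img <- img_rescale(img, stats::runif(1, config$scale[1], config$scale[2]))
  h <- nrow(img); w <- ncol(img)
  img <- img_translate(
    img,
    stats::runif(1, config$translate_frac[1], config$translate_frac[2]) * w,
    stats::runif(1, config$translate_frac[1], config$translate_frac[2]) * h
  )
  if (stats::runif(1) < config$reflect_x) img <- img_reflect(img, "x")
  if (stats::runif(1) < config$reflect_y) img <- img_reflect(img, "y")
  pmin(pmax(img, 0), 1)
}

#' Expand a labeled image set by random augmentation
#'
#' Keeps every original image and adds randomly augmented copies until the
#' set reaches `target_count`. Each added image is a random composition of
#' rotation, shear, scale, translation and x/y reflection with parameters
#' drawn from `config`; labels are preserved and the added images are
#' allocated to classes proportionally, so class proportions stay within one
#' image of the source proportions.
#'
#' @param data Labeled image tibble with columns `image` and `label`.
#' @param target_count Desired output size (>= `nrow(data)`).
#' @param config An [augmentation_config()].
#' @param seed Optional integer seed.
#' @return Tibble of `target_count` rows with columns `image`, `label`,
#'   `provenance` (`"original"` kept, added rows `"augmented"`).
#' @export
augment_dataset <- function(data, target_count,
                            config = augmentation_config(), seed = NULL) {
  stopifnot(is.data.frame(data), nrow(data) >= 1,
            all(c("image", "label") %in% names(data)))
  if (target_count < nrow(data)) {
    stop("`target_count` (", target_count, ") is below the input size (",
         nrow(data), ")")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- tibble::tibble(
    image = data$image,
    label = data$label,
    provenance = if ("provenance" %in% names(data)) data$provenance
                 else "original"
  )
  n_extra <- target_count - nrow(data)
  if (n_extra == 0) return(out)
  # Largest-remainder allocation of extra images across classes.
  tab <- table(data$label)
  share <- n_extra * as.numeric(tab) / sum(tab)
  alloc <- floor(share)
  rem <- n_extra - sum(alloc)
  if (rem > 0) {
    ord <- order(share - alloc, decreasing = TRUE)
    alloc[ord[seq_len(rem)]] <- alloc[ord[seq_len(rem)]] + 1
  }
  extra <- purrr::map2(names(tab), alloc, function(cls, k) {
    if (k == 0) return(NULL)
    src <- which(data$label == cls)
    picks <- src[sample.int(length(src), k, replace = TRUE)]
    tibble::tibble(
      image = lapply(picks, function(i) .augment_one(data$image[[i]], config)),
      label = data$label[picks],
      provenance = "augmented"
    )
  })
  dplyr::bind_rows(out, purrr::compact(extra))
}
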