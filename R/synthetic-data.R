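#' Generate a labelled feature dataset with planted informative features
#'
#' Emulates a three-class (normal / benign / malignant) feature table at
#' desk scale: `n_informative` columns carry class signal as Gaussians with
#' equally spaced class means `(-s, 0, +s)` where `s = class_separation`
#' (in units of the unit noise standard deviation), and the remaining
#' columns are class-independent standard normal noise. The planted column
#' indices are returned for recall scoring.
#'
#' @param n_per_class Samples per class; length-3 vector or scalar
#'   (default 50 each; use `c(25, 32, 32)` for the imbalanced regime).
#' @param n_features Total feature count N (default 30).
#' @param n_informative Number of signal-carrying columns (default 5).
#' @param class_separation Distance between adjacent class means on
#'   informative columns, in noise-SD units (default 2).
#' @param seed Integer seed; identical seeds give identical matrices.
#' @return A [labeled_dataset()] with an extra `informative_idx` element.
#' @export
make_feature_dataset <- function(n_per_class = c(50L, 50L, 50L),
                                 n_features = 30L,
                                 n_informative = 5L,
                                 class_separation = 2,
                                 seed = 0L) {
  n_per_class <- rep_len(as.integer(n_per_class), 3L)
  if (any(n_per_class < 1) || n_features < 1 || n_informative < 0)
    stop("make_feature_dataset: counts must be positive")
  if (n_informative > n_features)
    stop("make_feature_dataset: n_informative cannot exceed n_features")
  set.seed(seed)
  classes <- c("normal", "benign", "malignant")
  labels <- rep(classes, times = n_per_class)
  n <- sum(n_per_class)
  x <- matrix(stats::rnorm(n * n_features), nrow = n, ncol = n_features)
  class_idx <- rep(1:3, times = n_per_class)
  means <- (class_idx - 2) * class_separation   # -s, 0, +s
  if (n_informative > 0)
    for (j in seq_len(n_informative))
      x[, j] <- x[, j] + means
  ds <- labeled_dataset(x, labels,
                        feature_names = paste0("f", seq_len(n_features)))
  ds$informative_idx <- seq_len(n_informative)
  ds
}

#' Phantom specification
#'
#' @param side Image side length in pixels (square, default 128).
#' @param background Background intensity (8-bit scale, default 30).
#' @param nodules List of nodules, each `list(center = c(row, col),
#'   radius = r, intensity = v)`. `NULL` gives a default of three disjoint
#'   bright disks.
#' @param allow_overlap Logical; when `FALSE`, overlapping nodules are
#'   rejected.
#' @param seed Accepted for interface symmetry; rendering is deterministic.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(side = 128L, background = 30,
                         nodules = NULL, allow_overlap = FALSE, seed = 0L) {
  if (is.null(nodules))
    nodules <- list(
      list(center = c(35, 35), radius = 12, intensity = 200),
      list(center = c(40, 95), radius = 10, intensity = 220),
      list(center = c(95, 64), radius = 14, intensity = 180))
  structure(list(side = as.integer(side), background = background,
                 nodules = nodules, allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Render a CT-like phantom image with a known nodule mask
#'
#' Draws hard (anti-alias-free) disks on a uniform background. The ground
#' truth mask labels the disks 1..k in list order; a later disk overwrites
#' earlier labels where they overlap (only possible with
#' `allow_overlap = TRUE`).
#'
#' @param spec A [phantom_spec()].
#' @return A list with `image` (numeric matrix, 0-255 scale) and `mask`
#'   (integer label matrix).
#' @export
make_phantom <- function(spec = phantom_spec()) {
  s <- spec$side
  img <- matrix(spec$background, nrow = s, ncol = s)
  mask <- matrix(0L, nrow = s, ncol = s)
  rows <- matrix(seq_len(s), nrow = s, ncol = s)
  cols <- matrix(seq_len(s), nrow = s, ncol = s, byrow = TRUE)
  for (k in seq_along(spec$nodules)) {
    nd <- spec$nodules[[k]]
    ctr <- nd$center; r <- nd$radius
    if (ctr[1] - r < 1 || ctr[1] + r > s || ctr[2] - r < 1 || ctr[2] + r > s)
      stop("make_phantom: nodule ", k, " does not lie fully inside the image")
    inside <- (rows - ctr[1])^2 + (cols - ctr[2])^2 <= r^2
    if (!spec$allow_overlap && any(mask[inside] > 0))
      stop("make_phantom: nodule ", k, " overlaps an earlier nodule")
    img[inside] <- nd$intensity
    mask[inside] <- k
  }
  list(image = img, mask = mask)
}
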