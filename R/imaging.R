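#' Peak signal-to-noise ratio
#'
#' `10 log10(MAX^2 / MSE)` in decibels, with `MAX` the declared intensity
#' maximum (255 for 8-bit, 1 for normalized images) and MSE the mean
#' squared pixel difference. Identical images have zero MSE and return
#' `Inf`, the explicit infinite-PSNR marker.
#'
#' @param reference,test Numeric matrices of identical dimensions.
#' @param max_value Declared intensity maximum (default 255).
#' @return PSNR in dB, or `Inf` for identical images.
#' @export
psnr <- function(reference, test, max_value = 255) {
  if (!all(dim(reference) == dim(test)))
    stop("psnr: image dimensions differ")
  mse <- mean((reference - test)^2)
  if (mse == 0) return(Inf)
  10 * log10(max_value^2 / mse)
}

#' Add noise to a grayscale image
#'
#' `gaussian`: adds zero-mean Gaussian noise with standard deviation
#' `level` (intensity units) and clips to the declared range.
#' `salt-pepper`: replaces each pixel independently with 0 or `max_value`,
#' each with probability `level / 2`.
#'
#' @param image Numeric matrix.
#' @param model `"gaussian"` or `"salt-pepper"`.
#' @param level Noise level (SD in intensity units, or total corruption
#'   probability).
#' @param max_value Declared intensity maximum.
#' @return The noisy image matrix.
#' @export
add_noise <- function(image, model = c("gaussian", "salt-pepper"),
                      level = 10, max_value = 255) {
  model <- match.arg(model)
  if (level < 0) stop("add_noise: level must be nonnegative")
  if (level == 0) return(image)
  n <- length(image)
  if (model == "gaussian") {
    out <- image + stats::rnorm(n, 0, level)
    out[out < 0] <- 0
    out[out > max_value] <- max_value
    matrix(out, nrow = nrow(image))
  } else {
    u <- stats::runif(n)
    out <- as.vector(image)
    out[u < level / 2] <- 0
    out[u >= level / 2 & u < level] <- max_value
    matrix(out, nrow = nrow(image))
  }
}

#' Denoising filter specification
#'
#' Two filter families cover the mentions of median, adaptive and weighted
#' filtering in the pipeline: a sliding-window median, and a weighted local
#' mean whose center weight is the family-specific parameter (weight
#' `-> Inf` approaches the identity).
#'
#' @param family `"median"` or `"weighted"`.
#' @param window_radius Integer >= 1; the window side is
#'   `2 * window_radius + 1`.
#' @param weight_parameter Center weight of the weighted local mean
#'   (ignored by the median family).
#' @return A list of class `filter_spec`.
#' @export
filter_spec <- function(family = c("median", "weighted"),
                        window_radius = 1L, weight_parameter = 1) {
  family <- match.arg(family)
  if (window_radius < 1) stop("filter_spec: window_radius must be >= 1")
  if (family == "weighted" && weight_parameter <= 0)
    stop("filter_spec: weight_parameter must be positive")
  structure(list(family = family, window_radius = as.integer(window_radius),
                 weight_parameter = weight_parameter),
            class = "filter_spec")
}

# replicate-pad a matrix by r pixels on every side
pad_replicate <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  img[c(rep(1L, r), seq_len(n), rep(n, r)),
      c(rep(1L, r), seq_len(m), rep(m, r)), drop = FALSE]
}

# stack the (2r+1)^2 window shifts as columns of an (n*m) x w^2 matrix
window_stack <- function(img, r) {
  n <- nrow(img); m <- ncol(img)
  P <- pad_replicate(img, r)
  w <- 2L * r + 1L
  W <- matrix(0, nrow = n * m, ncol = w * w)
  k <- 0L
  for (dj in 0:(w - 1L)) for (di in 0:(w - 1L)) {
    k <- k + 1L
    W[, k] <- as.vector(P[(1L + di):(n + di), (1L + dj):(m + dj)])
  }
  W
}

#' Apply a denoising filter
#'
#' Sliding-window filtering with edge replication. The median family takes
#' the window median; the weighted family takes the normalized weighted
#' local mean with the center weight from the spec and unit weights
#' elsewhere.
#'
#' @param image Numeric matrix.
#' @param spec A [filter_spec()].
#' @return The filtered image matrix.
#' @export
apply_filter <- function(image, spec) {
  r <- spec$window_radius
  if (2 * r + 1 > min(dim(image)))
    stop("apply_filter: window larger than image")
  n <- nrow(image); m <- ncol(image)
  if (spec$family == "median") {
    W <- window_stack(image, r)
    matrix(apply(W, 1L, stats::median), nrow = n, ncol = m)
  } else {
    w <- 2L * r + 1L
    weights <- rep(1, w * w)
    center <- (w * w + 1L) %/% 2L
    weights[center] <- spec$weight_parameter
    weights <- weights / sum(weights)
    W <- window_stack(image, r)
    matrix(as.numeric(W %*% weights), nrow = n, ncol = m)
  }
}

# decode a point of the unit cube into a filter spec: dimension 1 picks the
# family, 2 the window radius (1..3), 3 the log-scaled center weight
decode_filter_position <- function(x) {
  family <- if (x[1] < 0.5) "median" else "weighted"
  radius <- 1L + as.integer(floor(min(x[2], 0.999999) * 3))
  weight <- 10^(3 * x[3])   # 1 .. 1000
  filter_spec(family, radius, weight)
}

#' Optimize a denoising filter by PSNR with the grey wolf optimizer
#'
#' Runs [run_gwo()] maximizing `psnr(reference, apply_filter(noisy, spec))`
#' over an encoded (family, window radius, center weight) search box. This
#' is the calibration setting: a clean reference must be available, as when
#' noise is injected synthetically.
#'
#' @param noisy,reference Numeric image matrices of equal size.
#' @param config An [optimizer_config()]; dimensionality is forced to 3 and
#'   orientation to maximize. Defaults to a modest budget
#'   (population 8, 20 iterations).
#' @param max_value Declared intensity maximum.
#' @return A list with `spec` (the best [filter_spec()]), `psnr_db`, the
#'   PSNR of the unfiltered noisy image `noisy_psnr_db`, and the full
#'   `result` from [run_gwo()] (NULL for the degenerate identical-input
#'   case).
#' @export
optimize_filter <- function(noisy, reference, config = NULL, max_value = 255) {
  if (!all(dim(noisy) == dim(reference)))
    stop("optimize_filter: image dimensions differ")
  noisy_db <- psnr(reference, noisy, max_value)
  if (is.infinite(noisy_db)) {
    # already clean: any spec attains infinite PSNR
    return(list(spec = filter_spec("weighted", 1L, 1000),
                psnr_db = Inf, noisy_psnr_db = Inf, result = NULL))
  }
  if (is.null(config))
    config <- optimizer_config(dimensionality = 3L, iterations = 20L,
                               use_ga_seeding = FALSE, sharing_radius = "off")
  config$dimensionality <- 3L
  config$domain_low <- rep(0, 3)
  config$domain_high <- rep(1, 3)
  config$orientation <- "maximize"
  objective <- function(x) {
    sp <- decode_filter_position(x)
    db <- psnr(reference, apply_filter(noisy, sp), max_value)
    # cap the (unreachable in practice) infinite marker for the optimizer
    min(db, 1e6)
  }
  res <- run_gwo(objective, config)
  best_spec <- decode_filter_position(res$best_position)
  list(spec = best_spec, psnr_db = res$best_fitness,
       noisy_psnr_db = noisy_db, result = res)
}

#' Otsu threshold
#'
#' Histogram-based global threshold maximizing between-class variance, on
#' 256 bins spanning the image's intensity range (hence invariant to
#' rescaling by a constant factor).
#'
#' @param image Numeric matrix.
#' @return Threshold value on the image's intensity scale.
#' @export
otsu_threshold <- function(image) {
  v <- as.vector(image)
  lo <- min(v); hi <- max(v)
  if (lo == hi) return(lo)
  nb <- 256L
  bins <- pmin(as.integer((v - lo) / (hi - lo) * nb), nb - 1L)
  h <- tabulate(bins + 1L, nbins = nb)
  p <- h / sum(h)
  omega <- cumsum(p)
  mu <- cumsum(p * (seq_len(nb) - 1L))
  mu_t <- mu[nb]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)        # threshold between bin k-1 and k
  lo + (k - 0.5) / nb * (hi - lo)
}

# offsets of a Euclidean disk structuring element
disk_offsets <- function(r) {
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= r^2, , drop = FALSE]
}

# shift a numeric matrix, padding with `fill`
shift_numeric <- function(x, dr, dc, fill = 0) {
  n <- nrow(x); m <- ncol(x)
  out <- matrix(fill, n, m)
  rs <- seq_len(n) - dr; cs <- seq_len(m) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
  out[ok_r, ok_c] <- x[rs[ok_r], cs[ok_c]]
  out
}

# shift a logical matrix, padding with `fill`
shift_logical <- function(mask, dr, dc, fill = FALSE) {
  n <- nrow(mask); m <- ncol(mask)
  out <- matrix(fill, n, m)
  rs <- seq_len(n) - dr; cs <- seq_len(m) - dc
  ok_r <- rs >= 1 & rs <= n; ok_c <- cs >= 1 & cs <= m
  out[ok_r, ok_c] <- mask[rs[ok_r], cs[ok_c]]
  out
}

#' Binary dilation and erosion with a disk
#'
#' @param mask Logical matrix (foreground = TRUE).
#' @param radius Disk radius in pixels.
#' @return The dilated / eroded logical matrix.
#' @export
dilate_disk <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out | shift_logical(mask, off$dr[i], off$dc[i], FALSE)
  out
}

#' @rdname dilate_disk
#' @export
erode_disk <- function(mask, radius) {
  off <- disk_offsets(radius)
  out <- matrix(TRUE, nrow(mask), ncol(mask))
  for (i in seq_len(nrow(off)))
    out <- out & shift_logical(mask, off$dr[i], off$dc[i], FALSE)
  out
}

# 3-4 chamfer distance transform: distance of each TRUE pixel to the
# nearest FALSE pixel (image border counts as background), scaled to ~pixels
chamfer_distance <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  big <- 3 * (n + m) + 10
  d <- matrix(0, n, m)
  d[mask] <- big
  # forward pass
  for (i in seq_len(n)) for (j in seq_len(m)) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i > 1) {
      v <- min(v, d[i - 1, j] + 3)
      if (j > 1) v <- min(v, d[i - 1, j - 1] + 4)
      if (j < m) v <- min(v, d[i - 1, j + 1] + 4)
    } else v <- min(v, 3)
    if (j > 1) v <- min(v, d[i, j - 1] + 3) else v <- min(v, 3)
    if (i == n) v <- min(v, 3)
    if (j == m) v <- min(v, 3)
    d[i, j] <- v
  }
  # backward pass
  for (i in n:1) for (j in m:1) {
    if (d[i, j] == 0) next
    v <- d[i, j]
    if (i < n) {
      v <- min(v, d[i + 1, j] + 3)
      if (j > 1) v <- min(v, d[i + 1, j - 1] + 4)
      if (j < m) v <- min(v, d[i + 1, j + 1] + 4)
    }
    if (j < m) v <- min(v, d[i, j + 1] + 3)
    d[i, j] <- v
  }
  d / 3
}

# 8-connected component labeling of a logical mask (flood fill)
label_components <- function(mask) {
  n <- nrow(mask); m <- ncol(mask)
  lab <- matrix(0L, n, m)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    stack <- p
    lab[p] <- cur
    while (length(stack)) {
      q <- stack[length(stack)]
      stack <- stack[-length(stack)]
      qi <- (q - 1L) %% n + 1L
      qj <- (q - 1L) %/% n + 1L
      for (dr in -1:1) for (dc in -1:1) {
        ri <- qi + dr; rj <- qj + dc
        if (ri < 1 || ri > n || rj < 1 || rj > m) next
        rp <- (rj - 1L) * n + ri
        if (mask[rp] && lab[rp] == 0L) {
          lab[rp] <- cur
          stack <- c(stack, rp)
        }
      }
    }
  }
  lab
}

# watershed markers: regional-maximum plateau components of the distance
# transform, one seed each, filtered per component so seeds keep a minimum
# separation
find_markers <- function(dt, comp, min_separation) {
  n <- nrow(dt); m <- ncol(dt)
  fg <- dt > 0
  nb_max <- matrix(-Inf, n, m)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    sh <- shift_numeric(dt, dr, dc, -Inf)
    nb_max <- pmax(nb_max, sh)
  }
  cand <- fg & (dt >= nb_max)
  plats <- label_components(cand)
  seeds <- data.frame(row = integer(0), col = integer(0),
                      dt = numeric(0), comp = integer(0))
  for (k in seq_len(max(plats, 0))) {
    pp <- which(plats == k)
    best <- pp[which.max(dt[pp])]
    seeds <- rbind(seeds, data.frame(
      row = (best - 1L) %% n + 1L, col = (best - 1L) %/% n + 1L,
      dt = dt[best], comp = comp[best]))
  }
  # per-component greedy min-separation filter, strongest seeds first
  keep <- logical(nrow(seeds))
  for (cc in unique(seeds$comp)) {
    si <- which(seeds$comp == cc)
    si <- si[order(-seeds$dt[si])]
    kept <- integer(0)
    for (s in si) {
      if (!length(kept) ||
          all((seeds$row[s] - seeds$row[kept])^2 +
              (seeds$col[s] - seeds$col[kept])^2 >= min_separation^2)) {
        kept <- c(kept, s)
        keep[s] <- TRUE
      }
    }
  }
  seeds[keep, , drop = FALSE]
}

# marker-based watershed on the distance transform: flood foreground
# pixels in decreasing-distance order from the seeds
watershed_labels <- function(dt, seeds) {
  n <- nrow(dt); m <- ncol(dt)
  lab <- matrix(0L, n, m)
  for (s in seq_len(nrow(seeds)))
    lab[seeds$row[s], seeds$col[s]] <- s
  fg <- which(dt > 0)
  fg <- fg[order(-dt[fg])]
  repeat {
    changed <- FALSE
    for (p in fg) {
      if (lab[p] != 0L) next
      qi <- (p - 1L) %% n + 1L
      qj <- (p - 1L) %/% n + 1L
      best_lab <- 0L; best_dt <- -1
      for (dr in -1:1) for (dc in -1:1) {
        ri <- qi + dr; rj <- qj + dc
        if (ri < 1 || ri > n || rj < 1 || rj > m) next
        if (lab[ri, rj] > 0L && dt[ri, rj] > best_dt) {
          best_dt <- dt[ri, rj]
          best_lab <- lab[ri, rj]
        }
      }
      if (best_lab > 0L) {
        lab[p] <- best_lab
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  lab
}

# Moore-neighbour boundary trace of one label, clockwise from the
# topmost-leftmost rim pixel; returns a data.frame(row, col)
trace_boundary <- function(lab, k) {
  n <- nrow(lab); m <- ncol(lab)
  inside <- function(i, j) i >= 1 && i <= n && j >= 1 && j <= m && lab[i, j] == k
  idx <- which(lab == k)
  if (!length(idx)) return(NULL)
  # row-major topmost-leftmost: minimize row then col
  ri <- (idx - 1L) %% n + 1L
  ci <- (idx - 1L) %/% n + 1L
  o <- order(ri, ci)[1]
  s <- c(ri[o], ci[o])
  # clockwise neighbourhood starting W
  dirs <- matrix(c(0, -1, -1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1),
                 ncol = 2, byrow = TRUE)
  if (length(idx) == 1L)
    return(data.frame(row = s[1], col = s[2]))
  dir_index <- function(delta)
    which(dirs[, 1] == delta[1] & dirs[, 2] == delta[2])
  path <- list(s)
  cur <- s
  b <- s + c(0, -1)   # backtrack W of start (outside: s is leftmost on top row)
  b0 <- b
  max_steps <- 8L * length(idx) + 8L
  steps <- 0L
  repeat {
    start_dir <- dir_index(b - cur)
    found <- FALSE
    for (t in 1:8) {
      di <- ((start_dir - 1L + t) %% 8L) + 1L
      ni <- cur[1] + dirs[di, 1]; nj <- cur[2] + dirs[di, 2]
      if (inside(ni, nj)) {
        prev <- ((di - 2L) %% 8L) + 1L
        b <- cur + dirs[prev, ]
        cur <- c(ni, nj)
        found <- TRUE
        break
      }
    }
    steps <- steps + 1L
    if (!found || steps >= max_steps) break
    if (cur[1] == s[1] && cur[2] == s[2] &&
        b[1] == b0[1] && b[2] == b0[2]) break   # Jacob's stopping criterion
    path[[length(path) + 1L]] <- cur
  }
  df <- do.call(rbind, path)
  data.frame(row = df[, 1], col = df[, 2])
}

#' Threshold, dilate and watershed-segment nodules in a grayscale image
#'
#' The segmentation chain: global threshold (Otsu by default), disk
#' dilation to close gaps and holes followed by an erosion of equal radius
#' (so regions do not grow on net), a chamfer distance transform,
#' marker-based watershed flooding to split touching nodules, consecutive
#' relabeling, and a clockwise 8-connected boundary trace per region.
#'
#' @param image Numeric matrix.
#' @param threshold `"otsu"` or a fixed numeric threshold.
#' @param dilation_radius Disk radius of the morphological gap-filling
#'   step, also the minimum marker separation.
#' @return A list of class `igwo_segmentation` with `labels` (integer
#'   matrix, 0 = background), `boundaries` (list of per-label
#'   `data.frame(row, col)` traces, 1-based coordinates), and
#'   `region_count`.
#' @export
segment_nodules <- function(image, threshold = "otsu", dilation_radius = 2L) {
  thr <- if (identical(threshold, "otsu")) otsu_threshold(image)
         else as.numeric(threshold)
  bin <- image > thr
  if (!any(bin))
    return(structure(list(labels = matrix(0L, nrow(image), ncol(image)),
                          boundaries = list(), region_count = 0L),
                     class = "igwo_segmentation"))
  if (dilation_radius > 0)
    bin <- erode_disk(dilate_disk(bin, dilation_radius), dilation_radius)
  comp <- label_components(bin)
  dt <- chamfer_distance(bin)
  seeds <- find_markers(dt, comp, max(dilation_radius, 1L))
  lab <- watershed_labels(dt, seeds)
  # consecutive labels in first-encounter order
  olds <- sort(unique(lab[lab > 0]))
  relab <- matrix(0L, nrow(lab), ncol(lab))
  if (length(olds)) {
    firsts <- match(olds, as.vector(lab))
    for (new_k in seq_along(olds)) {
      old <- olds[order(firsts)][new_k]
      relab[lab == old] <- new_k
    }
  }
  boundaries <- lapply(seq_len(max(relab, 0)),
                       function(k) trace_boundary(relab, k))
  structure(list(labels = relab, boundaries = boundaries,
                 region_count = max(relab, 0L)),
            class = "igwo_segmentation")
}

#' Read and write plain-text PGM images
#'
#' ASCII (P2) portable graymap support, the plain-text image format used by
#' the command line interface and test fixtures.
#'
#' @param path File path.
#' @param image Numeric matrix (values rounded to integers on write).
#' @param max_value Declared maximum intensity.
#' @return `read_pgm` returns a numeric matrix; `write_pgm` returns the
#'   path invisibly.
#' @export
read_pgm <- function(path) {
  txt <- readLines(path)
  txt <- txt[!grepl("^#", txt)]
  tokens <- scan(text = paste(txt, collapse = " "), what = character(),
                 quiet = TRUE)
  if (tokens[1] != "P2") stop("read_pgm: only ASCII (P2) PGM is supported")
  vals <- as.numeric(tokens[-1])
  w <- vals[1]; h <- vals[2]
  px <- vals[-(1:3)]
  if (length(px) != w * h) stop("read_pgm: pixel count mismatch")
  # PGM is row-major top-to-bottom
  matrix(px, nrow = h, ncol = w, byrow = TRUE)
}

#' @rdname read_pgm
#' @export
write_pgm <- function(image, path, max_value = 255) {
  px <- round(pmin(pmax(image, 0), max_value))
  lines <- c("P2", paste(ncol(image), nrow(image)), as.character(max_value),
             apply(px, 1L, paste, collapse = " "))
  writeLines(lines, path)
  invisible(path)
}
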