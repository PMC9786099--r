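#' Linear coefficient schedule
#'
#' The grey wolf pack's exploration parameter `a` decays linearly from 2 at
#' the first iteration to 0 at the last, shrinking the radius within which
#' wolves encircle the incumbent leaders.
#'
#' @param t Current iteration index, `0 <= t <= T`.
#' @param T Iteration budget, `T >= 1`.
#' @return The scalar `a = 2 - 2 t / T`, in `[0, 2]`.
#' @export
#' @examples
#' coefficient_schedule(0, 100)   # 2
#' coefficient_schedule(50, 100)  # 1
coefficient_schedule <- function(t, T) {
  if (!is.numeric(t) || !is.numeric(T) || length(t) != 1L || length(T) != 1L)
    stop("coefficient_schedule: t and T must be numeric scalars")
  if (T < 1) stop("coefficient_schedule: iteration budget T must be >= 1")
  if (t < 0 || t > T) stop("coefficient_schedule: t must satisfy 0 <= t <= T")
  2 - 2 * t / T
}

#' Draw the stochastic encircling coefficients
#'
#' Each leader term of the position update uses a fresh pair of coefficient
#' vectors: `A = 2 a r1 - a` with components in `[-a, a]` and `C = 2 r2`
#' with components in `[0, 2)`, where `r1`, `r2` are uniform on `[0, 1)`.
#' Draws consume the session RNG stream; seed with [set.seed()] for
#' reproducibility.
#'
#' @param a Schedule scalar in `[0, 2]`.
#' @param dimensionality Number of search dimensions.
#' @return A list with numeric vectors `A` and `C`.
#' @export
draw_coefficients <- function(a, dimensionality) {
  if (!is.numeric(a) || length(a) != 1L || a < 0 || a > 2)
    stop("draw_coefficients: a must lie in [0, 2]")
  r1 <- stats::runif(dimensionality)
  r2 <- stats::runif(dimensionality)
  list(A = 2 * a * r1 - a, C = 2 * r2)
}

#' Leader-guided position update
#'
#' Moves one wolf toward the consensus of the three pack leaders. For each
#' leader k in (alpha, beta, delta) the encircling displacement is
#' `D_k = |C_k * X_k - X|` and the candidate position `X_k' = X_k - A_k * D_k`;
#' the new position is the componentwise mean of the three candidates,
#' clamped to the search box.
#'
#' @param position Numeric vector, the wolf's current position.
#' @param leaders A leader triplet as returned by [select_leaders()], or any
#'   list with `alpha_position`, `beta_position`, `delta_position`.
#' @param a Schedule scalar in `[0, 2]` controlling the `A` draw.
#' @param domain_low,domain_high Box bounds (scalars or per-dimension vectors).
#' @param coef Optional list of three precomputed `list(A=, C=)` pairs (in
#'   alpha, beta, delta order); when `NULL` fresh pairs are drawn per leader.
#'   Exposing the draws keeps the deterministic update step testable against
#'   a straight-line transcription.
#' @return The clamped updated position vector.
#' @export
leader_guided_update <- function(position, leaders, a,
                                 domain_low = 0, domain_high = 1,
                                 coef = NULL) {
  d <- length(position)
  lead_pos <- list(leaders$alpha_position, leaders$beta_position,
                   leaders$delta_position)
  for (lp in lead_pos)
    if (length(lp) != d)
      stop("leader_guided_update: dimensionality mismatch between position and leaders")
  acc <- numeric(d)
  for (k in 1:3) {
    ck <- if (is.null(coef)) draw_coefficients(a, d) else coef[[k]]
    Dk <- abs(ck$C * lead_pos[[k]] - position)
    acc <- acc + (lead_pos[[k]] - ck$A * Dk)
  }
  pmin(pmax(acc / 3, domain_low), domain_high)
}

#' Optimizer configuration
#'
#' Collects every tunable of the IGWO family in one validated list. The
#' defaults mirror the reference hyper-parameter table: population size 8,
#' 100 iterations, unit search box, crossover probability 0.8, per-bit
#' mutation probability 0.01, and fitness weight `alpha = 0.99` (so the
#' subset-size term carries weight `beta = 0.01`).
#'
#' @param population_size Number of wolves (>= 3; three leaders are needed).
#' @param iterations Iteration budget of the main loop.
#' @param dimensionality Number of search dimensions.
#' @param domain_low,domain_high Per-dimension box bounds (recycled scalars ok).
#' @param orientation `"maximize"` (accuracy, PSNR) or `"minimize"`
#'   (benchmark objectives).
#' @param seed Integer seed; every run seeds the session RNG with it.
#' @param sharing_radius Fitness-sharing radius `sigma_s`; `"auto"` resolves
#'   to `0.1 * sqrt(dimensionality)`, `"off"` disables niching.
#' @param ga_crossover_prob,ga_mutation_prob,ga_generations,bits_per_dimension
#'   Genetic-algorithm seeding controls; `ga_generations = 0` decodes a
#'   purely random chromosome population.
#' @param use_ga_seeding Logical; `FALSE` starts from uniform random
#'   positions (the plain-GWO variant).
#' @param fitness_alpha Accuracy weight of the subset fitness.
#' @param k_folds,cv_repeats Cross-validation layout used when reporting the
#'   final accuracy of a selected subset.
#' @param verbose Logical; print a per-iteration progress line.
#' @return A list of class `igwo_config`.
#' @export
optimizer_config <- function(population_size = 8L,
                             iterations = 100L,
                             dimensionality = 2L,
                             domain_low = 0, domain_high = 1,
                             orientation = c("maximize", "minimize"),
                             seed = 0L,
                             sharing_radius = "auto",
                             ga_crossover_prob = 0.8,
                             ga_mutation_prob = 0.01,
                             ga_generations = 20L,
                             bits_per_dimension = 8L,
                             use_ga_seeding = TRUE,
                             fitness_alpha = 0.99,
                             k_folds = 10L,
                             cv_repeats = 10L,
                             verbose = FALSE) {
  orientation <- match.arg(orientation)
  if (population_size < 3)
    stop("optimizer_config: population_size must be >= 3 (alpha, beta, delta)")
  if (iterations < 1) stop("optimizer_config: iterations must be >= 1")
  if (dimensionality < 1) stop("optimizer_config: dimensionality must be >= 1")
  lo <- rep_len(domain_low, dimensionality)
  hi <- rep_len(domain_high, dimensionality)
  if (any(lo >= hi))
    stop("optimizer_config: domain_low must be < domain_high in every dimension")
  for (p in c(ga_crossover_prob = ga_crossover_prob,
              ga_mutation_prob = ga_mutation_prob,
              fitness_alpha = fitness_alpha))
    if (p < 0 || p > 1)
      stop("optimizer_config: probabilities and fitness_alpha must lie in [0, 1]")
  if (!identical(sharing_radius, "off") && !identical(sharing_radius, "auto")) {
    if (!is.numeric(sharing_radius) || sharing_radius <= 0)
      stop("optimizer_config: sharing_radius must be positive, \"auto\" or \"off\"")
  }
  structure(list(
    population_size = as.integer(population_size),
    iterations = as.integer(iterations),
    dimensionality = as.integer(dimensionality),
    domain_low = lo, domain_high = hi,
    orientation = orientation,
    seed = as.integer(seed),
    sharing_radius = sharing_radius,
    ga_crossover_prob = ga_crossover_prob,
    ga_mutation_prob = ga_mutation_prob,
    ga_generations = as.integer(ga_generations),
    bits_per_dimension = as.integer(bits_per_dimension),
    use_ga_seeding = isTRUE(use_ga_seeding),
    fitness_alpha = fitness_alpha,
    k_folds = as.integer(k_folds),
    cv_repeats = as.integer(cv_repeats),
    verbose = isTRUE(verbose)
  ), class = "igwo_config")
}

# Resolve the sharing radius to a number, or NA when niching is off.
resolve_sharing_radius <- function(config) {
  sr <- config$sharing_radius
  if (identical(sr, "off")) return(NA_real_)
  if (identical(sr, "auto")) return(0.1 * sqrt(config$dimensionality))
  as.numeric(sr)
}

# TRUE when fitness fa beats fb under the orientation; ties are not better.
fitness_beats <- function(fa, fb, orientation) {
  if (orientation == "maximize") fa > fb else fa < fb
}

#' Run the continuous grey wolf optimizer
#'
#' The canonical pack loop: evaluate all wolves, rank alpha/beta/delta,
#' then for each iteration update every wolf via [leader_guided_update()]
#' with the shrinking schedule from [coefficient_schedule()], re-evaluate,
#' and re-rank. When the configuration enables fitness sharing, leader
#' ranking uses shared fitness while the best-so-far record always tracks
#' raw fitness.
#'
#' @param objective Function mapping a position vector to a finite scalar.
#' @param config An [optimizer_config()].
#' @param initial_positions Optional numeric matrix
#'   (`population_size x dimensionality`) of starting positions; when `NULL`
#'   wolves start uniformly at random in the box.
#' @return A list of class `igwo_result` with `best_position`,
#'   `best_fitness`, `history` (per-iteration best-so-far raw fitness,
#'   length `iterations`) and `evaluations`.
#' @export
#' @examples
#' cfg <- optimizer_config(dimensionality = 2, domain_low = -1, domain_high = 1,
#'                         orientation = "minimize", seed = 1,
#'                         use_ga_seeding = FALSE, sharing_radius = "off")
#' res <- run_gwo(function(x) sum(x^2), cfg)
#' res$best_fitness
run_gwo <- function(objective, config, initial_positions = NULL) {
  n <- config$population_size
  d <- config$dimensionality
  Tmax <- config$iterations
  set.seed(config$seed)
  if (is.null(initial_positions)) {
    pos <- matrix(stats::runif(n * d, rep(config$domain_low, each = n),
                               rep(config$domain_high, each = n)),
                  nrow = n, ncol = d)
  } else {
    if (!is.matrix(initial_positions) ||
        nrow(initial_positions) != n || ncol(initial_positions) != d)
      stop("run_gwo: initial_positions must be a population_size x dimensionality matrix")
    pos <- initial_positions
  }
  eval_one <- function(x) {
    f <- objective(x)
    if (!is.numeric(f) || length(f) != 1L || is.na(f) || !is.finite(f))
      stop("run_gwo: objective returned a non-finite value")
    f
  }
  fit <- apply(pos, 1L, eval_one)
  evals <- n
  sigma <- resolve_sharing_radius(config)

  rank_leaders <- function(pos, fit) {
    shared <- if (is.na(sigma)) fit else {
      m <- niche_counts(pos, sigma)
      if (config$orientation == "maximize") fit / m else fit * m
    }
    select_leaders(pos, fit, shared, config$orientation)
  }

  leaders <- rank_leaders(pos, fit)
  ib <- if (config$orientation == "maximize") which.max(fit) else which.min(fit)
  best_pos <- pos[ib, ]
  best_fit <- fit[ib]
  history <- numeric(Tmax)

  for (t in seq_len(Tmax)) {
    a <- coefficient_schedule(t, Tmax)
    for (i in seq_len(n)) {
      pos[i, ] <- leader_guided_update(pos[i, ], leaders, a,
                                       config$domain_low, config$domain_high)
    }
    fit <- apply(pos, 1L, eval_one)
    evals <- evals + n
    ib <- if (config$orientation == "maximize") which.max(fit) else which.min(fit)
    if (fitness_beats(fit[ib], best_fit, config$orientation)) {
      best_fit <- fit[ib]
      best_pos <- pos[ib, ]
    }
    leaders <- rank_leaders(pos, fit)
    history[t] <- best_fit
    if (config$verbose)
      cat(sprintf("iter %d  best %.6g  a %.3f\n", t, best_fit, a))
  }

  structure(list(best_position = best_pos, best_fitness = best_fit,
                 history = history, evaluations = evals),
            class = "igwo_result")
}

#' @export
print.igwo_result <- function(x, ...) {
  cat("Grey wolf optimization result\n")
  cat(sprintf("  best fitness: %.6g after %d evaluations\n",
              x$best_fitness, x$evaluations))
  cat(sprintf("  dimensionality: %d, iterations: %d\n",
              length(x$best_position), length(x$history)))
  invisible(x)
}
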