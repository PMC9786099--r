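#' Stochastic binarization of a position into a flag vector
#'
#' Each component of a position in the unit box becomes a feature flag:
#' `flag_j = 1` iff `position_j > u_j` with fresh uniform thresholds
#' `u_j ~ U[0, 1)` per component per call. A coordinate near 1 is almost
#' always selected, near 0 almost never.
#'
#' @param position Numeric vector with components in `[0, 1]`.
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_position <- function(position) {
  if (any(position < 0 | position > 1))
    stop("binarize_position: position components must lie in [0, 1] (missing clamp upstream?)")
  as.integer(position > stats::runif(length(position)))
}

#' Accuracy-versus-size subset fitness
#'
#' The wrapper-selection objective `alpha * P + (1 - alpha) * (N - L) / N`:
#' a convex combination of the classifier accuracy `P` and the fraction of
#' features discarded. With the default `alpha = 0.99` accuracy dominates
#' and the size term breaks ties toward smaller subsets.
#'
#' @param P Classification accuracy in `[0, 1]`.
#' @param N Total number of features.
#' @param L Number of selected features, `1 <= L <= N`.
#' @param alpha Accuracy weight in `[0, 1]`.
#' @return The scalar fitness (maximization orientation).
#' @export
subset_fitness <- function(P, N, L, alpha = 0.99) {
  if (alpha < 0 || alpha > 1) stop("subset_fitness: alpha must lie in [0, 1]")
  if (L > N) stop("subset_fitness: L cannot exceed N")
  if (L < 1) stop("subset_fitness: empty subset (L = 0) is not admissible")
  alpha * P + (1 - alpha) * (N - L) / N
}

# evaluator with memoization on the flag pattern; wrapper loops revisit
# the same subsets often
make_cached_evaluator <- function(evaluator) {
  force(evaluator)   # callers rebind the same name; do not capture lazily
  cache <- new.env(parent = emptyenv())
  function(flags) {
    key <- paste(flags, collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- evaluator(flags)
    cache[[key]] <- val
    val
  }
}

#' IGWO wrapper feature selection
#'
#' The full improved-grey-wolf selection loop: a genetic algorithm seeds
#' the wolves' continuous positions in the unit box (unless disabled), each
#' iteration every position is stochastically binarized into a flag vector,
#' scored by `subset_fitness` with the evaluator's accuracy, fitness
#' sharing on the continuous positions re-ranks the pack before the alpha,
#' beta and delta leaders steer the update, and the best subset by raw
#' fitness is returned. An agent whose flags come out all-zero receives the
#' worst possible fitness instead of an evaluator call.
#'
#' @param dataset A [labeled_dataset()] with >= 2 classes and >= 2 features.
#' @param evaluator Function mapping a flag vector to an accuracy in
#'   `[0, 1]`; defaults to the built-in leave-one-out nearest-neighbour
#'   evaluator ([knn_evaluate()]).
#' @param config An [optimizer_config()] whose dimensionality is forced to
#'   the feature count; `use_ga_seeding` and `sharing_radius` select the
#'   IGWO / plain-GWO variants.
#' @param final_cv Logical; when `TRUE` the returned accuracy is re-measured
#'   by repeated stratified k-fold cross-validation
#'   ([repeated_kfold_accuracy()]) on the best subset.
#' @return A list of class `igwo_selection` with `best_flags`,
#'   `best_fitness`, `best_accuracy`, `selected_feature_names`, `history`
#'   (per-iteration best-so-far fitness), `evaluations`, `cv_accuracy`
#'   (when `final_cv`) and the `config` used.
#' @export
run_igwo_selection <- function(dataset, evaluator = NULL, config = NULL,
                               final_cv = FALSE) {
  N <- ncol(dataset$features)
  if (N < 2) stop("run_igwo_selection: need at least 2 features")
  if (is.null(config)) config <- optimizer_config(dimensionality = N)
  if (config$dimensionality != N) {
    config$dimensionality <- N
    config$domain_low <- rep_len(0, N)
    config$domain_high <- rep_len(1, N)
  }
  if (is.null(evaluator))
    evaluator <- function(flags) knn_evaluate(dataset, flags)
  evaluator <- make_cached_evaluator(evaluator)
  alpha_w <- config$fitness_alpha
  n <- config$population_size
  Tmax <- config$iterations
  set.seed(config$seed)

  score_flags <- function(flags) {
    L <- sum(flags)
    if (L == 0) return(list(fitness = -Inf, accuracy = NA_real_))
    P <- evaluator(flags)
    list(fitness = subset_fitness(P, N, L, alpha_w), accuracy = P)
  }

  pos <- if (config$use_ga_seeding) {
    ga_cfg <- config
    ga_cfg$orientation <- "maximize"
    generate_initial_population(function(x) {
      flags <- binarize_position(pmin(pmax(x, 0), 1))
      score_flags(flags)$fitness
    }, ga_cfg)
  } else {
    matrix(stats::runif(n * N), nrow = n, ncol = N)
  }

  sigma <- resolve_sharing_radius(config)
  evals <- 0L
  best_fit <- -Inf
  best_flags <- NULL
  best_acc <- NA_real_
  history <- numeric(Tmax)

  evaluate_pack <- function(pos) {
    flags <- matrix(0L, nrow = n, ncol = N)
    fit <- numeric(n)
    acc <- numeric(n)
    for (i in seq_len(n)) {
      flags[i, ] <- binarize_position(pos[i, ])
      s <- score_flags(flags[i, ])
      fit[i] <- s$fitness
      acc[i] <- s$accuracy
    }
    list(flags = flags, fit = fit, acc = acc)
  }

  pack <- evaluate_pack(pos)
  evals <- evals + n
  record_best <- function(pack) {
    ib <- which.max(pack$fit)
    if (length(ib) && pack$fit[ib] > best_fit) {
      best_fit <<- pack$fit[ib]
      best_flags <<- pack$flags[ib, ]
      best_acc <<- pack$acc[ib]
    }
  }
  record_best(pack)
  rank_leaders <- function(pos, fit) {
    shared <- if (is.na(sigma)) fit else fit / niche_counts(pos, sigma)
    select_leaders(pos, fit, shared, "maximize")
  }
  leaders <- rank_leaders(pos, pack$fit)

  for (t in seq_len(Tmax)) {
    a <- coefficient_schedule(t, Tmax)
    for (i in seq_len(n))
      pos[i, ] <- leader_guided_update(pos[i, ], leaders, a, 0, 1)
    pack <- evaluate_pack(pos)
    evals <- evals + n
    record_best(pack)
    leaders <- rank_leaders(pos, pack$fit)
    history[t] <- best_fit
    if (config$verbose)
      cat(sprintf("iter %d  best fitness %.5f  L %d  a %.3f\n",
                  t, best_fit, sum(best_flags), a))
  }

  res <- structure(list(
    best_flags = best_flags,
    best_fitness = best_fit,
    best_accuracy = best_acc,
    selected_feature_names = dataset$feature_names[best_flags == 1L],
    history = history,
    evaluations = evals,
    config = config
  ), class = "igwo_selection")
  if (final_cv) {
    cv <- repeated_kfold_accuracy(dataset, best_flags,
                                  k_folds = config$k_folds,
                                  repeats = config$cv_repeats,
                                  seed = config$seed)
    res$cv_accuracy <- cv$mean_accuracy
    res$cv_per_repeat <- cv$per_repeat
  }
  res
}

#' @export
print.igwo_selection <- function(x, ...) {
  N <- length(x$best_flags)
  L <- sum(x$best_flags)
  cat("IGWO feature selection result\n")
  cat(sprintf("  fitness %.5f  accuracy %.4f  selected %d of %d features\n",
              x$best_fitness, x$best_accuracy, L, N))
  if (!is.null(x$cv_accuracy))
    cat(sprintf("  repeated-CV accuracy %.4f\n", x$cv_accuracy))
  cat("  features:", paste(x$selected_feature_names, collapse = ", "), "\n")
  invisible(x)
}

#' Genetic-algorithm feature selection baseline
#'
#' Evolves flag vectors directly as binary chromosomes under the same
#' subset fitness: roulette selection, single-point crossover, bit-flip
#' mutation, one elite per generation. Serves as the GA arm of the variant
#' comparison.
#'
#' @inheritParams run_igwo_selection
#' @return A list shaped like [run_igwo_selection()] output (class
#'   `igwo_selection`).
#' @export
run_ga_selection <- function(dataset, evaluator = NULL, config = NULL) {
  N <- ncol(dataset$features)
  if (is.null(config)) config <- optimizer_config(dimensionality = N)
  if (is.null(evaluator))
    evaluator <- function(flags) knn_evaluate(dataset, flags)
  evaluator <- make_cached_evaluator(evaluator)
  alpha_w <- config$fitness_alpha
  n <- config$population_size
  gens <- config$iterations
  set.seed(config$seed)

  score <- function(flags) {
    L <- sum(flags)
    if (L == 0) return(list(fitness = -Inf, accuracy = NA_real_))
    P <- evaluator(flags)
    list(fitness = subset_fitness(P, N, L, alpha_w), accuracy = P)
  }
  chrom <- matrix(as.integer(stats::runif(n * N) < 0.5), nrow = n)
  sc <- apply(chrom, 1L, score)
  fit <- vapply(sc, `[[`, numeric(1), "fitness")
  acc <- vapply(sc, `[[`, numeric(1), "accuracy")
  evals <- n
  best_i <- which.max(fit)
  best <- list(flags = chrom[best_i, ], fitness = fit[best_i],
               accuracy = acc[best_i])
  history <- numeric(gens)
  for (g in seq_len(gens)) {
    finite <- is.finite(fit)
    mass <- fit - min(fit[finite], 0) + 1e-9
    mass[!finite] <- 1e-9
    nxt <- matrix(0L, nrow = n, ncol = N)
    nxt[1L, ] <- best$flags
    filled <- 1L
    while (filled < n) {
      pa <- chrom[roulette_select(mass), ]
      pb <- chrom[roulette_select(mass), ]
      kids <- single_point_crossover(pa, pb, config$ga_crossover_prob)
      filled <- filled + 1L
      nxt[filled, ] <- bit_flip_mutation(kids$child_a, config$ga_mutation_prob)
      if (filled < n) {
        filled <- filled + 1L
        nxt[filled, ] <- bit_flip_mutation(kids$child_b, config$ga_mutation_prob)
      }
    }
    chrom <- nxt
    sc <- apply(chrom, 1L, score)
    fit <- vapply(sc, `[[`, numeric(1), "fitness")
    acc <- vapply(sc, `[[`, numeric(1), "accuracy")
    evals <- evals + n
    ib <- which.max(fit)
    if (fit[ib] > best$fitness)
      best <- list(flags = chrom[ib, ], fitness = fit[ib], accuracy = acc[ib])
    history[g] <- best$fitness
  }
  structure(list(best_flags = best$flags, best_fitness = best$fitness,
                 best_accuracy = best$accuracy,
                 selected_feature_names = dataset$feature_names[best$flags == 1L],
                 history = history, evaluations = evals, config = config),
            class = "igwo_selection")
}

#' Random-subset selection baseline
#'
#' Draws flag vectors uniformly at random (each feature included with
#' probability 1/2, empty draws penalized like everywhere else) for the
#' same evaluation budget as an optimizer run, and keeps the best. The
#' floor any wrapper method must beat.
#'
#' @inheritParams run_igwo_selection
#' @param budget Number of subset evaluations; defaults to
#'   `population_size * (iterations + 1)` to match [run_igwo_selection()].
#' @return A list shaped like [run_igwo_selection()] output.
#' @export
run_random_selection <- function(dataset, evaluator = NULL, config = NULL,
                                 budget = NULL) {
  N <- ncol(dataset$features)
  if (is.null(config)) config <- optimizer_config(dimensionality = N)
  if (is.null(evaluator))
    evaluator <- function(flags) knn_evaluate(dataset, flags)
  evaluator <- make_cached_evaluator(evaluator)
  if (is.null(budget))
    budget <- config$population_size * (config$iterations + 1L)
  set.seed(config$seed)
  best <- list(flags = NULL, fitness = -Inf, accuracy = NA_real_)
  history <- numeric(budget)
  for (b in seq_len(budget)) {
    flags <- as.integer(stats::runif(N) < 0.5)
    if (sum(flags) == 0) {
      history[b] <- best$fitness
      next
    }
    P <- evaluator(flags)
    f <- subset_fitness(P, N, sum(flags), config$fitness_alpha)
    if (f > best$fitness)
      best <- list(flags = flags, fitness = f, accuracy = P)
    history[b] <- best$fitness
  }
  structure(list(best_flags = best$flags, best_fitness = best$fitness,
                 best_accuracy = best$accuracy,
                 selected_feature_names =
                   dataset$feature_names[best$flags == 1L],
                 history = history, evaluations = budget, config = config),
            class = "igwo_selection")
}
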