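#' Roulette-wheel selection
#'
#' Samples an index with probability proportional to fitness mass. Requires
#' nonnegative fitnesses with at least one strictly positive entry; callers
#' optimizing a cost transform to nonnegative mass first (see
#' [generate_initial_population()]).
#'
#' @param fitnesses Numeric vector of nonnegative selection masses.
#' @return A 1-based index.
#' @export
roulette_select <- function(fitnesses) {
  if (any(fitnesses < 0)) stop("roulette_select: fitnesses must be nonnegative")
  total <- sum(fitnesses)
  if (total <= 0) stop("roulette_select: all-zero fitness mass")
  u <- stats::runif(1) * total
  findInterval(u, cumsum(fitnesses), left.open = TRUE) + 1L
}

#' Single-point crossover
#'
#' With probability `crossover_prob` a cut point is drawn uniformly from the
#' interior of the chromosome and the tails are swapped; otherwise the
#' children are copies of the parents.
#'
#' @param parent_a,parent_b Binary integer vectors of equal length >= 2.
#' @param crossover_prob Probability that crossover happens at all.
#' @return A list with `child_a` and `child_b`.
#' @export
single_point_crossover <- function(parent_a, parent_b, crossover_prob = 0.8) {
  L <- length(parent_a)
  if (length(parent_b) != L)
    stop("single_point_crossover: parent length mismatch")
  if (L < 2) stop("single_point_crossover: chromosomes must have length >= 2")
  if (stats::runif(1) < crossover_prob) {
    k <- sample.int(L - 1L, 1L)
    list(child_a = c(parent_a[seq_len(k)], parent_b[(k + 1L):L]),
         child_b = c(parent_b[seq_len(k)], parent_a[(k + 1L):L]))
  } else {
    list(child_a = parent_a, child_b = parent_b)
  }
}

#' Bit-flip mutation
#'
#' Flips each bit independently with probability `mutation_prob`.
#'
#' @param chromosome Binary integer vector.
#' @param mutation_prob Per-bit flip probability in `[0, 1]`.
#' @return The mutated chromosome.
#' @export
bit_flip_mutation <- function(chromosome, mutation_prob = 0.01) {
  if (mutation_prob < 0 || mutation_prob > 1)
    stop("bit_flip_mutation: mutation_prob must lie in [0, 1]")
  flip <- stats::runif(length(chromosome)) < mutation_prob
  out <- chromosome
  out[flip] <- 1L - out[flip]
  out
}

#' Decode a chromosome to a continuous position
#'
#' Consecutive blocks of `bits_per_dimension` bits are read as unsigned
#' big-endian integers `v` and mapped affinely onto the search box:
#' `low + v / (2^b - 1) * (high - low)`.
#'
#' @param chromosome Binary vector of length
#'   `dimensionality * bits_per_dimension`.
#' @param dimensionality Number of decoded coordinates.
#' @param bits_per_dimension Bits per coordinate.
#' @param domain_low,domain_high Box bounds (recycled per dimension).
#' @return Numeric position vector.
#' @export
decode_chromosome <- function(chromosome, dimensionality, bits_per_dimension,
                              domain_low = 0, domain_high = 1) {
  b <- bits_per_dimension
  if (length(chromosome) != dimensionality * b)
    stop("decode_chromosome: chromosome length must equal dimensionality * bits_per_dimension")
  lo <- rep_len(domain_low, dimensionality)
  hi <- rep_len(domain_high, dimensionality)
  weights <- 2^((b - 1L):0)
  blocks <- matrix(chromosome, nrow = b, ncol = dimensionality)
  v <- as.numeric(crossprod(blocks, weights))
  lo + v / (2^b - 1) * (hi - lo)
}

#' Genetic-algorithm seeding of the wolf population
#'
#' Evolves a binary chromosome population (roulette selection, single-point
#' crossover, per-bit mutation, one-elite generational replacement) for
#' `ga_generations` generations, scoring each chromosome by the objective at
#' its decoded position, and returns the final generation decoded to a
#' position matrix. With `ga_generations = 0` this is a decoded uniform
#' random population.
#'
#' @param objective Function mapping a position vector to a scalar fitness.
#' @param config An [optimizer_config()]; uses the population size, box,
#'   orientation and the `ga_*` / `bits_per_dimension` fields. The caller is
#'   responsible for seeding the RNG.
#' @return A `population_size x dimensionality` matrix of positions inside
#'   the box.
#' @export
generate_initial_population <- function(objective, config) {
  n <- config$population_size
  d <- config$dimensionality
  b <- config$bits_per_dimension
  L <- d * b
  maximize <- config$orientation == "maximize"

  chrom <- matrix(as.integer(stats::runif(n * L) < 0.5), nrow = n, ncol = L)
  decode <- function(bits)
    decode_chromosome(bits, d, b, config$domain_low, config$domain_high)
  score <- function(ch) apply(ch, 1L, function(bits) objective(decode(bits)))
  fit <- score(chrom)

  # roulette needs nonnegative mass favouring good chromosomes; infinite
  # penalty fitnesses (e.g. empty feature subsets) get zero-ish mass
  mass <- function(fit) {
    fin <- is.finite(fit)
    if (!any(fin)) return(rep(1, length(fit)))
    m <- if (maximize) fit - min(fit[fin]) else max(fit[fin]) - fit
    good_inf <- !fin & (if (maximize) fit > 0 else fit < 0)
    m[!fin] <- 0
    m[good_inf] <- max(m[fin]) + 1
    m + 1e-9
  }

  gens <- config$ga_generations
  if (gens > 0) {
    for (g in seq_len(gens)) {
      elite <- if (maximize) which.max(fit) else which.min(fit)
      nxt <- matrix(0L, nrow = n, ncol = L)
      nxt[1L, ] <- chrom[elite, ]
      filled <- 1L
      w <- mass(fit)
      while (filled < n) {
        pa <- chrom[roulette_select(w), ]
        pb <- chrom[roulette_select(w), ]
        kids <- single_point_crossover(pa, pb, config$ga_crossover_prob)
        ca <- bit_flip_mutation(kids$child_a, config$ga_mutation_prob)
        filled <- filled + 1L
        nxt[filled, ] <- ca
        if (filled < n) {
          cb <- bit_flip_mutation(kids$child_b, config$ga_mutation_prob)
          filled <- filled + 1L
          nxt[filled, ] <- cb
        }
      }
      chrom <- nxt
      fit <- score(chrom)
    }
  }

  pos <- apply(chrom, 1L, decode)          # d x n (or length-n when d == 1)
  matrix(t(pos), nrow = n, ncol = d)
}
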