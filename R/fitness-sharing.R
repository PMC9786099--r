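#' Triangular sharing kernel
#'
#' The niching kernel: full similarity at zero distance, decaying linearly
#' to zero at the similarity radius `sigma_s`, and exactly zero beyond it
#' (strict inequality at the boundary).
#'
#' @param d Nonnegative distance(s).
#' @param sigma_s Similarity radius, > 0.
#' @return Kernel value(s) in `[0, 1]`.
#' @export
sharing_kernel <- function(d, sigma_s) {
  if (any(d < 0)) stop("sharing_kernel: distances must be nonnegative")
  if (!is.numeric(sigma_s) || sigma_s <= 0)
    stop("sharing_kernel: sigma_s must be > 0")
  ifelse(d < sigma_s, 1 - d / sigma_s, 0)
}

#' Niche counts
#'
#' For each agent, the sum of the sharing kernel over the Euclidean
#' distances to every agent including itself, so `m_i >= 1` always. Crowded
#' agents accumulate large counts; isolated agents have `m_i = 1`.
#'
#' @param positions Numeric matrix, one agent per row.
#' @param sigma_s Similarity radius.
#' @return Numeric vector of niche counts, one per agent.
#' @export
niche_counts <- function(positions, sigma_s) {
  positions <- as.matrix(positions)
  D <- as.matrix(stats::dist(positions))
  unname(rowSums(sharing_kernel(D, sigma_s)))
}

#' Shared fitness
#'
#' Divides each raw fitness by its niche count, `F_i' = F_i / m_i`, so
#' agents crowding the same peak split its reward.
#'
#' @param fitness Raw fitness vector.
#' @param niche Niche counts from [niche_counts()]; all >= 1.
#' @return Shared fitness vector.
#' @export
shared_fitness <- function(fitness, niche) {
  if (length(fitness) != length(niche))
    stop("shared_fitness: fitness and niche lengths differ")
  if (any(niche < 1)) stop("shared_fitness: niche counts must be >= 1")
  fitness / niche
}

#' Select the alpha, beta and delta leaders
#'
#' Ranks the pack by the supplied ranking fitness (shared fitness when
#' niching is on, raw fitness otherwise) under the given orientation and
#' returns the top three agents, carrying their positions and *raw*
#' fitnesses. Ties break toward the lower agent index.
#'
#' @param positions Matrix of agent positions (one per row).
#' @param fitness Raw fitness vector.
#' @param ranking_fitness Vector used for ordering; defaults to `fitness`.
#' @param orientation `"maximize"` or `"minimize"`.
#' @return A list with `alpha_position`, `beta_position`, `delta_position`,
#'   `alpha_fitness`, `beta_fitness`, `delta_fitness` and `indices`.
#' @export
select_leaders <- function(positions, fitness, ranking_fitness = fitness,
                           orientation = c("maximize", "minimize")) {
  orientation <- match.arg(orientation)
  positions <- as.matrix(positions)
  n <- nrow(positions)
  if (n < 3) stop("select_leaders: need at least 3 agents for alpha/beta/delta")
  ord <- if (orientation == "maximize")
    order(-ranking_fitness, seq_len(n)) else order(ranking_fitness, seq_len(n))
  top <- ord[1:3]
  list(alpha_position = positions[top[1], ],
       beta_position  = positions[top[2], ],
       delta_position = positions[top[3], ],
       alpha_fitness = fitness[top[1]],
       beta_fitness  = fitness[top[2]],
       delta_fitness = fitness[top[3]],
       indices = top)
}
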