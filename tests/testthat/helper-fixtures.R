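# Shared fixtures and memoized heavy runs. The planted-feature benchmark at
# the full budget (population 8, 100 iterations, 10 seeds, three variants)
# is computed once and reused by the module tests and the acceptance suite.

.igwolf_test_cache <- new.env(parent = emptyenv())

planted_benchmark_runs <- function() {
  if (!is.null(.igwolf_test_cache$bench)) return(.igwolf_test_cache$bench)
  seeds <- 0:9
  res <- lapply(seeds, function(s) {
    ds <- make_feature_dataset(seed = s)
    cfg <- optimizer_config(dimensionality = 30L, seed = s)
    igwo <- run_igwo_selection(ds, config = cfg)
    cfg_gwo <- cfg
    cfg_gwo$use_ga_seeding <- FALSE
    cfg_gwo$sharing_radius <- "off"
    gwo <- run_igwo_selection(ds, config = cfg_gwo)
    rnd <- run_random_selection(ds, config = cfg)
    list(dataset = ds, igwo = igwo, gwo = gwo, random = rnd,
         recall = mean(ds$informative_idx %in% which(igwo$best_flags == 1L)),
         size = sum(igwo$best_flags))
  })
  .igwolf_test_cache$bench <- res
  res
}

# small perfectly separable two-cluster dataset: feature 1 separates the
# classes completely, the rest is noise
separable_dataset <- function(n_per = 20L, n_features = 5L, seed = 1L) {
  set.seed(seed)
  n <- 2L * n_per
  x <- matrix(stats::rnorm(n * n_features), n, n_features)
  x[, 1] <- rep(c(-10, 10), each = n_per) + stats::rnorm(n, 0, 0.1)
  labeled_dataset(x, rep(c("a", "b"), each = n_per))
}

# straight-line transcription of the three-leader update equations,
# independent of the package implementation
oracle_update <- function(X, Xa, Xb, Xd, A, C) {
  D1 <- abs(C[[1]] * Xa - X); X1 <- Xa - A[[1]] * D1
  D2 <- abs(C[[2]] * Xb - X); X2 <- Xb - A[[2]] * D2
  D3 <- abs(C[[3]] * Xd - X); X3 <- Xd - A[[3]] * D3
  (X1 + X2 + X3) / 3
}
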