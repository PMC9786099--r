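test_that("coefficient schedule is linear with exact endpoints and validates input", {
  expect_identical(coefficient_schedule(0, 100), 2)
  expect_identical(coefficient_schedule(100, 100), 0)
  expect_identical(coefficient_schedule(50, 100), 1)
  expect_error(coefficient_schedule(-1, 10), "0 <= t <= T")
  expect_error(coefficient_schedule(11, 10), "0 <= t <= T")
  expect_error(coefficient_schedule(0, 0), "T must be >= 1")
})

test_that("coefficient draws respect their ranges and determinism", {
  set.seed(7)
  cc <- draw_coefficients(0, 5)
  expect_equal(cc$A, rep(0, 5))

  set.seed(11)
  draws <- replicate(2000, draw_coefficients(2, 5), simplify = FALSE)
  A <- unlist(lapply(draws, `[[`, "A"))
  C <- unlist(lapply(draws, `[[`, "C"))
  expect_true(all(A >= -2 & A <= 2))
  expect_true(all(C >= 0 & C <= 2))
  # 10^4 components cover the ranges
  expect_lt(min(A), -1.95); expect_gt(max(A), 1.95)
  expect_lt(min(C), 0.05);  expect_gt(max(C), 1.95)

  set.seed(3); a1 <- draw_coefficients(1.5, 4)
  set.seed(3); a2 <- draw_coefficients(1.5, 4)
  expect_identical(a1, a2)

  expect_error(draw_coefficients(2.5, 3), "\\[0, 2\\]")
})

test_that("leader-guided update matches hand and oracle computations", {
  # all three leaders at X with A = 0 leaves X fixed
  X <- c(0.3, 0.7)
  L <- list(alpha_position = X, beta_position = X, delta_position = X)
  coef0 <- replicate(3, list(A = c(0, 0), C = c(1, 1)), simplify = FALSE)
  expect_equal(leader_guided_update(X, L, 0, 0, 1, coef = coef0), X)

  # hand application: X = (0,0), leaders (1,0), (0,1), (0,0), A = 0, C = 1
  L2 <- list(alpha_position = c(1, 0), beta_position = c(0, 1),
             delta_position = c(0, 0))
  expect_equal(leader_guided_update(c(0, 0), L2, 0, 0, 1, coef = coef0),
               c(1 / 3, 1 / 3))

  # oracle equivalence on random instances with externally fixed A, C
  set.seed(42)
  for (rep in 1:25) {
    X <- runif(5, -2, 2)
    Xa <- runif(5, -2, 2); Xb <- runif(5, -2, 2); Xd <- runif(5, -2, 2)
    A <- replicate(3, runif(5, -1.5, 1.5), simplify = FALSE)
    C <- replicate(3, runif(5, 0, 2), simplify = FALSE)
    coef <- lapply(1:3, function(k) list(A = A[[k]], C = C[[k]]))
    got <- leader_guided_update(
      X, list(alpha_position = Xa, beta_position = Xb, delta_position = Xd),
      1, -1e6, 1e6, coef = coef)
    expect_equal(got, oracle_update(X, Xa, Xb, Xd, A, C), tolerance = 1e-12)
  }

  expect_error(
    leader_guided_update(c(0, 0, 0), L2, 1),
    "dimensionality mismatch")
})

test_that("updates always stay inside the domain box", {
  set.seed(5)
  L <- list(alpha_position = runif(3), beta_position = runif(3),
            delta_position = runif(3))
  for (i in 1:100) {
    out <- leader_guided_update(runif(3), L, 2, 0, 1)
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("run_gwo handles a constant landscape and enforces contracts", {
  cfg <- optimizer_config(dimensionality = 2, iterations = 10, seed = 1,
                          orientation = "minimize",
                          use_ga_seeding = FALSE, sharing_radius = "off")
  res <- run_gwo(function(x) 7, cfg)
  expect_equal(res$best_fitness, 7)
  expect_equal(res$history, rep(7, 10))
  expect_equal(res$evaluations, cfg$population_size * 11)

  expect_error(optimizer_config(population_size = 2), ">= 3")
  expect_error(run_gwo(function(x) NaN, cfg), "non-finite")
})

test_that("run_gwo minimizes the 2-D sphere with a non-worsening history", {
  cfg <- optimizer_config(dimensionality = 2, domain_low = -1, domain_high = 1,
                          orientation = "minimize", seed = 0,
                          use_ga_seeding = FALSE, sharing_radius = "off")
  res <- run_gwo(function(x) sum(x^2), cfg)
  expect_lte(res$best_fitness, 1e-2)
  expect_true(all(diff(res$history) <= 0))
})

test_that("identical seeds give bit-identical runs", {
  cfg <- optimizer_config(dimensionality = 3, iterations = 30, seed = 9,
                          orientation = "minimize",
                          use_ga_seeding = FALSE, sharing_radius = "off")
  r1 <- run_gwo(function(x) sum(abs(x)), cfg)
  r2 <- run_gwo(function(x) sum(abs(x)), cfg)
  expect_identical(r1$history, r2$history)
  expect_identical(r1$best_position, r2$best_position)
})
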