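test_that("instantaneous speed is the adjacent-frame distance", {
  const <- series_of(matrix(1, 10, 4))
  expect_equal(instantaneous_speed(const), rep(0, 9))
  alt <- series_of(matrix(c(rep(0, 4), 1, 0, 0, 0), 10, 4, byrow = TRUE))
  expect_equal(instantaneous_speed(alt), rep(1, 9))
  expect_length(instantaneous_speed(series_of(matrix(rnorm(28), 7, 4))), 6L)
  expect_error(instantaneous_speed(series_of(matrix(0, 1, 4))), "two frames")
})

test_that("inactivity removal follows the original-adjacency rule", {
  s <- series_of(matrix(rnorm(40), 10, 4))
  expect_identical(remove_inactivity(s, 0)$frames, s$frames)

  idle <- series_of(matrix(1, 5, 4))
  expect_warning(out <- remove_inactivity(idle, 0.3), "degenerates")
  expect_equal(nrow(out$frames), 1L)
  expect_true(isTRUE(attr(out, "degenerate")))

  # consecutive distances (0.5, 0.1, 0.4): only the 0.1 step is removed
  X <- rbind(rep(0, 4), c(0.5, 0, 0, 0), c(0.6, 0, 0, 0), c(1.0, 0, 0, 0))
  kept <- remove_inactivity(series_of(X), 0.3)
  expect_equal(kept$frames, X[c(1, 2, 4), ])
})

test_that("acceleration rules match their frame-removal definitions", {
  V <- matrix(as.numeric(seq_len(24)), 6, 4)
  s <- series_of(V)
  expect_identical(accelerate(s, 1)$frames, V)
  expect_equal(accelerate(s, 2)$frames, V[c(1, 3, 5), ])
  b15 <- accelerate(s, 1.5)$frames
  expect_equal(b15, rbind(V[1, ], (V[2, ] + V[3, ]) / 2,
                          V[4, ], (V[5, ] + V[6, ]) / 2))
  # trailing remainder kept unchanged
  V7 <- matrix(as.numeric(seq_len(28)), 7, 4)
  b15_7 <- accelerate(series_of(V7), 1.5)$frames
  expect_equal(nrow(b15_7), 5L)
  expect_equal(b15_7[5, ], V7[7, ])
  expect_error(accelerate(s, 3), "beta")
})

test_that("two-fold acceleration preserves occurrence but changes transitions", {
  # the canonical worked illustration: AABBCC... becomes ABC...
  states <- rep(rep(1:3, times = 4), each = 2)
  means <- matrix(0, 3, 4); means[, 1] <- c(0, 10, 20)
  V <- means[states, ]
  model <- structure(list(method = "kmeans", K = 3L, weights = rep(1 / 3, 3),
                          means = means, covariances = array(0, c(4, 4, 3)),
                          eps = NA, K_init = 3L, seed = 1L, n_iter = 1L,
                          objective_trace = numeric(0)),
                     class = "posture_state_model")
  orig <- series_of(V)
  acc <- accelerate(orig, 2)
  R0 <- responsibilities(model, orig)
  R2 <- responsibilities(model, acc)
  expect_equal(occurrence(R2), occurrence(R0), tolerance = 1e-12)
  expect_gt(jsd(transitions(R2), transitions(R0)), 0.01)
  # self-transitions vanish entirely after two-fold acceleration
  expect_equal(sum(diag(transitions(R2))), 0)
})

test_that("speed CDF distance equals the 1-D Wasserstein distance", {
  expect_equal(speed_cdf_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(speed_cdf_distance(2, 5), 3)
  expect_equal(speed_cdf_distance(c(0, 1), c(0.5, 0.5)), 0.5)
  set.seed(1)
  for (i in 1:50) {
    a <- rexp(20); b <- rexp(20)
    expect_equal(speed_cdf_distance(a, b), w1_equal_oracle(a, b),
                 tolerance = 1e-12)
    expect_equal(speed_cdf_distance(a, b), speed_cdf_distance(b, a),
                 tolerance = 1e-15)
  }
  expect_error(speed_cdf_distance(numeric(0), 1), "empty")
})

test_that("speed CDF distance satisfies the triangle inequality", {
  set.seed(2)
  for (i in 1:500) {
    a <- runif(sample(3:12, 1)); b <- runif(sample(3:12, 1))
    cc <- runif(sample(3:12, 1))
    expect_lte(speed_cdf_distance(a, b),
               speed_cdf_distance(a, cc) + speed_cdf_distance(cc, b) + 1e-12)
  }
})

test_that("transformation composition degenerates to its parts", {
  s <- series_of(matrix(rnorm(120), 30, 4))
  both_id <- accelerate(remove_inactivity(s, 0), 1)
  expect_identical(both_id$frames, s$frames)
  only_beta <- accelerate(remove_inactivity(s, 0), 2)
  expect_identical(only_beta$frames, accelerate(s, 2)$frames)
})

test_that("grid search recovers the transformation that built the target", {
  col <- tiny_collection(n_strains = 1, worms = 3, frames = 1200, seed = 31)
  wt <- col$series
  target <- lapply(wt, function(s) accelerate(remove_inactivity(s, 0.5), 2))
  fit <- fit_artificial_params(wt, target)
  expect_equal(fit$alpha, 0.5)
  expect_equal(fit$beta, 2)
  expect_equal(fit$D, 0, tolerance = 1e-12)

  # identity is optimal when the target is the wild type itself
  fit_id <- fit_artificial_params(wt, wt, include_identity = TRUE)
  expect_equal(fit_id$alpha, 0)
  expect_equal(fit_id$beta, 1)
  expect_equal(fit_id$D, 0, tolerance = 1e-12)

  # argmin contract: reported D is minimal over the whole grid
  target2 <- lapply(wt, function(s) accelerate(remove_inactivity(s, 0.7), 1.5))
  fit2 <- fit_artificial_params(wt, target2)
  tsp <- unlist(lapply(target2, instantaneous_speed))
  for (a in seq(0.3, 1, by = 0.1)) {
    for (b in c(1.5, 2)) {
      tr <- lapply(wt, function(s) accelerate(remove_inactivity(s, a), b))
      D <- speed_cdf_distance(unlist(lapply(tr, instantaneous_speed)), tsp)
      expect_gte(D, fit2$D - 1e-12)
    }
  }
})

test_that("a threshold between the speed modes splits rest from active frames", {
  cfg <- synthetic_config(n_strains = 1, worms_per_strain = 5,
                          frames_per_worm = 1500, gap_fraction = 0,
                          active_noise = 0.3, rest_noise = 0.01, seed = 41)
  col <- simulate_strains(cfg)
  for (s in col$series) {
    sp <- instantaneous_speed(s)
    rest <- sp < 0.1    # generous label: rest steps live near 0.02
    alpha <- 0.2        # between the rest and active modes
    removed <- sp < alpha
    expect_gte(mean(removed[rest]), 0.95)
    expect_lte(mean(removed[!rest]), 0.05)
  }
})

test_that("state usage conditional on speed is stable within a strain", {
  pert <- list(N2 = NULL, MU = list(kind = "reweight",
                                    pi_stat = exp(c(1, 0.5, 0, -0.5, -1, 0))))
  col <- tiny_collection(n_strains = 2, worms = 5, frames = 1500, seed = 51,
                         perturbations = pert)
  model <- oracle_model(col)
  wt <- subset_strains(col, "N2")$series
  cond <- vapply(wt, function(s) {
    R <- responsibilities(model, s)
    sp <- instantaneous_speed(s)
    slow <- c(FALSE, sp < 0.3)
    jsd(occurrence(R, frame_mask = slow), occurrence(R, frame_mask = !slow))
  }, numeric(1))
  b <- bin_collection(col, model)
  agg <- strain_aggregates(b)
  between <- jsd(agg$MU$r, agg$N2$r)
  expect_lt(mean(cond), between)
})

test_that("artificial strains reproduce divergences of matched targets", {
  col <- tiny_collection(n_strains = 1, worms = 4, frames = 1500, seed = 61)
  model <- oracle_model(col)
  reg <- structure(list(slope = 1.2, intercept = 0.001, residual_sd = 0.01,
                        adjusted_r2 = 0.99, n_strains = 20),
                   class = "divergence_regression")
  res_same <- evaluate_reproduction(col$series, col$series, model, reg)
  expect_equal(res_same$delta_r_a, 0)
  expect_equal(res_same$delta_T_a, 0)

  # dominance carries over to the artificial comparison
  target <- lapply(col$series, function(s) {
    accelerate(remove_inactivity(s, 0.4), 2)
  })
  res <- evaluate_reproduction(col$series, target, model, reg)
  FF <- 1500
  expect_gte(res$delta_T_a, res$delta_r_a - 2 * log(2) / FF)
})
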