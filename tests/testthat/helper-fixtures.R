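# Shared fixture builders and independent oracles.

# A small, fast synthetic collection for unit tests (not study scale).
tiny_collection <- function(n_strains = 2, worms = 3, frames = 300, seed = 42,
                            perturbations = NULL, gap_fraction = 0, ...) {
  cfg <- synthetic_config(n_strains = n_strains, worms_per_strain = worms,
                          frames_per_worm = frames,
                          gap_fraction = gap_fraction, seed = seed, ...)
  simulate_strains(cfg, perturbations)
}

# Hard-assignment state model at the true attractor means of a collection's
# generating configuration: an oracle binning independent of any fitting.
oracle_model <- function(collection) {
  cfg <- collection$config
  set.seed(cfg$seed)
  means <- cfg$attractor_means
  if (is.null(means)) {
    means <- matrix(stats::rnorm(cfg$n_attractors * 4,
                                 sd = 5 * cfg$active_noise),
                    cfg$n_attractors, 4)
  }
  G <- nrow(means)
  structure(list(method = "kmeans", K = G, weights = rep(1 / G, G),
                 means = means, covariances = array(0, c(4, 4, G)),
                 eps = NA, K_init = G, seed = cfg$seed, n_iter = 1L,
                 objective_trace = numeric(0)),
            class = "posture_state_model")
}

# Build an eigenworm series directly from a frame matrix.
series_of <- function(frames, fps = 5, strain = "A", worm = "w1",
                      gap_mask = NULL) {
  eigenworm_series(strain, worm, frames, fps, gap_mask = gap_mask)
}

# One-hot responsibility matrix from a state sequence.
onehot <- function(states, K = max(states)) {
  R <- matrix(0, length(states), K)
  R[cbind(seq_along(states), states)] <- 1
  R
}

# Independent JSD oracle: literal evaluation of the definition.
jsd_oracle <- function(p, q) {
  m <- (p + q) / 2
  term <- function(a) sum(ifelse(a > 0, a * log(a / m), 0))
  (term(p) + term(q)) / 2
}

# Exact one-sided WMW p-value by full enumeration of group assignments.
wmw_enum_oracle <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  ranks <- rank(pooled)
  u_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combos <- utils::combn(length(pooled), n)
  u_all <- apply(combos, 2, function(idx) {
    sum(rank(pooled)[idx]) - n * (n + 1) / 2
  })
  mean(u_all <= u_obs)
}

# Benjamini-Hochberg step-up oracle via the explicit recursion.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Wasserstein-1 oracle for equal-sized samples: mean |sorted differences|.
w1_equal_oracle <- function(a, b) mean(abs(sort(a) - sort(b)))

# Brute-force optimal matching of estimated to true component means
# (max row error after the best permutation).
perm_match_error <- function(est, truth) {
  K <- nrow(truth)
  stopifnot(K <= 8)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    }
    out
  }
  best <- Inf
  for (p in perms(seq_len(K))) {
    d <- max(sqrt(rowSums((est[p, , drop = FALSE] - truth)^2)))
    best <- min(best, d)
  }
  best
}

# Random point on the probability simplex.
rsimplex <- function(K) {
  x <- stats::rexp(K)
  x / sum(x)
}
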