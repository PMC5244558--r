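test_that("occurrence vectors are time-averaged responsibilities", {
  R <- onehot(c(1, 1, 2, 2))
  expect_equal(occurrence(R), c(0.5, 0.5))
  soft <- matrix(rep(c(0.3, 0.7), each = 4), 4, 2)
  expect_equal(occurrence(soft), c(0.3, 0.7))
  expect_equal(occurrence(R, frame_mask = c(TRUE, TRUE, FALSE, FALSE)),
               c(1, 0))
  expect_error(occurrence(R, frame_mask = rep(FALSE, 4)), "no frames")
})

test_that("transition matrices are mean outer products of adjacent frames", {
  R <- onehot(c(1, 2, 1))
  TT <- transitions(R)
  expect_equal(TT, matrix(c(0, 0.5, 0.5, 0), 2, 2))
  R2 <- rbind(c(0.5, 0.5), c(1, 0))
  expect_equal(transitions(R2), matrix(c(0.5, 0.5, 0, 0), 2, 2))
  set.seed(1)
  Rr <- t(apply(matrix(rexp(50 * 4), 50), 1, function(x) x / sum(x)))
  expect_equal(sum(transitions(Rr)), 1, tolerance = 1e-12)
  expect_error(transitions(Rr[1, , drop = FALSE]), "two frames")
})

test_that("Jensen-Shannon divergence matches its definition and bounds", {
  expect_equal(jsd(c(0.2, 0.8), c(0.2, 0.8)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), log(2), tolerance = 1e-12)
  expect_equal(jsd(c(0.5, 0.5), c(0.25, 0.75)),
               jsd_oracle(c(0.5, 0.5), c(0.25, 0.75)), tolerance = 1e-12)
  expect_equal(jsd(c(0.5, 0.5), c(0.25, 0.75)), 0.0338221, tolerance = 1e-6)
  set.seed(2)
  for (i in 1:50) {
    p <- rsimplex(6); q <- rsimplex(6)
    expect_equal(jsd(p, q), jsd(q, p), tolerance = 1e-12)
    expect_gte(jsd(p, q), 0)
    expect_lte(jsd(p, q), log(2) + 1e-12)
    expect_equal(jsd(p, q), jsd_oracle(p, q), tolerance = 1e-12)
  }
  expect_error(jsd(c(-0.1, 1.1), c(0.5, 0.5)), "nonnegative")
  expect_error(jsd(c(0.5, 0.6), c(0.5, 0.5)), "sum to 1")
})

test_that("the square root of JSD behaves as a metric", {
  set.seed(3)
  for (i in 1:500) {
    K <- sample(2:10, 1)
    p <- rsimplex(K); q <- rsimplex(K); r <- rsimplex(K)
    expect_lte(sqrt(jsd(p, q)),
               sqrt(jsd(p, r)) + sqrt(jsd(r, q)) + 1e-9)
  }
})

test_that("within/between strain divergences separate distinct strains", {
  occ <- rbind(c(1, 0), c(1, 0))
  expect_error(intra_inter_divergence(occ, c("A", "A"), seed = 1),
               "not enough")
  expect_error(intra_inter_divergence(occ, c("A", "B"), seed = 1),
               "at least 2")
  # identical worms across two strains: all divergences are zero
  occ4 <- matrix(rep(c(0.4, 0.6), each = 4), 4, 2)
  dd4 <- intra_inter_divergence(occ4, c("A", "A", "B", "B"), seed = 1)
  expect_equal(dd4$delta_intra, rep(0, 4))
  expect_equal(dd4$delta_inter, rep(0, 4))

  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    mk <- function(base, n) t(vapply(seq_len(n), function(i) {
      x <- base + abs(rnorm(4, sd = 0.05)); x / sum(x)
    }, numeric(4)))
    occ2 <- rbind(mk(c(0.7, 0.1, 0.1, 0.1), 6), mk(c(0.1, 0.7, 0.1, 0.1), 6))
    dd2 <- intra_inter_divergence(occ2, rep(c("A", "B"), each = 6),
                                  seed = seed)
    if (all(dd2$delta_intra < dd2$delta_inter)) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
})

test_that("one-sided rank-sum p-values match exact enumeration", {
  expect_equal(wmw_one_sided(c(1, 2), c(3, 4)), 1 / 6, tolerance = 1e-12)
  expect_equal(wmw_one_sided(1:3, 4:6), 1 / 20, tolerance = 1e-12)
  expect_gte(wmw_one_sided(c(1, 2, 3), c(1, 2, 3)), 0.5)
  expect_error(wmw_one_sided(numeric(0), 1), "empty")
  set.seed(4)
  for (i in 1:20) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    v <- sample(1000, n + m)  # distinct, tie-free
    x <- v[seq_len(n)]; y <- v[-seq_len(n)]
    expect_equal(wmw_one_sided(x, y), wmw_enum_oracle(x, y),
                 tolerance = 1e-12)
  }
})

test_that("Benjamini-Hochberg adjustment equals the step-up recursion", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(5)
  for (i in 1:100) {
    p <- runif(sample(1:30, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
})

test_that("strain separation testing flags truly distinct strains", {
  set.seed(6)
  mk <- function(base, n, sd) t(vapply(seq_len(n), function(i) {
    x <- pmax(base + rnorm(4, sd = sd), 1e-4); x / sum(x)
  }, numeric(4)))
  # strongly distinct usage: every strain should reach significance
  hits <- 0L
  for (seed in 1:10) {
    set.seed(seed)
    bases <- list(c(0.7, 0.1, 0.1, 0.1), c(0.1, 0.7, 0.1, 0.1),
                  c(0.1, 0.1, 0.7, 0.1), c(0.1, 0.1, 0.1, 0.7))
    occ <- do.call(rbind, lapply(bases, mk, n = 8, sd = 0.02))
    strains <- rep(paste0("S", 1:4), each = 8)
    dd <- intra_inter_divergence(occ, strains, seed = seed)
    res <- strain_separation_test(dd)
    if (res$n_significant == 4L) hits <- hits + 1L
  }
  expect_gte(hits, 9L)
  # single-strain edge case is impossible (needs other strains), but BH on
  # one p-value must equal the raw p-value
  expect_equal(bh_adjust(0.2), 0.2)
})

test_that("strain aggregation averages distributions onto the simplex", {
  occ <- rbind(c(1, 0), c(0, 1))
  tr <- list(matrix(c(1, 0, 0, 0), 2), matrix(c(0, 0, 0, 1), 2))
  agg <- aggregate_strain(occ, tr)
  expect_equal(agg$r, c(0.5, 0.5))
  expect_equal(agg$T, matrix(c(0.5, 0, 0, 0.5), 2))
  one <- aggregate_strain(occ[1, , drop = FALSE], tr[1])
  expect_equal(one$r, occ[1, ])
  expect_equal(one$T, tr[[1]])
})

test_that("reference divergences obey identity, bound and dominance", {
  R1 <- onehot(c(1, 1, 2, 3, 2, 1), K = 3)
  R2 <- onehot(c(2, 2, 3, 1, 3, 2), K = 3)
  aggs <- list(N2 = aggregate_strain(rbind(occurrence(R1)),
                                     list(transitions(R1))),
               S = aggregate_strain(rbind(occurrence(R2)),
                                    list(transitions(R2))),
               C = aggregate_strain(rbind(occurrence(R1)),
                                    list(transitions(R1))))
  rec <- divergence_from_reference(aggs, "N2")
  expect_setequal(rec$strain, c("S", "C"))
  expect_equal(rec$delta_r[rec$strain == "C"], 0)
  expect_equal(rec$delta_T[rec$strain == "C"], 0)
  expect_true(all(rec$delta_T <= log(2)))
  expect_error(divergence_from_reference(aggs, "missing"), "not present")

  # per-worm dominance: delta_T >= delta_r - 2 log(2) / F on shared frames
  set.seed(7)
  for (i in 1:100) {
    FF <- sample(50:200, 1)
    K <- sample(2:5, 1)
    Ra <- t(apply(matrix(rexp(FF * K), FF), 1, function(x) x / sum(x)))
    Rb <- t(apply(matrix(rexp(FF * K), FF), 1, function(x) x / sum(x)))
    dr <- jsd(occurrence(Ra), occurrence(Rb))
    dT <- jsd(transitions(Ra), transitions(Rb))
    expect_gte(dT - dr, -2 * log(2) / FF)
  }
})

test_that("joint transition divergence dominates its marginal divergence", {
  set.seed(8)
  for (i in 1:1000) {
    K <- sample(2:20, 1)
    A <- matrix(rexp(K * K), K); A <- A / sum(A)
    B <- matrix(rexp(K * K), K); B <- B / sum(B)
    expect_gte(jsd(A, B) - jsd(rowSums(A), rowSums(B)), -1e-10)
  }
})
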