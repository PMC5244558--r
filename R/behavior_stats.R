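#' Relative state occurrence frequencies
#'
#' Time-average of a worm's responsibility rows: a probability distribution
#' over postural states describing how often each state is used. An
#' optional frame mask restricts the average to selected frames (e.g.
#' frames below or above a postural change speed threshold).
#'
#' @param R an `F x K` responsibility matrix.
#' @param frame_mask optional logical vector selecting frames.
#' @return length-`K` occurrence vector summing to 1.
#' @export
occurrence <- function(R, frame_mask = NULL) {
  R <- as.matrix(R)
  if (!is.null(frame_mask)) {
    stopifnot(length(frame_mask) == nrow(R))
    if (!any(frame_mask)) stop("frame mask selects no frames")
    R <- R[frame_mask, , drop = FALSE]
  }
  if (nrow(R) < 1L) stop("need at least one frame")
  r <- colMeans(R)
  check_simplex(r, what = "occurrence vector")
  r
}

#' Relative state transition frequencies
#'
#' Mean outer product of consecutive responsibility rows: a joint
#' probability distribution over ordered state pairs at adjacent frames,
#' `T[k, l] = mean_f r[f, k] * r[f + 1, l]`. Because each row of `R` sums
#' to one, the matrix's grand total is exactly one.
#'
#' @param R an `F x K` responsibility matrix with `F >= 2`.
#' @return a `K x K` transition frequency matrix.
#' @export
transitions <- function(R) {
  R <- as.matrix(R)
  FF <- nrow(R)
  if (FF < 2L) stop("need at least two frames for transitions")
  TT <- crossprod(R[-FF, , drop = FALSE], R[-1L, , drop = FALSE]) / (FF - 1)
  check_simplex(as.vector(TT), what = "transition matrix")
  TT
}

#' Jensen-Shannon divergence
#'
#' Symmetric divergence between two probability distributions in natural-log
#' units: `0.5 KL(p || m) + 0.5 KL(q || m)` with `m = (p + q)/2` and
#' `0 log 0 = 0`. Bounded by `log(2)`; zero iff the distributions are
#' equal. Matrices (e.g. transition frequencies) are compared as flattened
#' distributions.
#'
#' @param p,q probability vectors or matrices of identical shape.
#' @return a nonnegative scalar in `[0, log(2)]`.
#' @export
jsd <- function(p, q) {
  p <- as.vector(p)
  q <- as.vector(q)
  if (length(p) != length(q)) stop("distributions differ in shape")
  if (any(p < 0) || any(q < 0)) stop("distributions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9) {
    stop("inputs must sum to 1")
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * (log(a[i]) - log(b[i])))
  }
  max(0, 0.5 * kl(p, m) + 0.5 * kl(q, m))
}

#' Within- and between-strain occurrence divergences
#'
#' For every worm `i`, computes the mean Jensen-Shannon divergence of its
#' occurrence vector against (a) all other worms of its own strain (`S_i`)
#' and (b) an equally sized random sample of worms from other strains
#' (`S-bar_i`, disjoint from `S_i` and not containing `i`). If worm
#' postures are represented faithfully, within-strain divergences should be
#' stochastically smaller than between-strain divergences.
#'
#' @param occ numeric matrix, one row per worm, of occurrence vectors.
#' @param strains character vector of strain labels, one per worm.
#' @param seed integer seed for the between-strain sampling.
#' @return data frame `worm`, `strain`, `delta_intra`, `delta_inter`,
#'   `set_size`.
#' @export
intra_inter_divergence <- function(occ, strains, seed = 1L) {
  occ <- as.matrix(occ)
  n <- nrow(occ)
  stopifnot(length(strains) == n)
  counts <- table(strains)
  if (any(counts < 2)) stop("every strain needs at least 2 worms")
  set.seed(as.integer(seed))
  worm <- rownames(occ)
  if (is.null(worm)) worm <- sprintf("w%04d", seq_len(n))
  out <- data.frame(worm = worm, strain = strains,
                    delta_intra = NA_real_, delta_inter = NA_real_,
                    set_size = NA_integer_)
  for (i in seq_len(n)) {
    same <- setdiff(which(strains == strains[i]), i)
    other <- which(strains != strains[i])
    if (length(other) < length(same)) {
      stop("not enough worms in other strains to match |S_i|")
    }
    pick <- sample(other, length(same))
    di <- vapply(same, function(j) jsd(occ[i, ], occ[j, ]), numeric(1))
    de <- vapply(pick, function(j) jsd(occ[i, ], occ[j, ]), numeric(1))
    out$delta_intra[i] <- mean(di)
    out$delta_inter[i] <- mean(de)
    out$set_size[i] <- length(same)
  }
  out
}

#' One-sided Wilcoxon-Mann-Whitney test
#'
#' Tests whether `x` is stochastically smaller than `y`. The p-value is
#' exact (full enumeration of rank assignments) when the combined sample is
#' small (`n + m <= 12`) and tie-free; otherwise the normal approximation
#' with tie and continuity corrections is used.
#'
#' @param x,y numeric samples.
#' @return the one-sided p-value.
#' @export
wmw_one_sided <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- (length(x) + length(y) <= 12L) &&
    !anyDuplicated(c(x, y))
  suppressWarnings(
    stats::wilcox.test(x, y, alternative = "less", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; input order is preserved.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return vector of q-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-strain test of within- vs between-strain similarity
#'
#' For each strain, a one-sided Wilcoxon-Mann-Whitney test of whether its
#' worms' within-strain divergences are stochastically smaller than their
#' between-strain divergences, with Benjamini-Hochberg adjustment across
#' strains. A strain is significant at `q < alpha`.
#'
#' @param pairs data frame from [intra_inter_divergence()].
#' @param alpha FDR level (default 0.05).
#' @return list with a per-strain data frame (`strain`, `p`, `q`,
#'   `significant`) and `n_significant`.
#' @export
strain_separation_test <- function(pairs, alpha = 0.05) {
  by_strain <- split(pairs, pairs$strain)
  p <- vapply(by_strain, function(d) {
    wmw_one_sided(d$delta_intra, d$delta_inter)
  }, numeric(1))
  q <- bh_adjust(p)
  tab <- data.frame(strain = names(by_strain), p = unname(p), q = unname(q),
                    significant = unname(q < alpha))
  list(table = tab, n_significant = sum(tab$significant))
}

#' Strain-level aggregates of occurrence and transition frequencies
#'
#' Unweighted arithmetic means of the per-worm occurrence vectors and
#' transition matrices of one strain. Means of distributions remain
#' distributions; outputs are renormalised only if numerical drift exceeds
#' 1e-12.
#'
#' @param occ matrix of per-worm occurrence vectors (rows).
#' @param trans list of per-worm transition matrices.
#' @return list with `r` (occurrence vector) and `T` (transition matrix).
#' @export
aggregate_strain <- function(occ, trans) {
  occ <- as.matrix(occ)
  stopifnot(nrow(occ) >= 1L, length(trans) == nrow(occ))
  r <- colMeans(occ)
  TT <- Reduce(`+`, trans) / length(trans)
  if (abs(sum(r) - 1) > 1e-12) r <- r / sum(r)
  if (abs(sum(TT) - 1) > 1e-12) TT <- TT / sum(TT)
  check_simplex(r, what = "strain occurrence")
  check_simplex(as.vector(TT), what = "strain transitions")
  list(r = r, T = TT)
}

#' Occurrence and transition divergences from a reference strain
#'
#' For every non-reference strain, the Jensen-Shannon divergence of its
#' aggregate occurrence vector and (flattened) transition matrix from
#' those of the reference strain. When occurrence and transitions are
#' computed from the same frames, the transition divergence dominates the
#' occurrence divergence up to an O(1/F) boundary term.
#'
#' @param aggregates named list of per-strain [aggregate_strain()] results.
#' @param reference reference strain label (e.g. the wild type).
#' @return data frame `strain`, `delta_r`, `delta_T` (z and q unset, filled
#'   by [regress_z()] / [detect_atypical()]).
#' @export
divergence_from_reference <- function(aggregates, reference) {
  if (!reference %in% names(aggregates)) {
    stop(sprintf("reference strain '%s' not present", reference))
  }
  ref <- aggregates[[reference]]
  K <- length(ref$r)
  others <- setdiff(names(aggregates), reference)
  rows <- lapply(others, function(s) {
    a <- aggregates[[s]]
    if (length(a$r) != K) stop("postural state model mismatch across strains")
    data.frame(strain = s,
               delta_r = jsd(a$r, ref$r),
               delta_T = jsd(a$T, ref$T))
  })
  out <- do.call(rbind, rows)
  out$z <- NA_real_
  out$q <- NA_real_
  out
}
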