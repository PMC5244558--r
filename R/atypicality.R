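#' Regression of transition divergence on occurrence divergence
#'
#' Across strains, the transition divergence from the reference tracks the
#' occurrence divergence almost linearly: strains that use different
#' postures necessarily transition differently. Ordinary least squares with
#' an intercept captures that trend; the standardized residual
#' `z = residual / residual_sd` measures how far a strain's transition
#' divergence sits above or below what its occurrence divergence predicts.
#'
#' Because the screen exists to find off-trend strains, the residual scale
#' is estimated robustly by default: a first-pass SD (`sqrt(RSS / (n - 2))`)
#' defines candidate outliers, and the final SD is recomputed from the
#' residuals within `trim` first-pass SDs, divided by the variance of a
#' standard normal truncated to `[-trim, trim]` so the scale stays
#' consistent when nothing is atypical. Without this, several equally
#' off-trend strains on a small panel inflate the very SD they are
#' standardized by and mask each other (with `k` equal outliers among `n`
#' records the naive z cannot exceed `sqrt((n - 2) / k)`). Set
#' `trim = Inf` for the naive estimator. With `leverage = TRUE`,
#' internally studentized residuals (`e / (s * sqrt(1 - h))`) are used.
#'
#' @param records data frame from [divergence_from_reference()].
#' @param trim robustness threshold in first-pass SD units (default 2;
#'   `Inf` disables trimming).
#' @param leverage use leverage-corrected (studentized) residuals.
#' @return list with `model` (slope, intercept, residual_sd, adjusted_r2,
#'   n_strains) and `records` with the `z` column filled.
#' @export
regress_z <- function(records, trim = 2, leverage = FALSE) {
  n <- nrow(records)
  if (n < 3L) stop("need at least 3 strains for the regression")
  if (stats::var(records$delta_r) < .Machine$double.eps) {
    stop("degenerate fit: no variance in delta_r")
  }
  fit <- stats::lm(delta_T ~ delta_r, data = records)
  e <- stats::residuals(fit)
  s0 <- sqrt(sum(e^2) / (n - 2))
  s <- s0
  if (is.finite(trim) && s0 > 1e-14) {
    # consistency factor: variance of N(0,1) truncated to [-trim, trim]
    cc <- 1 - 2 * trim * stats::dnorm(trim) / (2 * stats::pnorm(trim) - 1)
    # iterate the trim to a fixpoint: one extreme outlier otherwise
    # inflates the first-pass SD enough to shelter moderate ones
    keep_prev <- rep(TRUE, n)
    for (pass in seq_len(10L)) {
      keep <- abs(e / s) <= trim
      if (sum(keep) <= 2L || all(keep == keep_prev) && pass > 1L) break
      if (!all(keep)) {
        s <- sqrt(sum(e[keep]^2) / ((sum(keep) - 2) * cc))
      }
      keep_prev <- keep
      if (all(keep)) break
    }
  }
  z <- if (s < 1e-14) {
    rep(0, n)
  } else if (leverage) {
    h <- stats::hatvalues(fit)
    e / (s * sqrt(pmax(1 - h, .Machine$double.eps)))
  } else {
    e / s
  }
  records$z <- as.numeric(z)
  model <- structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         residual_sd = s,
         adjusted_r2 = suppressWarnings(summary(fit)$adj.r.squared),
         n_strains = n),
    class = "divergence_regression")
  list(model = model, records = records)
}

#' @export
print.divergence_regression <- function(x, ...) {
  cat(sprintf("<divergence_regression> delta_T = %.4f + %.4f * delta_r over %d strains (adj R2 = %.3f, residual SD = %.4g)\n",
              x$intercept, x$slope, x$n_strains, x$adjusted_r2,
              x$residual_sd))
  invisible(x)
}

#' Predicted transition divergence under the fitted trend
#' @param model a `divergence_regression`.
#' @param delta_r occurrence divergence value(s).
#' @return predicted transition divergence(s).
#' @export
predict_delta_T <- function(model, delta_r) {
  model$intercept + model$slope * delta_r
}

#' Flag strains with atypical transition patterns
#'
#' Converts each strain's standardized residual into a one-sided upper-tail
#' p-value `1 - Phi(z)` (only strains whose transition divergence is
#' atypically large given their occurrence divergence are of interest),
#' adjusts across strains by Benjamini-Hochberg, and flags strains with
#' `q < alpha`. Output is sorted by `z` descending.
#'
#' @param records data frame with the `z` column filled by [regress_z()].
#' @param alpha FDR level (default 0.05).
#' @return the records sorted by `z` with `q` and `atypical` columns.
#' @export
detect_atypical <- function(records, alpha = 0.05) {
  if (any(is.na(records$z))) stop("z values missing; run regress_z first")
  p <- stats::pnorm(records$z, lower.tail = FALSE)
  records$q <- bh_adjust(p)
  records$atypical <- records$q < alpha
  records[order(records$z, decreasing = TRUE), , drop = FALSE]
}

#' Per-state occurrence fold changes against a reference
#'
#' Ratio of a strain's occurrence frequency to the reference's for every
#' postural state, with a small pseudo-count `delta = 1 / (10 * K * mean_F)`
#' guarding against division by zero, ranked to give the most
#' over-represented and under-represented states.
#'
#' @param r_s strain occurrence vector.
#' @param r_ref reference occurrence vector (same length).
#' @param top_n how many states to list on each side (at most `K / 2`).
#' @param mean_frames mean frames per worm, used to scale the pseudo-count.
#' @return list with the per-state `table` (state, ratio, rank) and the
#'   `over` / `under` state index lists (disjoint).
#' @export
state_fold_change <- function(r_s, r_ref, top_n = 5L, mean_frames = 4500) {
  K <- length(r_s)
  stopifnot(length(r_ref) == K, top_n <= K / 2)
  delta <- 1 / (10 * K * mean_frames)
  ratio <- (r_s + delta) / (r_ref + delta)
  ord <- order(ratio, decreasing = TRUE)
  tab <- data.frame(state = seq_len(K), ratio = ratio,
                    rank = match(seq_len(K), ord))
  list(table = tab,
       over = ord[seq_len(top_n)],
       under = rev(ord)[seq_len(top_n)])
}

#' Reconstruct midline angles from a state mean
#'
#' Maps a 4-D posture-space point (typically a postural state's mean) back
#' to the midline tangent-angle profile through the eigenworm basis. The
#' basis columns are mean-centered, so the reconstructed angles average to
#' zero (overall body orientation is ignored by construction).
#'
#' @param state_mean numeric vector in eigenworm space.
#' @param basis an `eigenworm_basis`.
#' @return numeric vector of `n_angles` tangent angles.
#' @export
reconstruct_posture <- function(state_mean, basis) {
  if (length(state_mean) != basis$dims) {
    stop("state mean dimension does not match basis")
  }
  as.numeric(basis$matrix %*% state_mean)
}
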