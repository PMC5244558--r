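#' Instantaneous postural change speed
#'
#' Euclidean distance between the eigenworm vectors of adjacent frames, in
#' eigen-units per frame at the series' working frame rate. A near-zero
#' mode in this distribution marks inactivity (quiescence) bouts.
#'
#' @param series an [eigenworm_series] with `F >= 2` and no missing values.
#' @return numeric vector of length `F - 1`.
#' @export
instantaneous_speed <- function(series) {
  X <- series$frames
  if (nrow(X) < 2L) stop("need at least two frames for speeds")
  sqrt(rowSums((X[-1L, , drop = FALSE] - X[-nrow(X), , drop = FALSE])^2))
}

#' Remove inactivity frames below a speed threshold
#'
#' Single pass over the original frame adjacency: frame `f` (for `f >= 2`)
#' is removed iff its distance to the previous original frame is strictly
#' below `alpha`; the first frame is always kept and survivors are
#' concatenated in order. With `alpha = 0` nothing is removed.
#'
#' @param series an [eigenworm_series].
#' @param alpha nonnegative speed threshold.
#' @return the thinned series; if fewer than two frames survive, the result
#'   carries attribute `degenerate = TRUE` with a warning.
#' @export
remove_inactivity <- function(series, alpha) {
  stopifnot(alpha >= 0)
  if (alpha == 0) return(series)
  keep <- c(TRUE, instantaneous_speed(series) >= alpha)
  out <- eigenworm_series(series$strain, series$worm_id,
                          series$frames[keep, , drop = FALSE], series$fps,
                          gap_mask = series$gap_mask[keep])
  if (nrow(out$frames) < 2L) {
    warning(sprintf("worm %s degenerates to < 2 frames after inactivity removal",
                    series$worm_id))
    attr(out, "degenerate") <- TRUE
  }
  out
}

#' Uniformly accelerate a series
#'
#' Simulates `beta`-fold faster postural change by frame removal:
#' `beta = 2` keeps every other frame starting at the first; `beta = 1.5`
#' replaces, in every non-overlapping triple of consecutive frames, the
#' second and third frames by their average (a trailing remainder of one
#' or two frames is kept unchanged); `beta = 1` is the identity.
#'
#' @param series an [eigenworm_series].
#' @param beta acceleration factor, one of 1, 1.5, 2.
#' @return the accelerated series.
#' @export
accelerate <- function(series, beta) {
  if (!beta %in% c(1, 1.5, 2)) stop("beta must be 1, 1.5 or 2")
  if (beta == 1) return(series)
  X <- series$frames
  FF <- nrow(X)
  if (beta == 2) {
    idx <- seq(1L, FF, by = 2L)
    X <- X[idx, , drop = FALSE]
    mask <- series$gap_mask[idx]
  } else {
    n_triples <- FF %/% 3L
    rows <- list()
    mask <- logical(0)
    if (n_triples > 0L) {
      base <- (seq_len(n_triples) - 1L) * 3L
      first <- X[base + 1L, , drop = FALSE]
      avg <- (X[base + 2L, , drop = FALSE] + X[base + 3L, , drop = FALSE]) / 2
      Xo <- matrix(NA_real_, 2L * n_triples, ncol(X))
      Xo[seq(1L, 2L * n_triples, by = 2L), ] <- first
      Xo[seq(2L, 2L * n_triples, by = 2L), ] <- avg
      m1 <- series$gap_mask[base + 1L]
      m2 <- series$gap_mask[base + 2L] | series$gap_mask[base + 3L]
      mask <- as.vector(rbind(m1, m2))
    } else {
      Xo <- X[0L, , drop = FALSE]
    }
    rem <- FF - 3L * n_triples
    if (rem > 0L) {
      Xo <- rbind(Xo, X[(3L * n_triples + 1L):FF, , drop = FALSE])
      mask <- c(mask, series$gap_mask[(3L * n_triples + 1L):FF])
    }
    X <- Xo
  }
  eigenworm_series(series$strain, series$worm_id, X, series$fps,
                   gap_mask = mask)
}

#' L1 distance between empirical speed CDFs
#'
#' `D = integral |F_a(x) - F_b(x)| dx`, evaluated exactly on the merged
#' breakpoint grid of the two samples; equal to the one-dimensional
#' Wasserstein-1 distance between the empirical distributions.
#'
#' @param a,b numeric speed samples (nonnegative, non-empty).
#' @return nonnegative scalar distance.
#' @export
speed_cdf_distance <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty speed profile")
  z <- sort(unique(c(a, b)))
  if (length(z) == 1L) return(0)
  Fa <- stats::ecdf(a)(z)
  Fb <- stats::ecdf(b)(z)
  k <- length(z)
  sum(abs(Fa[-k] - Fb[-k]) * diff(z))
}

default_alpha_grid <- function() seq(0.3, 1.0, by = 0.1)
default_beta_grid <- function() c(1.5, 2.0)

#' Fit artificial-strain transformation parameters
#'
#' Transforms every reference (wild-type) worm by inactivity removal at
#' threshold `alpha` followed by `beta`-fold acceleration, for every pair
#' on the grid, and selects the pair whose pooled transformed speed
#' distribution is closest (in [speed_cdf_distance()]) to the target
#' strain's pooled speed distribution. Ties go to the smaller `alpha`,
#' then the smaller `beta`. The default grid is `alpha = 0.3, 0.4, ..., 1.0`
#' and `beta = 1.5, 2.0`; pass `include_identity = TRUE` to extend it with
#' `alpha = 0` and `beta = 1` (identity transformation).
#'
#' @param wildtype list of reference-strain [eigenworm_series].
#' @param target list of target-strain [eigenworm_series].
#' @param alpha_grid,beta_grid parameter grids.
#' @param include_identity extend the grid with `alpha = 0`, `beta = 1`.
#' @return list with `alpha`, `beta`, `D` (class `artificial_params`) and
#'   the transformed `series` at the optimum.
#' @export
fit_artificial_params <- function(wildtype, target,
                                  alpha_grid = default_alpha_grid(),
                                  beta_grid = default_beta_grid(),
                                  include_identity = FALSE) {
  if (include_identity) {
    alpha_grid <- sort(unique(c(0, alpha_grid)))
    beta_grid <- sort(unique(c(1, beta_grid)))
  }
  target_speeds <- unlist(lapply(target, instantaneous_speed))
  best <- NULL
  grid <- expand.grid(beta = beta_grid, alpha = alpha_grid)  # alpha varies slowest
  grid <- grid[order(grid$alpha, grid$beta), ]
  for (i in seq_len(nrow(grid))) {
    a <- grid$alpha[i]
    b <- grid$beta[i]
    transformed <- lapply(wildtype, function(s) {
      accelerate(remove_inactivity(s, a), b)
    })
    ok <- vapply(transformed, function(s) nrow(s$frames) >= 2L, logical(1))
    if (!all(ok)) {
      warning(sprintf("%d worm(s) degenerate at alpha = %g, beta = %g; excluded",
                      sum(!ok), a, b))
      transformed <- transformed[ok]
    }
    if (!length(transformed)) {
      stop(sprintf("all worms degenerate at alpha = %g, beta = %g", a, b))
    }
    speeds <- unlist(lapply(transformed, instantaneous_speed))
    D <- speed_cdf_distance(speeds, target_speeds)
    if (is.null(best) || D < best$D - 1e-15) {
      best <- list(alpha = a, beta = b, D = D, series = transformed)
    }
  }
  class(best) <- "artificial_params"
  best
}

#' @export
print.artificial_params <- function(x, ...) {
  cat(sprintf("<artificial_params> alpha = %g, beta = %g, D = %.4g (%d transformed worms)\n",
              x$alpha, x$beta, x$D, length(x$series)))
  invisible(x)
}

#' Does an artificial reference strain reproduce a target's divergences?
#'
#' Bins the transformed (artificial) reference worms and the target
#' strain's worms with the fixed postural state model, aggregates their
#' occurrence vectors and transition matrices, computes the divergences of
#' the target from the artificial reference, and standardizes the
#' transition divergence against the previously fitted occurrence-vs-
#' transition regression: `Z_a = (delta_T_a - predicted(delta_r_a)) /
#' residual_sd`. A small `|Z_a|` means the target's atypical transition
#' pattern is explained by inactivity removal plus acceleration alone.
#'
#' @param artificial list of transformed reference [eigenworm_series].
#' @param target list of target-strain [eigenworm_series].
#' @param model the shared `posture_state_model`.
#' @param regression the `divergence_regression` from [regress_z()].
#' @return list `delta_r_a`, `delta_T_a`, `z_a`.
#' @export
evaluate_reproduction <- function(artificial, target, model, regression) {
  agg <- function(series_list) {
    occ <- list(); tr <- list()
    for (i in seq_along(series_list)) {
      R <- responsibilities(model, series_list[[i]])
      occ[[i]] <- occurrence(R)
      tr[[i]] <- transitions(R)
    }
    aggregate_strain(do.call(rbind, occ), tr)
  }
  a <- agg(artificial)
  s <- agg(target)
  delta_r_a <- jsd(s$r, a$r)
  delta_T_a <- jsd(s$T, a$T)
  z_a <- if (regression$residual_sd < 1e-14) 0 else
    (delta_T_a - predict_delta_T(regression, delta_r_a)) / regression$residual_sd
  list(delta_r_a = delta_r_a, delta_T_a = delta_T_a, z_a = z_a)
}
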