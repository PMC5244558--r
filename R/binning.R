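#' Pool and subsample frames for model fitting
#'
#' Uniformly samples a fraction of the pooled frames of all worms, without
#' replacement. Fitting the state model on a 1\% subsample keeps mixture
#' estimation tractable on collection-scale data; responsibilities are then
#' computed for every frame.
#'
#' @param collection a preprocessed [strain_collection] (no missing values).
#' @param fraction fraction of pooled frames to keep (default 0.01).
#' @param seed integer seed.
#' @param k_init optional initial component count; if given, fewer than
#'   `10 * k_init` sampled points is an error.
#' @return numeric matrix of sampled 4-D points.
#' @export
sample_frames <- function(collection, fraction = 0.01, seed = 1L,
                          k_init = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  pooled <- do.call(rbind, lapply(collection$series, `[[`, "frames"))
  if (any(!is.finite(pooled))) {
    stop("collection contains missing frames; interpolate before sampling")
  }
  total <- nrow(pooled)
  n <- round(fraction * total)
  if (!is.null(k_init) && n < 10L * k_init) {
    stop(sprintf("insufficient sample: %d points for K_init = %d", n, k_init))
  }
  if (n >= total) return(pooled)
  set.seed(as.integer(seed))
  pooled[sort(sample.int(total, n)), , drop = FALSE]
}

# K-means++ seeding: iteratively sample centers proportional to squared
# distance from the nearest already-chosen center
kmeanspp_centers <- function(X, K) {
  n <- nrow(X)
  centers <- integer(K)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(X, 2L, X[centers[1L], ])^2)
  for (k in seq_len(K - 1L)) {
    d2sum <- sum(d2)
    centers[k + 1L] <- if (d2sum <= 0) sample.int(n, 1L) else
      sample.int(n, 1L, prob = d2 / d2sum)
    d2 <- pmin(d2, rowSums(sweep(X, 2L, X[centers[k + 1L], ])^2))
  }
  X[centers, , drop = FALSE]
}

new_posture_state_model <- function(method, weights, means, covs, eps = NA,
                                    k_init, seed, n_iter, trace) {
  ord <- order(weights, decreasing = TRUE)
  structure(list(method = method, K = length(weights),
                 weights = weights[ord],
                 means = means[ord, , drop = FALSE],
                 covariances = covs[, , ord, drop = FALSE],
                 eps = eps, K_init = k_init, seed = seed,
                 n_iter = n_iter, objective_trace = trace),
            class = "posture_state_model")
}

#' @export
print.posture_state_model <- function(x, ...) {
  cat(sprintf("<posture_state_model> %s, K = %d states (K_init = %d%s), %d iterations\n",
              x$method, x$K, x$K_init,
              if (is.finite(x$eps)) sprintf(", eps = %g", x$eps) else "",
              x$n_iter))
  invisible(x)
}

#' K-means baseline for postural state binning
#'
#' Lloyd iterations from a K-means++ initialisation until the assignment
#' fixpoint (or 300 iterations). Each resulting centroid is a postural
#' state; downstream binning is deterministic (one-hot). An emptied cluster
#' is reseeded to the point currently farthest from its assigned centroid.
#'
#' @param points numeric matrix of 4-D posture points.
#' @param K number of clusters.
#' @param seed integer seed for the initialisation.
#' @return a `posture_state_model` with `method = "kmeans"`; the
#'   `objective_trace` holds the within-cluster sum of squares per
#'   iteration (non-increasing).
#' @export
fit_kmeans <- function(points, K, seed = 1L) {
  if (K <= 0) stop("K must be positive")
  X <- as.matrix(points)
  n <- nrow(X)
  if (n < K) stop("fewer points than clusters")
  set.seed(as.integer(seed))
  centers <- kmeanspp_centers(X, K)
  assign_prev <- integer(n)
  trace <- numeric(0)
  for (iter in seq_len(300L)) {
    d2 <- point_center_dist2(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    mind2 <- d2[cbind(seq_len(n), assign)]
    for (k in which(tabulate(assign, K) == 0L)) {
      far <- which.max(mind2)
      centers[k, ] <- X[far, ]
      assign[far] <- k
      mind2[far] <- 0
    }
    trace <- c(trace, sum(mind2))
    if (iter > 1L && all(assign == assign_prev)) break
    assign_prev <- assign
    for (k in seq_len(K)) {
      centers[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    }
  }
  weights <- tabulate(assign, K) / n
  covs <- array(0, dim = c(ncol(X), ncol(X), K))
  new_posture_state_model("kmeans", weights, centers, covs, eps = NA,
                          k_init = K, seed = seed, n_iter = iter,
                          trace = trace)
}

point_center_dist2 <- function(X, centers) {
  # ||x - c||^2 = ||x||^2 - 2 x.c + ||c||^2, vectorised over all pairs
  xx <- rowSums(X^2)
  cc <- rowSums(centers^2)
  d2 <- outer(xx, cc, `+`) - 2 * tcrossprod(X, centers)
  pmax(d2, 0)
}

#' FAB-GMM: shrinkage EM with automatic state-count selection
#'
#' Fits a full-covariance Gaussian mixture by an EM procedure whose E-step
#' is modified with a factorized-information-criterion (FIC) shrinkage
#' factor: after computing standard posterior responsibilities, each
#' component column is multiplied by `exp(-D_c / (2 N_k))`, where
#' `D_c = d + d(d+1)/2` is the per-component parameter count (14 in 4-D)
#' and `N_k` the component's current effective count, and rows are
#' renormalised. The factor penalises components with little support, so
#' redundant components lose mass and are pruned once their mixture ratio
#' drops below `eps`; the surviving count is the selected number of
#' postural states. Convergence is declared when the relative change of the
#' FIC lower bound falls below `tol`.
#'
#' @param points numeric matrix of 4-D posture points.
#' @param eps mixture-ratio pruning threshold (paired in practice with
#'   `k_init` as 0.01/100, 0.005/200, 0.001/1000).
#' @param k_init initial component count (K-means++ initialisation).
#' @param seed integer seed for the initialisation.
#' @param shrink set `FALSE` to disable the FAB shrinkage factor, reducing
#'   the update to plain EM (used for verification against standard EM).
#' @param prune set `FALSE` to disable component elimination.
#' @param max_iter iteration cap (default 2000).
#' @param tol relative FIC-change convergence tolerance (default 1e-10; the
#'   FIC flattens long before slow component competition finishes, so the
#'   tolerance must sit well below the per-iteration objective drift).
#' @param reg ridge added to every covariance after each M-step.
#' @return a `posture_state_model` with `method = "gmm"`; the
#'   `objective_trace` holds the FIC lower bound per iteration (the
#'   log-likelihood per iteration when `shrink = FALSE`).
#' @export
fit_fab_gmm <- function(points, eps = 0.005, k_init = 200L, seed = 1L,
                        shrink = TRUE, prune = TRUE, max_iter = 2000L,
                        tol = 1e-10, reg = 1e-6) {
  X <- as.matrix(points)
  n <- nrow(X)
  d <- ncol(X)
  if (n < k_init) stop("fewer points than initial components")
  if (prune && k_init * eps >= 1) {
    stop("K_init * eps must be below 1")
  }
  Dc <- d + d * (d + 1) / 2

  set.seed(as.integer(seed))
  centers <- kmeanspp_centers(X, k_init)
  d2 <- point_center_dist2(X, centers)
  assign <- max.col(-d2, ties.method = "first")
  Rhard <- matrix(0, n, k_init)
  Rhard[cbind(seq_len(n), assign)] <- 1
  ms <- .gmm_mstep(X, Rhard, reg)
  weights <- as.numeric(ms$counts) / n
  means <- ms$means
  # components emptied at initialisation cannot be updated; drop them
  alive <- weights > 0
  weights <- weights[alive] / sum(weights[alive])
  means <- means[alive, , drop = FALSE]
  # all components start with the global covariance: broad initial overlap
  # lets the shrinkage compete components before any of them locks onto a
  # small pocket of points
  gcov <- stats::cov(X) + reg * diag(d)
  covs <- array(0, dim = c(d, d, sum(alive)))
  for (k in seq_len(sum(alive))) covs[, , k] <- gcov

  trace <- numeric(0)
  obj_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    K <- length(weights)
    logd <- .gmm_log_density(X, means, covs)
    logp <- sweep(logd, 2L, log(weights), `+`)
    mx <- logp[cbind(seq_len(n), max.col(logp, ties.method = "first"))]
    P <- exp(logp - mx)
    rs <- rowSums(P)
    R <- P / rs
    loglik <- sum(mx + log(rs))

    if (shrink && K > 1L) {
      # FAB E-step: solve the shrinkage to its fixpoint. Responsibilities
      # and effective counts must be self-consistent: columns with little
      # support shrink, which lowers their count and shrinks them further,
      # until either an equilibrium is reached or the component collapses.
      P <- R
      Nk <- colSums(R)
      for (inner in seq_len(30L)) {
        Rs <- sweep(P, 2L, exp(-Dc / (2 * pmax(Nk, 1e-12))), `*`)
        Rs <- Rs / rowSums(Rs)
        Nk_new <- colSums(Rs)
        # counts are O(n); far smaller changes no longer move the factor
        done <- max(abs(Nk_new - Nk)) < 1e-4
        Nk <- Nk_new
        R <- Rs
        if (done) break
      }
    }
    Nk <- colSums(R)

    keep <- rep(TRUE, K)
    if (prune && K > 1L) {
      keep <- (Nk / n) >= eps
      if (!any(keep)) keep[which.max(Nk)] <- TRUE
      if (!all(keep)) {
        R <- R[, keep, drop = FALSE]
        R <- R / rowSums(R)
        Nk <- colSums(R)
        K <- ncol(R)
      }
    }

    # FIC lower bound evaluated at the current (pre-M-step) parameters:
    # expected complete-data log-likelihood + responsibility entropy
    # - (D_c/2) sum_k log N_k - ((K-1)/2) log N
    obj <- if (shrink) {
      ecll <- sum(R * logp[, keep, drop = FALSE])
      ent <- -sum(ifelse(R > 0, R * log(R), 0))
      ecll + ent - (Dc / 2) * sum(log(pmax(Nk, .Machine$double.eps))) -
        ((K - 1) / 2) * log(n)
    } else loglik

    ms <- .gmm_mstep(X, R, reg)
    Nk <- as.numeric(ms$counts)
    weights <- Nk / n
    means <- ms$means
    covs <- ms$covs

    trace <- c(trace, obj)
    if (iter > 1L &&
        abs(obj - obj_prev) <= tol * (abs(obj_prev) + .Machine$double.eps)) {
      break
    }
    obj_prev <- obj
  }

  new_posture_state_model("gmm", weights, means, covs, eps = eps,
                          k_init = k_init, seed = seed, n_iter = iter,
                          trace = trace)
}

#' Per-frame state responsibilities
#'
#' For a Gaussian-mixture model, the posterior probability of every
#' postural state at every frame (rows normalised in log space and summing
#' to one). For a K-means model, a one-hot assignment to the nearest
#' centroid, with ties broken toward the lowest state index.
#'
#' @param model a converged `posture_state_model`.
#' @param series an [eigenworm_series] with no missing values.
#' @return an `F x K` responsibility matrix with attributes `worm_id`,
#'   `strain` and `method`.
#' @export
responsibilities <- function(model, series) {
  X <- series$frames
  if (any(!is.finite(X))) {
    stop("series contains non-finite frames; interpolate before binning")
  }
  if (ncol(X) != ncol(model$means)) stop("dimension mismatch with model")
  if (model$method == "gmm") {
    logp <- sweep(.gmm_log_density(X, model$means, model$covariances),
                  2L, log(model$weights), `+`)
    mx <- logp[cbind(seq_len(nrow(X)), max.col(logp, ties.method = "first"))]
    P <- exp(logp - mx)
    R <- P / rowSums(P)
  } else {
    d2 <- point_center_dist2(X, model$means)
    nearest <- max.col(-d2, ties.method = "first")
    R <- matrix(0, nrow(X), model$K)
    R[cbind(seq_len(nrow(X)), nearest)] <- 1
  }
  structure(R, worm_id = series$worm_id, strain = series$strain,
            method = model$method)
}
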