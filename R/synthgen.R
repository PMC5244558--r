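#' Synthetic eigenworm basis
#'
#' Generates an orthonormal, column-centered basis mapping the
#' low-dimensional eigenworm amplitudes back to midline tangent angles
#' (48 angles by default). Real eigenworm bases are principal axes of
#' mean-centered angle profiles, so every column is constrained to sum to
#' zero; this generator draws a random basis with the same structure.
#'
#' @param n_angles number of midline angles per posture (default 48).
#' @param dims number of eigenworm dimensions (default 4).
#' @param seed integer seed; the basis is deterministic given the seed.
#' @return object of class \code{eigenworm_basis}: list with
#'   \code{n_angles}, \code{dims} and the \code{n_angles x dims}
#'   coefficient \code{matrix}.
#' @export
make_basis <- function(n_angles = 48L, dims = 4L, seed = 1L) {
  if (dims > n_angles) stop("dims must not exceed n_angles")
  if (dims < 1L) stop("dims must be at least 1")
  set.seed(as.integer(seed))
  raw <- matrix(stats::rnorm(n_angles * dims), n_angles, dims)
  centered <- sweep(raw, 2L, colMeans(raw))
  q <- qr.Q(qr(centered))[, seq_len(dims), drop = FALSE]
  # fix column signs so the result does not depend on LAPACK conventions
  sgn <- sign(q[max.col(t(abs(q)), ties.method = "first") + (seq_len(dims) - 1L) * n_angles])
  q <- sweep(q, 2L, sgn, `*`)
  structure(list(n_angles = as.integer(n_angles), dims = as.integer(dims),
                 matrix = q),
            class = "eigenworm_basis")
}

#' @export
print.eigenworm_basis <- function(x, ...) {
  cat(sprintf("<eigenworm_basis> %d angles x %d dims (orthonormal, zero-mean columns)\n",
              x$n_angles, x$dims))
  invisible(x)
}

#' Configuration of the synthetic strain generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: each worm wanders through a small set of attractor regions in
#' 4-D posture space (multimodal state usage), switching attractors through
#' a sticky Markov chain (bout structure), occasionally entering rest bouts
#' during which the posture barely changes (the near-zero mode of postural
#' change speed seen in quiescent worms), with a fraction of frames missing.
#'
#' @param n_strains number of strains to simulate.
#' @param worms_per_strain individuals per strain (default 10; behavioral
#'   databases typically record tens of individuals per strain, and 5 is
#'   the minimum a strain needs to survive quality control).
#' @param frames_per_worm frames per worm (default 4500 = 900 s at 5 fps).
#' @param fps frames per second (default 5).
#' @param n_attractors number of attractor regions G (default 6).
#' @param attractor_means optional G x 4 matrix of attractor centers; drawn
#'   once per collection from a centered Gaussian with spread
#'   \code{5 * active_noise} when \code{NULL} so states are resolvable.
#' @param bout_transition optional G x G row-stochastic attractor switching
#'   matrix; built by [bout_transition_matrix()] with uniform stationary
#'   usage and stickiness 0.9 when \code{NULL}.
#' @param relaxation_rate pull toward the current attractor per frame,
#'   in (0, 1].
#' @param active_noise per-frame isotropic noise SD while active
#'   (eigen-units/frame).
#' @param rest_entry_prob probability of entering a rest bout at an
#'   attractor-switch boundary.
#' @param rest_exit_prob per-frame probability of leaving a rest bout
#'   (geometric bout durations).
#' @param rest_noise per-frame noise SD while resting; must be well below
#'   \code{active_noise} to produce a separated low-speed mode.
#' @param speed_factor overall speed multiplier applied to
#'   \code{relaxation_rate} and \code{active_noise}.
#' @param gap_fraction fraction of interior frames marked missing.
#' @param seed integer seed for the collection.
#' @return validated configuration list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_strains = 1L,
                             worms_per_strain = 10L,
                             frames_per_worm = 4500L,
                             fps = 5,
                             n_attractors = 6L,
                             attractor_means = NULL,
                             bout_transition = NULL,
                             relaxation_rate = 0.5,
                             active_noise = 0.2,
                             rest_entry_prob = 0.3,
                             rest_exit_prob = 0.05,
                             rest_noise = 0.02,
                             speed_factor = 1,
                             gap_fraction = 0.05,
                             seed = 1L) {
  cfg <- list(n_strains = as.integer(n_strains),
              worms_per_strain = as.integer(worms_per_strain),
              frames_per_worm = as.integer(frames_per_worm),
              fps = fps, n_attractors = as.integer(n_attractors),
              attractor_means = attractor_means,
              bout_transition = bout_transition,
              relaxation_rate = relaxation_rate, active_noise = active_noise,
              rest_entry_prob = rest_entry_prob,
              rest_exit_prob = rest_exit_prob, rest_noise = rest_noise,
              speed_factor = speed_factor, gap_fraction = gap_fraction,
              seed = as.integer(seed))
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_strains >= 1, worms_per_strain >= 1, frames_per_worm >= 2,
              fps > 0, n_attractors >= 1,
              relaxation_rate > 0, relaxation_rate <= 1,
              active_noise > 0, rest_noise >= 0, rest_noise < active_noise,
              rest_entry_prob >= 0, rest_entry_prob < 1,
              rest_exit_prob > 0, rest_exit_prob <= 1,
              speed_factor > 0, gap_fraction >= 0, gap_fraction < 0.4)
  })
  if (!is.null(cfg$bout_transition)) {
    A <- cfg$bout_transition
    stopifnot(is.matrix(A), nrow(A) == cfg$n_attractors,
              ncol(A) == cfg$n_attractors, all(A >= 0))
    if (max(abs(rowSums(A) - 1)) > 1e-9) {
      stop("bout_transition rows must sum to 1")
    }
  }
  if (!is.null(cfg$attractor_means)) {
    stopifnot(is.matrix(cfg$attractor_means),
              nrow(cfg$attractor_means) == cfg$n_attractors)
  }
  invisible(cfg)
}

#' Reversible attractor-switching matrix with a prescribed stationary law
#'
#' Builds a row-stochastic matrix from the symmetric edge-weight form
#' \code{W = (1 - stickiness) * pi pi' + stickiness * diag(pi)} (plus an
#' optional symmetric zero-row-sum edge perturbation), normalised by row.
#' Because the row sums of \code{W} equal \code{pi}, the chain is reversible
#' with stationary distribution \code{pi} for any stickiness: stickiness
#' changes dwell times and hence transition structure while leaving
#' long-run state usage untouched.
#'
#' @param pi_stat stationary distribution over attractors (nonnegative,
#'   normalised internally).
#' @param stickiness weight on the diagonal component in \[0, 1); larger
#'   values give longer bouts.
#' @param topology `"full"` (default): given a switch, the next attractor is
#'   drawn in proportion to its stationary weight; `"ring"`: switches go
#'   only to the two ring neighbours (requires uniform `pi_stat`). Both
#'   leave the diagonal, and hence dwell times, untouched, so rewiring the
#'   topology changes the transition structure at matched state usage.
#' @param edge_perturbation optional symmetric matrix with zero row sums
#'   added to \code{W} (advanced: reshapes individual edges at fixed
#'   stationary usage).
#' @return row-stochastic matrix with stationary distribution \code{pi_stat}.
#' @export
bout_transition_matrix <- function(pi_stat, stickiness = 0.9,
                                   topology = c("full", "ring"),
                                   edge_perturbation = NULL) {
  topology <- match.arg(topology)
  stopifnot(all(pi_stat >= 0), sum(pi_stat) > 0,
            stickiness >= 0, stickiness < 1)
  p <- pi_stat / sum(pi_stat)
  G <- length(p)
  if (topology == "full") {
    Q <- tcrossprod(p)
  } else {
    if (max(abs(p - 1 / G)) > 1e-12) {
      stop("ring topology requires a uniform stationary distribution")
    }
    if (G < 3L) stop("ring topology needs at least 3 attractors")
    # same diagonal as the full topology (so dwell times agree); the
    # off-diagonal mass of each row moves entirely onto the ring neighbours
    off <- (1 / G - 1 / G^2) / 2
    Q <- matrix(0, G, G)
    for (i in seq_len(G)) {
      Q[i, (i %% G) + 1L] <- off
      Q[i, ((i - 2L) %% G) + 1L] <- off
    }
    diag(Q) <- 1 / G^2
  }
  W <- (1 - stickiness) * Q + stickiness * diag(p, nrow = G)
  if (!is.null(edge_perturbation)) {
    E <- edge_perturbation
    stopifnot(isTRUE(all.equal(E, t(E))), max(abs(rowSums(E))) < 1e-12)
    W <- W + E
    if (any(W < 0)) stop("edge_perturbation drives edge weights negative")
  }
  W / rowSums(W)
}

#' Stationary distribution of a row-stochastic matrix
#' @param A row-stochastic matrix.
#' @return stationary probability vector.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  i <- which.min(abs(e$values - 1))
  v <- abs(Re(e$vectors[, i]))
  v / sum(v)
}

#' Simulate a synthetic strain collection
#'
#' Generates \code{n_strains} strains of eigenworm time series under a
#' shared attractor geometry, optionally perturbing individual strains the
#' way behavioral mutants differ from wild type. Perturbation kinds:
#' \describe{
#'   \item{none}{wild-type parameters.}
#'   \item{no_rest}{rest-bout entry probability set to zero (no quiescence).}
#'   \item{accelerate}{dynamics replaced by their \code{gamma}-step
#'     subsampled counterpart (\code{lambda' = 1 - (1 - lambda)^gamma},
#'     noise compounded accordingly, switching matrix raised to the
#'     \code{gamma}-th power): uniformly faster postural change with the
#'     stationary posture distribution, and hence state usage, preserved
#'     exactly.}
#'   \item{retransition}{attractor-switching matrix replaced by one with
#'     the same stationary distribution and dwell times but rewired switch
#'     targets (ring topology by default): altered transition structure at
#'     matched state usage.}
#'   \item{reweight}{stationary usage replaced by \code{pi_stat} (altered
#'     state usage; transitions change in proportion).}
#' }
#'
#' @param config a [synthetic_config()].
#' @param perturbations optional named list, one entry per strain (names are
#'   the strain labels); each entry a list with \code{kind} and the
#'   parameters of that kind (\code{gamma}, \code{stickiness},
#'   \code{pi_stat}, \code{matrix}). \code{kind} may be a vector of kinds
#'   applied in order (e.g. \code{c("no_rest", "accelerate")} for a fast,
#'   never-resting mutant). \code{NULL} entries mean no perturbation. When
#'   omitted, strains are labelled S01, S02, ...
#' @return a [strain_collection] carrying the config, seed and a shared
#'   synthetic basis as provenance.
#' @export
simulate_strains <- function(config, perturbations = NULL) {
  validate_synthetic_config(config)
  n <- config$n_strains
  labels <- if (!is.null(perturbations) && !is.null(names(perturbations))) {
    if (length(perturbations) != n) {
      stop("perturbations must have one entry per strain")
    }
    names(perturbations)
  } else sprintf("S%02d", seq_len(n))

  set.seed(config$seed)
  G <- config$n_attractors
  means <- config$attractor_means
  if (is.null(means)) {
    spread <- 5 * config$active_noise
    means <- matrix(stats::rnorm(G * 4, sd = spread), G, 4)
  }
  A0 <- config$bout_transition
  if (is.null(A0)) A0 <- bout_transition_matrix(rep(1 / G, G), stickiness = 0.9)
  pi0 <- stationary_distribution(A0)

  series <- vector("list", n * config$worms_per_strain)
  idx <- 0L
  for (s in seq_len(n)) {
    pert <- if (!is.null(perturbations)) perturbations[[s]] else NULL
    par <- strain_parameters(config, A0, pi0, pert)
    for (w in seq_len(config$worms_per_strain)) {
      idx <- idx + 1L
      wseed <- (config$seed %% 100000L) * 20011L + idx * 7919L
      series[[idx]] <- simulate_worm(
        strain = labels[s],
        worm_id = sprintf("%s_w%02d", labels[s], w),
        means = means, par = par, config = config,
        seed = wseed %% 2147483611L
      )
    }
  }
  basis <- make_basis(seed = config$seed)
  strain_collection(series, basis = basis, config = config,
                    seed = config$seed)
}

# resolve per-strain dynamics parameters from a perturbation entry;
# `kind` may be a vector of kinds applied in order (e.g. a fast, never
# resting mutant: c("no_rest", "accelerate"))
strain_parameters <- function(config, A0, pi0, pert) {
  par <- list(A = A0, lambda = config$relaxation_rate * config$speed_factor,
              sigma_act = config$active_noise * config$speed_factor,
              p_rest = config$rest_entry_prob)
  if (is.null(pert)) return(par)
  for (kind in pert$kind) {
    par <- apply_perturbation(par, kind, pert, pi0)
  }
  par
}

apply_perturbation <- function(par, kind, pert, pi0) {
  if (identical(kind, "none")) return(par)
  switch(kind,
    no_rest = {
      par$p_rest <- 0
    },
    accelerate = {
      # gamma-fold uniform acceleration = gamma-step subsampling of the
      # wild-type dynamics: same stationary posture distribution (state
      # usage preserved exactly), compressed transition structure
      g <- if (is.null(pert$gamma)) 2L else pert$gamma
      if (g != round(g) || g < 1) {
        stop("accelerate perturbation needs an integer gamma >= 1")
      }
      g <- as.integer(g)
      decay <- 1 - par$lambda
      par$sigma_act <- par$sigma_act * sqrt(sum(decay^(2 * (0:(g - 1)))))
      par$lambda <- 1 - decay^g
      Ag <- par$A
      if (g > 1) for (i in seq_len(g - 1)) Ag <- Ag %*% par$A
      par$A <- Ag
    },
    retransition = {
      Anew <- pert$matrix
      if (is.null(Anew)) {
        st <- if (is.null(pert$stickiness)) 0.9 else pert$stickiness
        topo <- if (is.null(pert$topology)) "ring" else pert$topology
        Anew <- bout_transition_matrix(pi0, stickiness = st, topology = topo,
                                       edge_perturbation = pert$edge_perturbation)
      }
      if (max(abs(stationary_distribution(Anew) - pi0)) > 1e-8) {
        stop("retransition perturbation changes the stationary distribution")
      }
      par$A <- Anew
    },
    reweight = {
      stopifnot(!is.null(pert$pi_stat))
      st <- if (is.null(pert$stickiness)) 0.9 else pert$stickiness
      par$A <- bout_transition_matrix(pert$pi_stat, stickiness = st)
    },
    stop(sprintf("unknown perturbation kind '%s'", kind))
  )
  par
}

# one worm: sticky latent attractor chain + mean-reverting active dynamics,
# rest bouts entered at attractor-switch boundaries with geometric duration
simulate_worm <- function(strain, worm_id, means, par, config, seed) {
  set.seed(as.integer(seed))
  FF <- config$frames_per_worm
  G <- nrow(means)
  A_cum <- t(apply(par$A, 1L, cumsum))
  pi_start <- stationary_distribution(par$A)
  noise <- matrix(stats::rnorm(FF * 4), FF, 4)
  u_switch <- stats::runif(FF)
  u_rest <- stats::runif(FF)

  V <- matrix(NA_real_, FF, 4)
  g <- findInterval(stats::runif(1), cumsum(pi_start)) + 1L
  g <- min(g, G)
  v <- means[g, ] + par$sigma_act * noise[1L, ]
  V[1L, ] <- v
  resting <- FALSE
  for (f in 2:FF) {
    if (resting) {
      v <- v + config$rest_noise * noise[f, ]
      if (u_rest[f] < config$rest_exit_prob) resting <- FALSE
    } else {
      v <- v + par$lambda * (means[g, ] - v) + par$sigma_act * noise[f, ]
      gnew <- findInterval(u_switch[f], A_cum[g, ]) + 1L
      gnew <- min(gnew, G)
      if (gnew != g) {
        g <- gnew
        if (u_rest[f] < par$p_rest) resting <- TRUE
      }
    }
    V[f, ] <- v
  }

  gap_mask <- rep(FALSE, FF)
  if (config$gap_fraction > 0 && FF > 2L) {
    interior <- 2:(FF - 1L)
    n_gap <- round(config$gap_fraction * length(interior))
    if (n_gap > 0) {
      gap_mask[sample(interior, n_gap)] <- TRUE
      V[gap_mask, ] <- NA_real_
    }
  }
  eigenworm_series(strain, worm_id, V, fps = config$fps, gap_mask = gap_mask)
}

#' Write a synthetic collection to disk
#'
#' Writes the dataset CSV (see [write_dataset()]), the generator
#' configuration plus seed as YAML, and the shared basis as JSON
#' (row-major coefficient array) next to the data.
#'
#' @param collection a [strain_collection] from [simulate_strains()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_collection <- function(collection, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data_path <- file.path(dir, "dataset.csv")
  write_dataset(collection, data_path)
  paths <- c(data = data_path)
  if (!is.null(collection$config)) {
    cfg <- collection$config
    cfg$attractor_means <- if (!is.null(cfg$attractor_means))
      as.vector(t(cfg$attractor_means))
    cfg$bout_transition <- if (!is.null(cfg$bout_transition))
      as.vector(t(cfg$bout_transition))
    yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))
    paths["config"] <- file.path(dir, "config.yaml")
  }
  if (!is.null(collection$basis)) {
    b <- collection$basis
    jsonlite::write_json(
      list(n_angles = b$n_angles, dims = b$dims,
           matrix = as.vector(t(b$matrix))),
      file.path(dir, "basis.json"), auto_unbox = TRUE, digits = NA)
    paths["basis"] <- file.path(dir, "basis.json")
  }
  invisible(paths)
}
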