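#' wormstates: postural state analysis of eigenworm time series
#'
#' Pipeline pieces: synthetic strain generation ([simulate_strains()]),
#' dataset IO and preprocessing ([read_dataset()], [qc_filter()],
#' [interpolate_gaps()], [downsample()]), postural state binning
#' ([fit_fab_gmm()], [fit_kmeans()], [responsibilities()]), divergence
#' statistics ([occurrence()], [transitions()], [jsd()],
#' [strain_separation_test()]), atypicality screening ([regress_z()],
#' [detect_atypical()]) and factor dissection
#' ([fit_artificial_params()], [evaluate_reproduction()]).
#'
#' @useDynLib wormstates, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @keywords internal
"_PACKAGE"

#' Bin every worm of a collection with a fixed state model
#'
#' Computes per-worm responsibilities, occurrence vectors and transition
#' matrices under one shared postural state model.
#'
#' @param collection a preprocessed [strain_collection].
#' @param model a `posture_state_model`.
#' @return list with `occurrence` (worms x K matrix, worm ids as row
#'   names), `transitions` (list of K x K matrices), `strains` and
#'   `worm_ids`, and `mean_frames`.
#' @export
bin_collection <- function(collection, model) {
  n <- length(collection$series)
  occ <- matrix(NA_real_, n, model$K)
  tr <- vector("list", n)
  for (i in seq_len(n)) {
    R <- responsibilities(model, collection$series[[i]])
    occ[i, ] <- occurrence(R)
    tr[[i]] <- transitions(R)
  }
  rownames(occ) <- collection_worm_ids(collection)
  list(occurrence = occ, transitions = tr,
       strains = collection_strains(collection),
       worm_ids = collection_worm_ids(collection),
       mean_frames = mean(vapply(collection$series, n_frames, numeric(1))))
}

#' Aggregate binned worms into per-strain profiles
#'
#' @param binned result of [bin_collection()].
#' @return named list, one [aggregate_strain()] result per strain.
#' @export
strain_aggregates <- function(binned) {
  idx <- split(seq_along(binned$strains), binned$strains)
  lapply(idx, function(i) {
    aggregate_strain(binned$occurrence[i, , drop = FALSE],
                     binned$transitions[i])
  })
}

#' Reference-divergence screen for atypical transition patterns
#'
#' Aggregates strains, computes occurrence/transition divergences from the
#' reference strain, fits the occurrence-vs-transition regression and flags
#' strains whose transition divergence is atypically large.
#'
#' @param binned result of [bin_collection()].
#' @param reference reference strain label.
#' @param alpha FDR level for flagging (default 0.05).
#' @return list with `aggregates`, `regression` and the flagged `records`
#'   (sorted by `z` descending).
#' @export
reference_screen <- function(binned, reference, alpha = 0.05) {
  aggregates <- strain_aggregates(binned)
  records <- divergence_from_reference(aggregates, reference)
  reg <- regress_z(records)
  records <- detect_atypical(reg$records, alpha = alpha)
  list(aggregates = aggregates, regression = reg$model, records = records)
}

#' Write a posture state model as JSON
#' @param model a `posture_state_model`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_state_model <- function(model, path) {
  covs <- lapply(seq_len(model$K), function(k) model$covariances[, , k])
  jsonlite::write_json(
    list(method = model$method, K = model$K, eps = model$eps,
         seed = model$seed, weights = model$weights,
         means = model$means, covariances = covs),
    path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' Read a posture state model from JSON
#' @param path JSON file written by [write_state_model()].
#' @return a `posture_state_model`.
#' @export
read_state_model <- function(path) {
  m <- jsonlite::fromJSON(path)
  K <- m$K
  d <- ncol(m$means)
  covs <- array(0, dim = c(d, d, K))
  for (k in seq_len(K)) covs[, , k] <- m$covariances[k, , ]
  new_posture_state_model(m$method, m$weights, m$means, covs,
                          eps = if (is.null(m$eps)) NA else m$eps,
                          k_init = K, seed = m$seed, n_iter = NA,
                          trace = numeric(0))
}
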