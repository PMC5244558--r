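#' Eigenworm time series for a single worm
#'
#' Container for one individual's time-ordered posture trajectory in
#' eigenworm space: an \code{F x 4} matrix of eigenworm amplitudes, a gap
#' mask marking frames whose posture was missing in the source data, the
#' frame rate, and strain/worm labels. Frame \code{f} (0-based in file
#' formats, 1-based in R) corresponds to time \code{(f - 1) / fps} seconds.
#'
#' @param strain strain label.
#' @param worm_id worm label, unique within a collection.
#' @param frames numeric matrix, one row per frame, one column per eigenworm
#'   dimension. Rows flagged in \code{gap_mask} may hold \code{NA}.
#' @param fps frames per second.
#' @param gap_mask logical vector, \code{TRUE} where the posture was missing
#'   before interpolation. Defaults to rows containing non-finite values.
#' @return an object of class \code{eigenworm_series}.
#' @export
eigenworm_series <- function(strain, worm_id, frames, fps, gap_mask = NULL) {
  frames <- as.matrix(frames)
  storage.mode(frames) <- "double"
  if (is.null(gap_mask)) gap_mask <- !stats::complete.cases(frames)
  stopifnot(is.numeric(fps), fps > 0, length(gap_mask) == nrow(frames))
  if (any(!is.finite(frames[!gap_mask, , drop = FALSE]))) {
    stop("non-finite eigenworm values outside the gap mask")
  }
  structure(
    list(strain = as.character(strain), worm_id = as.character(worm_id),
         frames = frames, fps = fps, gap_mask = as.logical(gap_mask)),
    class = "eigenworm_series"
  )
}

#' @export
print.eigenworm_series <- function(x, ...) {
  cat(sprintf("<eigenworm_series> worm %s (strain %s): %d frames x %d dims, %g fps, %.1f s, %.1f%% gaps\n",
              x$worm_id, x$strain, nrow(x$frames), ncol(x$frames), x$fps,
              nrow(x$frames) / x$fps, 100 * mean(x$gap_mask)))
  invisible(x)
}

n_frames <- function(series) nrow(series$frames)

duration_s <- function(series) nrow(series$frames) / series$fps

gap_fraction <- function(series) mean(series$gap_mask)

#' Collection of eigenworm series grouped by strain
#'
#' @param series list of [eigenworm_series] objects with unique worm ids.
#' @param basis optional [make_basis()] result shared by the collection.
#' @param config optional generator configuration (provenance).
#' @param seed optional integer seed used to generate the collection.
#' @return an object of class \code{strain_collection}.
#' @export
strain_collection <- function(series, basis = NULL, config = NULL, seed = NULL) {
  stopifnot(is.list(series),
            all(vapply(series, inherits, logical(1), "eigenworm_series")))
  ids <- vapply(series, `[[`, character(1), "worm_id")
  if (anyDuplicated(ids)) stop("duplicate worm_id in collection")
  structure(list(series = series, basis = basis, config = config, seed = seed),
            class = "strain_collection")
}

#' @export
print.strain_collection <- function(x, ...) {
  st <- collection_strains(x)
  cat(sprintf("<strain_collection> %d worms, %d strains (%s)\n",
              length(x$series), length(unique(st)),
              paste(utils::head(unique(st), 6), collapse = ", ")))
  invisible(x)
}

#' Strain label of every worm in a collection
#' @param collection a [strain_collection].
#' @return character vector, one entry per worm.
#' @export
collection_strains <- function(collection) {
  vapply(collection$series, `[[`, character(1), "strain")
}

#' Worm ids in a collection
#' @param collection a [strain_collection].
#' @return character vector, one entry per worm.
#' @export
collection_worm_ids <- function(collection) {
  vapply(collection$series, `[[`, character(1), "worm_id")
}

#' Subset a collection by strain
#' @param collection a [strain_collection].
#' @param strains character vector of strain labels to keep.
#' @return a [strain_collection] with only the requested strains.
#' @export
subset_strains <- function(collection, strains) {
  keep <- collection_strains(collection) %in% strains
  strain_collection(collection$series[keep], basis = collection$basis,
                    config = collection$config, seed = collection$seed)
}

# simplex sanity check used after every distribution-producing operation
check_simplex <- function(x, tol = 1e-9, what = "distribution") {
  if (any(x < -tol)) stop(sprintf("%s has negative entries", what))
  if (abs(sum(x) - 1) > tol) stop(sprintf("%s does not sum to 1", what))
  invisible(TRUE)
}
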