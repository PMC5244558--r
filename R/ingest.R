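#' Read an eigenworm dataset
#'
#' Reads a tabular eigenworm dataset into a [strain_collection]. The CSV
#' dialect has a header `strain,worm_id,frame_index,time_s,e1,e2,e3,e4`
#' with 0-based frame indices and empty fields for missing amplitudes; a
#' frame with any missing amplitude is flagged in the series' gap mask.
#' The minimal WCON (Worm tracker Commons Object Notation) import maps each
#' `data[i].id` to a worm id and expects a 4-column custom feature block
#' `"@eigenworm"` per worm; all other WCON content is ignored.
#'
#' @param path file to read.
#' @param format `"csv"` (default) or `"wcon"`.
#' @return a [strain_collection].
#' @export
read_dataset <- function(path, format = c("csv", "wcon")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "wcon") return(read_wcon_min(path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("strain", "worm_id", "frame_index", "time_s", "e1", "e2", "e3", "e4")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(sprintf("missing required columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  series <- lapply(split(df, df$worm_id), function(d) {
    if (anyDuplicated(d$frame_index)) {
      stop(sprintf("duplicate (worm_id, frame_index) for worm %s",
                   d$worm_id[1]))
    }
    d <- d[order(d$frame_index), , drop = FALSE]
    if (is.unsorted(d$time_s, strictly = TRUE)) {
      stop(sprintf("non-monotone time within worm %s", d$worm_id[1]))
    }
    frames <- as.matrix(d[, c("e1", "e2", "e3", "e4")])
    dimnames(frames) <- NULL
    fps <- if (nrow(d) >= 2) {
      1 / stats::median(diff(d$time_s))
    } else 5
    eigenworm_series(d$strain[1], d$worm_id[1], frames, fps = round(fps, 6))
  })
  strain_collection(unname(series))
}

read_wcon_min <- function(path) {
  w <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(w$data)) stop("WCON file has no data block")
  series <- lapply(w$data, function(d) {
    if (is.null(d$id)) stop("WCON data entry without id")
    feat <- d[["@eigenworm"]]
    if (is.null(feat)) stop("WCON data entry without @eigenworm block")
    frames <- do.call(rbind, lapply(feat, function(row) {
      vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
             numeric(1))
    }))
    t <- vapply(d$t, as.numeric, numeric(1))
    fps <- if (length(t) >= 2) 1 / stats::median(diff(t)) else 5
    strain <- if (!is.null(d$strain)) d$strain else "unknown"
    eigenworm_series(strain, d$id, frames, fps = round(fps, 6))
  })
  strain_collection(unname(series))
}

#' Write an eigenworm dataset CSV
#'
#' Inverse of [read_dataset()]: one row per frame, missing amplitudes as
#' empty fields, frame indices 0-based. Finite values round-trip exactly.
#'
#' @param collection a [strain_collection].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dataset <- function(collection, path) {
  rows <- lapply(collection$series, function(s) {
    f <- seq_len(nrow(s$frames)) - 1L
    data.frame(strain = s$strain, worm_id = s$worm_id, frame_index = f,
               time_s = f / s$fps,
               e1 = s$frames[, 1], e2 = s$frames[, 2],
               e3 = s$frames[, 3], e4 = s$frames[, 4])
  })
  df <- do.call(rbind, rows)
  # %.17g guarantees doubles survive the text round-trip bit-exactly
  for (col in c("time_s", "e1", "e2", "e3", "e4")) {
    v <- sprintf("%.17g", df[[col]])
    v[is.na(df[[col]])] <- ""
    df[[col]] <- v
  }
  utils::write.csv(df, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Quality-control filter for a strain collection
#'
#' Applies the dataset consistency rules: worms whose recording duration is
#' outside `[min_duration_s, max_duration_s]` (inclusive) are dropped, worms
#' whose eigenworm vectors are missing in more than `max_gap_fraction` of
#' all frames are dropped (the boundary itself is kept), and finally
#' strains left with fewer than `min_worms_per_strain` individuals are
#' dropped. Duration is `F / fps` of the raw series.
#'
#' @param collection a [strain_collection].
#' @param min_duration_s,max_duration_s duration window in seconds
#'   (defaults 890 and 910).
#' @param max_gap_fraction maximum tolerated missing-frame fraction
#'   (default 0.4, strict inequality).
#' @param min_worms_per_strain minimum surviving individuals per strain
#'   (default 5).
#' @return list with the filtered `collection` and an `exclusions` data
#'   frame (`worm_id`, `strain`, `rule`, `value`).
#' @export
qc_filter <- function(collection, min_duration_s = 890, max_duration_s = 910,
                      max_gap_fraction = 0.4, min_worms_per_strain = 5L) {
  if (!length(collection$series)) stop("empty collection")
  excl <- list()
  note <- function(s, rule, value) {
    data.frame(worm_id = s$worm_id, strain = s$strain, rule = rule,
               value = value)
  }
  keep <- vapply(collection$series, function(s) {
    dur <- duration_s(s)
    if (dur < min_duration_s || dur > max_duration_s) {
      excl[[length(excl) + 1L]] <<- note(s, "duration", dur)
      return(FALSE)
    }
    gf <- gap_fraction(s)
    if (gf > max_gap_fraction) {
      excl[[length(excl) + 1L]] <<- note(s, "gap_fraction", gf)
      return(FALSE)
    }
    TRUE
  }, logical(1))
  surviving <- collection$series[keep]
  st <- vapply(surviving, `[[`, character(1), "strain")
  counts <- table(st)
  small <- names(counts)[counts < min_worms_per_strain]
  for (s in surviving[st %in% small]) {
    excl[[length(excl) + 1L]] <- note(s, "strain_size",
                                      as.numeric(counts[[s$strain]]))
  }
  surviving <- surviving[!(st %in% small)]
  if (!length(surviving)) warning("no worms survived quality control")
  exclusions <- if (length(excl)) do.call(rbind, excl) else
    data.frame(worm_id = character(), strain = character(),
               rule = character(), value = numeric())
  list(collection = strain_collection(surviving, basis = collection$basis,
                                      config = collection$config,
                                      seed = collection$seed),
       exclusions = exclusions)
}

#' Write a QC exclusion report
#' @param exclusions the `exclusions` data frame from [qc_filter()].
#' @param path output TSV path.
#' @return invisibly, `path`.
#' @export
write_exclusion_report <- function(exclusions, path) {
  utils::write.table(exclusions, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Linearly interpolate missing frames
#'
#' Fills each interior run of missing frames by per-dimension linear
#' interpolation between the nearest non-missing flanking frames. Leading
#' and trailing missing frames have only one flank and are removed. The
#' (trimmed) gap mask is preserved as provenance; non-missing values are
#' untouched.
#'
#' @param series an [eigenworm_series] (or a [strain_collection], in which
#'   case every series is interpolated).
#' @return the interpolated object.
#' @export
interpolate_gaps <- function(series) {
  if (inherits(series, "strain_collection")) {
    series$series <- lapply(series$series, interpolate_gaps)
    return(series)
  }
  good <- !series$gap_mask
  if (!any(good)) stop("cannot interpolate: all frames missing")
  first <- which(good)[1]
  last <- max(which(good))
  frames <- series$frames[first:last, , drop = FALSE]
  mask <- series$gap_mask[first:last]
  if (any(mask)) {
    idx <- seq_len(nrow(frames))
    for (j in seq_len(ncol(frames))) {
      frames[mask, j] <- stats::approx(idx[!mask], frames[!mask, j],
                                       xout = idx[mask])$y
    }
  }
  eigenworm_series(series$strain, series$worm_id, frames, series$fps,
                   gap_mask = mask)
}

#' Downsample an eigenworm series
#'
#' Decimates to `target_fps`. Integer frame-rate ratios keep every
#' `ratio`-th frame starting at the first; non-integer ratios keep, for
#' each target time, the nearest source frame (ties to the earlier frame).
#' No smoothing is applied, so instantaneous postural change speed stays
#' measurable downstream.
#'
#' @param series an [eigenworm_series] (or a [strain_collection]).
#' @param target_fps target frame rate (default 5).
#' @return the downsampled object at `target_fps`.
#' @export
downsample <- function(series, target_fps = 5) {
  if (inherits(series, "strain_collection")) {
    series$series <- lapply(series$series, downsample, target_fps = target_fps)
    return(series)
  }
  if (series$fps < target_fps) {
    stop("upsampling not supported: source fps below target")
  }
  FF <- nrow(series$frames)
  ratio <- series$fps / target_fps
  if (abs(ratio - round(ratio)) < 1e-9) {
    idx <- seq(1L, FF, by = round(ratio))
  } else {
    n_out <- floor((FF - 1) / ratio) + 1L
    t_target <- (seq_len(n_out) - 1L) / target_fps
    src <- t_target * series$fps + 1
    lo <- floor(src)
    idx <- ifelse(src - lo > 0.5, lo + 1L, lo)  # ties (0.5) go to earlier
    idx <- pmin(as.integer(idx), FF)
  }
  eigenworm_series(series$strain, series$worm_id,
                   series$frames[idx, , drop = FALSE], target_fps,
                   gap_mask = series$gap_mask[idx])
}

#' Standard preprocessing pipeline
#'
#' Fixed order: quality control, then gap interpolation, then downsampling
#' to the working frame rate.
#'
#' @param collection a [strain_collection].
#' @param target_fps working frame rate (default 5).
#' @param ... passed to [qc_filter()].
#' @return list with the preprocessed `collection` and the QC `exclusions`.
#' @export
preprocess <- function(collection, target_fps = 5, ...) {
  qc <- qc_filter(collection, ...)
  out <- interpolate_gaps(qc$collection)
  out <- downsample(out, target_fps = target_fps)
  list(collection = out, exclusions = qc$exclusions)
}
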