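#' Dual EEG recording container
#'
#' Holds two synchronized channels-by-samples signal blocks, one per
#' participant, with a shared sampling rate. Band information is tracked so
#' that downstream phase estimation can refuse broadband input.
#'
#' @param p1,p2 numeric matrices, channels x samples; equal dimensions.
#' @param sampling_rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per channel (shared by
#'   both participants). Defaults to the first `nrow(p1)` entries of
#'   [channels_29].
#' @param band numeric `c(low, high)` in Hz if the signals are band-limited,
#'   else `NULL`.
#' @param band_tag one of `"none"`, `"broadband"`, a named band in
#'   [eeg_bands], or `"custom"`.
#' @param bad_channels list of two character vectors naming bad channels per
#'   participant.
#' @return An object of class `dual_recording`.
#' @export
dual_recording <- function(p1, p2, sampling_rate,
                           channel_labels = NULL,
                           band = NULL, band_tag = "none",
                           bad_channels = list(character(0), character(0))) {
  p1 <- as.matrix(p1)
  p2 <- as.matrix(p2)
  if (!all(dim(p1) == dim(p2))) {
    stop("participant blocks must have identical dimensions")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("sampling_rate must be a positive number")
  }
  if (is.null(channel_labels)) {
    if (nrow(p1) > length(channels_29)) {
      channel_labels <- sprintf("ch%02d", seq_len(nrow(p1)))
    } else {
      channel_labels <- channels_29[seq_len(nrow(p1))]
    }
  }
  if (length(channel_labels) != nrow(p1)) {
    stop("channel_labels length must equal the number of channels")
  }
  if (anyDuplicated(channel_labels)) {
    stop("channel_labels must be unique within a participant")
  }
  rownames(p1) <- rownames(p2) <- channel_labels
  structure(
    list(
      signals = list(p1, p2),
      sampling_rate = sampling_rate,
      channel_labels = channel_labels,
      band = band,
      band_tag = band_tag,
      bad_channels = bad_channels
    ),
    class = "dual_recording"
  )
}

#' @export
print.dual_recording <- function(x, ...) {
  cat(sprintf(
    "<dual_recording> %d channels x %d samples per participant @ %g Hz, band: %s\n",
    nrow(x$signals[[1]]), ncol(x$signals[[1]]), x$sampling_rate, x$band_tag
  ))
  invisible(x)
}

n_channels <- function(rec) nrow(rec$signals[[1]])
n_samples <- function(rec) ncol(rec$signals[[1]])

# Tag a (low, high) pair with its named band, if any.
match_band_tag <- function(low, high, bands = eeg_bands) {
  for (nm in names(bands)) {
    if (isTRUE(all.equal(c(low, high), unname(bands[[nm]])))) {
      return(nm)
    }
  }
  "custom"
}

#' Write / read dual-recording signal matrices as TSV
#'
#' One file per participant: samples in rows, channels in columns, header
#' row of channel labels. Plain-text sibling of binary EEG interchange
#' formats, and the fixture format used by the simulator.
#'
#' @param rec a [dual_recording()].
#' @param paths character vector of two output file paths.
#' @return `write_eeg_tsv`: `paths`, invisibly. `read_eeg_tsv`: a
#'   [dual_recording()].
#' @export
write_eeg_tsv <- function(rec, paths) {
  stopifnot(inherits(rec, "dual_recording"), length(paths) == 2)
  for (p in 1:2) {
    m <- t(rec$signals[[p]])
    colnames(m) <- rec$channel_labels
    utils::write.table(m, paths[p], sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' @rdname write_eeg_tsv
#' @param sampling_rate sampling rate (Hz) of the stored signals.
#' @export
read_eeg_tsv <- function(paths, sampling_rate) {
  stopifnot(length(paths) == 2)
  blocks <- lapply(paths, function(p) {
    m <- as.matrix(utils::read.table(p, sep = "\t", header = TRUE,
                                     check.names = FALSE))
    t(m)
  })
  if (!identical(rownames(blocks[[1]]), rownames(blocks[[2]]))) {
    stop("the two TSV files carry different channel labels")
  }
  dual_recording(blocks[[1]], blocks[[2]], sampling_rate,
                 channel_labels = rownames(blocks[[1]]))
}

#' Write / read tap-onset CSV files
#'
#' Two-column CSV (`participant_id`, `onset_seconds`), one row per tap,
#' holding both participants of a dyad; an optional `condition` column is
#' preserved.
#'
#' @param p1,p2 [tap_record()] objects.
#' @param path CSV file path.
#' @return `write_tap_csv`: `path` invisibly; `read_tap_csv`: list with
#'   elements `p1` and `p2` ([tap_record()]s).
#' @export
write_tap_csv <- function(p1, p2, path) {
  df <- rbind(
    data.frame(participant_id = p1$participant_id, onset_seconds = p1$onsets,
               condition = p1$condition),
    data.frame(participant_id = p2$participant_id, onset_seconds = p2$onsets,
               condition = p2$condition)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_tap_csv
#' @export
read_tap_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$participant_id)
  if (length(ids) != 2) {
    stop("tap CSV must contain exactly two participant ids, found ",
         length(ids))
  }
  recs <- lapply(ids, function(id) {
    sub <- df[df$participant_id == id, , drop = FALSE]
    cond <- if ("condition" %in% names(sub)) sub$condition[1] else "free"
    tap_record(sub$onset_seconds, participant_id = id, condition = cond)
  })
  names(recs) <- c("p1", "p2")
  recs
}
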