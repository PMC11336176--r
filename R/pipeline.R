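#' Study configuration
#'
#' Describes a full analysis: the dyads (recordings plus tap records per
#' condition), the frequency bands, and the surrogate/threshold settings.
#'
#' Each element of `pairs` is a list with fields:
#' \describe{
#'   \item{pair_id}{identifier.}
#'   \item{group}{e.g. `"stranger"` or `"acquaintance"`.}
#'   \item{recordings}{named list (by condition) of [dual_recording()]
#'     objects, or length-2 character vectors of TSV paths (then
#'     `raw_rate` must be given).}
#'   \item{taps}{named list (by condition) of either a
#'     `list(p1 =, p2 =)` of [tap_record()]s or a tap CSV path; optional.}
#'   \item{bad_channels}{optional list of two character vectors.}
#' }
#'
#' @param pairs list of pair descriptions (above).
#' @param bands named list of `c(low, high)` Hz (default theta, alpha,
#'   beta from [eeg_bands]).
#' @param conditions conditions to analyse (default: those present).
#' @param n_surrogates surrogate replicates per recording (default 100).
#' @param alpha family-wise significance level (default 0.05).
#' @param target_rate analysis sampling rate in Hz (default 250).
#' @param broadband broad artifact-rejection band applied before the
#'   narrow bands, Hz (default `c(1, 45)`).
#' @param trim_seconds edge trim forwarded to [hilbert_phase()].
#' @param raw_rate sampling rate of TSV recordings read from disk.
#' @param surrogate_method forwarded to [significance_mask()].
#' @param seed root seed; every (pair, condition, band) gets a derived
#'   substream.
#' @return Object of class `study_config`.
#' @export
study_config <- function(pairs, bands = eeg_bands,
                         conditions = NULL, n_surrogates = 100,
                         alpha = 0.05, target_rate = 250,
                         broadband = c(1, 45), trim_seconds = NULL,
                         raw_rate = 500,
                         surrogate_method = "t_test", seed = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (anyDuplicated(names(bands))) stop("band names must be unique")
  if (!is.null(conditions) && anyDuplicated(conditions)) {
    stop("condition names must be unique")
  }
  for (p in pairs) {
    if (is.null(p$pair_id) || is.null(p$recordings)) {
      stop("every pair needs pair_id and recordings")
    }
  }
  structure(
    list(pairs = pairs, bands = bands, conditions = conditions,
         n_surrogates = n_surrogates, alpha = alpha,
         target_rate = target_rate, broadband = broadband,
         trim_seconds = trim_seconds, raw_rate = raw_rate,
         surrogate_method = surrogate_method, seed = seed),
    class = "study_config"
  )
}

# Resolve one pair's recording for one condition into a dual_recording.
resolve_recording <- function(entry, config) {
  if (inherits(entry, "dual_recording")) {
    return(entry)
  }
  if (is.character(entry) && length(entry) == 2) {
    return(read_eeg_tsv(entry, sampling_rate = config$raw_rate))
  }
  stop("recording must be a dual_recording or two TSV paths")
}

resolve_taps <- function(entry) {
  if (is.null(entry)) {
    return(NULL)
  }
  if (is.character(entry) && length(entry) == 1) {
    return(read_tap_csv(entry))
  }
  if (is.list(entry) && inherits(entry$p1, "tap_record")) {
    return(entry)
  }
  stop("taps must be a tap CSV path or list(p1 =, p2 =) of tap_records")
}

#' Run the full hyperscanning pipeline
#'
#' For every pair x condition x band: preprocess (downsample, broadband
#' then narrow-band zero-phase filtering, bad-channel interpolation),
#' extract Hilbert phases, compute synchrony matrices and their averages,
#' build the surrogate-thresholded binary hyperbrain graph, and evaluate
#' its topology metrics; behavioral statistics are added once per pair x
#' condition. Per-pair failures are recorded and the run continues.
#'
#' @param config a [study_config()].
#' @param out_dir optional directory; when given, synchrony matrices and
#'   graphs are written there with provenance metadata.
#' @param verbose print per-stage progress lines.
#' @return A `results_table`: data.frame with one row per
#'   (pair, condition, band) carrying behavioral, synchrony, and topology
#'   columns, with attribute `failures` (character vector).
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  rows <- list()
  failures <- character(0)
  say <- function(...) if (verbose) message(sprintf(...))
  for (pi in seq_along(config$pairs)) {
    pair <- config$pairs[[pi]]
    conds <- config$conditions
    if (is.null(conds)) conds <- names(pair$recordings)
    for (cond in conds) {
      res <- tryCatch(
        run_one(pair, cond, config, out_dir, say, pair_idx = pi),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        failures <- c(failures, sprintf("%s/%s: %s", pair$pair_id, cond,
                                        conditionMessage(res)))
        next
      }
      rows <- c(rows, res)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failures") <- failures
  class(out) <- c("results_table", class(out))
  out
}

run_one <- function(pair, cond, config, out_dir, say, pair_idx = 1L) {
  rec <- resolve_recording(pair$recordings[[cond]], config)
  if (!is.null(pair$bad_channels)) rec$bad_channels <- pair$bad_channels
  say("[%s/%s] preprocessing (%d ch, %g Hz)", pair$pair_id, cond,
      n_channels(rec), rec$sampling_rate)
  rec <- eeg_downsample(rec, config$target_rate)
  rec <- eeg_bandpass(rec, config$broadband[1], config$broadband[2])
  rec$band_tag <- "broadband"
  rec <- interpolate_bad_channels(rec)

  taps <- resolve_taps(pair$taps[[cond]])
  behav <- if (is.null(taps)) {
    data.frame(mean_iti = NA_real_, sdrp = NA_real_,
               resultant_length = NA_real_, n_matched = NA_integer_)
  } else {
    behavioral_summary(taps$p1, taps$p2)[
      , c("mean_iti", "sdrp", "resultant_length", "n_matched")]
  }

  rows <- list()
  for (band_name in names(config$bands)) {
    b <- config$bands[[band_name]]
    sub_seed <- derive_seed(config$seed,
                            pair_idx * 7919 +
                              match(band_name, names(config$bands)) * 131 +
                              which(cond == names(pair$recordings)))
    say("[%s/%s] band %s (%g-%g Hz)", pair$pair_id, cond, band_name,
        b[1], b[2])
    narrow <- eeg_bandpass(rec, b[1], b[2])
    ps <- hilbert_phase(narrow, trim_seconds = config$trim_seconds)
    sync <- sync_matrices(ps)
    avg <- average_sync(sync)
    ens <- surrogate_ensemble(narrow, n = config$n_surrogates,
                              seed = sub_seed,
                              trim_seconds = config$trim_seconds)
    g <- significance_mask(sync, ens, alpha = config$alpha,
                           method = config$surrogate_method)
    gm <- graph_metrics(g)
    if (!is.null(out_dir)) {
      d <- file.path(out_dir, pair$pair_id, cond)
      write_sync_tsv(sync, d, prefix = band_name)
      write_graph_files(g, d, prefix = band_name)
    }
    rows[[band_name]] <- cbind(
      data.frame(pair_id = pair$pair_id,
                 group = if (is.null(pair$group)) NA_character_
                         else pair$group,
                 condition = cond, band = band_name,
                 n_samples_used = sync$n_samples_used,
                 seed = sub_seed,
                 averaged_wpli_1 = avg$averaged_wpli_1,
                 averaged_wpli_2 = avg$averaged_wpli_2,
                 averaged_plv = avg$averaged_plv,
                 stringsAsFactors = FALSE),
      behav, gm
    )
  }
  rows
}

#' Write the results table as tidy TSV
#'
#' @param results a `results_table` from [run_pipeline()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Paired t-tests over all condition contrasts with Holm correction
#'
#' @param values numeric matrix, one row per subject (or dyad), one column
#'   per condition (named).
#' @return data.frame with one row per unordered condition contrast:
#'   `contrast`, `t`, `df`, `p`, `p_adj` (Holm step-down over all
#'   contrasts). Contrasts with missing cells are skipped with a warning.
#' @export
paired_t_holm <- function(values) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("c", seq_len(ncol(values)))
  }
  combs <- utils::combn(colnames(values), 2, simplify = FALSE)
  rows <- list()
  for (cc in combs) {
    a <- values[, cc[1]]
    b <- values[, cc[2]]
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) < 2) {
      warning("contrast ", cc[1], "-", cc[2], " skipped: missing cells")
      next
    }
    d <- a[ok] - b[ok]
    if (stats::sd(d) == 0) {
      tt <- list(statistic = c(t = 0), parameter = c(df = sum(ok) - 1),
                 p.value = 1)
      if (mean(d) != 0) {
        tt$statistic <- c(t = sign(mean(d)) * Inf)
        tt$p.value <- 0
      }
    } else {
      tt <- stats::t.test(a[ok], b[ok], paired = TRUE)
    }
    rows[[length(rows) + 1]] <- data.frame(
      contrast = paste(cc[1], cc[2], sep = "-"),
      t = unname(tt$statistic), df = unname(tt$parameter),
      p = tt$p.value, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "holm")
  out
}

#' Bonferroni adjustment
#'
#' `min(1, p * m)` for each p-value; `m` defaults to the number of tests.
#'
#' @param pvals numeric p-values in `[0, 1]`.
#' @param m number of tests.
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(pvals, m = length(pvals)) {
  if (any(!is.finite(pvals)) || any(pvals < 0) || any(pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  pmin(1, pvals * m)
}
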