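#' Tap record
#'
#' Ordered tap-onset times for one participant in one session.
#'
#' @param onsets strictly increasing numeric vector of onset times
#'   (seconds), length >= 2.
#' @param participant_id identifier.
#' @param condition one of slow/fast/free/pseudo (free-form allowed).
#' @return Object of class `tap_record`.
#' @export
tap_record <- function(onsets, participant_id = "p1", condition = "free") {
  onsets <- as.numeric(onsets)
  if (length(onsets) < 2) {
    stop("a tap record needs at least two onsets")
  }
  if (any(diff(onsets) <= 0)) {
    stop("tap onsets must be strictly increasing")
  }
  structure(
    list(onsets = onsets, participant_id = participant_id,
         condition = condition),
    class = "tap_record"
  )
}

#' @export
print.tap_record <- function(x, ...) {
  cat(sprintf("<tap_record> %s (%s): %d taps over %.2f s\n",
              x$participant_id, x$condition, length(x$onsets),
              diff(range(x$onsets))))
  invisible(x)
}

#' Merge two tap records into one time-sorted dyadic stream
#'
#' The dyad-level mean inter-tap interval is defined on the merged stream
#' of both participants' taps (in alternating tapping the dyadic rate is
#' twice the individual rate).
#'
#' @param p1,p2 [tap_record()] objects.
#' @return A [tap_record()] with the union of onsets.
#' @export
merge_tap_records <- function(p1, p2) {
  onsets <- make_strict(sort(c(p1$onsets, p2$onsets)))
  tap_record(onsets, participant_id = "dyad", condition = p1$condition)
}

#' Inter-tap intervals and their mean
#'
#' `ITI_m = t(m+1) - t(m)` over consecutive onsets of the given record.
#' Pass a merged record (see [merge_tap_records()]) for the dyad-level
#' mean ITI; pass an individual record for per-participant intervals.
#'
#' @param taps a [tap_record()].
#' @return List with `iti` (numeric vector, length `M - 1`) and `mean_iti`.
#' @export
compute_iti <- function(taps) {
  stopifnot(inherits(taps, "tap_record"))
  iti <- diff(taps$onsets)
  list(iti = iti, mean_iti = mean(iti))
}

#' Relative phase of dyadic tapping
#'
#' For each participant-1 interval `[t(n), t(n+1))`, the first participant-2
#' onset falling in it (closed on the left) is matched, and
#' `RP_n = (t(n)_p2 - t(n)_p1) / (t(n+1)_p1 - t(n)_p1) * 360`, wrapped into
#' `[0, 360)`. 180 degrees is perfect anti-phase. Intervals holding no
#' participant-2 tap are skipped; intervals holding several use the first,
#' and both situations are counted in the returned coverage fields.
#'
#' @param p1,p2 [tap_record()] objects; participant 1 defines the intervals.
#' @return Object of class `relative_phase_series`: `rp_values` (degrees in
#'   `[0, 360)`), `n_points`, `n_skipped`, `n_multi`.
#' @export
relative_phase <- function(p1, p2) {
  stopifnot(inherits(p1, "tap_record"), inherits(p2, "tap_record"))
  t1 <- p1$onsets
  t2 <- p2$onsets
  rp <- numeric(0)
  n_skipped <- 0L
  n_multi <- 0L
  for (n in seq_len(length(t1) - 1)) {
    inside <- which(t2 >= t1[n] & t2 < t1[n + 1])
    if (length(inside) == 0) {
      n_skipped <- n_skipped + 1L
      next
    }
    if (length(inside) > 1) n_multi <- n_multi + 1L
    frac <- (t2[inside[1]] - t1[n]) / (t1[n + 1] - t1[n])
    rp <- c(rp, (frac * 360) %% 360)
  }
  structure(
    list(rp_values = rp, n_points = length(rp),
         n_skipped = n_skipped, n_multi = n_multi),
    class = "relative_phase_series"
  )
}

#' @export
print.relative_phase_series <- function(x, ...) {
  cat(sprintf(
    "<relative_phase_series> %d points (skipped %d, multi-tap %d), circular mean %.1f deg\n",
    x$n_points, x$n_skipped, x$n_multi,
    (Arg(mean(exp(1i * x$rp_values * pi / 180))) * 180 / pi) %% 360
  ))
  invisible(x)
}

#' Circular spread of the relative-phase distribution
#'
#' Resultant length `R = |mean(exp(i RP))|` (RP in radians) and the
#' circular standard deviation `SDRP = sqrt(-2 log R)`, the instability of
#' anti-phase coordination. `R = 0` (e.g. antipodal RP values) yields an
#' infinite SDRP, flagged via `degenerate = TRUE`.
#'
#' @param rp a [relative_phase()] result, or a numeric vector of RP values
#'   in degrees.
#' @return List with `resultant_length`, `sdrp`, `n`, `degenerate`.
#' @export
circular_sdrp <- function(rp) {
  vals <- if (inherits(rp, "relative_phase_series")) rp$rp_values else rp
  if (length(vals) < 1) stop("need at least one relative-phase value")
  rad <- vals * pi / 180
  R <- Mod(mean(exp(1i * rad)))
  degenerate <- R <= .Machine$double.eps^0.5
  sdrp <- if (degenerate) Inf else sqrt(-2 * log(min(R, 1)))
  list(resultant_length = R, sdrp = sdrp, n = length(vals),
       degenerate = degenerate)
}

#' Behavioral summary of one dyad/condition
#'
#' Dyad-level mean ITI (merged tap stream), per-participant mean ITIs,
#' relative phase coverage, resultant length, and SDRP.
#'
#' @param p1,p2 [tap_record()] objects.
#' @return One-row data.frame: `condition`, `mean_iti`, `mean_iti_p1`,
#'   `mean_iti_p2`, `resultant_length`, `sdrp`, `n_matched`, `n_skipped`.
#' @export
behavioral_summary <- function(p1, p2) {
  merged <- merge_tap_records(p1, p2)
  rp <- relative_phase(p1, p2)
  circ <- circular_sdrp(rp)
  data.frame(
    condition = p1$condition,
    mean_iti = compute_iti(merged)$mean_iti,
    mean_iti_p1 = compute_iti(p1)$mean_iti,
    mean_iti_p2 = compute_iti(p2)$mean_iti,
    resultant_length = circ$resultant_length,
    sdrp = circ$sdrp,
    n_matched = rp$n_points,
    n_skipped = rp$n_skipped,
    stringsAsFactors = FALSE
  )
}

#' Welch's unequal-variance two-sample t-test
#'
#' Thin wrapper around [stats::t.test()] (`var.equal = FALSE`) returning
#' the statistic, Welch-Satterthwaite degrees of freedom, and two-sided p.
#' The degenerate case of two zero-variance groups is resolved by
#' convention: equal means give `t = 0, p = 1`; distinct means give
#' `t = +/-Inf, p = 0`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop("each group needs at least two values")
  }
  if (!all(is.finite(group_a)) || !all(is.finite(group_b))) {
    stop("groups must contain only finite values")
  }
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      return(list(t = 0, df = length(group_a) + length(group_b) - 2, p = 1))
    }
    return(list(t = sign(mean(group_a) - mean(group_b)) * Inf,
                df = length(group_a) + length(group_b) - 2, p = 0))
  }
  fit <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(fit$statistic), df = unname(fit$parameter),
       p = fit$p.value)
}
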