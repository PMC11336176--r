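#' Weighted phase lag index of two analytic signals
#'
#' `wPLI = |sum_t |Im(C_t)| sgn(Im(C_t))| / sum_t |Im(C_t)|` where
#' `C_t = x(t) * Conj(y(t))` is the per-sample cross-spectrum of the two
#' Hilbert analytic signals. Weighting by `|Im(C)|` discounts phase
#' differences near 0 or pi, making the index insensitive to zero-lag
#' (volume-conducted) synchrony. When every `Im(C_t)` is zero (identical
#' or exactly in/anti-phase signals) the index is 0 by convention, with
#' attribute `degenerate = TRUE`.
#'
#' @param x_analytic,y_analytic complex vectors of equal length >= 2.
#' @return Scalar in `[0, 1]`.
#' @export
wpli <- function(x_analytic, y_analytic) {
  if (length(x_analytic) != length(y_analytic)) {
    stop("signals must have equal length")
  }
  if (length(x_analytic) < 2) stop("need at least two samples")
  im_c <- Im(x_analytic * Conj(y_analytic))
  den <- sum(abs(im_c))
  if (den == 0) {
    return(structure(0, degenerate = TRUE))
  }
  abs(sum(abs(im_c) * sign(im_c))) / den
}

#' Phase locking value of two phase series
#'
#' `PLV = |mean_t exp(i (phi(t) - psi(t)))|`: the length of the average
#' unit phasor of the phase difference. 1 means a constant phase
#' difference, 0 a uniformly dispersed one.
#'
#' @param phase_i,phase_k numeric phase vectors (radians), equal length.
#' @return Scalar in `[0, 1]`.
#' @export
plv <- function(phase_i, phase_k) {
  if (length(phase_i) != length(phase_k)) {
    stop("phase series must have equal length")
  }
  if (length(phase_i) < 1) stop("need at least one sample")
  Mod(mean(exp(1i * (phase_i - phase_k))))
}

# Dense symmetric wPLI matrix over all unordered channel pairs of one
# participant's analytic block (channels x samples). Diagonal is NA.
wpli_matrix <- function(A) {
  nch <- nrow(A)
  M <- matrix(NA_real_, nch, nch, dimnames = list(rownames(A), rownames(A)))
  for (i in seq_len(nch - 1)) {
    C <- sweep(A[(i + 1):nch, , drop = FALSE], 2, Conj(A[i, ]), `*`)
    im_c <- Im(C)
    num <- abs(rowSums(im_c))
    den <- rowSums(abs(im_c))
    v <- ifelse(den == 0, 0, num / pmax(den, .Machine$double.xmin))
    M[i, (i + 1):nch] <- v
    M[(i + 1):nch, i] <- v
  }
  M
}

#' Intra- and inter-brain synchrony matrices
#'
#' Applies [wpli()] to every unordered within-participant channel pair
#' (29 channels give choose(29, 2) = 406 pairs each) and [plv()] to every
#' cross-participant pair (29 x 29 = 841), after discarding the
#' edge-trimmed samples flagged by [hilbert_phase()].
#'
#' @param phases a `phase_set` from [hilbert_phase()].
#' @return Object of class `sync_matrices`: `intra_1`, `intra_2` (symmetric
#'   wPLI matrices, `NA` diagonal), `inter` (PLV matrix, rows =
#'   participant-1 channels), `band_tag`, `n_samples_used`.
#' @export
sync_matrices <- function(phases) {
  stopifnot(inherits(phases, "phase_set"))
  keep <- kept_samples(phases)
  A1 <- phases$analytic[[1]][, keep, drop = FALSE]
  A2 <- phases$analytic[[2]][, keep, drop = FALSE]
  P1 <- phases$phases[[1]][, keep, drop = FALSE]
  P2 <- phases$phases[[2]][, keep, drop = FALSE]
  E1 <- exp(1i * P1)
  E2 <- exp(1i * P2)
  inter <- Mod(E1 %*% Conj(t(E2))) / ncol(P1)
  dimnames(inter) <- list(phases$channel_labels, phases$channel_labels)
  structure(
    list(intra_1 = wpli_matrix(A1), intra_2 = wpli_matrix(A2),
         inter = inter, band_tag = phases$band_tag,
         n_samples_used = length(keep)),
    class = "sync_matrices"
  )
}

#' @export
print.sync_matrices <- function(x, ...) {
  cat(sprintf(
    "<sync_matrices> %d channels/participant, band %s, T = %d\n",
    nrow(x$inter), x$band_tag, x$n_samples_used
  ))
  invisible(x)
}

#' Average synchrony strengths
#'
#' Arithmetic means over all intra-brain wPLI pairs per participant
#' (averaged-wPLI) and over all inter-brain PLV pairs (averaged-PLV).
#' `NA` entries (masked diagonal aside) are excluded and counted.
#'
#' @param sync a [sync_matrices()] result.
#' @return List with `averaged_wpli_1`, `averaged_wpli_2`, `averaged_plv`,
#'   `n_intra_pairs`, `n_inter_pairs`, `n_masked`.
#' @export
average_sync <- function(sync) {
  stopifnot(inherits(sync, "sync_matrices"))
  up1 <- sync$intra_1[upper.tri(sync$intra_1)]
  up2 <- sync$intra_2[upper.tri(sync$intra_2)]
  inter <- as.vector(sync$inter)
  n_masked <- sum(is.na(up1)) + sum(is.na(up2)) + sum(is.na(inter))
  list(
    averaged_wpli_1 = mean(up1, na.rm = TRUE),
    averaged_wpli_2 = mean(up2, na.rm = TRUE),
    averaged_plv = mean(inter, na.rm = TRUE),
    n_intra_pairs = sum(!is.na(up1)),
    n_inter_pairs = sum(!is.na(inter)),
    n_masked = n_masked
  )
}

# 2n x 2n combined synchrony matrix with blocks
# [intra_1, inter; t(inter), intra_2]; node i pairs with node k at [i, k].
combined_sync_matrix <- function(sync) {
  rbind(
    cbind(sync$intra_1, sync$inter),
    cbind(t(sync$inter), sync$intra_2)
  )
}

#' Write synchrony matrices as labeled TSV
#'
#' One file per matrix (`intra_1`, `intra_2`, `inter`) with row and column
#' channel labels, plus a small JSON-ish metadata file (band, T).
#'
#' @param sync a [sync_matrices()] result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Paths written, invisibly.
#' @export
write_sync_tsv <- function(sync, dir, prefix = "sync") {
  stopifnot(inherits(sync, "sync_matrices"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("intra_1", "intra_2", "inter")) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    utils::write.table(sync[[nm]], p, sep = "\t", quote = FALSE,
                       col.names = NA)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, paste0(prefix, "_meta.txt"))
  writeLines(c(paste("band_tag", sync$band_tag),
               paste("n_samples_used", sync$n_samples_used)), meta)
  invisible(c(paths, meta))
}
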