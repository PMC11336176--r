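#' Fourier phase-randomization surrogate of one signal
#'
#' Transforms the signal to the frequency domain, randomly permutes the
#' phase values of the positive-frequency bins while keeping every bin's
#' amplitude (so the power spectrum is preserved bin-for-bin), enforces
#' conjugate symmetry (DC and Nyquist bins stay real), and inverse
#' transforms. Phase relations with every other signal are destroyed;
#' the autospectrum is untouched.
#'
#' @param x real numeric vector, length >= 4.
#' @param seed optional RNG seed (caller's RNG state is restored).
#' @return Real numeric vector of the same length.
#' @export
phase_randomize <- function(x, seed = NULL) {
  n <- length(x)
  if (n < 4) stop("signal too short to phase-randomize (need >= 4 samples)")
  if (!all(is.finite(x))) stop("signal must be finite")
  with_seed(seed, {
    X <- stats::fft(x)
    pos <- if (n %% 2 == 0) 2:(n / 2) else 2:((n + 1) / 2)
    ph <- Arg(X[pos])
    ph_perm <- sample(ph, length(ph))
    X[pos] <- Mod(X[pos]) * exp(1i * ph_perm)
    neg <- n + 2 - pos
    X[neg] <- Conj(X[pos])
    Re(stats::fft(X, inverse = TRUE)) / n
  })
}

#' Surrogate ensemble of synchrony values
#'
#' For each of `n` surrogate replicates, every channel of the band-limited
#' recording is independently phase-randomized, Hilbert phases are
#' recomputed, and the full channel-pair metric set (intra-brain wPLI,
#' inter-brain PLV) is evaluated — yielding, per channel pair, a null
#' distribution of synchrony values under preserved power spectra but
#' destroyed phase relations.
#'
#' @param rec a band-limited [dual_recording()] (after [eeg_bandpass()]).
#' @param n number of surrogate replicates (default 100; >= 2).
#' @param seed root seed; each replicate and channel gets a derived
#'   substream.
#' @param trim_seconds forwarded to [hilbert_phase()].
#' @return Object of class `surrogate_ensemble`: `values`
#'   (2n_ch x 2n_ch x n array of combined synchrony matrices),
#'   `n_surrogates`, `band_tag`, `channel_labels`.
#' @export
surrogate_ensemble <- function(rec, n = 100, seed = 1, trim_seconds = NULL) {
  stopifnot(inherits(rec, "dual_recording"))
  if (rec$band_tag %in% c("none", "broadband") || is.null(rec$band)) {
    stop("surrogates are built from band-limited recordings")
  }
  if (n < 2) {
    stop("need at least 2 surrogates to form a null distribution")
  }
  nch <- n_channels(rec)
  vals <- array(NA_real_, dim = c(2 * nch, 2 * nch, n))
  for (r in seq_len(n)) {
    blocks <- rec$signals
    for (p in 1:2) {
      for (ch in seq_len(nch)) {
        s <- derive_seed(seed, (r - 1) * 2 * nch + (p - 1) * nch + ch)
        blocks[[p]][ch, ] <- phase_randomize(blocks[[p]][ch, ], seed = s)
      }
    }
    surr <- dual_recording(blocks[[1]], blocks[[2]],
                           sampling_rate = rec$sampling_rate,
                           channel_labels = rec$channel_labels,
                           band = rec$band, band_tag = rec$band_tag)
    ps <- hilbert_phase(surr, trim_seconds = trim_seconds)
    vals[, , r] <- combined_sync_matrix(sync_matrices(ps))
  }
  structure(
    list(values = vals, n_surrogates = n, band_tag = rec$band_tag,
         channel_labels = rec$channel_labels),
    class = "surrogate_ensemble"
  )
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  nch <- dim(x$values)[1] / 2
  cat(sprintf(
    "<surrogate_ensemble> %d surrogates, %d channels/participant, band %s\n",
    x$n_surrogates, nch, x$band_tag
  ))
  invisible(x)
}

#' Binary hyperbrain graph container
#'
#' @param adjacency symmetric binary matrix, zero diagonal; nodes are
#'   participant-1 channels then participant-2 channels.
#' @param module_of integer vector (1 or 2) giving each node's participant.
#' @param node_labels node names.
#' @param band_tag,alpha_per_test,n_surrogates metadata carried along.
#' @return Object of class `hyperbrain_graph`.
#' @export
hyperbrain_graph <- function(adjacency, module_of,
                             node_labels = rownames(adjacency),
                             band_tag = "custom", alpha_per_test = NA_real_,
                             n_surrogates = NA_integer_) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!isTRUE(all.equal(adjacency, t(adjacency)))) {
    stop("adjacency must be symmetric")
  }
  if (length(module_of) != nrow(adjacency)) {
    stop("module_of must assign every node")
  }
  if (is.null(node_labels)) {
    node_labels <- sprintf("n%02d", seq_len(nrow(adjacency)))
  }
  dimnames(adjacency) <- list(node_labels, node_labels)
  structure(
    list(adjacency = adjacency, module_of = as.integer(module_of),
         node_labels = node_labels, band_tag = band_tag,
         alpha_per_test = alpha_per_test, n_surrogates = n_surrogates),
    class = "hyperbrain_graph"
  )
}

#' @export
print.hyperbrain_graph <- function(x, ...) {
  cat(sprintf(
    "<hyperbrain_graph> %d nodes, %d edges, band %s, alpha/test %.3g\n",
    nrow(x$adjacency), sum(x$adjacency) / 2, x$band_tag, x$alpha_per_test
  ))
  invisible(x)
}

#' Surrogate significance test and binary hyperbrain adjacency
#'
#' Per channel pair, the original synchrony value is compared with its
#' surrogate null distribution; pairs whose original value is
#' significantly larger than their surrogates become edges of a binary
#' undirected graph over the `2 * n_ch` nodes (participant-1 channels
#' first).
#'
#' Methods:
#' \describe{
#'   \item{`"t_test"`}{one-sample t-test of the surrogate values against
#'     the original value, one-sided (surrogate mean below the original);
#'     the study procedure. Note this extrapolates far into the null tail
#'     and is anti-conservative under the null (see the methods vignette).}
#'   \item{`"percentile"`}{empirical rank p-value
#'     `(1 + #\{surrogate >= original\}) / (n + 1)`; exact and
#'     conservative, but with `n` surrogates it cannot reject below
#'     `1 / (n + 1)`.}
#' }
#' The significance level is Bonferroni-corrected over all tested pairs:
#' for two 29-channel participants, 406 + 406 + 841 = 1653 pairs, so each
#' pair is tested at `alpha / 1653`. The pair count is recomputed from the
#' actual montage; pass `m` to force a fixed denominator.
#'
#' @param original a [sync_matrices()] result from the original recording.
#' @param ensemble a [surrogate_ensemble()] over the same recording.
#' @param alpha family-wise significance level (default 0.05).
#' @param method `"t_test"` (default) or `"percentile"`.
#' @param m Bonferroni denominator; default: number of tested pairs.
#' @return A [hyperbrain_graph()] with `alpha_per_test` set.
#' @export
significance_mask <- function(original, ensemble, alpha = 0.05,
                              method = c("t_test", "percentile"), m = NULL) {
  stopifnot(inherits(original, "sync_matrices"),
            inherits(ensemble, "surrogate_ensemble"))
  method <- match.arg(method)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  orig <- combined_sync_matrix(original)
  s <- nrow(orig)
  if (!all(dim(ensemble$values)[1:2] == s)) {
    stop("original and ensemble cover different channel sets")
  }
  nch <- s / 2
  n_pairs <- nch * (nch - 1) + nch * nch   # 2 * choose(nch, 2) + nch^2
  if (is.null(m)) m <- n_pairs
  alpha_per_test <- alpha / m

  n <- ensemble$n_surrogates
  surr_mean <- apply(ensemble$values, c(1, 2), mean)
  if (method == "t_test") {
    surr_sd <- apply(ensemble$values, c(1, 2), stats::sd)
    se <- surr_sd / sqrt(n)
    tstat <- (surr_mean - orig) / se
    p <- stats::pt(tstat, df = n - 1)            # one-sided: mean < original
    # Zero surrogate variance: infinite separation if the original differs,
    # no evidence if it coincides with the constant surrogate value.
    zero_var <- is.finite(orig) & surr_sd == 0
    p[zero_var] <- ifelse(orig[zero_var] > surr_mean[zero_var], 0, 1)
  } else {
    exceed <- apply(sweep(ensemble$values, c(1, 2), orig, `>=`),
                    c(1, 2), sum)
    p <- (1 + exceed) / (n + 1)
  }
  adj <- (orig > surr_mean) & (p < alpha_per_test)
  adj[is.na(adj)] <- FALSE                       # masked diagonal
  adj <- adj | t(adj)                            # symmetry (blocks already are)
  storage.mode(adj) <- "double"
  diag(adj) <- 0
  labels <- c(paste0("P1_", ensemble$channel_labels),
              paste0("P2_", ensemble$channel_labels))
  g <- hyperbrain_graph(adj, module_of = rep(1:2, each = nch),
                        node_labels = labels, band_tag = original$band_tag,
                        alpha_per_test = alpha_per_test, n_surrogates = n)
  attr(g, "n_pairs_tested") <- n_pairs
  g
}

#' Serialize a hyperbrain graph
#'
#' Writes (a) the labeled adjacency TSV, (b) an edge list
#' (`node_i`, `node_k`), and (c) a plain-text metadata file.
#'
#' @param g a [hyperbrain_graph()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @return Paths, invisibly.
#' @export
write_graph_files <- function(g, dir, prefix = "graph") {
  stopifnot(inherits(g, "hyperbrain_graph"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  adj_path <- file.path(dir, paste0(prefix, "_adjacency.tsv"))
  utils::write.table(g$adjacency, adj_path, sep = "\t", quote = FALSE,
                     col.names = NA)
  ek <- which(g$adjacency == 1 & upper.tri(g$adjacency), arr.ind = TRUE)
  el <- data.frame(node_i = g$node_labels[ek[, 1]],
                   node_k = g$node_labels[ek[, 2]])
  el_path <- file.path(dir, paste0(prefix, "_edges.tsv"))
  utils::write.table(el, el_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  meta_path <- file.path(dir, paste0(prefix, "_meta.txt"))
  writeLines(c(paste("band_tag", g$band_tag),
               paste("alpha_per_test", g$alpha_per_test),
               paste("n_surrogates", g$n_surrogates)), meta_path)
  invisible(c(adj_path, el_path, meta_path))
}
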