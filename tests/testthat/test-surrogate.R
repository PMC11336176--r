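# Small band-limited dyad used across surrogate tests.
small_band_rec <- function(n_ch = 3, seed = 5, duration = 8, k_inter = 0,
                           noise_sd = 0.2, fs = 125) {
  cfg <- sim_config(n_channels = n_ch, sampling_rate = fs,
                    duration = duration, k_intra_1 = 0, k_intra_2 = 0,
                    k_inter = k_inter, noise_sd = noise_sd, seed = seed)
  eeg_bandpass(generate_coupled_pair(cfg), 8, 12)
}

test_that("phase randomization preserves the power spectrum bin-for-bin", {
  set.seed(10)
  inputs <- list(
    rnorm(1024),
    sin(2 * pi * 7 * seq(0, 4, length.out = 1001)),    # odd length
    cumsum(rnorm(500))
  )
  for (x in inputs) {
    y <- phase_randomize(x, seed = 3)
    expect_true(is.numeric(y) && length(y) == length(x))
    px <- Mod(stats::fft(x))^2
    py <- Mod(stats::fft(y))^2
    expect_lt(max(abs(px - py)) / max(px), 1e-9)
    # Parseval: variance is carried over (up to the randomized mean bin)
    expect_equal(sum(scale(y, scale = FALSE)^2),
                 sum(scale(x, scale = FALSE)^2), tolerance = 1e-6)
  }
  expect_error(phase_randomize(c(1, 2, 3)), "too short")
})

test_that("surrogates destroy genuine inter-brain coupling", {
  # Coupled oscillators with real spectral width (phase diffusion): the
  # shared phase fluctuations live in many frequency bins, so independent
  # phase scrambling decorrelates the channels. (A noiseless, perfectly
  # locked pair is a pure tone, whose PLV a Fourier surrogate cannot
  # lower: randomization only shifts its constant phase.)
  run_seed <- function(s) {
    cfg <- sim_config(n_channels = 3, sampling_rate = 125, duration = 16,
                      k_intra_1 = 0, k_intra_2 = 0, k_inter = 10,
                      noise_sd = 0.4, phase_diffusion = 2, seed = s)
    rec <- eeg_bandpass(generate_coupled_pair(cfg), 8, 12)
    orig <- sync_matrices(hilbert_phase(rec))
    surr <- rec
    for (p in 1:2) {
      for (ch in 1:3) {
        surr$signals[[p]][ch, ] <- phase_randomize(
          surr$signals[[p]][ch, ], seed = 7000 + p * 10 + ch + s)
      }
    }
    sm_surr <- sync_matrices(hilbert_phase(surr))
    c(orig = mean(orig$inter), surr = mean(sm_surr$inter))
  }
  r <- rowMeans(vapply(c(8, 9, 10), run_seed, numeric(2)))
  expect_gt(r["orig"], 0.4)            # coupling visible in the original
  expect_lt(r["surr"], r["orig"] - 0.3)
  expect_lt(r["surr"], 0.2)            # near the independent-pair null
})

test_that("ensemble bookkeeping: every pair gets n values, reproducibly", {
  rec <- small_band_rec(n_ch = 2, seed = 4, duration = 6)
  ens <- surrogate_ensemble(rec, n = 3, seed = 42)
  expect_equal(dim(ens$values), c(4, 4, 3))
  # intra pair (1,2) of each participant + 4 inter pairs hold 3 values each
  expect_true(all(is.finite(ens$values[1, 2, ])))
  expect_true(all(is.finite(ens$values[1, 3, ])))
  expect_true(all(ens$values[is.finite(ens$values)] >= 0 &
                    ens$values[is.finite(ens$values)] <= 1))

  ens2 <- surrogate_ensemble(rec, n = 3, seed = 42)
  expect_identical(ens$values, ens2$values)
  expect_error(surrogate_ensemble(rec, n = 1, seed = 1), "at least 2")
})

test_that("significance mask: separation, one-sidedness, structure", {
  n_ch <- 3
  labels <- c("Fz", "Cz", "Pz")
  n_sur <- 100
  # synthetic originals and surrogate nulls with overwhelming separation
  combined_dim <- 2 * n_ch
  orig <- structure(
    list(intra_1 = matrix(0.9, n_ch, n_ch), intra_2 = matrix(0.9, n_ch, n_ch),
         inter = matrix(0.9, n_ch, n_ch), band_tag = "alpha",
         n_samples_used = 1000),
    class = "sync_matrices")
  diag(orig$intra_1) <- diag(orig$intra_2) <- NA
  set.seed(9)
  vals <- array(rnorm(combined_dim^2 * n_sur, 0.1, 0.02),
                dim = c(combined_dim, combined_dim, n_sur))
  for (r in seq_len(n_sur)) {          # keep each replicate symmetric
    m <- vals[, , r]
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    vals[, , r] <- m
  }
  ens <- structure(list(values = vals, n_surrogates = n_sur,
                        band_tag = "alpha", channel_labels = labels),
                   class = "surrogate_ensemble")

  g <- significance_mask(orig, ens, alpha = 0.05)
  expect_s3_class(g, "hyperbrain_graph")
  expect_equal(dim(g$adjacency), c(6, 6))
  expect_equal(edge_number(g), attr(g, "n_pairs_tested"))  # complete graph
  expect_equal(attr(g, "n_pairs_tested"), 15)              # 3+3+9
  expect_equal(g$alpha_per_test, 0.05 / 15)
  expect_equal(g$adjacency, t(g$adjacency))
  expect_true(all(diag(g$adjacency) == 0))
  expect_equal(g$module_of, rep(1:2, each = 3))

  # originals below the surrogate mean never become edges
  orig_low <- orig
  orig_low$intra_1[] <- orig_low$intra_2[] <- orig_low$inter[] <- 0.01
  diag(orig_low$intra_1) <- diag(orig_low$intra_2) <- NA
  g_low <- significance_mask(orig_low, ens, alpha = 0.05)
  expect_equal(edge_number(g_low), 0)

  # raising an original value never removes an edge
  orig_mid <- orig
  orig_mid$inter[1, 1] <- 0.12
  g_mid <- significance_mask(orig_mid, ens, alpha = 0.05)
  expect_true(all(g$adjacency >= g_mid$adjacency))

  # percentile method: rank p-values, conservative by construction
  g_pct <- significance_mask(orig, ens, alpha = 0.5, method = "percentile",
                             m = 1)
  expect_equal(edge_number(g_pct), 15)
})

test_that("zero surrogate variance yields no edge when values coincide", {
  n_ch <- 2
  orig <- structure(
    list(intra_1 = matrix(0.3, 2, 2), intra_2 = matrix(0.3, 2, 2),
         inter = matrix(0.3, 2, 2), band_tag = "alpha",
         n_samples_used = 100),
    class = "sync_matrices")
  diag(orig$intra_1) <- diag(orig$intra_2) <- NA
  vals <- array(0.3, dim = c(4, 4, 10))
  ens <- structure(list(values = vals, n_surrogates = 10,
                        band_tag = "alpha", channel_labels = c("Fz", "Cz")),
                   class = "surrogate_ensemble")
  g <- significance_mask(orig, ens)
  expect_equal(edge_number(g), 0)

  # ... but an original strictly above a constant null is kept
  orig$inter[1, 2] <- 0.9
  g2 <- significance_mask(orig, ens)
  expect_equal(g2$adjacency["P1_Fz", "P2_Cz"], 1)
})

test_that("percentile thresholding is conservative under the null", {
  # zero-coupling dyads, rank p-values: no edge can pass Bonferroni
  rates <- vapply(1:3, function(s) {
    rec <- small_band_rec(n_ch = 3, seed = 200 + s, duration = 8)
    sm <- sync_matrices(hilbert_phase(rec))
    ens <- surrogate_ensemble(rec, n = 20, seed = s)
    g <- significance_mask(sm, ens, alpha = 0.05, method = "percentile")
    edge_number(g) / attr(g, "n_pairs_tested")
  }, numeric(1))
  expect_true(all(rates == 0))
})

test_that("graph files round-trip the adjacency to disk", {
  set.seed(2)
  A <- random_adjacency(6, 0.5)
  g <- hyperbrain_graph(A, module_of = rep(1:2, each = 3),
                        band_tag = "theta", alpha_per_test = 0.01)
  d <- file.path(tempdir(), "graph_out")
  paths <- write_graph_files(g, d)
  back <- as.matrix(utils::read.table(paths[1], sep = "\t", header = TRUE,
                                      row.names = 1, check.names = FALSE))
  expect_equal(unname(back), unname(A))
  el <- utils::read.table(paths[2], sep = "\t", header = TRUE)
  expect_equal(nrow(el), edge_number(g))
})
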