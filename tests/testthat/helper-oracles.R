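# Independent brute-force graph oracles. Deliberately naive (explicit
# loops, Floyd-Warshall) and shared by unit and acceptance tests; they
# never call the package's metric functions.

fw_distances <- function(A) {
  s <- nrow(A)
  D <- matrix(Inf, s, s)
  D[A == 1] <- 1
  diag(D) <- 0
  for (k in seq_len(s)) {
    for (i in seq_len(s)) {
      for (j in seq_len(s)) {
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
      }
    }
  }
  D
}

oracle_global_efficiency <- function(A) {
  s <- nrow(A)
  D <- fw_distances(A)
  acc <- 0
  for (i in seq_len(s)) {
    for (k in seq_len(s)) {
      if (i != k && is.finite(D[i, k])) acc <- acc + 1 / D[i, k]
    }
  }
  acc / (s * (s - 1))
}

oracle_local_efficiency <- function(A) {
  s <- nrow(A)
  total <- 0
  for (i in seq_len(s)) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) next
    Dn <- fw_distances(A[nb, nb, drop = FALSE])
    acc <- 0
    for (k in seq_len(d)) {
      for (h in seq_len(d)) {
        if (k != h && is.finite(Dn[k, h])) acc <- acc + 1 / Dn[k, h]
      }
    }
    total <- total + acc / (d * (d - 1))
  }
  total / s
}

oracle_modularity <- function(A, modules) {
  two_en <- sum(A)
  d <- rowSums(A)
  q <- 0
  for (i in seq_len(nrow(A))) {
    for (k in seq_len(nrow(A))) {
      if (modules[i] == modules[k]) {
        q <- q + A[i, k] - d[i] * d[k] / two_en
      }
    }
  }
  q / two_en
}

oracle_char_path_length <- function(A) {
  D <- fw_distances(A)
  vals <- D[row(D) != col(D)]
  mean(vals[is.finite(vals)])
}

oracle_clustering <- function(A) {
  s <- nrow(A)
  cc <- numeric(s)
  for (i in seq_len(s)) {
    nb <- which(A[i, ] == 1)
    d <- length(nb)
    if (d < 2) next
    tri <- 0
    for (k in nb) {
      for (h in nb) {
        if (k != h && A[k, h] == 1) tri <- tri + 1
      }
    }
    cc[i] <- tri / (d * (d - 1))
  }
  mean(cc)
}

# Erdos-Renyi binary adjacency (symmetric, zero diagonal).
random_adjacency <- function(s, p) {
  A <- matrix(0, s, s)
  up <- which(upper.tri(A))
  A[up] <- as.numeric(stats::runif(length(up)) < p)
  A + t(A)
}
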