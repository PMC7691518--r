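# Shared fixtures, built in code at test time.

# A small but structurally complete synthetic study.
small_study <- function(seed = 1, n_days = 10, n_nodes = 12, n_samples = 256, ...) {
  simulate_study(
    n_days = n_days, n_nodes = n_nodes, n_samples = n_samples,
    seed = seed, ...
  )
}

# A stack of random symmetric "coherence" matrices with iid edges across
# days: the null for edgewise regression (no hormone relationship).
null_stack <- function(n_days, n_nodes, seed = 1) {
  withr::with_seed(seed, lapply(seq_len(n_days), function(d) {
    vals <- runif(n_nodes * (n_nodes - 1) / 2)
    M <- matrix(0, n_nodes, n_nodes)
    M[upper.tri(M)] <- vals
    M <- M + t(M)
    diag(M) <- 1
    list(day = d, values = M)
  }))
}

new_partition_for_test <- function(tbl) cyclecoh:::new_network_partition(tbl)

# Independent brute-force BH step-up: largest k with p_(k) <= k q / m,
# reject the k smallest p-values.
bh_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  k <- 0
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- rep(FALSE, m)
  if (k > 0) rej[ord[seq_len(k)]] <- TRUE
  rej
}

# Independent all-pairs shortest paths by repeated relaxation
# (Bellman-Ford style), lengths = 1/weight.
shortest_paths_bruteforce <- function(W) {
  n <- nrow(W)
  L <- ifelse(W > 0, 1 / W, Inf)
  diag(L) <- 0
  D <- L
  for (rep in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        D[i, j] <- min(D[i, j], D[i, ] + L[, j])
      }
    }
  }
  D
}

# FFT-domain oracle for a MODWT detail component: analysis followed by
# synthesis is circular filtering by the squared magnitude of the
# cascaded level filter.
modwt_detail_fft_oracle <- function(x, j) {
  n <- length(x)
  g <- cyclecoh:::.db4_g / sqrt(2)
  h <- cyclecoh:::.db4_h / sqrt(2)
  dft <- function(filt, upsample) {
    # frequency response of the filter upsampled by 2^upsample
    taps <- rep(0, (length(filt) - 1) * 2^upsample + 1)
    taps[seq(1, length(taps), by = 2^upsample)] <- filt
    fft(c(taps, rep(0, n - length(taps))))
  }
  H <- dft(h, j - 1)
  if (j > 1) for (l in 0:(j - 2)) H <- H * dft(g, l)
  Re(fft(Mod(H)^2 * fft(x), inverse = TRUE)) / n
}
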