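# Independent oracles used across the suite. These deliberately re-derive
# quantities by brute force / closed form, never by calling the code paths
# they check.

# Reduced-size simulation for unit tests (acceptance tests use the default
# study conditions).
small_sim_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_primary = 60, n_cell_line = 12, n_pdx = 6, n_caf = 5,
         n_normal_pancreas = 8, n_acc = 4, n_metastasis = 10,
         n_normal_other = 5,
         block_sizes = c(tumor_shared = 20, tumor_basal = 20,
                         tumor_classical = 20, acinar = 20,
                         immune = 20, caf = 20, background = 80),
         adex_background_genes = 10, housekeeping_set_size = 20,
         seed = seed),
    list(...))
  do.call(simulation_config, args)
}

# Exact two-sided rank-sum p by direct enumeration of all group splits of
# the pooled sample, computing rank sums from scratch.
oracle_rank_sum_exact <- function(a, b) {
  pooled <- c(a, b)
  N <- length(pooled)
  na <- length(a)
  r <- rank(pooled, ties.method = "average")
  u_of <- function(idx) sum(r[idx]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  eu <- na * length(b) / 2
  splits <- utils::combn(N, na)
  us <- apply(splits, 2, u_of)
  mean(abs(us - eu) >= abs(u_obs - eu) - 1e-9)
}

# Spearman rho via an explicitly constructed rank table and the raw Pearson
# sum formula; p via the t transform computed from scratch.
oracle_spearman <- function(x, y) {
  n <- length(x)
  rk <- function(v) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      less <- sum(v < v[i])
      eq <- sum(v == v[i])
      out[i] <- less + (eq + 1) / 2
    }
    out
  }
  rx <- rk(x); ry <- rk(y)
  sxy <- sum((rx - mean(rx)) * (ry - mean(ry)))
  sxx <- sum((rx - mean(rx))^2)
  syy <- sum((ry - mean(ry))^2)
  rho <- sxy / sqrt(sxx * syy)
  p <- if (abs(rho) >= 1 - 1e-12) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p)
}

# Plain (unadjusted) Rand index between two labelings.
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a == same_b) agree <- agree + 1
    }
  }
  agree / (n * (n - 1) / 2)
}

# Naive replay of the resampled-k-means consensus procedure: mirrors the
# seeded RNG stream (substream per resample, k-means++ draws, Lloyd k-means)
# but does all consensus bookkeeping with independent scalar loops.
naive_consensus_replay <- function(x, k, resamples, subsample_fraction,
                                   seed, restarts = 10, iter_max = 300) {
  n <- nrow(x)
  m <- ceiling(subsample_fraction * n)
  C <- matrix(0, n, n)
  N <- matrix(0, n, n)
  for (b in seq_len(resamples)) {
    set.seed(sigaudit:::.substream_seed(seed, b))
    idx <- sample.int(n, m)
    xs <- x[idx, , drop = FALSE]
    best_lab <- NULL
    best_wss <- Inf
    for (r in seq_len(restarts)) {
      centers <- matrix(NA_real_, k, ncol(xs))
      ci <- sample.int(m, 1)
      centers[1, ] <- xs[ci, ]
      if (k > 1) {
        d2 <- rowSums((xs - matrix(centers[1, ], m, ncol(xs), byrow = TRUE))^2)
        for (j in 2:k) {
          ci <- if (sum(d2) <= 0) sample.int(m, 1) else
            sample.int(m, 1, prob = d2)
          centers[j, ] <- xs[ci, ]
          d2 <- pmin(d2, rowSums((xs - matrix(centers[j, ], m, ncol(xs),
                                              byrow = TRUE))^2))
        }
      }
      km <- suppressWarnings(stats::kmeans(xs, centers = centers,
                                           iter.max = iter_max,
                                           algorithm = "Lloyd"))
      if (km$tot.withinss < best_wss) {
        best_wss <- km$tot.withinss
        best_lab <- km$cluster
      }
    }
    for (p in seq_len(m)) {
      for (q in seq_len(m)) {
        N[idx[p], idx[q]] <- N[idx[p], idx[q]] + 1
        if (best_lab[p] == best_lab[q]) {
          C[idx[p], idx[q]] <- C[idx[p], idx[q]] + 1
        }
      }
    }
  }
  M <- matrix(0, n, n)
  M[N > 0] <- C[N > 0] / N[N > 0]
  diag(M) <- 1
  M
}
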