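# Independent brute-force oracles used to verify the implementation.
# These deliberately use the most direct (slow) formulation of each
# quantity and share no code with the package internals.

# mean pairwise Pearson correlation in each k-window, by explicit double loop
oracle_landscape <- function(x, k) {
  p <- ncol(x)
  out <- rep(NA_real_, p)
  for (j in seq_len(p - k + 1)) {
    vals <- c()
    for (a in j:(j + k - 2)) for (b in (a + 1):(j + k - 1)) {
      ca <- x[, a]; cb <- x[, b]
      r <- if (stats::sd(ca) == 0 || stats::sd(cb) == 0) 0 else
        stats::cor(ca, cb)
      vals <- c(vals, r)
    }
    out[j] <- mean(vals)
  }
  out
}

# Durbin-Levinson partial autocorrelations
oracle_pacf <- function(x, max_lag) {
  x <- x - mean(x)
  n <- length(x)
  r <- vapply(0:max_lag, function(h)
    sum(x[1:(n - h)] * x[(1 + h):n]) / n, numeric(1))
  rho <- r[-1] / r[1]
  phi <- matrix(0, max_lag, max_lag)
  phi[1, 1] <- rho[1]
  if (max_lag > 1) {
    for (m in 2:max_lag) {
      num <- rho[m] - sum(phi[m - 1, 1:(m - 1)] * rho[(m - 1):1])
      den <- 1 - sum(phi[m - 1, 1:(m - 1)] * rho[1:(m - 1)])
      phi[m, m] <- num / den
      for (j in 1:(m - 1))
        phi[m, j] <- phi[m - 1, j] - phi[m, m] * phi[m - 1, m - j]
    }
  }
  diag(phi)
}

# prediction strength of `scored` clusters given the other half's labels,
# via the full p x p co-membership matrix
oracle_pd <- function(scored_ranges, labels_other, p) {
  D <- matrix(0L, p, p)
  for (t in setdiff(unique(labels_other), 0L)) {
    idx <- which(labels_other == t)
    D[idx, idx] <- 1L
  }
  fracs <- c()
  for (r in seq_len(nrow(scored_ranges))) {
    members <- scored_ranges$start[r]:scored_ranges$end[r]
    m <- length(members)
    if (m < 2) next
    tot <- 0L
    for (i in members) for (i2 in members) if (i != i2)
      tot <- tot + D[i, i2]
    fracs <- c(fracs, tot / (m * (m - 1)))
  }
  if (!length(fracs)) 0 else stats::median(fracs)
}

# per-datapoint coverage by explicit set membership
oracle_coverage <- function(ranges, truth_idx, p) {
  covered <- rep(FALSE, p)
  for (r in seq_len(nrow(ranges)))
    covered[ranges$start[r]:ranges$end[r]] <- TRUE
  signal <- seq_len(p) %in% truth_idx
  c(true_cov = 100 * sum(covered & signal) / sum(signal),
    noise_cov = 100 * sum(covered & !signal) / sum(!signal))
}

# connected components of a thresholded correlation graph by label
# propagation to a fixed point
oracle_components <- function(r, th) {
  n <- nrow(r)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (i != j && r[i, j] >= th && lab[j] > lab[i]) {
        lab[lab == lab[j]] <- lab[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# strict local maxima by direct scan (plateaus: midpoint)
oracle_local_maxima <- function(y) {
  out <- integer()
  i <- 2L
  m <- length(y)
  while (i <= m - 1L) {
    if (y[i] > y[i - 1L] && y[i] > y[i + 1L]) {
      out <- c(out, i); i <- i + 1L
    } else if (y[i] > y[i - 1L] && y[i] == y[i + 1L]) {
      j <- i
      while (j < m && y[j] == y[i]) j <- j + 1L
      if (y[j] < y[i]) out <- c(out, floor((i + j - 1L) / 2L))
      i <- j
    } else i <- i + 1L
  }
  out
}

# small spectrum set with block-correlated columns and a fixed seed
toy_block_spectra <- function(n = 20, blocks = c(5, 5, 5), gap = 3,
                              seed = 42, noise = 0.05) {
  set.seed(seed)
  cols <- list()
  for (b in seq_along(blocks)) {
    driver <- rnorm(n)
    for (j in seq_len(blocks[b]))
      cols[[length(cols) + 1L]] <- driver + rnorm(n, 0, noise)
    if (b < length(blocks))
      for (g in seq_len(gap))
        cols[[length(cols) + 1L]] <- rep(0, n)   # zeroed baseline gap
  }
  x <- do.call(cbind, cols)
  spectrum_set(seq(0.5, by = 0.001, length.out = ncol(x)), x)
}
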