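# Independent oracles used to cross-check the package implementations.
# These are deliberately written from first principles and share no code
# with the functions they verify.

# Exact dynamic-programming segmentation: minimizes
#   sum of squared residuals + lambda * n_segments
# over all partitions into segments of >= min_probes probes.
# Returns the segment end indices of the optimum.
dp_segment_oracle <- function(x, lambda, min_probes) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  rss <- function(i, j) {
    s <- cs[j + 1] - cs[i]
    (cs2[j + 1] - cs2[i]) - s^2 / (j - i + 1)
  }
  best <- rep(Inf, n + 1)
  best[1] <- 0
  prev <- rep(NA_integer_, n + 1)
  for (j in seq_len(n)) {
    if (j < min_probes) next
    for (i in 0:(j - min_probes)) {
      if (is.infinite(best[i + 1])) next
      cost <- best[i + 1] + rss(i + 1, j) + lambda
      if (cost < best[j + 1] - 1e-12) {
        best[j + 1] <- cost
        prev[j + 1] <- i
      }
    }
  }
  ends <- integer(0)
  j <- n
  while (j > 0) {
    ends <- c(j, ends)
    j <- prev[j + 1]
  }
  ends
}

# Piecewise-constant signal with k true breakpoints, all segments at least
# min_len probes long, level changes drawn from +-step.
random_step_signal <- function(n, k, step = 0.585, noise_sd = 0.1,
                               min_len = 5) {
  repeat {
    bp <- sort(sample(seq(min_len, n - min_len), k))
    if (k < 2 || min(diff(bp)) >= min_len) break
  }
  levels <- cumsum(c(0, sample(c(-step, step), k, replace = TRUE)))
  seg_id <- findInterval(seq_len(n), bp + 1) + 1
  levels[seg_id] + rnorm(n, 0, noise_sd)
}

# Unweighted log-rank chi-square from the observed-minus-expected /
# hypergeometric-variance definition, summed over distinct event times.
logrank_oracle <- function(time, event, group) {
  g <- factor(group)
  k <- nlevels(g)
  ts <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (t in ts) {
    n_at <- vapply(levels(g), function(l) sum(time >= t & g == l),
                   numeric(1))
    d_at <- vapply(levels(g), function(l)
      sum(time == t & event == 1 & g == l), numeric(1))
    N <- sum(n_at)
    D <- sum(d_at)
    O <- O + d_at
    E <- E + D * n_at / N
    if (N > 1) {
      frac <- D * (N - D) / (N - 1)
      for (a in seq_len(k)) for (b in seq_len(k)) {
        V[a, b] <- V[a, b] + frac *
          (if (a == b) n_at[a] * (N - n_at[a]) else -n_at[a] * n_at[b]) / N^2
      }
    }
  }
  u <- (O - E)[-k]
  Vm <- V[-k, -k, drop = FALSE]
  drop(t(u) %*% solve(Vm) %*% u)
}

# Pearson correlation straight from the covariance formula.
pearson_oracle <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Small helpers shared by tests -------------------------------------------

# A binned_profile on a given grid with prescribed logR values.
profile_on_grid <- function(grid, logR, sample_id = "T") {
  out <- as.data.frame(grid)
  out$logR <- logR
  structure(out, class = c("binned_profile", "data.frame"),
            sample_id = sample_id, grid = grid)
}

# A tiny two-chromosome genome and grid reused across tests.
tiny_genome <- function() build_genome(lengths = c(100e6, 80e6),
                                       centromere_frac = 0.4)
tiny_grid <- function(width = 10e6) make_bins(tiny_genome(), width)
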