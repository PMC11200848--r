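# Independent brute-force reference implementations used as oracles.
# Deliberately naive: explicit loops, no shared code with the package paths
# they check.

oracle_embed <- function(x, tau, m) {
  n <- length(x) - (m - 1) * tau
  out <- matrix(NA_real_, n, m)
  for (r in seq_len(n)) {
    j <- r + (m - 1) * tau
    for (k in 0:(m - 1)) out[r, k + 1] <- x[j - k * tau]
  }
  out
}

oracle_ami <- function(x, max_lag, n_bins) {
  n <- length(x)
  edges <- seq(min(x), max(x), length.out = n_bins + 1)
  assign_bin <- function(v) {
    for (b in seq_len(n_bins)) {
      hi <- edges[b + 1]
      if (v <= hi || b == n_bins) return(b)
    }
  }
  bins <- vapply(x, assign_bin, integer(1))
  sapply(0:max_lag, function(lag) {
    a <- bins[1:(n - lag)]
    b <- bins[(1 + lag):n]
    np <- length(a)
    joint <- matrix(0, n_bins, n_bins)
    for (i in seq_len(np)) joint[a[i], b[i]] <- joint[a[i], b[i]] + 1
    joint <- joint / np
    px <- rowSums(joint); py <- colSums(joint)
    mi <- 0
    for (i in seq_len(n_bins)) for (j in seq_len(n_bins)) {
      if (joint[i, j] > 0)
        mi <- mi + joint[i, j] * log2(joint[i, j] / (px[i] * py[j]))
    }
    mi
  })
}

# Kennel FNN by exhaustive all-pairs search, one dimension at a time.
oracle_fnn <- function(x, tau, m_max, r_tol = 15, a_tol = 2, theiler = tau) {
  n <- length(x)
  ra <- sd(x)
  sapply(seq_len(m_max), function(m) {
    j <- (m * tau + 1):n
    np <- length(j)
    flags <- logical(0)
    for (a in seq_len(np)) {
      best <- Inf; bi <- NA
      for (b in seq_len(np)) {
        if (abs(a - b) <= theiler) next
        d2 <- 0
        for (k in 0:(m - 1))
          d2 <- d2 + (x[j[a] - k * tau] - x[j[b] - k * tau])^2
        if (d2 < best) { best <- d2; bi <- b }
      }
      if (!is.finite(best) || best <= 0) next
      extra <- abs(x[j[a] - m * tau] - x[j[bi] - m * tau])
      flags <- c(flags,
                 extra / sqrt(best) > r_tol ||
                   sqrt(best + extra^2) / ra > a_tol)
    }
    if (!length(flags)) 0 else mean(flags)
  })
}

oracle_cosines <- function(v) {
  n <- nrow(v)
  out <- numeric(0)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    out <- c(out, sum(v[i, ] * v[j, ]) /
               (sqrt(sum(v[i, ]^2)) * sqrt(sum(v[j, ]^2))))
  }
  out
}

# bin masses from a mesh density by explicit accumulation; bins are
# [e_b, e_{b+1}) with the last bin closed on the right
oracle_bin_masses <- function(mesh, density, dx, edges) {
  B <- length(edges) - 1
  mass <- numeric(B)
  for (i in seq_along(mesh)) {
    v <- mesh[i]
    if (v < edges[1] || v > edges[B + 1]) next
    b <- B
    for (k in seq_len(B)) {
      if (v < edges[k + 1]) { b <- k; break }
    }
    mass[b] <- mass[b] + density[i] * dx
  }
  mass / sum(mass)
}

oracle_renyi2 <- function(p) -log2(sum(p * p))

# exact two-sided signed-rank p by enumeration of all 2^n sign assignments
oracle_signed_rank_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  sums <- numeric(2^n)
  for (mask in 0:(2^n - 1)) {
    s <- 0
    for (k in seq_len(n)) if (bitwAnd(mask, bitwShiftL(1L, k - 1L)) != 0)
      s <- s + r[k]
    sums[mask + 1] <- s
  }
  p_le <- mean(sums <= V + 1e-9)
  p_ge <- mean(sums >= V - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

oracle_trapz <- function(x, y) {
  s <- 0
  for (i in seq_len(length(x) - 1))
    s <- s + (x[i + 1] - x[i]) * (y[i] + y[i + 1]) / 2
  s
}
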