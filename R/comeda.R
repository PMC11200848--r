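#' Pairwise angular distances between embedded vectors
#'
#' Cosine of the angle between every unordered pair of phase-space vectors,
#' `d_ij = <Y(i), Y(j)> / (||Y(i)|| ||Y(j)||)`, excluding self-matches. Pairs
#' in which either vector has near-zero Euclidean norm (< 1e-12) are skipped
#' and counted; more than 1% skipped pairs is a hard error.
#'
#' @param emb An `eda_embedding` from [embed_series()] with n >= 3 vectors.
#' @return Object of class `eda_angular`: list with `d` (cosines, one per
#'   retained unordered pair, all in [-1, 1]), `n_pairs`, `n_skipped`.
#' @export
pairwise_angular <- function(emb) {
  stopifnot(inherits(emb, "eda_embedding"))
  v <- emb$vectors
  n <- nrow(v)
  if (n < 3L) stop("pairwise_angular: need at least 3 vectors")
  nrm <- sqrt(rowSums(v^2))
  good <- nrm >= 1e-12
  if (!any(good))
    stop("pairwise_angular: degenerate attractor (all vectors near zero)")
  total <- n * (n - 1) / 2
  n_bad <- sum(!good)
  n_skipped <- n_bad * (n - n_bad) + n_bad * (n_bad - 1) / 2
  if (n_skipped > 0.01 * total)
    stop(sprintf(
      "pairwise_angular: %d of %d pairs involve a near-zero-norm vector (> 1%%)",
      n_skipped, total))
  vg <- v[good, , drop = FALSE] / nrm[good]
  cm <- tcrossprod(vg)
  d <- cm[upper.tri(cm)]
  d <- pmin(1, pmax(-1, d))        # guard rounding past the cosine range
  structure(list(d = d, n_pairs = length(d), n_skipped = n_skipped),
            class = "eda_angular")
}

#' Sturges bin count
#'
#' `B = ceiling(log2(n)) + 1`.
#'
#' @param n_samples Number of samples the histogram will hold (>= 2).
#' @return Integer bin count.
#' @export
sturges_bins <- function(n_samples) {
  if (n_samples < 2) stop("sturges_bins: need n_samples >= 2")
  as.integer(ceiling(log2(n_samples)) + 1L)
}

# --- diffusion KDE (Botev, Grotowski & Kroese 2010) -------------------------
#
# Gaussian kernel density estimation viewed as the solution of the linear
# diffusion equation, with the bandwidth t* chosen by the improved
# Sheather-Jones fixed point solved in the DCT domain. Ported formulas; the
# fixed-point uses l = 7 plug-in stages.

dct1d <- function(x) {
  n <- length(x)
  w <- c(1, 2 * exp(-1i * (1:(n - 1)) * pi / (2 * n)))
  reord <- c(x[seq(1L, n, by = 2L)], x[seq(n - n %% 2, 2L, by = -2L)])
  Re(w * stats::fft(reord))
}

idct1d <- function(a) {
  n <- length(a)
  w <- n * exp(1i * (0:(n - 1)) * pi / (2 * n))
  y <- Re(stats::fft(w * a, inverse = TRUE)) / n
  out <- numeric(n)
  out[seq(1L, n, by = 2L)] <- y[1:(n / 2)]
  out[seq(2L, n, by = 2L)] <- y[n:(n / 2 + 1L)]
  out / n
}

isj_fixed_point <- function(t, N, I, a2) {
  l <- 7
  f <- 2 * pi^(2 * l) * sum(I^l * a2 * exp(-I * pi^2 * t))
  if (f <= 0) return(Inf)
  for (s in (l - 1):2) {
    K0 <- prod(seq(1, 2 * s - 1, by = 2)) / sqrt(2 * pi)
    const <- (1 + (1 / 2)^(s + 1 / 2)) / 3
    time <- (2 * const * K0 / (N * f))^(2 / (3 + 2 * s))
    f <- 2 * pi^(2 * s) * sum(I^s * a2 * exp(-I * pi^2 * time))
    if (f <= 0) return(Inf)
  }
  (2 * N * sqrt(pi) * f)^(-2 / 5)
}

# Density on a regular mesh of 2^grid_pow points spanning [lo, hi].
# Returns list(mesh, density); density integrates to ~1 over [lo, hi].
diffusion_kde <- function(d, lo, hi, grid_pow = 14L) {
  n <- 2^grid_pow
  N <- length(unique(d))
  R <- hi - lo
  edges <- seq(lo, hi, length.out = n + 1L)
  counts <- tabulate(findInterval(d, edges, rightmost.closed = TRUE,
                                  all.inside = TRUE), nbins = n)
  a <- dct1d(counts / length(d))
  I <- (1:(n - 1))^2
  a2 <- (a[-1] / 2)^2
  g <- function(t) isj_fixed_point(t, N, I, a2) - t
  t_star <- tryCatch({
    # bracket the root; g(0+) > 0 for non-degenerate data
    hi_t <- 0.1
    while (!is.finite(g(hi_t)) || g(hi_t) > 0) {
      hi_t <- hi_t * 2
      if (hi_t > 10) stop("no bracket")
    }
    stats::uniroot(g, c(1e-12, hi_t), tol = 1e-12)$root
  }, error = function(e) 0.28 * N^(-2 / 5))
  a_t <- a * exp(-(0:(n - 1))^2 * pi^2 * t_star / 2)
  dens <- idct1d(a_t) / R
  dens[dens < 0] <- 0
  mesh <- lo + (seq_len(n) - 0.5) * R / n    # cell centers
  list(mesh = mesh, density = dens, bandwidth_t = t_star, dx = R / n)
}

#' Binned probability mass of angular distances via diffusion KDE
#'
#' Fits a Gaussian diffusion kernel density estimate (bandwidth by the
#' improved Sheather-Jones fixed point) to the cosine distances on a fine
#' mesh of 2^14 points spanning [-1, 1] (the geometric support of a cosine),
#' then integrates the mesh density over `B` equal-width bins covering the
#' observed data range and renormalizes to total mass 1.
#'
#' @param d An `eda_angular` from [pairwise_angular()], or a numeric vector
#'   of distance samples in [-1, 1] (>= 10 samples).
#' @param B Number of bins (>= 2), typically [sturges_bins()] of the number
#'   of distance samples.
#' @return Object of class `eda_binned_pdf`: list with `B`, `edges` (B + 1
#'   increasing values), `p` (B probabilities summing to 1). If all distances
#'   are identical the degenerate single-bin PDF `p = 1` is returned with a
#'   warning.
#' @export
diffusion_pdf <- function(d, B) {
  x <- if (inherits(d, "eda_angular")) d$d else as.numeric(d)
  if (length(x) < 10L) stop("diffusion_pdf: need at least 10 distance samples")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning("diffusion_pdf: all distances identical; degenerate single-bin PDF")
    return(structure(list(B = 1L, edges = c(rng[1] - 1e-9, rng[1] + 1e-9),
                          p = 1), class = "eda_binned_pdf"))
  }
  if (B < 2L) stop("diffusion_pdf: B must be >= 2")
  kde <- diffusion_kde(x, -1, 1)
  edges <- seq(rng[1], rng[2], length.out = B + 1L)
  bin <- findInterval(kde$mesh, edges, rightmost.closed = TRUE,
                      all.inside = FALSE)
  inside <- bin >= 1L & bin <= B
  mass <- vapply(seq_len(B), function(b)
    sum(kde$density[inside & bin == b]) * kde$dx, numeric(1))
  if (sum(mass) <= 0)
    stop("diffusion_pdf: zero mass over the data range (numerical failure)")
  p <- mass / sum(mass)
  structure(list(B = as.integer(B), edges = edges, p = p),
            class = "eda_binned_pdf")
}

#' Quadratic (order-2) Renyi entropy of a binned PDF
#'
#' `R2 = -log2(sum(p_i^2))`, in bits; bounded by `[0, log2(B)]`.
#'
#' @param pdf An `eda_binned_pdf` from [diffusion_pdf()], or a probability
#'   vector.
#' @return Entropy in bits.
#' @export
renyi2 <- function(pdf) {
  p <- if (inherits(pdf, "eda_binned_pdf")) pdf$p else as.numeric(pdf)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-6)
    stop("renyi2: not a probability vector")
  -log2(sum(p^2))
}

#' Single-scale ComEDA complexity index
#'
#' Complexity of a signal's phase-space geometry: the series is
#' delay-embedded at (tau, m), the cosine of the angle between every pair of
#' embedded vectors is computed, the distribution of these angular distances
#' is estimated with a diffusion kernel density estimator binned into a
#' Sturges histogram, and the quadratic Renyi entropy of the bin masses is
#' normalized by its maximum `log2(B)` to give an index in [0, 1]. Low values
#' indicate angular distances concentrated in few directions (regular,
#' low-complexity dynamics); values near 1 indicate a spread-out, complex
#' attractor geometry.
#'
#' Because only angles enter, the index is exactly invariant to positive
#' rescaling of the signal — the property that makes it robust to the large
#' amplitude fluctuations of electrodermal recordings.
#'
#' @param sig An [eda_signal()] or numeric vector (typically pre-processed
#'   with [preprocess_eda()]).
#' @param params An `eda_embedding_params` (see [estimate_embedding()],
#'   [embedding_params()]), or NULL to estimate (tau, m) from the signal.
#' @return A single number in [0, 1]. The degenerate single-bin case returns
#'   0 with a warning.
#' @examples
#' set.seed(1)
#' x <- eda_signal(cumsum(rnorm(200)), fs = 5)
#' comeda(x, embedding_params(tau = 2, m = 3))
#' @export
comeda <- function(sig, params = NULL) {
  if (is.null(params)) params <- estimate_embedding(sig)
  stopifnot(inherits(params, "eda_embedding_params"))
  emb <- embed_series(sig, params$tau, params$m)
  ang <- pairwise_angular(emb)
  B <- sturges_bins(ang$n_pairs)
  pdf <- diffusion_pdf(ang, B)
  if (pdf$B == 1L) {
    warning("comeda: degenerate single-bin PDF; index = 0")
    return(0)
  }
  renyi2(pdf) / log2(pdf$B)
}
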