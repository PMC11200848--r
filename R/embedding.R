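#' Auto mutual information curve
#'
#' Mutual information (in bits) between a series and its lagged copy, for lags
#' 0..`max_lag`, estimated with an equal-width two-dimensional histogram
#' (plug-in estimator). Bin edges are fixed from the range of the full series,
#' so `ami[1]` (lag 0) equals the plug-in entropy of the binned marginal.
#'
#' @param sig An [eda_signal()] or numeric vector.
#' @param max_lag Largest lag in samples; must be < N/2. Default
#'   `min(floor(N/4), 100)`.
#' @param n_bins Number of histogram bins per axis (>= 2). Default
#'   `min(ceiling(sqrt(N)), 64)`.
#' @return Numeric vector of length `max_lag + 1`; element `k` is AMI at lag
#'   `k - 1`, in bits.
#' @seealso [select_tau()]
#' @export
auto_mutual_information <- function(sig, max_lag = NULL, n_bins = NULL) {
  x <- if (inherits(sig, "eda_signal")) sig$values else as.numeric(sig)
  n <- length(x)
  if (is.null(max_lag)) max_lag <- min(floor(n / 4), 100L)
  if (is.null(n_bins)) n_bins <- min(ceiling(sqrt(n)), 64L)
  if (max_lag >= n / 2) stop("auto_mutual_information: max_lag must be < N/2")
  if (n_bins < 2L) stop("auto_mutual_information: n_bins must be >= 2")
  rng <- range(x)
  if (rng[1] == rng[2]) stop("auto_mutual_information: constant signal")
  # right-closed equal-width bins; nudge the top edge so the max falls inside
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  vapply(0:max_lag, function(lag) {
    a <- bin[seq_len(n - lag)]
    b <- bin[(1L + lag):n]
    joint <- table(factor(a, levels = seq_len(n_bins)),
                   factor(b, levels = seq_len(n_bins))) / (n - lag)
    px <- rowSums(joint); py <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer(px, py)[nz]))
  }, numeric(1))
}

#' Select the embedding lag from an AMI curve
#'
#' Takes the first local minimum of the auto-mutual-information curve: the
#' smallest lag `l >= 1` with `ami[l] < ami[l-1]` and `ami[l] <= ami[l+1]`.
#' If no local minimum exists, falls back to the lag of the global minimum;
#' if the curve is monotone non-increasing throughout, falls back to the
#' largest lag with a warning.
#'
#' @param ami AMI curve as returned by [auto_mutual_information()] (element 1
#'   is lag 0). Length >= 3.
#' @return Integer lag in samples (>= 1).
#' @export
select_tau <- function(ami) {
  if (length(ami) < 3L) stop("select_tau: ami curve too short")
  max_lag <- length(ami) - 1L
  for (l in 1:(max_lag - 1L)) {
    if (ami[l + 1L] < ami[l] && ami[l + 1L] <= ami[l + 2L]) return(l)
  }
  if (all(diff(ami) <= 0)) {
    warning("select_tau: AMI monotone non-increasing; falling back to max lag ",
            max_lag)
    return(max_lag)
  }
  which.min(ami[-1L])[1]
}

#' False-nearest-neighbour fractions over candidate dimensions
#'
#' For each candidate embedding dimension m = 1..`m_max`, embeds the series,
#' finds every point's nearest neighbour (excluding a Theiler window of
#' temporally close points), and flags the pair as "false" if the extra
#' coordinate gained at dimension m+1 separates them, using the two Kennel
#' criteria: relative separation `> r_tol`, or separation relative to the
#' attractor size `> a_tol`.
#'
#' @param sig An [eda_signal()] or numeric vector.
#' @param tau Embedding lag in samples.
#' @param m_max Largest candidate dimension (>= 2). Default 10.
#' @param r_tol Relative-increase threshold; default 15 (Kennel et al.).
#' @param a_tol Attractor-size threshold; default 2.
#' @param theiler Theiler exclusion window in samples; default `tau`.
#' @return Numeric vector of length `m_max`: the false-neighbour fraction at
#'   each dimension, each in [0, 1].
#' @seealso [select_m()]
#' @export
fnn_fractions <- function(sig, tau, m_max = 10L, r_tol = 15, a_tol = 2,
                          theiler = tau) {
  x <- if (inherits(sig, "eda_signal")) sig$values else as.numeric(sig)
  n <- length(x)
  if (m_max < 2L) stop("fnn_fractions: m_max must be >= 2")
  # points must support the (m_max + 1)-dimensional coordinate for the test
  need <- m_max * tau + 2L
  if (n < need)
    stop("fnn_fractions: series too short for m_max = ", m_max,
         " at tau = ", tau, " (need N >= ", need, ", got ", n, ")")
  ra <- stats::sd(x)
  if (ra == 0) stop("fnn_fractions: constant signal")
  vapply(seq_len(m_max), function(m) {
    # indices j with both the m-dim vector and the (m+1)-th coordinate valid
    j <- (m * tau + 1L):n
    emb <- vapply(0:(m - 1L), function(k) x[j - k * tau],
                  numeric(length(j)))
    emb <- matrix(emb, nrow = length(j))
    extra <- x[j - m * tau]
    d2 <- as.matrix(stats::dist(emb))^2
    np <- length(j)
    excl <- abs(outer(seq_len(np), seq_len(np), "-")) <= theiler
    d2[excl] <- Inf
    nn <- apply(d2, 1L, which.min)
    rm2 <- d2[cbind(seq_len(np), nn)]
    ok <- is.finite(rm2) & rm2 > 0
    dd <- abs(extra - extra[nn])
    rm <- sqrt(rm2)
    false1 <- dd[ok] / rm[ok] > r_tol
    false2 <- sqrt(rm2[ok] + dd[ok]^2) / ra > a_tol
    if (!any(ok)) return(0)
    mean(false1 | false2)
  }, numeric(1))
}

#' Select the embedding dimension from FNN fractions
#'
#' Smallest dimension whose false-neighbour fraction drops below `threshold`;
#' if none does, the dimension with the smallest fraction, with a warning.
#' The result is floored at 2: angular statistics in the phase space need at
#' least a plane.
#'
#' @param fractions Vector of FNN fractions for dimensions 1..m_max, as from
#'   [fnn_fractions()].
#' @param threshold Acceptable false-neighbour fraction; default 0.05.
#' @return Integer dimension >= 2.
#' @export
select_m <- function(fractions, threshold = 0.05) {
  if (!length(fractions)) stop("select_m: empty fractions")
  below <- which(fractions < threshold)
  if (length(below)) {
    m <- below[1]
  } else {
    m <- which.min(fractions)[1]
    warning("select_m: no dimension below threshold ", threshold,
            "; using argmin m = ", m)
  }
  if (m < 2L) {
    warning("select_m: dimension ", m, " floored at 2")
    m <- 2L
  }
  as.integer(m)
}

#' Delay-embed a series into phase-space vectors
#'
#' Builds the n = N - (m-1)*tau delay vectors
#' `Y(j) = [y(j), y(j - tau), ..., y(j - (m-1) tau)]` for
#' `j = (m-1) tau + 1, ..., N`.
#'
#' @param sig An [eda_signal()] or numeric vector of length N.
#' @param tau Lag in samples (>= 1).
#' @param m Embedding dimension (>= 1).
#' @return Object of class `eda_embedding`: list with `vectors` (n x m
#'   matrix), `tau`, `m`, `n`.
#' @examples
#' e <- embed_series(1:6, tau = 1, m = 3)
#' e$vectors[1, ]  # c(3, 2, 1)
#' @export
embed_series <- function(sig, tau, m) {
  x <- if (inherits(sig, "eda_signal")) sig$values else as.numeric(sig)
  n_in <- length(x)
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1L || m < 1L) stop("embed_series: tau and m must be >= 1")
  if (n_in <= (m - 1L) * tau)
    stop("embed_series: series too short: N = ", n_in,
         " <= (m-1)*tau = ", (m - 1L) * tau)
  j <- ((m - 1L) * tau + 1L):n_in
  v <- vapply(0:(m - 1L), function(k) x[j - k * tau], numeric(length(j)))
  structure(list(vectors = matrix(v, nrow = length(j)),
                 tau = tau, m = m, n = length(j)),
            class = "eda_embedding")
}

#' Estimate embedding parameters (tau, m) for a signal
#'
#' Convenience wrapper: computes the AMI curve and takes its first local
#' minimum as tau, then computes FNN fractions at that tau and takes the
#' first dimension below the false-neighbour threshold as m.
#'
#' @inheritParams auto_mutual_information
#' @inheritParams fnn_fractions
#' @param threshold FNN acceptance threshold for [select_m()].
#' @return Object of class `eda_embedding_params`: list with `tau`, `m`,
#'   `ami_curve`, `fnn_fractions`.
#' @export
estimate_embedding <- function(sig, max_lag = NULL, n_bins = NULL,
                               m_max = 10L, r_tol = 15, a_tol = 2,
                               threshold = 0.05) {
  ami <- auto_mutual_information(sig, max_lag = max_lag, n_bins = n_bins)
  tau <- select_tau(ami)
  x <- if (inherits(sig, "eda_signal")) sig$values else as.numeric(sig)
  # shrink m_max if the series cannot support it at this tau
  m_ok <- max(2L, min(m_max, floor((length(x) - 2L) / tau)))
  fr <- fnn_fractions(sig, tau, m_max = m_ok, r_tol = r_tol, a_tol = a_tol)
  m <- select_m(fr, threshold)
  structure(list(tau = as.integer(tau), m = as.integer(m),
                 ami_curve = ami, fnn_fractions = fr),
            class = "eda_embedding_params")
}

#' @export
print.eda_embedding_params <- function(x, ...) {
  cat(sprintf("<embedding params> tau = %d samples, m = %d\n", x$tau, x$m))
  invisible(x)
}

#' Explicit embedding parameters
#'
#' Constructs an `eda_embedding_params` object from known values of tau and
#' m, bypassing estimation (useful when parameters are fixed by protocol).
#'
#' @param tau Lag in samples (>= 1).
#' @param m Dimension (>= 2).
#' @return An `eda_embedding_params` object with empty diagnostics.
#' @export
embedding_params <- function(tau, m) {
  tau <- as.integer(tau); m <- as.integer(m)
  if (tau < 1L) stop("embedding_params: tau must be >= 1")
  if (m < 2L) stop("embedding_params: m must be >= 2")
  structure(list(tau = tau, m = m, ami_curve = numeric(0),
                 fnn_fractions = numeric(0)),
            class = "eda_embedding_params")
}
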