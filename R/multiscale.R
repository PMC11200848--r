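#' Coarse-grain a signal by non-overlapping block averaging
#'
#' Element i of the scale-beta series is the mean of the i-th consecutive
#' block of `beta` samples; trailing samples that do not fill a block are
#' dropped (standard multiscale-entropy coarse-graining). The sampling rate
#' is divided by `beta`.
#'
#' @param sig An [eda_signal()] or numeric vector.
#' @param beta Integer scale factor >= 1.
#' @return An [eda_signal()] of length `floor(N / beta)`.
#' @examples
#' coarse_grain(eda_signal(c(1, 2, 3, 4, 5), fs = 5), 2)$values  # 1.5 3.5
#' @export
coarse_grain <- function(sig, beta) {
  s <- as_signal(sig, fs = 1)
  beta <- as.integer(beta)
  if (beta < 1L) stop("coarse_grain: beta must be >= 1")
  n_out <- length(s$values) %/% beta
  if (n_out < 2L)
    stop("coarse_grain: fewer than 2 coarse samples at beta = ", beta)
  if (beta == 1L) return(s)
  x <- s$values[seq_len(n_out * beta)]
  y <- colMeans(matrix(x, nrow = beta))
  eda_signal(y, s$fs / beta, meta = s$meta)
}

#' Largest usable scale factor
#'
#' The largest integer beta such that the coarse-grained series still has at
#' least `min_samples` samples: `beta_max = floor(N / min_samples)`.
#'
#' @param N Length of the original series.
#' @param min_samples Minimum acceptable coarse-grained length. 30 retains
#'   scales up to 20 for a 600-sample (two-minute, 5 Hz) recording; 25 is the
#'   looser floor used for shorter recordings.
#' @return Integer `beta_max >= 1`.
#' @export
max_scale <- function(N, min_samples) {
  if (N < 2 * min_samples)
    stop("max_scale: N = ", N, " too short for min_samples = ", min_samples)
  as.integer(N %/% min_samples)
}

#' ComEDA across time scales
#'
#' Evaluates [comeda()] on the coarse-grained series at every scale factor in
#' `betas`, holding the embedding parameters (tau, m) fixed at the values
#' estimated for the original (scale 1) series.
#'
#' @param sig An [eda_signal()] or numeric vector (pre-processed).
#' @param params `eda_embedding_params` estimated at scale 1, or NULL to
#'   estimate them here.
#' @param betas Integer scale factors, strictly increasing and starting at 1.
#'   Default: `1:20` when `floor(N/20) >= 30` (long recordings), otherwise
#'   `1:max_scale(N, 25)`.
#' @param on_short What to do when a coarse-grained series is too short to
#'   embed at (tau, m): `"error"` (default) or `"truncate"` the trend at the
#'   last valid scale with a warning.
#' @return Object of class `eda_mstrend`: list with `betas`, `values` (ComEDA
#'   per scale, each in [0, 1]), `tau`, `m`, `lengths` (coarse length per
#'   scale).
#' @export
multiscale_trend <- function(sig, params = NULL, betas = NULL,
                             on_short = c("error", "truncate")) {
  on_short <- match.arg(on_short)
  s <- as_signal(sig, fs = 1)
  N <- length(s$values)
  if (is.null(params)) params <- estimate_embedding(s)
  stopifnot(inherits(params, "eda_embedding_params"))
  if (is.null(betas)) {
    betas <- if (N %/% 20L >= 30L) 1:20 else seq_len(max_scale(N, 25L))
  }
  betas <- as.integer(betas)
  if (betas[1] != 1L || any(diff(betas) <= 0))
    stop("multiscale_trend: betas must be strictly increasing from 1")
  values <- numeric(0)
  lengths <- integer(0)
  for (b in betas) {
    len <- N %/% b
    # need n = len - (m-1)*tau >= 5 embedded vectors (>= 10 pairwise cosines)
    ok <- len >= (params$m - 1L) * params$tau + 5L
    if (!ok) {
      if (on_short == "truncate") {
        warning("multiscale_trend: trend truncated before beta = ", b,
                " (coarse length ", len, " too short for tau = ", params$tau,
                ", m = ", params$m, ")")
        break
      }
      stop("multiscale_trend: coarse series at beta = ", b, " (length ", len,
           ") too short to embed at tau = ", params$tau, ", m = ", params$m)
    }
    values <- c(values, comeda(coarse_grain(s, b), params))
    lengths <- c(lengths, len)
  }
  structure(list(betas = betas[seq_along(values)], values = values,
                 tau = params$tau, m = params$m, lengths = lengths),
            class = "eda_mstrend")
}

#' @export
print.eda_mstrend <- function(x, ...) {
  cat(sprintf("<multiscale trend> beta 1..%d (tau = %d, m = %d)\n",
              max(x$betas), x$tau, x$m))
  print(round(stats::setNames(x$values, paste0("b", x$betas)), 4))
  invisible(x)
}

#' MComEDA: area under the multiscale complexity trend
#'
#' Trapezoidal area of ComEDA as a function of the scale factor beta (unit
#' spacing between consecutive integer scales). The raw area lies in
#' [0, beta_max - 1]; the normalized variant divides by (beta_max - 1) to
#' return to [0, 1].
#'
#' @param trend An `eda_mstrend` from [multiscale_trend()] with at least two
#'   scales.
#' @param normalize Divide by the beta span? Default FALSE (raw trapezoid).
#' @return A single number.
#' @export
mcomeda <- function(trend, normalize = FALSE) {
  stopifnot(inherits(trend, "eda_mstrend"))
  k <- length(trend$betas)
  if (k < 2L) stop("mcomeda: AUC undefined for a single scale")
  auc <- sum(diff(trend$betas) *
               (trend$values[-k] + trend$values[-1]) / 2)
  if (normalize) auc / (trend$betas[k] - trend$betas[1]) else auc
}
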