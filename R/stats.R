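#' EDASymp: sympathetic-band spectral index of EDA
#'
#' Mean power spectral density of the signal in the sympathetic band
#' [0.045, 0.25] Hz, computed per non-overlapping 30-second window (one
#' tapered periodogram per window) and averaged across full windows; a
#' trailing partial window is dropped.
#'
#' @param sig An [eda_signal()] with `fs > 0.5` Hz and length >= 30 s.
#' @param window_s Window length in seconds, default 30.
#' @param band Frequency band in Hz, default `c(0.045, 0.25)`.
#' @param taper `"hamming"` (default) or `"none"`.
#' @return Mean in-band PSD (power per Hz), averaged over windows.
#' @export
edasymp <- function(sig, window_s = 30, band = c(0.045, 0.25),
                    taper = c("hamming", "none")) {
  stopifnot(inherits(sig, "eda_signal"))
  taper <- match.arg(taper)
  fs <- sig$fs
  if (fs <= 0.5) stop("edasymp: fs must exceed 0.5 Hz")
  nw <- floor(window_s * fs)
  n_win <- length(sig$values) %/% nw
  if (n_win < 1L)
    stop("edasymp: signal shorter than one ", window_s, " s window")
  w <- if (taper == "hamming")
    0.54 - 0.46 * cos(2 * pi * (0:(nw - 1)) / (nw - 1)) else rep(1, nw)
  freqs <- (0:(nw - 1)) * fs / nw
  in_band <- freqs >= band[1] & freqs <= band[2]
  if (!any(in_band))
    stop("edasymp: no frequency sample falls in the band; window too short")
  vals <- vapply(seq_len(n_win), function(k) {
    x <- sig$values[((k - 1L) * nw + 1L):(k * nw)]
    X <- stats::fft(x * w)
    psd <- (Mod(X)^2) / (fs * sum(w^2))
    # one-sided scaling for the interior frequencies (band excludes DC/Nyquist)
    mean(2 * psd[in_band])
  }, numeric(1))
  mean(vals)
}

#' Aggregate per-stimulus values into a subjects x conditions matrix
#'
#' Each cell is the arithmetic mean of one subject's values for one condition
#' (a subject typically sees several stimuli per condition). Every subject
#' must have at least one value for every condition.
#'
#' @param records Data frame with columns `subject`, `condition`, `value`.
#' @return Numeric matrix, rows = subjects, columns = conditions (sorted
#'   label order), no missing cells.
#' @export
aggregate_by_condition <- function(records) {
  need <- c("subject", "condition", "value")
  if (!all(need %in% names(records)))
    stop("aggregate_by_condition: records need columns ",
         paste(need, collapse = ", "))
  subjects <- sort(unique(as.character(records$subject)))
  conditions <- sort(unique(as.character(records$condition)))
  if (length(conditions) < 2L)
    stop("aggregate_by_condition: need >= 2 conditions")
  m <- matrix(NA_real_, length(subjects), length(conditions),
              dimnames = list(subjects, conditions))
  agg <- stats::aggregate(value ~ subject + condition, data = records, FUN = mean)
  m[cbind(as.character(agg$subject), as.character(agg$condition))] <- agg$value
  if (anyNA(m)) {
    gaps <- which(is.na(m), arr.ind = TRUE)
    stop("aggregate_by_condition: missing subject x condition cells: ",
         paste(sprintf("%s/%s", subjects[gaps[, 1]], conditions[gaps[, 2]]),
               collapse = ", "))
  }
  m
}

#' Lilliefors test of normality
#'
#' Kolmogorov-Smirnov distance between the sample's empirical CDF and a
#' normal distribution with mean and SD estimated from the same sample. The
#' p-value is obtained by Monte-Carlo simulation of the null (default) or by
#' the Dallal-Wilkinson analytic approximation. The statistic is invariant to
#' affine transforms of the sample.
#'
#' @param x Numeric sample, n >= 5, non-constant.
#' @param alpha Significance level for the `reject` flag, default 0.05.
#' @param method `"monte-carlo"` (default) or `"approx"`.
#' @param nsim Monte-Carlo replicates, default 2000. Uses the current RNG
#'   stream; seed beforehand for reproducibility.
#' @return List with `statistic`, `p`, `reject`.
#' @export
lilliefors <- function(x, alpha = 0.05, method = c("monte-carlo", "approx"),
                       nsim = 2000L) {
  method <- match.arg(method)
  x <- as.numeric(x)
  n <- length(x)
  if (n < 5L) stop("lilliefors: need n >= 5")
  if (stats::sd(x) == 0) stop("lilliefors: constant sample")
  stat <- lillie_stat(x)
  p <- switch(method,
    "monte-carlo" = {
      sims <- vapply(seq_len(nsim), function(i) lillie_stat(stats::rnorm(n)),
                     numeric(1))
      (sum(sims >= stat) + 1) / (nsim + 1)
    },
    "approx" = lillie_p_dallal(stat, n))
  list(statistic = stat, p = p, reject = p < alpha)
}

lillie_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  F0 <- stats::pnorm(z)
  d_plus <- max(seq_len(n) / n - F0)
  d_minus <- max(F0 - (seq_len(n) - 1) / n)
  max(d_plus, d_minus)
}

# Dallal & Wilkinson (1986) approximation, as used by standard
# implementations; accurate in the upper tail, clamped to [0, 1].
lillie_p_dallal <- function(D, n) {
  if (n > 100) { D <- D * (n / 100)^0.49; n <- 100 }
  p <- exp(-7.01256 * D^2 * (n + 2.78019) +
             2.99587 * D * sqrt(n + 2.78019) - 0.122119 +
             0.974598 / sqrt(n) + 1.67997 / n)
  min(1, max(0, p))
}

#' Friedman rank test for paired designs
#'
#' Nonparametric test for differences among k >= 2 repeated conditions
#' measured on the same n subjects. Within-subject values are ranked (ties by
#' mid-ranks), and the chi-square statistic with the standard tie correction
#' is referred to a chi-square distribution with k - 1 degrees of freedom.
#'
#' @param m Numeric matrix, subjects in rows, conditions in columns (such as
#'   from [aggregate_by_condition()]).
#' @return List with `chi2`, `df`, `p`. All-equal rows yield `chi2 = 0`,
#'   `p = 1`.
#' @export
friedman_test <- function(m) {
  m <- as.matrix(m)
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("friedman_test: need >= 2 subjects and conditions")
  r <- t(apply(m, 1L, rank))
  Rj <- colSums(r)
  # tie correction: 1 - sum(t^3 - t) / (n k (k^2 - 1))
  tie_term <- sum(apply(m, 1L, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - tie_term / (n * k * (k^2 - 1))
  if (C <= 0) return(list(chi2 = 0, df = k - 1L, p = 1))  # all rows constant
  chi2 <- (12 / (n * k * (k + 1)) * sum(Rj^2) - 3 * n * (k + 1)) / C
  chi2 <- max(0, chi2)
  list(chi2 = chi2, df = k - 1L,
       p = stats::pchisq(chi2, df = k - 1L, lower.tail = FALSE))
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Two-sided test on paired differences. Zero differences are dropped
#' (classical Wilcoxon convention); ties among absolute differences take
#' mid-ranks. For n <= `exact_max` retained pairs the null distribution of
#' the positive-rank sum is computed exactly by dynamic programming over sign
#' assignments (valid under mid-ranks); above that, a normal approximation
#' with tie correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest n for the exact null, default 25.
#' @return List with `statistic` (positive-rank sum V), `n` (pairs retained),
#'   `p`, `method`. If every difference is zero, `p = 1` with a warning.
#' @export
wilcoxon_signed_rank <- function(x, y, exact_max = 25L) {
  d <- as.numeric(x) - as.numeric(y)
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    warning("wilcoxon_signed_rank: all differences zero; p = 1")
    return(list(statistic = 0, n = 0L, p = 1, method = "degenerate"))
  }
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    # exact: distribution of sum of a random subset of the (doubled) ranks
    r2 <- round(2 * r)                      # mid-ranks -> integers
    total <- sum(r2)
    f <- numeric(total + 1L); f[1] <- 1     # f[s+1] = #assignments with sum s
    for (w in r2) {
      f[(w + 1L):(total + 1L)] <- f[(w + 1L):(total + 1L)] + f[1:(total + 1L - w)]
    }
    probs <- f / 2^n
    v2 <- round(2 * V)
    p_le <- sum(probs[1:(v2 + 1L)])
    p_ge <- sum(probs[(v2 + 1L):(total + 1L)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal-approximation"
  }
  list(statistic = V, n = n, p = p, method = method)
}

#' Pairwise Wilcoxon signed-rank tests with Bonferroni correction
#'
#' Runs a two-sided paired Wilcoxon test on every unordered pair of condition
#' columns and multiplies each raw p-value by the number of comparisons
#' k(k-1)/2, capped at 1.
#'
#' @param m Subjects x conditions matrix.
#' @param alpha Significance level, default 0.05.
#' @return Object of class `eda_test_report`: list with `pairwise_raw` and
#'   `pairwise_adj` (symmetric k x k matrices, diagonal NA), `n_comparisons`,
#'   `alpha`, `significant` (logical matrix at `alpha` after correction).
#' @export
wilcoxon_pairwise_bonferroni <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  k <- ncol(m)
  if (k < 2L) stop("wilcoxon_pairwise_bonferroni: need >= 2 conditions")
  labs <- colnames(m)
  if (is.null(labs)) labs <- paste0("C", seq_len(k))
  raw <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  n_comp <- k * (k - 1) / 2
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    p <- wilcoxon_signed_rank(m[, i], m[, j])$p
    raw[i, j] <- raw[j, i] <- p
  }
  adj <- raw * n_comp
  adj[!is.na(adj) & adj > 1] <- 1
  structure(list(pairwise_raw = raw, pairwise_adj = adj,
                 n_comparisons = n_comp, alpha = alpha,
                 significant = adj < alpha),
            class = "eda_test_report")
}

#' @export
print.eda_test_report <- function(x, ...) {
  cat(sprintf("<test report> %d pairwise comparisons, Bonferroni-adjusted\n",
              x$n_comparisons))
  if (!is.null(x$friedman))
    cat(sprintf("  Friedman chi2 = %.3f, p = %.4g%s\n", x$friedman$chi2,
                x$friedman$p,
                if (isTRUE(x$posthoc_run)) "" else " (post hoc not run)"))
  if (!is.null(x$pairwise_adj)) {
    cat("  adjusted p-values:\n")
    print(signif(x$pairwise_adj, 3))
  }
  invisible(x)
}

#' Full group-comparison workflow on a condition matrix
#'
#' Per condition: Lilliefors normality flag. Then a Friedman test across
#' conditions; if it rejects at `alpha` (or `gate = FALSE`), post hoc paired
#' Wilcoxon signed-rank tests on all condition pairs with Bonferroni
#' correction.
#'
#' @param m Subjects x conditions matrix (>= 5 subjects).
#' @param alpha Significance level, default 0.05.
#' @param gate Only run the post hoc tests when Friedman p < alpha (default
#'   TRUE, mirroring standard practice).
#' @param lillie_method,lillie_nsim Passed to [lilliefors()].
#' @return `eda_test_report` with `normality` (per-condition list),
#'   `friedman`, `posthoc_run`, and, when post hoc ran, the pairwise tables
#'   of [wilcoxon_pairwise_bonferroni()].
#' @export
compare_conditions <- function(m, alpha = 0.05, gate = TRUE,
                               lillie_method = "monte-carlo",
                               lillie_nsim = 1000L) {
  m <- as.matrix(m)
  if (nrow(m) < 5L) stop("compare_conditions: need >= 5 subjects")
  normality <- lapply(seq_len(ncol(m)), function(j)
    lilliefors(m[, j], alpha = alpha, method = lillie_method,
               nsim = lillie_nsim))
  names(normality) <- colnames(m)
  fr <- friedman_test(m)
  run_posthoc <- !gate || fr$p < alpha
  rep <- if (run_posthoc) wilcoxon_pairwise_bonferroni(m, alpha)
         else structure(list(pairwise_raw = NULL, pairwise_adj = NULL,
                             n_comparisons = ncol(m) * (ncol(m) - 1) / 2,
                             alpha = alpha, significant = NULL),
                        class = "eda_test_report")
  rep$normality <- normality
  rep$friedman <- fr
  rep$posthoc_run <- run_posthoc
  rep
}
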