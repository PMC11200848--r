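#' Bateman skin-conductance-response kernel
#'
#' Difference-of-exponentials impulse response
#' `h(t) = exp(-t/decay) - exp(-t/rise)`, peak-normalized to 1. This is the
#' standard model of a single skin-conductance response: fast rise, slow
#' recovery. The analytic peak time is
#' `log(decay/rise) * rise * decay / (decay - rise)`.
#'
#' @param rise_s Rise time constant in seconds (> 0).
#' @param decay_s Decay time constant in seconds (> rise_s).
#' @param fs Sampling rate in Hz.
#' @param length_s Kernel duration in seconds; default long enough for the
#'   tail to fall below 1% of the peak.
#' @return Numeric vector, `h[1] = h(0) = 0`, `max(h) = 1`.
#' @export
bateman_kernel <- function(rise_s = 0.75, decay_s = 10, fs = 5,
                           length_s = NULL) {
  if (!(decay_s > rise_s && rise_s > 0))
    stop("bateman_kernel: need decay_s > rise_s > 0")
  if (is.null(length_s)) length_s <- decay_s * 5
  t <- seq(0, length_s, by = 1 / fs)
  h <- exp(-t / decay_s) - exp(-t / rise_s)
  h / max(h)
}

#' Synthetic-signal configuration
#'
#' Bundles the generator parameters of [generate_eda()] with validation.
#' "Arousal" is operationalized as the rate of phasic skin-conductance
#' responses (SCRs).
#'
#' @param duration_s Recording length in seconds (> 0). Default 120 (the
#'   ultra-short stimulus windows the analysis targets).
#' @param fs Sampling rate in Hz. Default 5, the analysis rate.
#' @param scr_rate SCR events per minute (Poisson-timed). Default 4.
#' @param scr_amp Mean SCR amplitude in microsiemens (log-normal across
#'   events, coefficient of variation 0.5). Default 0.5.
#' @param rise_s,decay_s Bateman kernel time constants, seconds. Defaults
#'   0.75 and 10 (physiologically typical).
#' @param tonic_level Baseline skin conductance, microsiemens. Default 2.
#' @param tonic_drift Amplitude of a slow (0.003 Hz) sinusoidal baseline
#'   drift, microsiemens. Default 0.3.
#' @param noise_sd Additive white measurement noise SD, microsiemens.
#'   Default 0.02.
#' @param seed RNG seed, or NULL to use the current stream.
#' @return A validated list of class `eda_synth_config`.
#' @export
synth_config <- function(duration_s = 120, fs = 5, scr_rate = 4,
                         scr_amp = 0.5, rise_s = 0.75, decay_s = 10,
                         tonic_level = 2, tonic_drift = 0.3,
                         noise_sd = 0.02, seed = NULL) {
  stopifnot(duration_s > 0, fs > 0, scr_rate >= 0, scr_amp > 0,
            decay_s > rise_s, rise_s > 0, noise_sd >= 0)
  structure(list(duration_s = duration_s, fs = fs, scr_rate = scr_rate,
                 scr_amp = scr_amp, rise_s = rise_s, decay_s = decay_s,
                 tonic_level = tonic_level, tonic_drift = tonic_drift,
                 noise_sd = noise_sd, seed = seed),
            class = "eda_synth_config")
}

#' Generate a synthetic EDA-like signal
#'
#' Tonic baseline (constant level plus a slow sinusoidal drift with random
#' phase) + phasic component (Poisson-timed SCR events with log-normal
#' amplitudes, convolved with the Bateman kernel) + white Gaussian
#' measurement noise. Fully reproducible given `cfg$seed`.
#'
#' @param cfg An `eda_synth_config` from [synth_config()].
#' @return An [eda_signal()] of exactly `duration_s * fs` samples;
#'   `meta$n_scr` records the number of SCR events drawn.
#' @export
generate_eda <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "eda_synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- round(cfg$duration_s * cfg$fs)
  t <- (seq_len(n) - 1L) / cfg$fs
  phase <- stats::runif(1, 0, 2 * pi)
  tonic <- cfg$tonic_level + cfg$tonic_drift * sin(2 * pi * 0.003 * t + phase)
  n_ev <- stats::rpois(1, cfg$scr_rate * cfg$duration_s / 60)
  driver <- numeric(n)
  if (n_ev > 0) {
    at <- sample.int(n, n_ev, replace = TRUE)
    # log-normal amplitudes with mean scr_amp and CV 0.5
    sl2 <- log(1 + 0.5^2)
    amp <- stats::rlnorm(n_ev, meanlog = log(cfg$scr_amp) - sl2 / 2,
                         sdlog = sqrt(sl2))
    for (k in seq_len(n_ev)) driver[at[k]] <- driver[at[k]] + amp[k]
  }
  kern <- bateman_kernel(cfg$rise_s, cfg$decay_s, cfg$fs)
  phasic <- stats::convolve(driver, rev(kern), type = "open")[seq_len(n)]
  noise <- if (cfg$noise_sd > 0) stats::rnorm(n, 0, cfg$noise_sd) else numeric(n)
  eda_signal(tonic + phasic + noise, cfg$fs,
             meta = list(synthetic = TRUE, n_scr = n_ev,
                         scr_rate = cfg$scr_rate))
}

#' Generate a paired multi-subject cohort of synthetic EDA signals
#'
#' Each subject receives one signal per condition. Subject-level random
#' effects (tonic level and SCR-amplitude scaling) are shared across that
#' subject's conditions, so within-subject pairing carries real structure
#' for the paired statistics. Child seeds are derived deterministically from
#' the master seed.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param conditions Named list of `eda_synth_config` objects, one per
#'   condition. Any per-config `seed` entries are ignored.
#' @param seed Master RNG seed.
#' @return Data frame with columns `subject`, `condition`, and a list-column
#'   `signal` of [eda_signal()] objects.
#' @export
generate_cohort <- function(n_subjects, conditions, seed = 1L) {
  stopifnot(n_subjects >= 2, length(conditions) >= 1,
            !is.null(names(conditions)))
  set.seed(seed)
  tonic_off <- stats::rnorm(n_subjects, 0, 0.4)
  amp_scale <- stats::rlnorm(n_subjects, 0, 0.25)
  child <- sample.int(2^31 - 1L, n_subjects * length(conditions))
  rows <- list()
  i <- 0L
  for (s in seq_len(n_subjects)) {
    for (cn in names(conditions)) {
      i <- i + 1L
      cfg <- conditions[[cn]]
      cfg$seed <- child[i]
      cfg$tonic_level <- max(0.2, cfg$tonic_level + tonic_off[s])
      cfg$scr_amp <- cfg$scr_amp * amp_scale[s]
      sig <- generate_eda(cfg)
      sig$meta$subject <- sprintf("S%02d", s)
      sig$meta$condition <- cn
      rows[[i]] <- list(subject = sprintf("S%02d", s), condition = cn,
                        signal = sig)
    }
  }
  data.frame(subject = vapply(rows, `[[`, "", "subject"),
             condition = vapply(rows, `[[`, "", "condition"),
             signal = I(lapply(rows, `[[`, "signal")),
             stringsAsFactors = FALSE)
}
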