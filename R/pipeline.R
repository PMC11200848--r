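#' End-to-end metric computation over a collection of recordings
#'
#' For every row of `records`, pre-processes the raw signal (resample to
#' `target_fs`, tonic/phasic decomposition, noiseless reconstruction,
#' z-score), estimates the embedding parameters at scale 1, and computes the
#' requested indices: single-scale ComEDA, the multiscale MComEDA area, and
#' the spectral EDASymp index.
#'
#' @param records Data frame with columns `subject`, `condition`, optionally
#'   `stimulus`, and either a list-column `signal` of [eda_signal()] objects
#'   (e.g. from [generate_cohort()]) or a column `path` of CSV files read
#'   with [load_signal()] at rate `fs`.
#' @param fs Sampling rate for `path`-based records, Hz.
#' @param target_fs Analysis rate, default 5 Hz.
#' @param backend Decomposition backend, see [decompose_eda()].
#' @param params Fixed `eda_embedding_params`, or NULL (default) to estimate
#'   (tau, m) per recording.
#' @param betas Scale factors for [multiscale_trend()], or NULL for the
#'   length-based default, using `min_samples`.
#' @param min_samples Minimum coarse-grained length when `betas` is NULL;
#'   default 30.
#' @param metrics Character subset of `c("comeda", "mcomeda", "edasymp")`.
#' @param on_short Policy for scales too short to embed; see
#'   [multiscale_trend()]. Default `"truncate"`.
#' @param out_dir If non-NULL, writes `metrics.csv` and the resolved
#'   configuration `run_config.json` there.
#' @return Data frame with one row per recording: identifiers, `tau`, `m`,
#'   `beta_max`, and one column per requested metric.
#' @export
run_compute <- function(records, fs = NULL, target_fs = 5,
                        backend = "lowpass", params = NULL, betas = NULL,
                        min_samples = 30L,
                        metrics = c("comeda", "mcomeda", "edasymp"),
                        on_short = "truncate", out_dir = NULL) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  has_sig <- "signal" %in% names(records)
  if (!has_sig && !"path" %in% names(records))
    stop("run_compute: records need a 'signal' or 'path' column")
  if (!has_sig && is.null(fs))
    stop("run_compute: fs required for path-based records")
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    sig <- if (has_sig) records$signal[[i]]
           else load_signal(records$path[i], fs)
    pre <- preprocess_eda(sig, target_fs = target_fs, backend = backend)
    N <- length(pre$values)
    p <- if (is.null(params)) estimate_embedding(pre) else params
    b <- if (is.null(betas)) seq_len(max_scale(N, min_samples)) else betas
    row <- list(
      subject = if ("subject" %in% names(records)) records$subject[i] else NA,
      condition = if ("condition" %in% names(records)) records$condition[i] else NA,
      stimulus = if ("stimulus" %in% names(records)) records$stimulus[i] else i,
      tau = p$tau, m = p$m)
    if ("comeda" %in% metrics) row$comeda <- comeda(pre, p)
    if ("mcomeda" %in% metrics) {
      tr <- multiscale_trend(pre, p, betas = b, on_short = on_short)
      row$mcomeda <- mcomeda(tr)
      row$beta_max <- max(tr$betas)
    }
    if ("edasymp" %in% metrics) row$edasymp <- edasymp(pre)
    out[[i]] <- row
  }
  tab <- do.call(rbind, lapply(out, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(tab, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    cfg <- list(target_fs = target_fs, backend = backend,
                betas = betas, min_samples = min_samples, metrics = metrics,
                on_short = on_short,
                package_version = as.character(utils::packageVersion("mcomeda")))
    jsonlite::write_json(cfg, file.path(out_dir, "run_config.json"),
                         auto_unbox = TRUE, null = "null")
  }
  tab
}

#' Group statistics over a per-stimulus metric table
#'
#' For each requested metric column: averages values per subject and
#' condition into a condition matrix, then runs the paired nonparametric
#' workflow of [compare_conditions()] (Lilliefors flags, Friedman gate,
#' pairwise Wilcoxon signed-rank with Bonferroni correction).
#'
#' @param metric_table Data frame from [run_compute()], or a path to such a
#'   CSV.
#' @param metrics Metric column names to test; default every one of
#'   `c("comeda", "mcomeda", "edasymp")` present in the table.
#' @param alpha Significance level, default 0.05.
#' @param gate Friedman gate for the post hoc tests, default TRUE.
#' @param out_dir If non-NULL, writes per-metric `stats_<metric>.json` and
#'   adjusted p-value tables `pairwise_<metric>.csv` there.
#' @return Named list of `eda_test_report` objects, one per metric.
#' @export
run_stats <- function(metric_table, metrics = NULL, alpha = 0.05,
                      gate = TRUE, out_dir = NULL) {
  if (is.character(metric_table))
    metric_table <- utils::read.csv(metric_table, stringsAsFactors = FALSE)
  if (is.null(metrics))
    metrics <- intersect(c("comeda", "mcomeda", "edasymp"),
                         names(metric_table))
  if (!length(metrics)) stop("run_stats: no metric columns found")
  reports <- lapply(metrics, function(mname) {
    recs <- data.frame(subject = metric_table$subject,
                       condition = metric_table$condition,
                       value = metric_table[[mname]])
    cm <- aggregate_by_condition(recs)
    compare_conditions(cm, alpha = alpha, gate = gate)
  })
  names(reports) <- metrics
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (mname in metrics) {
      r <- reports[[mname]]
      jsonlite::write_json(
        list(friedman = r$friedman, posthoc_run = r$posthoc_run,
             alpha = r$alpha,
             pairwise_adj = r$pairwise_adj,
             normality_reject = lapply(r$normality, `[[`, "reject")),
        file.path(out_dir, paste0("stats_", mname, ".json")),
        auto_unbox = TRUE, null = "null", digits = NA)
      if (!is.null(r$pairwise_adj))
        utils::write.csv(r$pairwise_adj,
                         file.path(out_dir, paste0("pairwise_", mname, ".csv")))
    }
  }
  reports
}
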