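test_that("edasymp separates in-band from out-of-band power", {
  t <- (0:599) / 5                         # 120 s at 5 Hz
  in_band <- eda_signal(sin(2 * pi * 0.1 * t), 5)
  out_band <- eda_signal(sin(2 * pi * 0.5 * t), 5)
  expect_gt(edasymp(in_band), 100 * edasymp(out_band))

  expect_equal(edasymp(eda_signal(rep(0, 300), 5)), 0)
  expect_error(edasymp(eda_signal(rnorm(100), 5)), "shorter")
})

test_that("edasymp windows 30 s blocks and drops the partial tail", {
  set.seed(19)
  x <- rnorm(300)                          # 60 s at 5 Hz: two windows
  s60 <- eda_signal(x, 5)
  w1 <- edasymp(eda_signal(x[1:150], 5) )
  w2 <- edasymp(eda_signal(x[151:300], 5))
  expect_equal(edasymp(s60), (w1 + w2) / 2, tolerance = 1e-12)
  # 59 s: only the first window counts
  s59 <- eda_signal(x[1:295], 5)
  expect_equal(edasymp(s59), w1, tolerance = 1e-12)
})

test_that("aggregate_by_condition averages within subject x condition", {
  rec <- data.frame(subject = c("a", "a", "a", "b", "b"),
                    condition = c("sca", "sca", "rel", "sca", "rel"),
                    value = c(0.4, 0.6, 0.2, 0.8, 0.1))
  m <- aggregate_by_condition(rec)
  expect_equal(m["a", "sca"], 0.5)
  expect_equal(m["b", "rel"], 0.1)
  expect_equal(dim(m), c(2L, 2L))

  # one value per cell: identity
  rec1 <- data.frame(subject = rep(c("a", "b"), each = 2),
                     condition = rep(c("x", "y"), 2),
                     value = 1:4)
  expect_equal(as.numeric(aggregate_by_condition(rec1)),
               as.numeric(matrix(c(1, 3, 2, 4), 2)))

  # 30 subjects x 4 conditions x 2 stimuli -> 30 x 4
  big <- expand.grid(subject = sprintf("s%02d", 1:30),
                     condition = c("amu", "bor", "rel", "sca"),
                     stim = 1:2)
  big$value <- runif(nrow(big))
  expect_equal(dim(aggregate_by_condition(big)), c(30L, 4L))

  expect_error(aggregate_by_condition(rec[-3, ]), "missing")
})

test_that("lilliefors rejects uniform, accepts normal, affine-invariant", {
  set.seed(20)
  u <- runif(200)
  lu <- lilliefors(u, nsim = 500)
  expect_true(lu$reject)
  expect_lt(lu$p, 0.05)

  set.seed(21)
  g <- rnorm(200)
  lg <- lilliefors(g, nsim = 500)
  expect_gt(lg$p, 0.01)

  expect_equal(mcomeda:::lillie_stat(g), mcomeda:::lillie_stat(3 * g - 7),
               tolerance = 1e-12)

  # analytic approximation agrees in direction
  expect_lt(lilliefors(u, method = "approx")$p, 0.05)
  expect_error(lilliefors(rep(1, 10)), "constant")
  expect_error(lilliefors(1:4), "n >= 5")
})

test_that("friedman_test reproduces the worked example and the stats oracle", {
  m <- rbind(c(1, 2, 3), c(1.1, 2.2, 3.1), c(0.9, 2.1, 3.4))
  fr <- friedman_test(m)
  expect_equal(fr$chi2, 6)
  expect_equal(fr$p, exp(-3), tolerance = 1e-9)

  expect_equal(friedman_test(matrix(2, 4, 3))$chi2, 0)
  expect_equal(friedman_test(matrix(2, 4, 3))$p, 1)

  set.seed(22)
  r <- matrix(rnorm(40), 10, 4)
  fr2 <- friedman_test(r)
  oracle <- stats::friedman.test(r)
  expect_equal(fr2$chi2, unname(oracle$statistic), tolerance = 1e-9)
  expect_equal(fr2$p, oracle$p.value, tolerance = 1e-9)

  # invariant to column permutation and to strictly monotone transforms
  expect_equal(friedman_test(r[, c(3, 1, 4, 2)])$chi2, fr2$chi2)
  expect_equal(friedman_test(exp(r))$chi2, fr2$chi2)
})

test_that("wilcoxon_signed_rank matches full enumeration (ties included)", {
  # 6 uniformly signed pairs: exact two-sided p = 2/64
  x <- c(2, 3, 4, 5, 6, 7); y <- c(1, 2, 3, 4, 5, 6) - c(0, .1, .2, .3, .4, .5)
  w <- wilcoxon_signed_rank(x, y)
  expect_equal(w$p, 2 / 64)
  expect_equal(w$method, "exact")

  set.seed(23)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    a <- sample(1:8, n, replace = TRUE)      # integer values force ties/zeros
    b <- sample(1:8, n, replace = TRUE)
    if (all(a == b)) next
    got <- wilcoxon_signed_rank(a, b)$p
    expect_equal(got, oracle_signed_rank_p(a, b), tolerance = 1e-12,
                 info = paste("rep", rep))
  }

  # tie-free case agrees with stats::wilcox.test exact path
  set.seed(24)
  a <- rnorm(12); b <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(a, b)$p,
               stats::wilcox.test(a, b, paired = TRUE, exact = TRUE)$p.value,
               tolerance = 1e-12)

  expect_warning(wz <- wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3)), "zero")
  expect_equal(wz$p, 1)

  # statistic depends only on signs and rank order of |differences|:
  # invariant under positive affine maps of the paired values
  set.seed(25)
  a <- runif(15); b <- runif(15)
  expect_equal(wilcoxon_signed_rank(a, b)$statistic,
               wilcoxon_signed_rank(4 * a + 2, 4 * b + 2)$statistic)
})

test_that("large-sample Wilcoxon uses the tie-corrected normal approximation", {
  set.seed(26)
  a <- rnorm(40); b <- rnorm(40) + 1
  w <- wilcoxon_signed_rank(a, b)
  expect_equal(w$method, "normal-approximation")
  ref <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE,
                            correct = TRUE)$p.value
  expect_equal(w$p, ref, tolerance = 1e-9)
  expect_lt(w$p, 0.01)
})

test_that("pairwise Bonferroni report caps, orders and symmetrizes", {
  set.seed(27)
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("amu", "bor", "rel", "sca")))
  rep4 <- wilcoxon_pairwise_bonferroni(m)
  expect_equal(rep4$n_comparisons, 6)
  expect_true(all(is.na(diag(rep4$pairwise_adj))))
  expect_equal(rep4$pairwise_adj, t(rep4$pairwise_adj))
  off <- rep4$pairwise_adj[upper.tri(rep4$pairwise_adj)]
  raw <- rep4$pairwise_raw[upper.tri(rep4$pairwise_raw)]
  expect_equal(off, pmin(1, raw * 6))
  expect_true(all(off >= raw))             # adjusted >= raw, monotone
  # null data: most adjusted p hit the 1.0 cap
  expect_true(any(off == 1))
})

test_that("compare_conditions gates the post hoc on Friedman", {
  m_null <- matrix(rep(1:8, 3), 8, 3)      # identical columns
  set.seed(28)
  r <- compare_conditions(m_null, lillie_nsim = 200)
  expect_equal(r$friedman$p, 1)
  expect_false(r$posthoc_run)
  expect_null(r$pairwise_adj)

  m_eff <- cbind(rnorm(10), rnorm(10) + 3)
  colnames(m_eff) <- c("lo", "hi")
  r2 <- compare_conditions(m_eff, lillie_nsim = 200)
  expect_true(r2$posthoc_run)
  expect_equal(dim(r2$pairwise_adj), c(2L, 2L))
  expect_length(r2$normality, 2L)
})
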