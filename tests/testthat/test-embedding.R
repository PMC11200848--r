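test_that("AMI matches the brute-force histogram oracle", {
  set.seed(3)
  x <- cumsum(rnorm(50))
  for (nb in c(4, 7)) {
    got <- auto_mutual_information(x, max_lag = 10, n_bins = nb)
    want <- oracle_ami(x, max_lag = 10, n_bins = nb)
    expect_lt(max(abs(got - want)), 1e-9)
  }
})

test_that("AMI behaves on canonical inputs", {
  set.seed(4)
  u <- runif(2000)
  ami <- auto_mutual_information(u, max_lag = 5, n_bins = 10)
  expect_true(all(ami >= 0))
  expect_true(all(ami[-1] < 0.1))      # iid: near zero for every lag >= 1

  # lag-0 value is the plug-in entropy of the binned marginal
  nb <- 10
  edges <- seq(min(u), max(u), length.out = nb + 1)
  bin <- findInterval(u, edges, rightmost.closed = TRUE, all.inside = TRUE)
  p <- as.numeric(table(bin)) / length(u)
  expect_lt(abs(ami[1] + sum(p * log2(p))), 1e-9)

  # periodic series: AMI at one full period recovers (almost) the lag-0 value
  x <- sin(2 * pi * (0:399) / 40)
  amis <- auto_mutual_information(x, max_lag = 45, n_bins = 8)
  expect_gt(amis[41], 0.9 * amis[1])

  expect_error(auto_mutual_information(rep(1, 100), max_lag = 10), "constant")
  expect_error(auto_mutual_information(u, max_lag = 1500), "max_lag")
})

test_that("select_tau takes the first local minimum with contracted fallbacks", {
  expect_equal(select_tau(c(2.0, 1.0, 1.5, 0.5, 0.6)), 1L)
  expect_warning(tau <- select_tau(c(5, 4, 3, 2, 1)), "monotone")
  expect_equal(tau, 4L)
  # no local min but not monotone: global minimum
  expect_equal(select_tau(c(1.0, 1.1, 0.9, 1.2, 1.3)), 2L)
  # plateau: first index of the dip
  expect_equal(select_tau(c(2, 1, 1, 2, 3)), 1L)

  # sine of period 40: the histogram-AMI dip is a flat basin between the
  # lag-0 peak and the full-period revival at lag 40; tau must land in it
  # and agree with the brute-force AMI curve
  x <- sin(2 * pi * (0:599) / 40)
  ami_sine <- auto_mutual_information(x, max_lag = 30)
  tau <- select_tau(ami_sine)
  expect_true(tau >= 4 && tau <= 16)
  expect_equal(tau, select_tau(oracle_ami(x, 30, min(ceiling(sqrt(600)), 64))))
})

test_that("FNN matches the brute-force oracle and canonical limits", {
  set.seed(5)
  x <- cumsum(rnorm(60))
  got <- fnn_fractions(x, tau = 2, m_max = 3)
  want <- oracle_fnn(x, tau = 2, m_max = 3)
  expect_lt(max(abs(got - want)), 1e-9)
  expect_true(all(got >= 0 & got <= 1))

  # clean sine unfolds by dimension 2 (incommensurate period so sampled
  # points do not repeat exactly)
  s <- sin(2 * pi * (0:499) / 23.7)
  fr <- fnn_fractions(s, tau = 6, m_max = 4)
  expect_lt(fr[2], 0.05)

  # iid noise never unfolds
  set.seed(6)
  nf <- fnn_fractions(rnorm(500), tau = 1, m_max = 6)
  expect_true(all(nf > 0.1))

  expect_error(fnn_fractions(x, tau = 2, m_max = 40), "too short")
})

test_that("select_m applies threshold, fallback and the floor of 2", {
  expect_equal(select_m(c(0.9, 0.02, 0.01), 0.05), 2L)
  expect_warning(m <- select_m(c(0.9, 0.8, 0.7), 0.05), "argmin")
  expect_equal(m, 3L)
  expect_warning(m2 <- select_m(c(0.0, 0.3), 0.05), "floored")
  expect_equal(m2, 2L)
})

test_that("embed_series builds Takens vectors with the exact count", {
  e <- embed_series(1:6, tau = 1, m = 3)
  expect_equal(e$n, 4L)
  expect_equal(e$vectors[1, ], c(3, 2, 1))
  expect_equal(e$vectors[4, ], c(6, 5, 4))

  # m = 1 is the identity embedding
  e1 <- embed_series(1:10, tau = 3, m = 1)
  expect_equal(e1$vectors[, 1], as.numeric(1:10))

  # count formula
  set.seed(8)
  x <- rnorm(100)
  e2 <- embed_series(x, tau = 7, m = 4)
  expect_equal(e2$n, 100L - 21L)
  expect_equal(nrow(e2$vectors), 79L)

  # oracle rows + determinism
  expect_equal(e2$vectors, oracle_embed(x, 7, 4))
  expect_identical(e2$vectors, embed_series(x, 7, 4)$vectors)

  expect_error(embed_series(1:5, tau = 2, m = 4), "too short")
})

test_that("count conservation holds across random (tau, m)", {
  set.seed(9)
  for (rep in 1:20) {
    N <- sample(30:120, 1)
    tau <- sample(1:5, 1)
    m <- sample(2:5, 1)
    if (N <= (m - 1) * tau) next
    e <- embed_series(rnorm(N), tau, m)
    expect_equal(e$n, N - (m - 1) * tau)
  }
})

test_that("estimate_embedding returns valid parameters on synthetic EDA", {
  s <- preprocess_eda(generate_eda(synth_config(seed = 12)))
  p <- suppressWarnings(estimate_embedding(s))
  expect_gte(p$tau, 1L)
  expect_gte(p$m, 2L)
  expect_true(all(p$fnn_fractions >= 0 & p$fnn_fractions <= 1))
})
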