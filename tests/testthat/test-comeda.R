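make_emb <- function(v) {
  structure(list(vectors = v, tau = 1L, m = ncol(v), n = nrow(v)),
            class = "eda_embedding")
}

test_that("pairwise_angular reproduces hand cosines and the oracle", {
  v <- rbind(c(1, 0), c(0, 1), c(1, 1), c(2, 0))
  ang <- pairwise_angular(make_emb(v))
  # pairs in column-major upper-triangle order: (1,2),(1,3),(2,3),(1,4),(2,4),(3,4)
  expect_equal(ang$n_pairs, 6L)
  expect_equal(sort(ang$d),
               sort(c(0, 1 / sqrt(2), 1 / sqrt(2), 1, 0, 1 / sqrt(2))),
               tolerance = 1e-12)
  expect_true(all(ang$d >= -1 & ang$d <= 1))

  set.seed(10)
  e <- embed_series(cumsum(rnorm(80)), tau = 2, m = 3)
  got <- sort(pairwise_angular(e)$d)
  want <- sort(oracle_cosines(e$vectors))
  expect_lt(max(abs(got - want)), 1e-9)
})

test_that("pairwise_angular guards degenerate and near-zero-norm inputs", {
  z <- matrix(0, 5, 2)
  expect_error(pairwise_angular(make_emb(z)), "degenerate attractor")
  # a single zero vector among many is over the 1% skip budget at n = 5
  v <- rbind(matrix(rnorm(8), 4, 2), c(0, 0))
  expect_error(pairwise_angular(make_emb(v)), "near-zero")
})

test_that("sturges_bins is the ceiling-log2 rule", {
  expect_equal(sturges_bins(4950), 14L)
  expect_equal(sturges_bins(2), 2L)
  expect_equal(sturges_bins(1024), 11L)
  expect_error(sturges_bins(1), "n_samples")
})

test_that("diffusion_pdf yields a normalized PDF matching the binning oracle", {
  set.seed(11)
  d <- tanh(rnorm(500))
  pdf <- diffusion_pdf(d, 9)
  expect_equal(sum(pdf$p), 1, tolerance = 1e-9)
  expect_true(all(pdf$p >= 0))
  expect_true(all(diff(pdf$edges) > 0))
  expect_equal(length(pdf$edges), 10L)

  # bin masses equal an explicit accumulation over the same mesh density
  kde <- mcomeda:::diffusion_kde(d, -1, 1)
  want <- oracle_bin_masses(kde$mesh, kde$density, kde$dx, pdf$edges)
  expect_lt(max(abs(pdf$p - want)), 1e-9)

  # degenerate: all distances identical
  expect_warning(dg <- diffusion_pdf(rep(0.5, 50), 5), "degenerate")
  expect_equal(dg$p, 1)
  expect_equal(dg$B, 1L)

  expect_error(diffusion_pdf(d[1:5], 5), "at least 10")
})

test_that("diffusion_pdf recovers a flat density from uniform draws", {
  set.seed(12)
  d <- runif(10000, -1, 1)
  p <- diffusion_pdf(d, 14)$p
  expect_lt(max(abs(p - 1 / 14)), 0.01)
})

test_that("renyi2 matches closed forms and is below Shannon entropy", {
  expect_equal(renyi2(rep(1 / 8, 8)), 3)
  expect_equal(renyi2(c(1, 0, 0)), 0)
  expect_equal(renyi2(c(0.5, 0.5, 0, 0)), 1)
  expect_equal(renyi2(c(0.2, 0.8)), oracle_renyi2(c(0.2, 0.8)))
  expect_error(renyi2(c(0.5, 0.2)), "probability")

  set.seed(13)
  for (i in 1:20) {
    p <- runif(sample(2:16, 1)); p <- p / sum(p)
    shannon <- -sum(p * log2(p))
    expect_lte(renyi2(p), shannon + 1e-12)
    expect_lte(renyi2(p), log2(length(p)) + 1e-12)
    expect_gte(renyi2(p), 0)
  }
})

test_that("comeda is in [0,1] and scale-invariant", {
  set.seed(14)
  x <- cumsum(rnorm(200))
  par <- embedding_params(tau = 2, m = 3)
  v <- comeda(eda_signal(x, 5), par)
  expect_gte(v, 0); expect_lte(v, 1)

  v_scaled <- comeda(eda_signal(3.7 * x, 5), par)
  expect_lt(abs(v - v_scaled), 1e-12)
})

test_that("comeda equals the stagewise naive reference on a short series", {
  set.seed(15)
  x <- cumsum(rnorm(70))
  par <- embedding_params(tau = 3, m = 2)
  # naive chain: oracle embed -> oracle cosines -> package KDE binning ->
  # oracle Renyi / log2 B
  vec <- oracle_embed(x, 3, 2)
  d <- oracle_cosines(vec)
  B <- ceiling(log2(length(d))) + 1
  p <- diffusion_pdf(d, B)$p
  want <- oracle_renyi2(p) / log2(B)
  expect_equal(comeda(eda_signal(x, 5), par), want, tolerance = 1e-9)
})
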