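test_that("log-likelihood matches a brute-force independent implementation", {
  set.seed(21)
  for (rep in 1:5) {
    K <- sample(2:4, 1)
    mu <- matrix(rnorm(2 * K, 0, 10), 2, K)
    om <- matrix(runif(2 * K, 0.1, 4), 2, K)
    off <- matrix(rnorm(2 * K, 0, 0.5), 2, K)
    sources <- lapply(seq_len(K), function(k)
      source_profile(paste0("s", k),
                     c(d15N = mu[1, k], D17O = mu[2, k]),
                     c(d15N = om[1, k], D17O = om[2, k]),
                     c(d15N = off[1, k], D17O = off[2, k])))
    p <- as.vector(rgamma(K, 1)); p <- p / sum(p)
    sigma <- runif(2, 0.2, 3)
    X <- matrix(rnorm(6, 0, 5), 3, 2,
                dimnames = list(NULL, c("d15N", "D17O")))
    expect_equal(log_likelihood(as.data.frame(X), p, sigma, sources),
                 oracle_loglik(X, p, sigma, mu, om, off),
                 tolerance = 1e-9)
  }
})

test_that("log-likelihood has the closed-form value and symmetries", {
  one <- list(source_profile("only", c(d15N = 5), c(d15N = 0)))
  val <- log_likelihood(data.frame(d15N = 5), p = 1, sigma = 1, one,
                        tracers = "d15N")
  expect_equal(val, log(1 / sqrt(2 * pi)), tolerance = 1e-12)
  # swapping two identical sources leaves the value unchanged
  twin <- make_identical_sources(2)
  X <- data.frame(d15N = c(1, 3), D17O = c(4, 6))
  expect_equal(log_likelihood(X, c(0.3, 0.7), c(1, 1), twin),
               log_likelihood(X, c(0.7, 0.3), c(1, 1), rev(twin)),
               tolerance = 1e-12)
  # missing tracer values are reported with the sample id
  Xbad <- data.frame(sample_id = c("ok", "gap"), d15N = c(1, NA),
                     D17O = c(1, 2))
  expect_error(log_likelihood(Xbad, c(0.5, 0.5), c(1, 1), twin), "gap")
})

test_that("posterior mean matches fine-grid numerical integration in a 1-tracer 2-source case", {
  # independent oracle: flat prior on p2, likelihood integrated on a grid
  grid <- seq(0, 1, length.out = 20001L)
  dens <- dnorm(25, 100 * grid,
                sqrt((1 - grid)^2 * 0.01 + grid^2 * 0.01 + 1))
  oracle_mean <- sum(grid * dens) / sum(dens)
  expect_equal(oracle_mean, 0.25, tolerance = 0.001)
  s2 <- list(source_profile("a", c(x = 0), c(x = 0.1)),
             source_profile("b", c(x = 100), c(x = 0.1)))
  fit <- fit_mixing_model(data.frame(x = 25), s2,
                          quick_config(tracers = "x", sigma_fixed = 1,
                                       seed = 4))
  expect_equal(mean(fit$p[, 2]), oracle_mean, tolerance = 0.01)
})

test_that("identical sources share the posterior equally", {
  src <- make_identical_sources(3)
  X <- data.frame(d15N = rnorm(8, 2, 1), D17O = rnorm(8, 5, 1))
  fit <- fit_mixing_model(X, src, quick_config(seed = 6))
  expect_equal(unname(colMeans(fit$p)), rep(1 / 3, 3), tolerance = 0.03)
})

test_that("every retained draw lies on the simplex and sigma is positive", {
  src <- make_two_sources()
  set.seed(7)
  X <- data.frame(d15N = rnorm(10, 5, 1), D17O = rnorm(10, 10, 1))
  fit <- fit_mixing_model(X, src, quick_config(seed = 7))
  expect_true(all(fit$p >= 0 & fit$p <= 1))
  expect_equal(rowSums(fit$p), rep(1, nrow(fit$p)), tolerance = 1e-9)
  expect_true(all(fit$sigma > 0))
  expect_gt(fit$acceptance_rate, 0)
  expect_lt(fit$acceptance_rate, 1)
  # deterministic given the seed
  fit2 <- fit_mixing_model(X, src, quick_config(seed = 7))
  expect_identical(fit$p, fit2$p)
})

test_that("posterior predictive mean is consistent with the sample mean", {
  src <- make_two_sources()
  sc <- mixture_scenario(c(0.4, 0.6), src,
                         residual_sd = c(d15N = 0.5, D17O = 0.5),
                         n = 40, seed = 31)
  X <- generate_mixture_samples(sc)
  fit <- fit_mixing_model(X, src, quick_config(seed = 31))
  pbar <- colMeans(fit$p)
  mu <- sapply(src, function(s) s$means[c("d15N", "D17O")])
  pred <- drop(mu %*% pbar)
  pooled_se <- apply(X, 2, sd) / sqrt(nrow(X))
  expect_true(all(abs(pred - colMeans(X)) <= 3 * pooled_se))
})

test_that("prior-only sampling recovers the Dirichlet mean", {
  src <- make_identical_sources(4)
  fit <- fit_mixing_model(NULL, src,
                          quick_config(seed = 3, prior_only = TRUE))
  expect_equal(unname(colMeans(fit$p)), rep(0.25, 4), tolerance = 0.02)
  # non-uniform concentration shifts the mean accordingly
  fit2 <- fit_mixing_model(NULL, src,
                           quick_config(seed = 3, prior_only = TRUE,
                                        dirichlet_alpha = c(4, 1, 1, 1)))
  expect_equal(unname(colMeans(fit2$p)), c(4, 1, 1, 1) / 7, tolerance = 0.03)
})

test_that("multi-chain fits report a split-Rhat diagnostic near 1", {
  src <- make_two_sources()
  set.seed(9)
  X <- data.frame(d15N = rnorm(10, 5, 1), D17O = rnorm(10, 10, 1))
  fit <- fit_mixing_model(X, src, quick_config(seed = 9, chains = 2L))
  expect_length(fit$diagnostics$rhat, 2L)
  expect_true(all(fit$diagnostics$rhat < 1.05))
})

test_that("source aggregation is exact moment matching", {
  a <- source_profile("a", c(d15N = 0), c(d15N = 0))
  b <- source_profile("b", c(d15N = 10), c(d15N = 0))
  ab <- aggregate_sources(a, b, c(0.5, 0.5))
  expect_equal(unname(ab$means), 5)
  expect_equal(unname(ab$sds), 5)  # half the gap: sqrt(0.25 * 100)
  # identical sources are unchanged under any weights
  cc <- make_identical_sources(2)
  agg <- aggregate_sources(cc[[1]], cc[[2]], c(0.3, 0.7))
  expect_equal(agg$means, cc[[1]]$means)
  expect_equal(agg$sds, cc[[1]]$sds)
  # spread grows with the mean gap at fixed weights
  gaps <- c(1, 4, 9)
  sds <- sapply(gaps, function(g)
    aggregate_sources(a, source_profile("b", c(d15N = g), c(d15N = 0)),
                      c(0.5, 0.5))$sds[["d15N"]])
  expect_true(all(diff(sds) > 0))
  # general moment identity against direct mixture simulation moments
  x <- source_profile("x", c(d15N = -2), c(d15N = 1.5))
  y <- source_profile("y", c(d15N = 6), c(d15N = 2.5))
  m <- aggregate_sources(x, y, c(0.25, 0.75))
  expect_equal(unname(m$means), 0.25 * -2 + 0.75 * 6)
  expect_equal(unname(m$sds)^2,
               0.25 * 1.5^2 + 0.75 * 2.5^2 + 0.25 * 0.75 * 64,
               tolerance = 1e-12)
  z <- source_profile("z", c(D17O = 0), c(D17O = 1))
  expect_error(aggregate_sources(a, z), "tracer sets differ")
})

test_that("tracer redundancy check flags collinear oxygen tracers", {
  col <- data.frame(d18O = 1:10, D17O = 0.36 * (1:10))
  res <- tracer_redundancy_check(col)
  expect_equal(res$r_squared, 1, tolerance = 1e-12)
  expect_true(res$drop_d18O)
  set.seed(13)
  ind <- data.frame(d18O = rnorm(200), D17O = rnorm(200))
  res2 <- tracer_redundancy_check(ind)
  expect_lt(res2$r_squared, 0.1)
  expect_false(res2$drop_d18O)
  expect_error(tracer_redundancy_check(col[1:2, ]), ">= 3 samples")
})
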