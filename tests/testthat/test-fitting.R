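test_that("log-likelihood equals the sum of elementwise log densities", {
  expect_equal(sn_loglik(0, skewnorm(0, 1, 1)), log(dnorm(0)))
  expect_equal(sn_loglik(0, skewnorm(0, 1, 1)), -0.91894, tolerance = 1e-5)

  withr::with_seed(3, {
    v <- rnorm(10, 2, 3)
    d <- skewnorm(1, 2, 1.7)
    expect_equal(sn_loglik(v, d),
                 sum(dskewnorm(v, 1, 2, 1.7, log = TRUE)), tolerance = 1e-12)
    # direct oracle: formula-level evaluation on 100 random points
    x <- rnorm(100, 0, 4)
    expect_equal(sn_loglik(x, d), brute_loglik(x, 1, 2, 1.7),
                 tolerance = 1e-10)
  })
  expect_error(sn_loglik(numeric(0), skewnorm()), "nonempty")
})

test_that("shape-only fit keeps sample moments exactly and finds the ML shape", {
  v <- c(-2, -1, -1, 0, 0, 0, 1, 1, 2) + 5.3
  f <- snorm_fit(v)
  expect_identical(coef(f)[["mean"]], mean(v))
  expect_identical(coef(f)[["sd"]], sd(v))
  expect_lt(abs(coef(f)[["shape"]] - 1), 1e-2)

  x <- rskewnorm(5000, 5, 2, 2, seed = 1)
  f2 <- snorm_fit(x)
  expect_true(coef(f2)[["shape"]] >= 1.8 && coef(f2)[["shape"]] <= 2.2)
  orc <- oracle_shape_grid(x, mean(x), sd(x))
  expect_lt(abs(f2$logLik - orc$logLik), 1e-4)
  expect_gte(f2$logLik, orc$coarse_logLik - 1e-4)

  expect_error(snorm_fit(rep(3, 10)), "degenerate")
  expect_error(snorm_fit(2), "at least 2")
})

test_that("the bounds sample encodes the 100/10/10 weighting deterministically", {
  s <- bounds_sample(10, 8, 14)
  expect_length(s, 120)
  expect_equal(as.vector(table(s)), c(10, 100, 10))
  expect_equal(s, c(rep(10, 100), rep(8, 10), rep(14, 10)))
  expect_equal(mean(bounds_sample(0, -1, 1)), 0)

  withr::with_seed(21, {
    for (i in 1:5) {
      mu <- rnorm(1); lo <- mu - rexp(1) - 0.01; hi <- mu + rexp(1) + 0.01
      nc <- sample(5:200, 1); nb <- sample(1:50, 1)
      s <- bounds_sample(mu, lo, hi, nc, nb)
      expect_length(s, nc + 2 * nb)
      expect_equal(sum(s == mu), nc)
      expect_equal(sum(s == lo), nb)
      expect_equal(sum(s == hi), nb)
    }
  })
  expect_error(bounds_sample(10, 11, 14), "bracket")
})

test_that("bounds fit constrains the mean exactly and matches the 2-D grid oracle", {
  sym <- fit_bounds(10, 8, 12)
  expect_identical(coef(sym)[["mean"]], 10)
  expect_lt(abs(coef(sym)[["shape"]] - 1), 1e-2)
  # symmetric about 10
  expect_equal(qskewnorm(0.25, 10, sym$dist$sd, sym$dist$shape) +
                 qskewnorm(0.75, 10, sym$dist$sd, sym$dist$shape), 20,
               tolerance = 1e-4)

  rsk <- fit_bounds(10, 9, 14)
  expect_identical(coef(rsk)[["mean"]], 10)
  expect_gt(coef(rsk)[["shape"]], 1)
  orc <- oracle_bounds_grid(bounds_sample(10, 9, 14), 10)
  expect_lt(abs(rsk$logLik - orc$logLik), 1e-4)
  expect_error(fit_bounds(10, 11, 14), "bracket")
})

test_that("both fitting stages agree with exhaustive grid-search oracles", {
  withr::with_seed(31, {
    for (i in 1:10) {
      x <- rskewnorm(200, rnorm(1), rexp(1) + 0.3, exp(runif(1, -1, 1)),
                     seed = 500 + i)
      f <- snorm_fit(x)
      orc <- oracle_shape_grid(x, mean(x), sd(x))
      expect_lt(abs(f$logLik - orc$logLik), 1e-4)
    }
    for (i in 1:10) {
      mu <- rnorm(1)
      lo <- mu - rexp(1) - 0.05
      hi <- mu + rexp(1) + 0.05
      f <- fit_bounds(mu, lo, hi)
      orc <- oracle_bounds_grid(bounds_sample(mu, lo, hi), mu)
      expect_lt(abs(f$logLik - orc$logLik), 1e-4)
    }
  })
})

test_that("fits are scale-equivariant and reflection inverts the shape", {
  x <- rskewnorm(800, 2, 1, 1.8, seed = 77)
  f <- snorm_fit(x)
  a <- 3.5; b <- -4
  g <- snorm_fit(a * x + b)
  expect_equal(coef(g)[["mean"]], a * coef(f)[["mean"]] + b, tolerance = 1e-10)
  expect_equal(coef(g)[["sd"]], a * coef(f)[["sd"]], tolerance = 1e-10)
  expect_equal(coef(g)[["shape"]], coef(f)[["shape"]], tolerance = 1e-4)

  h <- snorm_fit(-x)
  expect_equal(coef(h)[["shape"]], 1 / coef(f)[["shape"]], tolerance = 1e-4)
})

test_that("widening the upper bound never decreases the fitted shape", {
  uppers <- c(10.5, 11, 12, 14, 18)
  shapes <- vapply(uppers,
                   function(u) coef(fit_bounds(10, 8, u))[["shape"]],
                   numeric(1))
  expect_true(all(diff(shapes) >= -1e-6))
})

test_that("snorm_fit objects support the standard modelling methods", {
  x <- rskewnorm(400, 1, 2, 2, seed = 13)
  f <- snorm_fit(x)
  expect_output(print(f), "sample moments")
  expect_output(print(summary(f)), "Quantiles")
  expect_named(coef(f), c("mean", "sd", "shape"))
  expect_equal(as.numeric(logLik(f)), f$logLik)
  expect_equal(attr(logLik(f), "df"), 1L)
  q <- quantile(f, c(0.1, 0.9))
  expect_true(q[1] < q[2])
  expect_identical(simulate(f, 5, seed = 2), simulate(f, 5, seed = 2))
  r <- residuals(f)
  expect_length(r, 400)
  expect_lt(abs(mean(r)), 0.2)  # near-standard-normal quantile residuals
  pdf(NULL); on.exit(dev.off())
  expect_invisible(plot(f))
})
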