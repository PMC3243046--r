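make_gaussian_data <- function(n = 800, d = 2, mean = 10, seed = 11) {
  set.seed(seed)
  matrix(rnorm(n * d, mean = mean), ncol = d)
}

test_that("profile objective reduces to the covariance log-determinant for unit Jacobians", {
  y <- make_gaussian_data()
  n <- nrow(y)
  ctr <- sweep(y, 2, colMeans(y))
  direct <- as.numeric(determinant(crossprod(ctr) / n)$modulus)
  expect_equal(profile_objective(y, transform_spec("identity")), direct,
               tolerance = 1e-12)
  # Box-Cox theta = 1 shifts by -1: covariance unchanged, Jacobian = 1
  expect_equal(profile_objective(y, transform_spec("boxcox", theta = 1)),
               direct, tolerance = 1e-12)
})

test_that("loglik matches an independent Gaussian density computation", {
  skip_if_not_installed("mvtnorm")
  y <- make_gaussian_data(n = 400)
  n <- nrow(y)
  xm <- y  # identity transform
  sig <- crossprod(sweep(xm, 2, colMeans(xm))) / n
  oracle <- sum(mvtnorm::dmvnorm(xm, mean = colMeans(xm), sigma = sig,
                                 log = TRUE))
  expect_equal(transform_loglik(y, transform_spec("identity")), oracle,
               tolerance = 1e-8)
})

test_that("loglik ranks specs in the reverse order of the profile objective", {
  set.seed(21)
  y <- matrix(rlnorm(1200, 1, 0.8), ncol = 2)
  specs <- list(transform_spec("boxcox", theta = 0.2),
                transform_spec("boxcox", theta = 1),
                transform_spec("arcsinh", a = 0, b = 1, c = 0),
                transform_spec("linlog", theta = stats::median(y)))
  obj <- vapply(specs, function(s) profile_objective(y, s), numeric(1))
  ll <- vapply(specs, function(s) transform_loglik(y, s), numeric(1))
  expect_identical(order(obj), rev(order(ll)))
  # and the relation is exactly affine: loglik = const - (n/2) logS
  n <- nrow(y)
  expect_equal(diff(ll), -(n / 2) * diff(obj), tolerance = 1e-8)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(fit_transform(matrix(rnorm(6), ncol = 2), "boxcox"),
               "too few events")
  y <- cbind(rnorm(100), rep(1, 100))
  expect_error(fit_transform(y, "boxcox"), "distinct values")
})

test_that("already-Gaussian data needs no Box-Cox transformation (theta near 1)", {
  y <- make_gaussian_data(n = 2000, mean = 10, seed = 31)
  fit <- fit_transform(y, "boxcox")
  expect_true(fit$converged)
  expect_equal(unname(fit$spec$params[["theta"]]), 1, tolerance = 0.15)
})

test_that("the continuous optimizer attains the dense-grid minimum (1-parameter families)", {
  set.seed(41)
  y <- matrix(rnorm(2000, mean = 6, sd = 1), ncol = 1)
  fit <- fit_transform(y, "boxcox")
  grid <- seq(0.1, 3, length.out = 200)
  vals <- vapply(grid, function(th) {
    profile_objective(y, transform_spec("boxcox", theta = th))
  }, numeric(1))
  expect_lte(fit$objective, min(vals) + 1e-8)
  expect_lt(abs(fit$spec$params[["theta"]] - grid[which.min(vals)]),
            2 * diff(grid)[1])

  yl <- matrix(rlnorm(2000, 2, 1), ncol = 1)
  fitl <- fit_transform(yl, "linlog")
  gridl <- exp(seq(log(max(min(yl), 1e-6)), log(max(yl)),
                   length.out = 200))
  valsl <- vapply(gridl, function(th) {
    profile_objective(yl, transform_spec("linlog", theta = th))
  }, numeric(1))
  expect_lte(fitl$objective, min(valsl) + 1e-8)
})

test_that("fitted objective beats 50 random admissible draws (multi-parameter families)", {
  set.seed(51)
  sim <- simulate_dataset(seed = 9, n = 1500)
  y <- sim$events
  for (family in c("arcsinh", "biexp")) {
    fit <- fit_transform(y, family, seed = 3)
    draws <- vapply(1:50, function(i) {
      profile_objective(y, rand_admissible_spec(family))
    }, numeric(1))
    expect_lte(fit$objective, min(draws, na.rm = TRUE) + 1e-8,
               label = paste("random-restart oracle", family))
  }
})

test_that("the linlog optimum scales with the data (scale equivariance)", {
  set.seed(61)
  y <- matrix(rlnorm(3000, 2, 1), ncol = 1)
  th1 <- fit_transform(y, "linlog")$spec$params[["theta"]]
  th10 <- fit_transform(y * 10, "linlog")$spec$params[["theta"]]
  expect_equal(th10 / th1, 10, tolerance = 0.05)
})

test_that("per-channel fitting returns one fit per channel", {
  set.seed(71)
  y <- cbind(a = rlnorm(500, 1, 0.5), b = rlnorm(500, 3, 0.8))
  fits <- fit_transform(y, "boxcox", per_channel = TRUE)
  expect_named(fits, c("a", "b"))
  expect_s3_class(fits$a$spec, "transform_spec")
  # joint fit on a single channel agrees with the per-channel fit of it
  single <- fit_transform(y[, 1, drop = FALSE], "boxcox", seed = 2)
  expect_equal(fits$a$spec$params[["theta"]],
               single$spec$params[["theta"]], tolerance = 1e-4)
})

test_that("fit results carry provenance (seed, evaluations, data fingerprint)", {
  y <- make_gaussian_data(n = 300, seed = 81)
  fit <- fit_transform(y, "arcsinh", seed = 7)
  expect_identical(fit$seed, 7L)
  expect_gt(fit$n_evals, 10)
  expect_identical(fit$data_hash, cytotrans:::data_fingerprint(y))
  expect_equal(fit$loglik, transform_loglik(y, fit$spec))
})
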