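test_that("closed-form values match the transform definitions", {
  # linlog continuity point: both branches give log(theta)
  expect_equal(forward(transform_spec("linlog", theta = 1), 1), 0)
  expect_equal(forward(transform_spec("linlog", theta = 3), 3), log(3))
  # default arcsinh at zero
  expect_equal(forward(transform_spec("arcsinh", a = 1, b = 1, c = 0), 0),
               log(1 + sqrt(2)), tolerance = 1e-12)
  # Box-Cox at theta = 1 is a unit shift
  expect_equal(forward(transform_spec("boxcox", theta = 1), 5), 4)
  expect_equal(inverse(transform_spec("boxcox", theta = 2), 4), 3)
  expect_equal(inverse(transform_spec("linlog", theta = 1), 0), 1)
  # symmetric biexponential is 2*sinh, odd, so forward(0) = 0
  bx <- transform_spec("biexp", a = 1, b = 1, c = 1, d = 1, f = 0, w = 0)
  expect_equal(biexp_function(bx, 0), 0)
  expect_equal(forward(bx, 0), 0, tolerance = 1e-10)
  # jacobians with known closed forms
  expect_equal(log_jacobian(transform_spec("boxcox", theta = 1), 7), 0)
  expect_equal(log_jacobian(transform_spec("linlog", theta = 2), 1),
               log(1 / 2))
})

test_that("parameter bounds from the transform table are enforced", {
  expect_error(transform_spec("linlog", theta = -1), "theta > 0")
  expect_error(transform_spec("arcsinh", b = 0), "b > 0")
  expect_error(transform_spec("arcsinh", a = -0.1), "a >= 0")
  expect_error(transform_spec("biexp", a = 1.5), "in \\(0, 1\\]")
  expect_error(transform_spec("biexp", f = 0.5), "fixed at 0")
  expect_error(forward(transform_spec("log"), c(1, -2)), "y > 0")
  expect_error(forward(transform_spec("arcsinh"), c(1, NaN)), "non-finite")
})

test_that("every family roundtrips inverse(forward(y)) = y within 1e-8", {
  set.seed(101)
  for (family in c("linlog", "arcsinh", "biexp", "boxcox", "log",
                   "identity")) {
    for (rep in 1:5) {
      spec <- rand_admissible_spec(family)
      y <- roundtrip_grid(family)
      if (family == "linlog") {
        # theta must lie within the fitted data range by construction
        y <- sort(c(y, spec$params[["theta"]]))
      }
      x <- forward(spec, y)
      expect_lt(max(abs(inverse(spec, x) - y)), 1e-8,
                label = paste("roundtrip", family, "rep", rep))
      # forward of inverse as well, on the transformed range (relative:
      # x spans many orders of magnitude, e.g. Box-Cox with theta near 3)
      expect_lt(max(abs(forward(spec, inverse(spec, x)) - x) /
                    pmax(1, abs(x))), 1e-9,
                label = paste("fwd-of-inv", family, "rep", rep))
    }
  }
})

test_that("all transforms are strictly increasing on sorted grids", {
  set.seed(202)
  for (family in c("linlog", "arcsinh", "biexp", "boxcox")) {
    spec <- rand_admissible_spec(family)
    y <- roundtrip_grid(family)
    x <- forward(spec, y)
    expect_true(all(diff(x) > 0), label = paste("monotone", family))
  }
})

test_that("exp(log_jacobian) equals the numerical derivative of forward", {
  set.seed(303)
  pts <- list(linlog = c(0.2, 1.5, 7, 40, 300),
              arcsinh = c(-50, -2, 0, 3, 500),
              boxcox = c(0.2, 1.1, 8, 120),
              biexp = c(-30, -1, 0, 2, 80, 2000),
              log = c(0.5, 3, 41))
  for (family in names(pts)) {
    for (rep in 1:4) {
      spec <- rand_admissible_spec(family)
      y <- pts[[family]]
      if (family == "linlog") {
        # keep evaluation points away from the kink at y = theta
        y <- y[abs(y - spec$params[["theta"]]) > 0.05]
      }
      h <- 1e-6 * pmax(1, abs(y))
      fd <- (forward(spec, y + h) - forward(spec, y - h)) / (2 * h)
      jac <- exp(log_jacobian(spec, y))
      expect_lt(max(abs(jac - fd) / abs(fd)), 1e-6,
                label = paste("jacobian", family, "rep", rep))
    }
  }
})

test_that("Box-Cox approaches sgn(y)*log|y| as theta -> 0", {
  y <- c(0.05, 0.7, 1, 13, 5000)
  near0 <- forward(transform_spec("boxcox", theta = 1e-6), y)
  expect_lt(max(abs(near0 - log(y))), 1e-4)
  # theta = 0 is defined as the analytic limit, including negative y
  at0 <- forward(transform_spec("boxcox", theta = 0), c(-3, 0.5, 2))
  expect_equal(at0, c(-log(3), log(0.5), log(2)))
})

test_that("linlog is continuous at y = theta with Jacobian 1/theta on both sides", {
  th <- 4.7
  spec <- transform_spec("linlog", theta = th)
  eps <- 1e-9
  expect_equal(forward(spec, th - eps), forward(spec, th + eps),
               tolerance = 1e-7)
  expect_equal(exp(log_jacobian(spec, th)), 1 / th)
  expect_equal(exp(log_jacobian(spec, th + 1e-12)), 1 / th,
               tolerance = 1e-9)
})

test_that("biexp_function derivative matches central differences", {
  set.seed(404)
  for (rep in 1:6) {
    spec <- rand_admissible_spec("biexp")
    x <- seq(-4, 4, length.out = 41)
    h <- 1e-6
    fd <- (biexp_function(spec, x + h) - biexp_function(spec, x - h)) /
      (2 * h)
    dv <- cytotrans:::biexp_function_deriv(spec$params, x)
    expect_lt(max(abs(dv - fd) / abs(fd)), 1e-6)
  }
})

test_that("the full biexponential parameterization is weakly identifiable", {
  # two very different parameter vectors induce virtually the same map:
  # (a=1, b=1, c=1, d=1e-10, f=0) vs (a=1, b=1, c'=1e-10, d'=1e-10, f'=-1)
  p1 <- c(a = 1, b = 1, c = 1, d = 1e-10, f = 0, w = 0)
  p2 <- c(a = 1, b = 1, c = 1e-10, d = 1e-10, f = -1, w = 0)
  x <- seq(-5, 5, length.out = 201)
  expect_lt(max(abs(biexp_function(p1, x) - biexp_function(p2, x))), 1e-6)
})

test_that("biexp forward reports failure for unattainable targets", {
  # with b = 0 the function is bounded above by a + f
  expect_error(
    forward(transform_spec("biexp", a = 0.5, b = 0, c = 0.5, d = 1), 10),
    "outside attainable range")
})

test_that("transform specs roundtrip through text serialization bit-identically", {
  set.seed(505)
  path <- tempfile(fileext = ".txt")
  for (family in c("linlog", "arcsinh", "biexp", "boxcox")) {
    spec <- rand_admissible_spec(family)
    write_transform_spec(spec, path)
    back <- read_transform_spec(path)
    expect_identical(back$family, spec$family)
    expect_identical(back$params, spec$params)
  }
})
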