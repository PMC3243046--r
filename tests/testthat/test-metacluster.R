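test_that("population Mahalanobis distance has the documented closed form", {
  p <- population("s1", 1, mu = c(0, 0), sigma = diag(c(1, 4)))
  q <- population("s2", 1, mu = c(1, 2), sigma = diag(2))
  expect_equal(pop_mahalanobis(p, q), 1 / 1 + 4 / 4)
  expect_equal(pop_mahalanobis(p, p), 0)
  # asymmetric: only the first argument's covariance enters
  set.seed(3)
  a <- population("s1", 1, mu = rnorm(3), sigma = rand_spd(3))
  b <- population("s2", 1, mu = rnorm(3), sigma = rand_spd(3))
  expect_false(isTRUE(all.equal(pop_mahalanobis(a, b),
                                pop_mahalanobis(b, a))))
  # and it matches the quadratic form computed directly
  direct <- drop(t(a$mu - b$mu) %*% solve(a$sigma) %*% (a$mu - b$mu))
  expect_equal(pop_mahalanobis(a, b), direct, tolerance = 1e-12)
})

test_that("a single sample yields singleton metaclusters", {
  set.seed(5)
  pops <- list(lapply(1:4, function(j) rand_population("s1", j)))
  mc <- metacluster(pops)
  expect_identical(mc$K, 4L)
  expect_identical(mc$assignments$metacluster, 1:4)
  expect_true(all(lengths(mc$metaclusters) == 1))
})

test_that("two samples with well-separated pairs pair up correctly", {
  mk <- function(s, j, mu) population(s, j, mu = mu, sigma = diag(2))
  pops <- list(list(mk("s1", 1, c(0, 0)), mk("s1", 2, c(10, 10))),
               list(mk("s2", 1, c(0.5, 0)), mk("s2", 2, c(10, 10.5))))
  mc <- metacluster(pops)
  expect_identical(mc$K, 2L)
  lab <- mc$assignments
  expect_identical(lab$metacluster[lab$sample_id == "s1"], 1:2)
  expect_identical(lab$metacluster[lab$sample_id == "s2"], 1:2)
})

test_that("greedy trace matches a hand-simulated run with a forced conflict", {
  # Metaclusters seeded from s1 at (0,0), (10,0), (0,10). Unassigned:
  #   s2: (1,0), (2,0)       both nearest metacluster 1
  #   s3: (0.2,0), (9.8,0.3)
  # Hand trace of globally-minimal single-linkage picks (identity sigmas):
  #   1. s3 p1 -> M1 (d = 0.04)
  #   2. s3 p2 -> M2 (d = 0.13)
  #   3. s2 p1 -> M1 (d = 0.64 to member (0.2,0))
  #   4. s2 p2: M1 blocked by s2 p1 -> M2 (d = 60.93 to (9.8,0.3))
  mk <- function(s, j, mu) population(s, j, mu = mu, sigma = diag(2))
  pops <- list(list(mk("s1", 1, c(0, 0)), mk("s1", 2, c(10, 0)),
                    mk("s1", 3, c(0, 10))),
               list(mk("s2", 1, c(1, 0)), mk("s2", 2, c(2, 0))),
               list(mk("s3", 1, c(0.2, 0)), mk("s3", 2, c(9.8, 0.3))))
  mc <- metacluster(pops)
  lab <- mc$assignments
  expect_identical(lab$metacluster[lab$sample_id == "s1"], 1:3)
  expect_identical(lab$metacluster[lab$sample_id == "s2"], c(1L, 2L))
  expect_identical(lab$metacluster[lab$sample_id == "s3"], c(1L, 2L))
})

test_that("seed-sample ties are broken by the gating log-likelihood", {
  set.seed(7)
  pops <- list(lapply(1:2, function(j) rand_population("s1", j)),
               lapply(1:2, function(j) rand_population("s2", j)))
  mc <- metacluster(pops, sample_loglik = c(-50, -10))
  expect_identical(mc$seed_sample, 2L)
  mc2 <- metacluster(pops, sample_loglik = c(-10, -50))
  expect_identical(mc2$seed_sample, 1L)
})

test_that("no metacluster ever holds two populations from one sample (randomized)", {
  set.seed(11)
  for (rep in 1:1000) {
    n_samples <- sample(2:4, 1)
    pops <- lapply(seq_len(n_samples), function(n) {
      lapply(seq_len(sample(1:4, 1)), function(j) {
        rand_population(paste0("s", n), j)
      })
    })
    mc <- metacluster(pops)
    lab <- mc$assignments
    expect_identical(mc$K, max(lengths(pops)))
    expect_identical(nrow(lab), sum(lengths(pops)))
    expect_false(any(duplicated(lab[, c("sample_id", "metacluster")])))
    expect_true(all(lab$metacluster %in% seq_len(mc$K)))
  }
})

test_that("intra-metacluster variability matches independent recomputation", {
  # closed form: one metacluster with 1-D centers 0 and 2 -> SS = 2
  mk <- function(s, mu) population(s, 1, mu = mu, sigma = diag(1))
  mc1 <- metacluster(list(list(mk("s1", 0)), list(mk("s2", 2))))
  expect_equal(intra_metacluster_variability(mc1), 2)
  # identical centers -> 0
  mc0 <- metacluster(list(list(mk("s1", 1.3)), list(mk("s2", 1.3))))
  expect_equal(intra_metacluster_variability(mc0), 0)
  # random instances vs a naive two-pass recomputation
  set.seed(13)
  for (rep in 1:20) {
    pops <- lapply(1:3, function(n) {
      lapply(1:3, function(j) rand_population(paste0("s", n), j, d = 3))
    })
    mc <- metacluster(pops)
    naive <- 0
    for (k in seq_len(mc$K)) {
      mus <- t(vapply(mc$metaclusters[[k]], `[[`, numeric(3), "mu"))
      ctr <- colMeans(mus)
      for (i in seq_len(nrow(mus))) {
        naive <- naive + sum((mus[i, ] - ctr)^2)
      }
    }
    expect_equal(intra_metacluster_variability(mc), naive,
                 tolerance = 1e-10)
  }
})

test_that("empty input is rejected", {
  expect_error(metacluster(list()), "at least one population")
  expect_error(metacluster(list(list(), list())), "at least one population")
})
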