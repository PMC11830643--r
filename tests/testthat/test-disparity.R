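test_that("constant input yields a zero curve; full sample is recovered at n = N", {
  cur <- rarefy(rep(3, 10), "variance", n_min = 5, reps = 50, seed = 1)
  expect_true(all(cur$median == 0))
  expect_true(all(cur$ci_low == 0 & cur$ci_high == 0))

  set.seed(8)
  x <- rnorm(12)
  for (m in c("variance", "range")) {
    cur <- rarefy(x, m, n_min = 5, reps = 100, seed = 2)
    full <- if (m == "variance") var(x) else diff(range(x))
    last <- cur[cur$n == 12, ]
    expect_identical(last$median, full)
    expect_identical(last$ci_low, full)
    expect_identical(last$ci_high, full)
    expect_true(all(cur$ci_low <= cur$median & cur$median <= cur$ci_high))
  }
})

test_that("closed-form values on {0,1,2,3}", {
  cur <- rarefy(c(0, 1, 2, 3), "variance", n_min = 4, reps = 10, seed = 1)
  expect_equal(cur$median, 5 / 3)        # sample variance of the full set
  curr <- rarefy(c(0, 1, 2, 3), "range", n_min = 4, reps = 10, seed = 1)
  expect_equal(curr$median, 3)
  # exhaustive enumeration of all C(4,2) pairs: ranges {1,1,1,2,2,3}
  ex <- rarefy_exhaustive(c(0, 1, 2, 3), "range", n_min = 2)
  expect_equal(ex$median[ex$n == 2], 1.5)
})

test_that("Monte-Carlo envelopes agree with exhaustive enumeration in the mean", {
  # the MC mean over reps estimates the enumeration mean with known SE
  set.seed(31)
  x <- rnorm(8, mean = 10)
  N <- length(x)
  for (m in c("variance", "range")) {
    stat <- if (m == "variance") var else function(v) diff(range(v))
    for (n in 5:7) {
      all_vals <- utils::combn(x, n, stat)
      set.seed(50 + n)
      draws <- vapply(seq_len(5000),
                      function(i) stat(x[sample.int(N, n)]), numeric(1))
      se <- sd(all_vals) / sqrt(5000)
      expect_lt(abs(mean(draws) - mean(all_vals)), 4 * se)
    }
  }
})

test_that("rarefied sample variance is unbiased in the mean", {
  set.seed(5)
  x <- rnorm(200, sd = 2)          # population variance 4
  pop_var <- 4
  reps <- 2000
  set.seed(6)
  draws <- vapply(seq_len(reps), function(i) var(x[sample.int(200, 20)]),
                  numeric(1))
  se <- sd(draws) / sqrt(reps)
  expect_lt(abs(mean(draws) - pop_var), 3 * se + abs(var(x) - pop_var))
})

test_that("curves are bit-identical given the seed", {
  x <- rnorm(30)
  a <- rarefy(x, "variance", reps = 200, seed = 123)
  b <- rarefy(x, "variance", reps = 200, seed = 123)
  expect_identical(a, b)
  c2 <- rarefy(x, "variance", reps = 200, seed = 124)
  expect_false(identical(a$median, c2$median))
})

test_that("groups below n_min are skipped with a warning", {
  expect_warning(out <- rarefy(1:3, "variance", n_min = 5), "skipped")
  expect_null(out)
})

test_that("divergence threshold finds persistent envelope separation", {
  set.seed(4)
  a <- rarefy(rnorm(60, sd = 1), "variance", seed = 10, variable = "x")
  b <- rarefy(rnorm(60, sd = 5), "variance", seed = 11, variable = "x")
  thr <- divergence_threshold(a, b)
  expect_false(is.na(thr))
  # self-consistency with a direct scan of the stored envelopes
  shared <- intersect(a$n, b$n)
  disjoint <- vapply(shared, function(n) {
    ia <- which(a$n == n); ib <- which(b$n == n)
    a$ci_low[ia] > b$ci_high[ib] || b$ci_low[ib] > a$ci_high[ia]
  }, logical(1))
  scan <- shared[which(rev(cumprod(rev(disjoint))) == 1)[1]]
  expect_identical(thr, scan)

  # identical curves never diverge
  expect_true(is.na(divergence_threshold(a, a)))

  # strictly separated curves diverge at the smallest shared n
  hi <- a
  hi$ci_low <- b$ci_high + 1
  hi$ci_high <- hi$ci_low + 1
  hi$median <- hi$ci_low + 0.5
  expect_identical(divergence_threshold(b, hi), min(shared))

  bad <- b
  bad$variable <- "y"
  expect_error(divergence_threshold(a, bad), "different metrics or variables")
})

test_that("range stabilization responds to outlier structure", {
  # constant data: full range 0, reached immediately
  flat <- rarefy(rep(2, 12), "range", reps = 100, seed = 1)
  expect_identical(range_stabilization(flat), min(flat$n))

  # a uniform grid saturates its range well before the full sample
  grid_vals <- seq(0, 1, length.out = 20)
  cg <- rarefy(grid_vals, "range", reps = 2000, seed = 7)
  expect_lt(range_stabilization(cg, tol = 0.05), 20)

  # one extreme outlier among 50: rarely sampled at small n, so the median
  # range cannot stabilise until n approaches the group size.
  # Exact expectation check: median subsample range at n reaches the full
  # range only when P(outlier included) = n/N > 1/2, i.e. n > 25.
  vals <- c(rnorm(49), 1000)
  co <- rarefy(vals, "range", reps = 2000, seed = 8)
  expect_gt(range_stabilization(co), 25)
})
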