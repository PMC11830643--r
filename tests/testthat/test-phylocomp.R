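test_that("phylogenetic covariance encodes shared path lengths", {
  two <- ape::read.tree(text = "(A:3,B:3);")
  C2 <- phylo_vcv(two)
  expect_equal(unname(C2), rbind(c(3, 0), c(0, 3)), ignore_attr = TRUE)

  three <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  C3 <- phylo_vcv(three)
  expect_equal(C3["A", "B"], 1)
  expect_equal(C3["A", "C"], 0)
  expect_equal(unname(diag(C3)), c(2, 2, 2))

  # lambda transform scales off-diagonals only
  C0 <- phylo_vcv(three, lambda = 0)
  expect_true(all(C0[upper.tri(C0)] == 0))
  expect_equal(diag(C0), diag(C3))
  Ch <- phylo_vcv(three, lambda = 0.5)
  expect_equal(Ch["A", "B"], 0.5)

  dup <- three
  dup$tip.label <- c("A", "A", "C")
  expect_error(phylo_vcv(dup), "not unique")
})

test_that("phylo_vcv agrees with the independent ape implementation", {
  tree <- simulate_tree(40, 0.5, 0.2, seed = 13)
  C <- phylo_vcv(tree)
  C_ape <- ape::vcv.phylo(tree)
  expect_equal(C, C_ape[rownames(C), colnames(C)], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("Blomberg's K matches a brute-force dense-matrix oracle", {
  tree <- ape::read.tree(text = "((A:1,B:1):2,(C:2,D:2):1);")
  y <- c(A = 1.3, B = 0.9, C = -0.2, D = 2.1)
  # oracle written straight from the definition, separate linear algebra
  C <- ape::vcv.phylo(tree)[names(y), names(y)]
  n <- 4
  Ci <- solve(C)
  one <- rep(1, n)
  a0 <- drop((t(one) %*% Ci %*% y) / (t(one) %*% Ci %*% one))
  mse0 <- drop(t(y - a0) %*% (y - a0)) / (n - 1)
  mse <- drop(t(y - a0) %*% Ci %*% (y - a0)) / (n - 1)
  expected_ratio <- (sum(diag(C)) - n / sum(Ci)) / (n - 1)
  K_oracle <- (mse0 / mse) / expected_ratio
  fit <- blomberg_K(y, tree, n_perm = 0)
  expect_equal(fit$K, K_oracle, tolerance = 1e-10)
  # and against picante's independent implementation
  expect_equal(fit$K, as.numeric(picante::Kcalc(y[tree$tip.label], tree)),
               tolerance = 1e-8)
})

test_that("K permutation p detects Brownian signal and respects its floor", {
  tree <- simulate_tree(48, 0.4, 0.1, seed = 3)
  y <- simulate_bm(tree, 1, 0, seed = 4)
  fit <- blomberg_K(y, tree, n_perm = 199, seed = 5)
  expect_gte(fit$p, 1 / 200)
  expect_lt(fit$p, 0.05)          # strong signal on BM data
  set.seed(6)
  # shuffle values across tips (sample() alone would carry the names along)
  fit_null <- blomberg_K(setNames(sample(y), names(y)), tree,
                         n_perm = 199, seed = 7)
  expect_gt(fit_null$p, 0.05)     # shuffling destroys the signal
  expect_error(blomberg_K(rep(1, 48), tree), "constant")
})

test_that("lambda at 0 equals the diagonal-covariance normal likelihood", {
  tree <- simulate_tree(24, 0.4, 0.1, seed = 8)
  y <- simulate_bm(tree, 1, 0, seed = 9)
  fit <- pagel_lambda(y, tree)
  d <- diag(phylo_vcv(tree))
  # profile MLE under a star covariance sigma2 * diag(d)
  w <- 1 / d
  mu <- sum(w * y) / sum(w)
  s2 <- mean((y - mu)^2 / d)
  ll0 <- sum(dnorm(y, mu, sqrt(s2 * d), log = TRUE))
  expect_equal(fit$loglik0, ll0, tolerance = 1e-8)
})

test_that("lambda recovery separates Brownian from shuffled traits", {
  tree <- simulate_tree(64, 0.4, 0.1, seed = 10)
  lam_bm <- vapply(1:20, function(i) {
    pagel_lambda(simulate_bm(tree, 1, 0, seed = 100 + i), tree)$lambda
  }, numeric(1))
  expect_gte(mean(lam_bm), 0.9)
  set.seed(11)
  lam_sh <- vapply(1:20, function(i) {
    y <- simulate_bm(tree, 1, 0, seed = 200 + i)
    pagel_lambda(setNames(sample(y), names(y)), tree)$lambda
  }, numeric(1))
  expect_lte(mean(lam_sh), 0.1)
})

test_that("the toy two-group fixture gives the closed-form F", {
  toy <- data.frame(y = 1:6, g = factor(rep(c("a", "b"), each = 3)))
  fit <- pgls_rrpp(y ~ g, toy, n_perm = 999, seed = 1)
  expect_equal(fit["g", "F"], 13.5)             # SSB = 13.5, SSW/df = 1
  expect_identical(fit["g", "Df"], 1L)
  expect_identical(fit["Residuals", "Df"], 4L)
  expect_equal(fit["g", "SS"], 13.5)
  expect_equal(fit["Residuals", "SS"], 4)
})

test_that("a perfectly collinear covariate saturates its term", {
  d <- data.frame(y = 1:10 * 2 + 3, x = 1:10)
  fit <- pgls_rrpp(y ~ x, d, n_perm = 99, seed = 1)
  expect_gt(fit["x", "Rsq"], 1 - 1e-9)
  expect_lt(fit["Residuals", "SS"], 1e-16)
})

test_that("ANOVA bookkeeping identities hold on phylogenetic fits", {
  co <- make_cohort(small_cohort_config(seed = 31L))
  for (fm in list(pSV ~ substratum + logSL + XS + family,
                  logSL ~ substratum + XS + pSV + family,
                  XS ~ substratum + logSL + pSV + family)) {
    fit <- pgls_rrpp(fm, co$traits, phy = co$tree, n_perm = 199, seed = 5)
    k <- nrow(fit) - 2L
    expect_identical(sum(fit$Df[1:(k + 1)]), fit$Df[k + 2])
    expect_identical(fit$Df[k + 2], nrow(co$traits) - 1L)
    expect_equal(sum(fit$SS[1:(k + 1)]), fit$SS[k + 2], tolerance = 1e-10)
    expect_equal(sum(fit$Rsq[1:(k + 1)]), 1, tolerance = 1e-10)
    expect_true(all(fit$p[1:k] >= 1 / 200 & fit$p[1:k] <= 1))
  }
})

test_that("permutation p never reaches zero and fits are seed-reproducible", {
  set.seed(12)
  d <- data.frame(y = c(rnorm(10), rnorm(10) + 50),
                  g = factor(rep(c("a", "b"), each = 10)))
  fit <- pgls_rrpp(y ~ g, d, n_perm = 999, seed = 3)
  expect_equal(fit["g", "p"], 1 / 1000)   # floor, not zero
  fit2 <- pgls_rrpp(y ~ g, d, n_perm = 999, seed = 3)
  expect_identical(as.data.frame(fit), as.data.frame(fit2))
  fit3 <- pgls_rrpp(y ~ g, d, n_perm = 999, seed = 4)
  expect_false(identical(fit["g", "Z"], fit3["g", "Z"]))
})

test_that("RRPP p approaches the parametric ANOVA p with identity covariance", {
  set.seed(14)
  d <- data.frame(g = factor(rep(letters[1:3], each = 10)))
  d$y <- rnorm(30) + c(0, 0.9, 0.4)[as.integer(d$g)]
  fit <- suppressWarnings(pgls_rrpp(y ~ g, d, n_perm = 9999, seed = 15))
  p_param <- anova(lm(y ~ g, d))[["Pr(>F)"]][1]
  expect_equal(fit["g", "p"], p_param, tolerance = 0.02)
})

test_that("tip/data mismatches are hard errors naming the taxa", {
  co <- make_cohort(small_cohort_config(seed = 41L))
  traits <- co$traits[-3, ]          # drop one taxon from the table
  expect_error(pgls_rrpp(pSV ~ family, traits, phy = co$tree),
               co$traits$taxon[3])
})

test_that("pearson_r reproduces closed-form correlations", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_r(x, 2 * x + 1), 1)
  expect_equal(pearson_r(x, -x), -1)
  expect_equal(pearson_r(x, c(1, 3, 2, 4)), 0.8)
  expect_error(pearson_r(x, rep(1, 4)), "constant")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  m <- pearson_matrix(data.frame(pSV = x, logSL = 2 * x + 1,
                                 XS = c(1, 3, 2, 4)))
  expect_equal(m["pSV", "logSL"], 1)
  expect_equal(m["pSV", "XS"], 0.8)
  expect_equal(m, t(m))
})
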