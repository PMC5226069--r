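test_that("degenerate atlases behave (zero variance, rank one)", {
  v <- shapeVector(theTemplate())
  X <- rbind(v, v, v, v)
  expect_warning(a <- buildAtlas(X, K = 10), "rank")
  expect_lt(max(a@eigenvalues), 1e-10)
  expect_equal(a@mean, unname(v))

  v2 <- v + rnorm(length(v))
  X2 <- rbind(v, v2, v, v2)
  expect_warning(a2 <- buildAtlas(X2, K = 10), "rank")
  expect_equal(a2@K, 1L)
  expect_equal(explainedVariance(a2, 1), 1.0)
  expect_error(buildAtlas(X[1:2, ]), "at least 3")
})

test_that("eigenvalues match a brute-force covariance eigendecomposition", {
  sim <- simulateDilationCohort(10, 0, seed = 31, fullWorld = TRUE)
  a <- buildAtlas(sim$X, K = 10)
  # independent oracle: full eigendecomposition of the sample covariance
  ev <- eigen(stats::cov(sim$X), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(a@eigenvalues, ev[1:10], tolerance = 1e-6)
  expect_equal(explainedVariance(a, 10),
               sum(ev[1:10]) / sum(pmax(ev, 0)), tolerance = 1e-9)
  # monotone non-decreasing explained variance
  evk <- vapply(1:10, function(k) explainedVariance(a, k), numeric(1))
  expect_true(all(diff(evk) >= 0))
  expect_error(explainedVariance(a, 0), "between")
  expect_error(explainedVariance(a, 11), "between")
})

test_that("projection and reconstruction are exact inverses on the modes", {
  sim <- simulateDilationCohort(8, 0, seed = 32)
  a <- buildAtlas(sim$X, K = 10)
  # typed invariants
  expect_lt(max(abs(crossprod(a@modes) - diag(a@K))), 1e-8)
  expect_lt(max(abs(colMeans(a@scores))), 1e-8)
  expect_true(all(diff(a@eigenvalues) <= 1e-8))

  expect_equal(projectShape(a, a@mean), rep(0, a@K))
  s1 <- sqrt(a@eigenvalues[1])
  shape <- a@mean + 2 * s1 * a@modes[, 1]
  pr <- projectShape(a, shape)
  expect_equal(pr[1], 2 * s1, tolerance = 1e-9)
  expect_lt(max(abs(pr[-1])), 1e-8)
  # stored training scores are reproduced by projection
  expect_equal(a@scores[3, ], projectShape(a, sim$X[3, ]), tolerance = 1e-8)
  # the (mode, k_sd) form uses score = k_sd * sqrt(lambda)
  rec <- reconstructShape(a, mode = 1, k_sd = 3)
  expect_equal(projectShape(a, rec)[1], 3 * s1, tolerance = 1e-8)
  expect_equal(reconstructShape(a, numeric(a@K)), unname(a@mean))
  expect_warning(reconstructShape(a, mode = 1, k_sd = 6), "extrapolating")
  expect_error(projectShape(a, 1:5), "length")
})

test_that("reconstruction error decreases monotonically with more modes", {
  sim <- simulateDilationCohort(8, 0, seed = 33, fullWorld = TRUE)
  a <- buildAtlas(sim$X, K = 10)
  x <- sim$X[5, ]
  sc <- projectShape(a, x)
  errs <- vapply(1:10, function(k) {
    sqrt(mean((reconstructShape(a, sc[1:k]) - x)^2))
  }, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("full-rank reconstruction reproduces training shapes", {
  sim <- simulateDilationCohort(4, 0, seed = 34)
  X <- sim$X
  a <- buildAtlas(X, K = nrow(X) - 1)
  for (i in c(1, 8)) {
    rec <- reconstructShape(a, projectShape(a, X[i, ]))
    expect_lt(max(abs(rec - X[i, ])), 1e-8)
  }
})

test_that("mode comparison reduces to the squared t-test for two groups", {
  sim <- simulateDilationCohort(12, 0.8, seed = 35)
  a <- buildAtlas(sim$X, K = 10)
  cmp <- compareModes(a, sim$groups)
  expect_equal(cmp$p_adj, pmin(1, cmp$p * 10))
  expect_identical(cmp$significant, cmp$p_adj < 0.05)
  for (k in c(1, 5)) {
    tt <- t.test(a@scores[sim$groups == "MBT", k],
                 a@scores[sim$groups == "RVPA", k], var.equal = TRUE)
    expect_equal(cmp$F[k], unname(tt$statistic)^2, tolerance = 1e-9)
  }
  expect_error(compareModes(a, rep("A", nrow(sim$X))), "two groups")
})

test_that("zero-variance groups fall back to a seeded permutation test", {
  scores <- cbind(c(rep(0, 5), rep(1, 5)), rnorm(10))
  g <- rep(c("A", "B"), each = 5)
  cmp <- compareModes(scores, g)
  expect_lt(cmp$p[1], 0.02)           # completely separated
  cmp2 <- compareModes(scores, g)
  expect_identical(cmp$p, cmp2$p)     # seeded, reproducible
})

test_that("an injected dilation effect is recovered as one interpretable mode", {
  sim <- simulateDilationCohort(40, 1.2, seed = 36)
  a <- buildAtlas(sim$X, K = 10)
  cmp <- compareModes(a, sim$groups)
  sig <- which(cmp$significant)
  expect_length(sig, 1)
  expect_gt(abs(cor(a@scores[, sig], sim$dilation)), 0.9)
})

test_that("pose is removed upstream of the atlas, not by the PCA", {
  sim <- simulateDilationCohort(10, 0, seed = 37)
  tm <- theTemplate()
  set.seed(99)
  Xp <- t(apply(sim$X, 1, function(v) {
    m <- unflattenShape(v, tm)
    th <- runif(1, -pi, pi)
    R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
    shapeVector(standardizeMeshPose(applyRigid(m, R, rnorm(3, 0, 10))))
  }))
  X0 <- t(apply(sim$X, 1, function(v)
    shapeVector(standardizeMeshPose(unflattenShape(v, tm)))))
  a0 <- buildAtlas(X0, K = 5)
  ap <- buildAtlas(Xp, K = 5)
  expect_equal(ap@eigenvalues, a0@eigenvalues, tolerance = 0.05)
})
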