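# Negative binomial log-likelihood used as the independent logistic oracle.
negLogLik <- function(beta, X, y) {
  eta <- drop(cbind(1, X) %*% beta)
  -sum(y * eta - log1p(exp(eta)))
}

test_that("column centering matches hand computations and is idempotent", {
  cc <- centerColumns(rbind(c(1, 3), c(3, 5)))
  expect_equal(cc$Y, rbind(c(-1, -1), c(1, 1)))
  expect_equal(cc$means, c(2, 4))

  cc2 <- centerColumns(rbind(c(1, 0), c(2, 3), c(3, 3)))
  expect_equal(cc2$means, c(2, 2))
  expect_equal(cc2$Y, rbind(c(-1, -2), c(0, 1), c(1, 1)))

  again <- centerColumns(cc2$Y)
  expect_equal(again$Y, cc2$Y)
  expect_equal(again$means, c(0, 0))

  expect_error(centerColumns(matrix(1:3, 1)), "two spectra")
})

test_that("PCA solves the rank-one hand example", {
  Y <- rbind(c(1, 1), c(-1, -1), c(2, 2), c(-2, -2))
  pca <- fitPCA(Y)
  # only one non-degenerate direction: (1, 1) / sqrt(2), eigenvalue 20/3
  expect_equal(ncol(pca@rotation), 1L)
  expect_equal(pca@rotation[, 1], rep(1 / sqrt(2), 2))
  expect_equal(pca@sdev[1]^2, 20 / 3)
  expect_equal(propVariance(pca), 1)

  expect_error(fitPCA(matrix(1, 5, 3)), "degenerate")
})

test_that("PCA agrees with independent eigendecompositions", {
  set.seed(33)
  for (rep in 1:5) {
    X <- matrix(rnorm(20 * 8), 20, 8)
    pca <- fitPCA(X)
    Y <- scale(X, scale = FALSE)
    ev <- eigen(crossprod(Y) / 19, symmetric = TRUE)
    expect_equal(pca@sdev^2, ev$values[seq_along(pca@sdev)],
                 tolerance = 1e-8)
    for (j in seq_len(ncol(pca@rotation)))     # directions up to sign
      expect_equal(abs(sum(pca@rotation[, j] * ev$vectors[, j])), 1,
                   tolerance = 1e-8)
    pr <- prcomp(X)
    expect_equal(pca@sdev, pr$sdev[seq_along(pca@sdev)], tolerance = 1e-10)
    expect_equal(sum(propVariance(pca)), 1)
  }
})

test_that("an isotropic cloud yields two equal eigenvalues", {
  set.seed(4)
  pca <- fitPCA(matrix(rnorm(2e4), 1e4, 2))
  expect_equal(pca@sdev[1] / pca@sdev[2], 1, tolerance = 0.05)
})

test_that("all scores reconstruct the centered matrix", {
  set.seed(5)
  X <- matrix(rnorm(15 * 6), 15, 6)
  pca <- fitPCA(X)
  z <- projectSpectra(pca, X)
  expect_equal(z %*% t(pca@rotation), centerColumns(X)$Y,
               tolerance = 1e-9)
  expect_equal(unname(colMeans(z)), rep(0, ncol(z)), tolerance = 1e-12)
})

test_that("projection centers new data with the training means", {
  set.seed(6)
  X <- matrix(rnorm(30 * 5), 30, 5)
  pca <- fitPCA(X)
  expect_equal(projectSpectra(pca, X), projectSpectra(pca, X))
  expect_equal(drop(projectSpectra(pca, pca@center)),
               rep(0, ncol(pca@rotation)))

  toy <- methods::new("SpectralPCA",
                      rotation = matrix(c(1, 1) / sqrt(2), 2, 1),
                      sdev = 1, center = c(0, 0), totalVariance = 1)
  expect_equal(drop(projectSpectra(toy, c(3, 1))), 2 * sqrt(2))

  expect_error(projectSpectra(pca, matrix(0, 2, 4)), "channel count")
  expect_error(projectSpectra(pca, X, m = 99), "between 1")
})

test_that("logistic fit matches closed forms and an independent optimizer", {
  # intercept-only, balanced labels: beta0 = 0, probability one half
  fit0 <- fitLogistic(matrix(numeric(0), 20, 0), rep(c(0, 1), 10))
  expect_equal(fit0$beta, 0, tolerance = 1e-8)

  # 2x2 table: slope equals the log odds ratio log(30*30 / (10*10))
  z <- c(rep(1, 40), rep(0, 40))
  y <- c(rep(1, 30), rep(0, 10), rep(1, 10), rep(0, 30))
  fit <- fitLogistic(matrix(z), y)
  expect_equal(fit$beta[2], log(9), tolerance = 1e-6)
  expect_equal(fit$beta[1], log(10 / 30), tolerance = 1e-6)

  # generic convex optimization of the same likelihood as the oracle
  set.seed(8)
  Z <- matrix(rnorm(160), 80, 2)
  yy <- rbinom(80, 1, plogis(0.5 + Z %*% c(1, -0.7)))
  fit2 <- fitLogistic(Z, yy)
  orc <- optim(c(0, 0, 0), negLogLik, X = Z, y = yy, method = "BFGS",
               control = list(reltol = 1e-14), hessian = TRUE)
  expect_equal(fit2$beta, orc$par, tolerance = 1e-4)
  expect_equal(fit2$se, sqrt(diag(solve(orc$hessian))), tolerance = 1e-4)
  expect_true(fit2$converged)
  expect_false(fit2$separation)

  expect_error(fitLogistic(Z, rep(1, 80)), "both classes")
})

test_that("independent labels give slopes within two standard errors of 0", {
  set.seed(9)
  Z <- matrix(rnorm(4000), 2000, 2)
  y <- rbinom(2000, 1, 0.5)
  fit <- fitLogistic(Z, y)
  expect_true(all(abs(fit$beta[-1]) <= 2 * fit$se[-1]))
})

test_that("complete separation is flagged, not raised", {
  z <- c(-(5:1), 1:5)
  y <- rep(c(0, 1), each = 5)
  fit <- fitLogistic(matrix(z), y)
  expect_true(fit$separation)
})

test_that("component selection follows the fixed and cumulative rules", {
  props <- c(0.78068, 0.15684, 0.02203, 0.00994, 0.00724, 0.00483,
             0.00314, 0.00238)
  expect_equal(selectComponents(props, rule = "cumulative",
                                threshold = 0.95), 3L)
  expect_equal(selectComponents(props, rule = "cumulative",
                                threshold = 0.969), 4L)
  expect_equal(selectComponents(props, rule = "fixed", m = 4), 4L)
  expect_error(selectComponents(props, rule = "cumulative", threshold = 1.2),
               "threshold")
  expect_error(selectComponents(props, rule = "cumulative",
                                threshold = 0.999), "never reaches")

  set.seed(10)
  pca <- fitPCA(matrix(rnorm(200), 20, 10))
  m <- selectComponents(pca, rule = "cumulative", threshold = 0.5)
  expect_gte(sum(propVariance(pca)[seq_len(m)]), 0.5)
  if (m > 1)
    expect_lt(sum(propVariance(pca)[seq_len(m - 1L)]), 0.5)
})

test_that("local classification thresholds inclusively at lambda", {
  toy <- methods::new("SpectralPCA", rotation = matrix(1), sdev = 1,
                      center = 0, totalVariance = 1)
  mkModel <- function(lambda)
    methods::new("LocalModel", pca = toy, m = 1L, beta = c(0, 0),
                 se = c(1, 1), lambda = lambda, converged = TRUE,
                 separation = FALSE)
  x <- matrix(0.3)                       # fitted probability exactly 0.5
  expect_equal(predictLocal(mkModel(0.5), x), 0.5)
  expect_equal(classifyLocal(mkModel(0.5), x), 1L)   # boundary inclusive
  expect_equal(classifyLocal(mkModel(0.46), x), 1L)
  expect_equal(classifyLocal(mkModel(0.51), x), 0L)
  expect_equal(classifyLocal(mkModel(0), x), 1L)     # lambda 0: always 1
  expect_equal(classifyLocal(mkModel(1), x), 0L)     # prob < 1 at lambda 1
  expect_error(classifyLocal(mkModel(0.5), x, lambda = 1.5), "lambda")
})

test_that("the fitted local model separates a strong synthetic effect", {
  s <- simulateSpectra(cleanConfig(p = 150, nPerClass = 40, seed = 14))
  model <- fitLocalModel(s, m = 4, lambda = 0.5)
  pred <- classifyLocal(model, s)
  expect_gt(mean(pred == spectraLabels(s)), 0.95)
  expect_length(model@beta, 5L)
})
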