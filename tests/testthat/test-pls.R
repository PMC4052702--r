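test_that("autoscale centers, scales, drops constant probes and centers y", {
  m <- rbind(P1 = c(1, 2, 3, 4), P2 = c(5, 5, 5, 5), P3 = c(2, 0, 4, 1))
  colnames(m) <- paste0("S", 1:4)
  sc <- autoscale(tinySe(m, c(1, 1, 0, 0)))
  expect_identical(colnames(sc$X), c("P1", "P3"))
  expect_equal(unname(colMeans(sc$X)), c(0, 0))
  expect_equal(unname(apply(sc$X, 2, sd)), c(1, 1))
  expect_identical(sc$preprocessing$droppedProbes, "P2")
  expect_equal(sc$y, c(0.5, 0.5, -0.5, -0.5))

  const <- matrix(3, 2, 4, dimnames = list(c("P1", "P2"), paste0("S", 1:4)))
  expect_error(autoscale(tinySe(const, c(1, 1, 0, 0))), "zero variance")
})

test_that("first NIPALS weight is the normalized X^T y direction", {
  set.seed(5)
  for (rep in 1:5) {
    X <- scale(matrix(rnorm(8 * 6), 8, 6))
    y <- c(rep(0.5, 4), rep(-0.5, 4))
    fit <- nipalsPls(X, y, nComponents = 1)
    w1 <- drop(crossprod(X, y)); w1 <- w1 / sqrt(sum(w1^2))
    expect_equal(unname(plsWeights(fit)[, 1]), unname(w1), tolerance = 1e-12)
  }
})

test_that("two identical separating columns share weight and exhaust y", {
  X <- cbind(a = c(-1, -1, 1, 1), b = c(-1, -1, 1, 1))
  y <- c(-0.5, -0.5, 0.5, 0.5)
  expect_warning(fit <- nipalsPls(X, y, nComponents = 2), "early stop")
  expect_equal(nComponents(fit), 1L)
  expect_equal(unname(plsWeights(fit)[, 1]), c(1, 1) / sqrt(2))
  expect_equal(unname(fittedY(fit)), y, tolerance = 1e-12)  # one component exhausts y
})

test_that("NIPALS agrees with the plain-loop PLS1 reference on random instances", {
  set.seed(19)
  for (rep in 1:8) {
    n <- sample(4:10, 1); p <- sample(2:10, 1)
    A <- sample(seq_len(min(n - 1, p, 3)), 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- rnorm(n); y <- y - mean(y)
    fit <- nipalsPls(X, y, nComponents = A)
    ref <- refPls1(X, y, A)
    expect_equal(unname(plsWeights(fit)), ref$W, tolerance = 1e-8)
    expect_equal(unname(plsScores(fit)), ref$T, tolerance = 1e-8)
    expect_equal(unname(fittedY(fit)), ref$yhat, tolerance = 1e-8)
    expect_equal(unname(vip(fit)), ref$vip, tolerance = 1e-8)
  }
})

test_that("deflation conserves the response sum of squares", {
  set.seed(23)
  for (rep in 1:6) {
    n <- 12; p <- 30
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- rnorm(n); y <- y - mean(y)
    A <- sample(1:3, 1)
    fit <- nipalsPls(X, y, nComponents = A)
    resid <- y - unname(fittedY(fit))
    expect_equal(sum(y^2), sum(explainedSSY(fit)) + sum(resid^2),
                 tolerance = 1e-8 * sum(y^2))
  }
})

test_that("requested components beyond min(n-1, p) are an error", {
  X <- scale(matrix(rnorm(5 * 3), 5, 3))
  y <- c(1, 1, 0, 0, 0) - 0.4
  expect_error(nipalsPls(X, y, nComponents = 5), "min\\(n - 1, p\\)")
})

test_that("VIP matches hand-evaluated closed forms", {
  mkModel <- function(W, ssy) {
    p <- nrow(W); A <- ncol(W)
    new("PLSModel", weights = W, scores = diag(4)[, seq_len(A), drop = FALSE],
        xLoadings = matrix(0, p, A), yLoadings = rep(1, A), ssy = ssy,
        ssyTotal = sum(ssy) + 1, probeIds = paste0("P", seq_len(p)),
        sampleIds = paste0("S", 1:4), preprocessing = list(), tol = 1e-12)
  }
  # equal weights: every VIP is 1
  m1 <- mkModel(matrix(c(1, 1) / sqrt(2), 2, 1), ssy = 2)
  expect_equal(unname(vip(m1)), c(1, 1))
  # all weight on one probe: sqrt(2), 0
  m2 <- mkModel(matrix(c(1, 0), 2, 1), ssy = 2)
  expect_equal(unname(vip(m2)), c(sqrt(2), 0))
  # two components, identity weights, SSY (3, 1)
  m3 <- mkModel(diag(2), ssy = c(3, 1))
  expect_equal(unname(vip(m3)), c(sqrt(1.5), sqrt(0.5)))
  # zero explained variance is an error
  m4 <- mkModel(matrix(c(1, 0), 2, 1), ssy = 0)
  expect_error(vip(m4), "no response variance")
})

test_that("VIP normalization identity holds on fitted models", {
  set.seed(31)
  for (rep in 1:10) {
    n <- sample(6:20, 1); p <- sample(3:80, 1)
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- rnorm(n); y <- y - mean(y)
    fit <- nipalsPls(X, y, nComponents = min(3, n - 1, p))
    v <- vip(fit)
    expect_equal(sum(v^2), p, tolerance = 1e-6 * p)
  }
})

test_that("one-component VIP ranking equals the |corr(x, y)| ranking", {
  set.seed(37)
  for (rep in 1:5) {
    n <- 15; p <- 40
    X <- scale(matrix(rnorm(n * p), n, p))
    y <- sample(c(rep(1, 8), rep(0, 7))); y <- y - mean(y)
    fit <- nipalsPls(X, y, nComponents = 1)
    expect_identical(order(vip(fit)), order(abs(cor(X, y))[, 1]))
  }
})

test_that("sample scores export the latent coordinates", {
  sim <- simulateExpression(syntheticConfig(nProbes = 100, nDe = 20, hubTargetDegrees = numeric(0),
                                            effectSize = 3, seed = 41))
  sc <- autoscale(sim$se)
  fit <- nipalsPls(sc$X, sc$y, nComponents = 3, preprocessing = sc$preprocessing)
  tab <- sampleScores(fit, status = sim$labels$status)
  expect_identical(colnames(tab), c("sample_id", "class", "t1", "t2", "t3"))
  # strong planted effect: classes split perfectly on the sign of t1
  splitSign <- sign(tab$t1[tab$class == 1])
  expect_true(length(unique(splitSign)) == 1)
  expect_true(all(sign(tab$t1[tab$class == 0]) == -splitSign[1]))

  fit1 <- nipalsPls(sc$X, sc$y, nComponents = 1)
  tab1 <- sampleScores(fit1)
  expect_identical(colnames(tab1), c("sample_id", "t1"))
  expect_equal(tab1$t1, unname(drop(sc$X %*% plsWeights(fit1)[, 1])))
})

test_that("fit agrees with an established PLS implementation", {
  skip_if_not_installed("mixOmics")
  sim <- simulateExpression(syntheticConfig(nProbes = 150, seed = 43))
  sc <- autoscale(sim$se)
  fit <- nipalsPls(sc$X, sc$y, nComponents = 3)
  ref <- mixOmics::pls(sc$X, sc$y, ncomp = 3, scale = FALSE, mode = "regression")
  expect_equal(unname(vip(fit)), unname(mixOmics::vip(ref)[, 3]), tolerance = 1e-8)
  for (a in 1:3)
    expect_equal(abs(cor(plsScores(fit)[, a], ref$variates$X[, a])), 1,
                 tolerance = 1e-8)
})
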