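test_that("permutation null is reproducible and satisfies the VIP identity per row", {
  sim <- simulateExpression(syntheticConfig(nProbes = 60, nDe = 6, hubTargetDegrees = numeric(0), seed = 47))
  sc <- autoscale(sim$se)
  n1 <- permutationNull(sc$X, sc$y, nComponents = 2, nPermutations = 25, seed = 9)
  n2 <- permutationNull(sc$X, sc$y, nComponents = 2, nPermutations = 25, seed = 9)
  expect_identical(n1@nullVip, n2@nullVip)
  p <- ncol(n1@nullVip)
  expect_true(all(abs(rowSums(n1@nullVip^2) - p) <= 1e-6 * p))
  n3 <- permutationNull(sc$X, sc$y, nComponents = 2, nPermutations = 25, seed = 10)
  expect_false(identical(n1@nullVip, n3@nullVip))
})

test_that("empirical FDR reproduces hand-counted tail ratios", {
  obs <- c(A = 3, B = 2, C = 1)
  null <- matrix(c(0.5, 0.6, 2.5), 1, 3, dimnames = list(NULL, c("A", "B", "C")))
  raw <- empiricalFdr(obs, null, monotonize = FALSE)
  expect_equal(unname(raw), c(0, 1/2, 1/3))
  # monotonized: each probe takes the min raw over smaller-or-equal VIPs
  mono <- empiricalFdr(obs, null)
  expect_equal(unname(mono), c(0, 1/3, 1/3))
})

test_that("degenerate nulls: self-null gives FDR 1, sub-minimal null gives 0", {
  obs <- c(P1 = 2.2, P2 = 1.4, P3 = 0.7)
  self <- matrix(obs, 1, 3, dimnames = list(NULL, names(obs)))
  expect_equal(unname(empiricalFdr(obs, self)), c(1, 1, 1))
  below <- matrix(c(0.1, 0.3, 0.6), 1, 3, dimnames = list(NULL, names(obs)))
  expect_equal(unname(empiricalFdr(obs, below)), c(0, 0, 0))
  expect_error(empiricalFdr(obs[1:2], below), "probe-axis mismatch")
})

test_that("FDR is monotone in VIP, bounded in [0,1], and ties share a value", {
  set.seed(53)
  obs <- c(round(runif(30, 0, 4), 1), 2.0, 2.0)  # forced tie
  names(obs) <- paste0("P", seq_along(obs))
  nv <- matrix(abs(rnorm(20 * length(obs))), 20, length(obs))
  nv <- nv / sqrt(rowSums(nv^2)) * sqrt(length(obs))
  colnames(nv) <- names(obs)
  null <- new("PermutationNull", nullVip = nv, seed = 1L, nDegenerate = 0L)
  expect_true(validObject(null))
  fdr <- empiricalFdr(obs, null)
  expect_true(all(fdr >= 0 & fdr <= 1))
  ord <- order(obs, decreasing = TRUE)
  expect_true(all(diff(fdr[ord]) >= 0))
  tied <- names(obs)[obs == 2.0]
  expect_equal(length(unique(fdr[tied])), 1L)
})

test_that("pooled-null empirical p-values are uniform under the global null", {
  sim <- simulateExpression(syntheticConfig(nPatients = 10, nControls = 10,
                                            nProbes = 300, nDe = 0, seed = 59))
  sc <- autoscale(sim$se)
  fit <- nipalsPls(sc$X, sc$y, nComponents = 3, preprocessing = sc$preprocessing)
  v <- vip(fit)
  nul <- permutationNull(sc$X, sc$y, nComponents = 3, nPermutations = 200, seed = 59)
  pooled <- sort(as.numeric(nul@nullVip))
  pvals <- (length(pooled) - findInterval(v, pooled, left.open = TRUE) + 1) /
    (length(pooled) + 1)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("direction comes from group means with ties labeled down", {
  m <- rbind(P1 = c(8, 8, 6, 6), P2 = c(5, 5, 7, 7), P3 = c(4, 4, 4, 4))
  colnames(m) <- paste0("S", 1:4)
  expect_warning(d <- probeDirection(m, status = c(1, 1, 0, 0)), "equal group means")
  expect_identical(unname(d), c("up", "down", "down"))
})

test_that("planted shift signs are recovered at the study design", {
  sim <- simulateExpression(syntheticConfig(seed = 61))  # 23 vs 11, |shift| 1, sigma 0.5
  d <- probeDirection(sim$se)
  truth <- sim$truth$deProbes
  expect_identical(unname(d[truth$probe_id]), truth$sign)
})

test_that("selection is strict at the threshold and reports the up/down split", {
  obs <- c(P1 = 3, P2 = 2, P3 = 1)
  fdr <- c(P1 = 0.01, P2 = 0.05, P3 = 0.9)
  dir <- c(P1 = "up", P2 = "down", P3 = "down")
  expect_message(tab <- selectDE(obs, fdr, dir), "selected 1")
  expect_identical(tab$probe_id, c("P1", "P2", "P3"))     # sorted by VIP desc
  expect_identical(tab$selected, c(TRUE, FALSE, FALSE))   # 0.05 is NOT < 0.05
  allOne <- setNames(rep(1, 3), names(obs))
  tabEmpty <- suppressMessages(selectDE(obs, allOne, dir))
  expect_equal(sum(tabEmpty$selected), 0L)
  expect_error(selectDE(obs, fdr, dir, threshold = 0), "threshold")
})

test_that("probe relabeling permutes the analysis outputs identically", {
  sim <- simulateExpression(syntheticConfig(nProbes = 80, nDe = 8, hubTargetDegrees = numeric(0), seed = 67))
  res1 <- suppressMessages(plsSignificance(sim$se, nPermutations = 40, seed = 5))
  perm <- sample(nrow(sim$se))
  res2 <- suppressMessages(plsSignificance(sim$se[perm, ], nPermutations = 40, seed = 5))
  t1 <- as.data.frame(res1$table); rownames(t1) <- t1$probe_id
  t2 <- as.data.frame(res2$table); rownames(t2) <- t2$probe_id
  expect_equal(t2[t1$probe_id, c("vip", "fdr", "direction", "selected")],
               t1[, c("vip", "fdr", "direction", "selected")])
})

test_that("permutation selection keeps false-discovery control where t-tests are swamped by a class-correlated array factor", {
  # A hidden factor correlated with disease status inflates per-probe
  # t-statistics genome-wide; the label-permutation null absorbs the factor,
  # so VIP selection stays conservative while t + BH does not.
  for (s in 1:3) {
    cfg <- syntheticConfig(confounderSd = 1, confounderClassCorrelated = TRUE, seed = s)
    sim <- simulateExpression(cfg)
    de <- sim$truth$deProbes$probe_id
    res <- suppressMessages(plsSignificance(sim$se, nPermutations = 200, seed = s))
    sel <- res$table$probe_id[res$table$selected]
    m <- SummarizedExperiment::assay(sim$se)
    st <- SummarizedExperiment::colData(sim$se)$status
    pt <- apply(m, 1, function(x) t.test(x[st == 1], x[st == 0])$p.value)
    selT <- names(pt)[p.adjust(pt, "BH") < 0.05]
    fdp <- function(sl) if (length(sl)) length(setdiff(sl, de)) / length(sl) else 0
    expect_lte(fdp(sel), fdp(selT))
    expect_lte(fdp(sel), 0.05)
  }
})
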