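#' Autoscale an expression matrix and center the class response
#'
#' Transposes the probes x samples matrix to the samples x probes design
#' matrix X, centers every probe column and (by default) scales it to unit
#' variance, and centers the 0/1 class coding. Zero-variance probes cannot
#' be scaled and are excluded, with their identifiers recorded. Autoscaling
#' is the convention under which the VIP normalization identity
#' \eqn{\sum_j VIP_j^2 = p} and the usual VIP > 1 rule of thumb hold.
#'
#' @param se SummarizedExperiment with assay `"exprs"` and integer 0/1
#'   `status` in `colData` (see [alignSamples()]), or a probes x samples
#'   matrix if `status` is given.
#' @param status optional 0/1 vector overriding `colData(se)$status`
#' @param scale scale columns to unit variance (default `TRUE`); centering
#'   is always applied
#' @return list with `X` (n x p scaled design matrix), `y` (centered
#'   response), and `preprocessing` (list: `center`, `scale`,
#'   `droppedProbes`, `yMean`, `scaled`)
#' @export
autoscale <- function(se, status = NULL, scale = TRUE) {
  if (is(se, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(se, "exprs")
    if (is.null(status)) status <- SummarizedExperiment::colData(se)$status
  } else m <- se
  if (is.null(status)) stop("status (0/1 per sample) is required")
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) stop("status must be coded 0/1")
  if (sum(status) < 2L || sum(1L - status) < 2L) stop("each class needs at least 2 samples")
  X <- t(m)                                   # n x p
  ctr <- colMeans(X)
  Xc <- sweep(X, 2L, ctr)
  sdv <- sqrt(colSums(Xc^2) / (nrow(X) - 1L))
  dropped <- colnames(X)[sdv == 0]
  if (length(dropped) == ncol(X)) stop("all probes have zero variance")
  keep <- sdv > 0
  Xc <- Xc[, keep, drop = FALSE]
  scl <- if (scale) sdv[keep] else rep(1, sum(keep))
  Xs <- sweep(Xc, 2L, scl, "/")
  yMean <- mean(status)
  list(
    X = Xs,
    y = status - yMean,
    preprocessing = list(center = ctr[keep], scale = scl,
                         droppedProbes = dropped, yMean = yMean, scaled = scale)
  )
}

#' Fit a single-response PLS model by the NIPALS recursion
#'
#' Extracts up to `nComponents` latent variables from an autoscaled design
#' matrix X (samples x probes) and centered response y. With a single
#' response the NIPALS inner iteration collapses to the closed-form PLS1
#' step: for component a,
#' \deqn{w_a = X_a^T y_a / \|X_a^T y_a\|,\quad t_a = X_a w_a,\quad
#'       p_a = X_a^T t_a / t_a^T t_a,\quad q_a = y_a^T t_a / t_a^T t_a,}
#' followed by deflation \eqn{X_{a+1} = X_a - t_a p_a^T},
#' \eqn{y_{a+1} = y_a - q_a t_a}. The explained response sum of squares per
#' component is \eqn{SSY_a = q_a^2\, t_a^T t_a}.
#'
#' If \eqn{\|X_a^T y_a\|} falls below `tol` (residual response exhausted or
#' rank deficiency), extraction stops early and the model is returned with
#' the components obtained so far, with a warning.
#'
#' @param X n x p autoscaled design matrix (see [autoscale()])
#' @param y centered response vector of length n
#' @param nComponents number of latent variables to extract (default 3);
#'   must not exceed `min(n - 1, p)`
#' @param tol early-stop tolerance on \eqn{\|X_a^T y_a\|} (default 1e-12)
#' @param preprocessing optional preprocessing record to store in the model
#' @return a [PLSModel-class]
#' @examples
#' sim <- simulateExpression(syntheticConfig(nProbes = 60, seed = 7))
#' sc <- autoscale(sim$se)
#' fit <- nipalsPls(sc$X, sc$y, nComponents = 3, preprocessing = sc$preprocessing)
#' fit
#' @export
nipalsPls <- function(X, y, nComponents = 3, tol = 1e-12, preprocessing = list()) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (nComponents < 1) stop("nComponents must be >= 1")
  if (nComponents > min(n - 1L, p))
    stop("nComponents must not exceed min(n - 1, p) = ", min(n - 1L, p))
  probeIds <- colnames(X); if (is.null(probeIds)) probeIds <- paste0("V", seq_len(p))
  sampleIds <- rownames(X); if (is.null(sampleIds)) sampleIds <- paste0("S", seq_len(n))
  W <- matrix(0, p, nComponents); Tm <- matrix(0, n, nComponents)
  P <- matrix(0, p, nComponents); q <- numeric(nComponents); ssy <- numeric(nComponents)
  ssyTotal <- sum(y^2)
  Xa <- X; ya <- y
  A <- 0L
  for (a in seq_len(nComponents)) {
    wraw <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(wraw^2))
    if (nw < tol) {
      warning("early stop at component ", a, ": residual covariance below tolerance; returning ",
              a - 1L, " component(s)")
      break
    }
    w <- wraw / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    pa <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pa)
    ya <- ya - qa * t
    W[, a] <- w; Tm[, a] <- t; P[, a] <- pa; q[a] <- qa; ssy[a] <- qa^2 * tt
    A <- a
  }
  if (A == 0L) stop("no component could be extracted: X^T y is numerically zero")
  idx <- seq_len(A)
  W <- W[, idx, drop = FALSE]
  dimnames(W) <- list(probeIds, paste0("comp", idx))
  new("PLSModel",
      weights = W,
      scores = matrix(Tm[, idx], n, A, dimnames = list(sampleIds, paste0("t", idx))),
      xLoadings = matrix(P[, idx], p, A, dimnames = list(probeIds, paste0("comp", idx))),
      yLoadings = q[idx], ssy = ssy[idx], ssyTotal = ssyTotal,
      probeIds = probeIds, sampleIds = sampleIds,
      preprocessing = preprocessing, tol = tol)
}

#' @rdname nComponents
#' @export
setMethod("nComponents", "PLSModel", function(object) ncol(object@weights))

#' @rdname plsWeights
#' @export
setMethod("plsWeights", "PLSModel", function(object) object@weights)

#' @rdname plsScores
#' @export
setMethod("plsScores", "PLSModel", function(object) object@scores)

#' @rdname plsLoadings
#' @export
setMethod("plsLoadings", "PLSModel", function(object) object@xLoadings)

#' @rdname explainedSSY
#' @export
setMethod("explainedSSY", "PLSModel", function(object) object@ssy)

#' @rdname fittedY
#' @export
setMethod("fittedY", "PLSModel", function(object) {
  drop(object@scores %*% object@yLoadings)
})

#' @describeIn vip VIP from a fitted NIPALS PLS1 model:
#'   \eqn{VIP_j = \sqrt{p \sum_a SSY_a w_{ja}^2 / \sum_a SSY_a}} with
#'   unit-norm weight columns (NIPALS weights `w`, not rotated weights).
#' @export
setMethod("vip", "PLSModel", function(object) {
  s <- object@ssy
  tot <- sum(s)
  if (tot <= 0) stop("model explains no response variance; VIP is undefined")
  p <- nrow(object@weights)
  v <- sqrt(p * drop(object@weights^2 %*% s) / tot)
  names(v) <- object@probeIds
  v
})

#' Export per-sample latent-variable scores
#'
#' The score coordinates place each sample on the selected latent variables;
#' plotted pairwise (colored by class) they give the usual PLS sample
#' classification view.
#'
#' @param model a fitted [PLSModel-class]
#' @param status optional 0/1 class vector to include as a `class` column
#' @return data.frame with `sample_id`, optional `class`, and one column
#'   per latent variable `t1..tA`
#' @export
sampleScores <- function(model, status = NULL) {
  stopifnot(is(model, "PLSModel"))
  df <- data.frame(sample_id = model@sampleIds, stringsAsFactors = FALSE)
  if (!is.null(status)) df$class <- as.integer(status)
  cbind(df, as.data.frame(model@scores))
}

setMethod("show", "PLSModel", function(object) {
  A <- nComponents(object)
  cat("PLSModel (single-response NIPALS)\n")
  cat("  probes:", length(object@probeIds), " samples:", length(object@sampleIds),
      " components:", A, "\n")
  expl <- if (object@ssyTotal > 0) sum(object@ssy) / object@ssyTotal else NA_real_
  cat(sprintf("  explained y-variance: %.1f%% (per component: %s)\n",
              100 * expl, paste(sprintf("%.1f%%", 100 * object@ssy / object@ssyTotal),
                                collapse = ", ")))
  if (length(object@preprocessing))
    cat("  preprocessing: centered",
        if (isTRUE(object@preprocessing$scaled)) "+ unit-variance scaled", "\n")
})

setMethod("show", "PermutationNull", function(object) {
  cat("PermutationNull\n")
  cat("  permutations:", nrow(object@nullVip), " probes:", ncol(object@nullVip),
      " seed:", object@seed, "\n")
  if (object@nDegenerate > 0L)
    cat("  degenerate permutations (all-zero VIP rows):", object@nDegenerate, "\n")
})
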