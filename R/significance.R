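#' Empirical VIP null distribution by label permutation
#'
#' For each permutation the class labels are shuffled uniformly at random
#' (preserving class sizes), the shuffled 0/1 coding is re-centered, and the
#' full PLS + VIP pipeline is recomputed on the unchanged scaled matrix X.
#' X's autoscaling is not recomputed: it is independent of y, so only the
#' response changes under the null. A permutation whose fit explains no
#' response variance is recorded as an all-zero VIP row (conservative) and
#' counted.
#'
#' @param X n x p autoscaled design matrix (see [autoscale()])
#' @param y centered response (only its 0/1 pattern matters; permutations
#'   shuffle the underlying class coding)
#' @param nComponents latent variables per refit (all components are refit
#'   in every permutation; default 3)
#' @param nPermutations number of label shuffles (default 10000; analyses at
#'   desk scale typically use a few hundred)
#' @param seed integer seed making the permutation stream reproducible
#' @param tol NIPALS early-stop tolerance
#' @return a [PermutationNull-class]
#' @export
permutationNull <- function(X, y, nComponents = 3, nPermutations = 10000,
                            seed = 1, tol = 1e-12) {
  if (nPermutations < 1) stop("nPermutations must be >= 1")
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  set.seed(as.integer(seed))
  nullVip <- matrix(0, nPermutations, p)
  colnames(nullVip) <- colnames(X)
  nDeg <- 0L
  for (b in seq_len(nPermutations)) {
    yp <- y[sample.int(n)]
    yp <- yp - mean(yp)    # re-center (no-op for balanced shuffles, kept for exactness)
    fit <- tryCatch(
      suppressWarnings(nipalsPls(X, yp, nComponents = nComponents, tol = tol)),
      error = function(e) NULL
    )
    if (is.null(fit) || sum(explainedSSY(fit)) <= 0) {
      nDeg <- nDeg + 1L
      next
    }
    nullVip[b, ] <- vip(fit)
  }
  if (nDeg > 0L)
    message(nDeg, " permutation(s) explained no response variance; recorded as all-zero VIP rows")
  new("PermutationNull", nullVip = nullVip, seed = as.integer(seed), nDegenerate = nDeg)
}

#' Pooled empirical FDR for observed VIP scores
#'
#' For probe j with observed VIP \eqn{v_j}, the estimate is
#' \deqn{FDR_j = \min\left(1, \frac{E_{perm}[\#\{k : vip^{null}_k \ge v_j\}]}
#'   {\#\{k : v_k \ge v_j\}}\right),}
#' the expected null tail count (mean over permutations, pooled across the
#' probe axis) divided by the observed tail count, with closed (\eqn{\ge})
#' tail counting so ties are conservative. The raw estimates are then
#' monotonized q-value style — each probe takes the minimum raw estimate
#' over all probes with smaller or equal VIP (the most favorable selection
#' threshold that still includes it) — so that a larger VIP never has a
#' larger FDR.
#'
#' @param observed named numeric vector of observed VIP scores (see [vip()])
#' @param null a [PermutationNull-class] over the same probe axis, or a
#'   permutations x probes matrix of null VIP values
#' @param monotonize apply the q-value-style monotonization (default
#'   `TRUE`); `FALSE` returns the raw tail-ratio estimates
#' @return named numeric vector of FDR values in `[0, 1]`, same order as
#'   `observed`
#' @export
empiricalFdr <- function(observed, null, monotonize = TRUE) {
  nullVip <- if (is(null, "PermutationNull")) null@nullVip else as.matrix(null)
  p <- length(observed)
  if (ncol(nullVip) != p)
    stop("probe-axis mismatch: ", p, " observed vs ", ncol(nullVip), " null columns")
  if (!is.null(names(observed)) && !is.null(colnames(nullVip)) &&
      !identical(names(observed), colnames(nullVip)))
    stop("probe-axis mismatch: observed and null probe identifiers differ")
  nPerm <- nrow(nullVip)
  nullSorted <- sort(as.numeric(nullVip))           # all permutations pooled
  obsSorted <- sort(observed)
  # closed tail counts #{x : x >= v} via positions in the ascending sort
  nullGe <- length(nullSorted) - findInterval(observed, nullSorted, left.open = TRUE)
  obsGe <- p - findInterval(observed, obsSorted, left.open = TRUE)
  raw <- pmin(1, (nullGe / nPerm) / obsGe)
  fdr <- raw
  if (monotonize) {
    # q-value style: min raw over selection thresholds at or below each VIP
    ord <- order(observed)
    fdr[ord] <- cummin(raw[ord])
  }
  names(fdr) <- names(observed)
  fdr
}

#' Per-probe expression direction from group means
#'
#' A probe is "up" (overexpressed in patients) if its mean log2 expression
#' in patients exceeds the control mean, else "down" (depressed). Directions
#' come from the raw log2 group means, not from model loadings. Exact ties
#' are labeled "down" with a warning naming the count.
#'
#' @param se SummarizedExperiment with assay `"exprs"` and 0/1 `status` in
#'   `colData`, or a probes x samples matrix if `status` is given
#' @param status optional 0/1 vector overriding `colData(se)$status`
#' @return named character vector, `"up"` or `"down"` per probe
#' @export
probeDirection <- function(se, status = NULL) {
  if (is(se, "SummarizedExperiment")) {
    m <- SummarizedExperiment::assay(se, "exprs")
    if (is.null(status)) status <- SummarizedExperiment::colData(se)$status
  } else m <- se
  status <- as.integer(status)
  dPat <- rowMeans(m[, status == 1L, drop = FALSE])
  dCtl <- rowMeans(m[, status == 0L, drop = FALSE])
  nTies <- sum(dPat == dCtl)
  if (nTies > 0L)
    warning(nTies, " probe(s) with exactly equal group means labeled 'down'")
  out <- ifelse(dPat > dCtl, "up", "down")
  names(out) <- rownames(m)
  out
}

#' Select differentially expressed probes by empirical FDR
#'
#' A probe is selected when its FDR is strictly below the threshold
#' (a probe with FDR exactly at the threshold is not selected). The table
#' is sorted by VIP descending and the up/down split of the selection is
#' reported via a message, mirroring the usual "total = depressed +
#' overexpressed" summary.
#'
#' @param observed named numeric VIP vector
#' @param fdr named numeric FDR vector from [empiricalFdr()]
#' @param direction named character direction vector from [probeDirection()]
#' @param threshold FDR cutoff, strict (default 0.05)
#' @param geneIds optional named character vector mapping probe id to gene
#'   id; probes absent from it get `NA` gene ids
#' @return a [S4Vectors::DataFrame] with columns `probe_id`, `gene_id`,
#'   `vip`, `fdr`, `direction`, `selected`, sorted by `vip` descending
#' @export
selectDE <- function(observed, fdr, direction, threshold = 0.05, geneIds = NULL) {
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  probes <- names(observed)
  if (!identical(probes, names(fdr)) )
    stop("observed and fdr must share the same probe axis")
  direction <- direction[probes]
  if (anyNA(direction)) stop("direction missing for some probes")
  gid <- if (is.null(geneIds)) probes else unname(geneIds[probes])
  tab <- S4Vectors::DataFrame(
    probe_id = probes,
    gene_id = gid,
    vip = unname(observed),
    fdr = unname(fdr),
    direction = unname(direction),
    selected = unname(fdr < threshold)
  )
  tab <- tab[order(tab$vip, decreasing = TRUE), ]
  rownames(tab) <- NULL
  nSel <- sum(tab$selected)
  nUp <- sum(tab$selected & tab$direction == "up")
  message("selected ", nSel, " probe(s) at FDR < ", threshold,
          " (", nSel - nUp, " down, ", nUp, " up)")
  tab
}

#' One-call PLS-VIP significance analysis
#'
#' Convenience wrapper running autoscaling, the NIPALS fit, VIP scoring,
#' the permutation null, empirical FDR, direction calls and selection on an
#' aligned SummarizedExperiment. Probes dropped as zero-variance during
#' autoscaling are excluded from the result.
#'
#' @param se SummarizedExperiment with assay `"exprs"` and 0/1 `status` in
#'   `colData` (see [alignSamples()])
#' @param nComponents latent variables (default 3)
#' @param nPermutations permutations for the empirical null (default 10000)
#' @param fdrThreshold strict selection cutoff (default 0.05)
#' @param seed permutation seed
#' @param scale autoscale to unit variance (default `TRUE`)
#' @param geneIds optional probe-to-gene named character vector
#' @return list with `table` (the significance DataFrame), `model`
#'   ([PLSModel-class]), `null` ([PermutationNull-class]) and `scores`
#'   (per-sample latent-variable data.frame)
#' @examples
#' sim <- simulateExpression(syntheticConfig(nProbes = 80, nDe = 8, seed = 3))
#' res <- plsSignificance(sim$se, nPermutations = 50, seed = 3)
#' head(as.data.frame(res$table))
#' @export
plsSignificance <- function(se, nComponents = 3, nPermutations = 10000,
                            fdrThreshold = 0.05, seed = 1, scale = TRUE,
                            geneIds = NULL) {
  sc <- autoscale(se, scale = scale)
  model <- nipalsPls(sc$X, sc$y, nComponents = nComponents,
                     preprocessing = sc$preprocessing)
  v <- vip(model)
  nul <- permutationNull(sc$X, sc$y, nComponents = nComponents,
                         nPermutations = nPermutations, seed = seed)
  fdr <- empiricalFdr(v, nul)
  dir <- probeDirection(se)
  tab <- selectDE(v, fdr, dir, threshold = fdrThreshold, geneIds = geneIds)
  list(table = tab, model = model, null = nul,
       scores = sampleScores(model, status = SummarizedExperiment::colData(se)$status))
}
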