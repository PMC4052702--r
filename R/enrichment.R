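#' Upper-tail hypergeometric probability
#'
#' Probability of drawing at least `k` annotated genes when `n` genes are
#' selected without replacement from a universe of `N` genes of which `K`
#' carry the annotation:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(K, n)} \binom{K}{i}\binom{N-K}{n-i}
#'   \big/ \binom{N}{n}.}
#' Computed through [stats::phyper()], which works on log scale internally
#' and is stable for large universes.
#'
#' @param N universe (background) size
#' @param K annotated genes in the universe
#' @param n selected genes
#' @param k annotated genes among the selected
#' @return the upper-tail probability, in `(0, 1]`
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  for (nm in c("N", "K", "n", "k")) {
    v <- get(nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v != round(v))
      stop(nm, " must be a single nonnegative integer")
  }
  if (K > N) stop("bound violated: K <= N required (K = ", K, ", N = ", N, ")")
  if (n > N) stop("bound violated: n <= N required (n = ", n, ", N = ", N, ")")
  if (k > min(K, n)) stop("bound violated: k <= min(K, n) required (k = ", k, ")")
  if (k < max(0, n - (N - K))) stop("bound violated: k >= max(0, n - (N - K)) required")
  if (k == 0) return(1)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Hypergeometric over-representation of selected genes per term
#'
#' Tests each annotation term for over-representation of the selected genes
#' against the background universe. The universe defaults to the background
#' genes that carry at least one annotation (platform-as-universe
#' convention); selected genes outside the universe are dropped with a
#' message stating the count. One result row is produced per term with at
#' least one background gene, including terms with zero selected genes
#' (p = 1). Raw p-values are reported; an optional Benjamini-Hochberg
#' column can be added.
#'
#' @param selectedGenes character vector of selected gene ids
#' @param background character vector of background gene ids (e.g. all
#'   genes on the platform)
#' @param annotation data.frame of flat (gene_id, term_id, term_name,
#'   term_class) pairs (see [readAnnotation()])
#' @param adjust add a `p_adjust` Benjamini-Hochberg column (default
#'   `FALSE`, matching raw-p reporting)
#' @return data.frame with one row per term: `term_id`, `term_name`,
#'   `term_class`, `N`, `K`, `n`, `k`, `p_value` (unsorted)
#' @export
enrichTerms <- function(selectedGenes, background, annotation, adjust = FALSE) {
  selectedGenes <- unique(selectedGenes)
  background <- unique(background)
  if (!all(selectedGenes %in% background))
    stop("selected genes must be a subset of the background")
  annotation <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  universe <- unique(annotation$gene_id)
  N <- length(universe)
  if (N == 0L) stop("no background gene carries an annotation")
  selInU <- intersect(selectedGenes, universe)
  nOut <- length(selectedGenes) - length(selInU)
  if (nOut > 0L)
    message(nOut, " selected gene(s) without annotation dropped from enrichment")
  n <- length(selInU)
  if (n == 0L) {
    out <- data.frame(term_id = character(0), term_name = character(0),
                      term_class = character(0), N = integer(0), K = integer(0),
                      n = integer(0), k = integer(0), p_value = numeric(0))
    return(out)
  }
  byTerm <- split(annotation$gene_id, annotation$term_id)
  meta <- annotation[!duplicated(annotation$term_id), c("term_id", "term_name", "term_class")]
  rownames(meta) <- meta$term_id
  termIds <- names(byTerm)
  K <- vapply(byTerm, length, integer(1))
  k <- vapply(byTerm, function(g) length(intersect(g, selInU)), integer(1))
  p <- vapply(seq_along(termIds),
              function(i) hypergeomUpperTail(N, K[i], n, k[i]), numeric(1))
  out <- data.frame(
    term_id = termIds,
    term_name = meta[termIds, "term_name"],
    term_class = meta[termIds, "term_class"],
    N = N, K = unname(K), n = n, k = unname(k), p_value = p,
    stringsAsFactors = FALSE
  )
  if (adjust) out$p_adjust <- p.adjust(out$p_value, method = "BH")
  rownames(out) <- NULL
  out
}

#' Top enriched terms
#'
#' Ranks enrichment results by ascending p-value, breaking ties by larger
#' overlap `k` and then lexicographic term id, and returns the first `K`.
#'
#' @param results data.frame from [enrichTerms()]
#' @param K number of terms to return (default 10)
#' @return the ranked sublist (all rows if fewer than `K`)
#' @export
topTerms <- function(results, K = 10) {
  if (K < 1) stop("K must be >= 1")
  ord <- order(results$p_value, -results$k, results$term_id)
  out <- results[ord, , drop = FALSE][seq_len(min(K, nrow(results))), , drop = FALSE]
  rownames(out) <- NULL
  out
}
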