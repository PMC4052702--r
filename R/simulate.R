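#' Configuration for the synthetic two-group microarray study
#'
#' Defaults reproduce the study design the package targets: 23 patients vs
#' 11 controls, log2-scale Gaussian expression, 50 planted differential
#' probes of |log2 shift| 1.0 among 1000 (a quarter shifted up, mirroring
#' the usual minority of overexpressed genes), per-probe noise SD 0.5, and
#' an optional array-specific latent confounder (off by default). Synthetic
#' gene ids equal probe ids (a 1:1 probe-to-gene map).
#'
#' @param nPatients patients (class 1); default 23
#' @param nControls controls (class 0); default 11
#' @param nProbes probes on the synthetic platform; default 1000
#' @param nDe planted differential probes; default 50
#' @param effectSize |log2 shift| of planted probes; default 1.0
#' @param fracUp fraction of planted shifts that are positive; default 0.25
#' @param sigma per-probe noise SD (log2); default 0.5
#' @param confounderSd SD of the per-sample latent array factor; 0 disables
#'   (default). Probe loadings on the factor are standard normal.
#' @param confounderClassCorrelated if `TRUE` the latent factor's mean
#'   differs by class (half its SD each way), stressing methods that cannot
#'   absorb hidden structure; default `FALSE` (class-balanced)
#' @param baselineRange range of per-probe baseline means, log2 units;
#'   default `c(6, 12)`
#' @param nTerms annotation terms; default 30
#' @param termBaseRate probability a term annotates any given gene; default 0.1
#' @param enrichedRate fraction of planted DE genes deterministically
#'   included in the designated enriched term; default 0.8
#' @param hubTargetDegrees degrees forced for the planted hub genes inside
#'   the DE-induced subgraph; default `c(20, 12)`; `numeric(0)` plants none
#' @param hubThreshold exclusive degree cutoff the generator guarantees
#'   non-planted DE genes stay at or below; default 10
#' @param seed integer seed; every generator draws from a stream derived
#'   from it (expression: seed, annotation: seed + 1, edges: seed + 2)
#' @return validated configuration list of class `syntheticConfig`
#' @export
syntheticConfig <- function(nPatients = 23, nControls = 11, nProbes = 1000,
                            nDe = 50, effectSize = 1.0, fracUp = 0.25,
                            sigma = 0.5, confounderSd = 0,
                            confounderClassCorrelated = FALSE,
                            baselineRange = c(6, 12),
                            nTerms = 30, termBaseRate = 0.1, enrichedRate = 0.8,
                            hubTargetDegrees = c(20, 12), hubThreshold = 10,
                            seed = 1) {
  cfg <- list(nPatients = nPatients, nControls = nControls, nProbes = nProbes,
              nDe = nDe, effectSize = effectSize, fracUp = fracUp, sigma = sigma,
              confounderSd = confounderSd,
              confounderClassCorrelated = confounderClassCorrelated,
              baselineRange = baselineRange, nTerms = nTerms,
              termBaseRate = termBaseRate, enrichedRate = enrichedRate,
              hubTargetDegrees = hubTargetDegrees, hubThreshold = hubThreshold,
              seed = seed)
  chk <- function(cond, field, what) if (!cond) stop("invalid config field '", field, "': ", what)
  chk(nPatients >= 2 && nControls >= 2, "nPatients/nControls", "at least 2 samples per class")
  chk(nProbes >= 1, "nProbes", "must be positive")
  chk(nDe >= 0 && nDe <= nProbes, "nDe", "must satisfy 0 <= nDe <= nProbes")
  chk(effectSize >= 0, "effectSize", "must be nonnegative")
  chk(fracUp >= 0 && fracUp <= 1, "fracUp", "must be in [0, 1]")
  chk(sigma > 0, "sigma", "must be positive")
  chk(confounderSd >= 0, "confounderSd", "must be nonnegative")
  chk(length(baselineRange) == 2 && baselineRange[1] <= baselineRange[2],
      "baselineRange", "must be an increasing pair")
  chk(nTerms >= 1, "nTerms", "must be positive")
  chk(termBaseRate > 0 && termBaseRate < 1, "termBaseRate", "must be in (0, 1)")
  chk(enrichedRate > 0 && enrichedRate <= 1, "enrichedRate", "must be in (0, 1]")
  chk(all(hubTargetDegrees > hubThreshold), "hubTargetDegrees",
      "planted hub degrees must exceed hubThreshold")
  if (nDe > 0) {   # hub planting only applies when DE genes exist
    chk(length(hubTargetDegrees) <= nDe, "hubTargetDegrees", "more hubs than DE genes")
    chk(all(hubTargetDegrees <= nDe - 1), "hubTargetDegrees",
        "hub degree cannot exceed nDe - 1 within the DE subgraph")
  }
  class(cfg) <- "syntheticConfig"
  cfg
}

#' Simulate a two-group log2 expression matrix with planted effects
#'
#' Each value follows
#' \deqn{x_{js} = \mu_j + \delta_j\,class_s + \gamma_j\,b_s + \epsilon_{js}}
#' with per-probe baselines \eqn{\mu_j} uniform over the baseline range,
#' planted shifts \eqn{\delta_j = \pm effectSize} for the `nDe` planted
#' probes (0 otherwise), an optional latent array factor \eqn{b_s} with
#' standard-normal probe loadings \eqn{\gamma_j}, and Gaussian noise with
#' SD `sigma`. Fully reproducible given the config seed.
#'
#' @param config a [syntheticConfig()]
#' @return list with `se` (SummarizedExperiment, assay `"exprs"`, labels in
#'   `colData`), `labels` (sample-label data.frame), and `truth` (list:
#'   `deProbes` data.frame of planted probe ids and signs)
#' @export
simulateExpression <- function(config) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(as.integer(config$seed))
  p <- config$nProbes
  nPat <- config$nPatients; nCtl <- config$nControls
  n <- nPat + nCtl
  probes <- sprintf("P%04d", seq_len(p))
  samples <- c(sprintf("PAT%02d", seq_len(nPat)), sprintf("CTL%02d", seq_len(nCtl)))
  status <- c(rep(1L, nPat), rep(0L, nCtl))
  mu <- runif(p, config$baselineRange[1], config$baselineRange[2])
  delta <- numeric(p)
  deIdx <- integer(0)
  if (config$nDe > 0) {
    deIdx <- sort(sample.int(p, config$nDe))
    nUp <- round(config$fracUp * config$nDe)
    upIdx <- if (nUp > 0) sample(deIdx, nUp) else integer(0)
    delta[deIdx] <- -config$effectSize
    delta[upIdx] <- config$effectSize
  }
  X <- matrix(rnorm(p * n, sd = config$sigma), p, n) + mu +
    outer(delta, as.numeric(status))
  if (config$confounderSd > 0) {
    bMean <- if (config$confounderClassCorrelated)
      config$confounderSd * (status - 0.5) else rep(0, n)
    b <- rnorm(n, mean = bMean, sd = config$confounderSd)
    gamma <- rnorm(p)
    X <- X + outer(gamma, b)
  }
  dimnames(X) <- list(probes, samples)
  labels <- data.frame(sample_id = samples,
                       group = ifelse(status == 1L, "patient", "control"),
                       status = status, stringsAsFactors = FALSE)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = X),
    colData = S4Vectors::DataFrame(group = labels$group, status = labels$status,
                                   row.names = samples))
  truth <- list(deProbes = data.frame(
    probe_id = probes[deIdx],
    sign = ifelse(delta[deIdx] > 0, "up", "down"),
    stringsAsFactors = FALSE))
  list(se = se, labels = labels, truth = truth)
}

#' Simulate a flat gene-to-term annotation with one planted enriched term
#'
#' Terms annotate genes independently at the base rate; one designated term
#' additionally contains a fixed fraction (`enrichedRate`) of the planted
#' DE genes, chosen deterministically given the seed, so its
#' over-representation among DE genes is guaranteed by construction. Every
#' term is kept non-empty. Term classes cycle through
#' Process/Function/Component.
#'
#' @param config a [syntheticConfig()]
#' @param truth truth list from [simulateExpression()]
#' @return list with `annotation` (data.frame gene_id, term_id, term_name,
#'   term_class) and `truth` extended with `enrichedTermId`
#' @export
simulateAnnotation <- function(config, truth) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(as.integer(config$seed) + 1L)
  genes <- sprintf("P%04d", seq_len(config$nProbes))
  deGenes <- truth$deProbes$probe_id
  termIds <- sprintf("T%03d", seq_len(config$nTerms))
  classes <- rep(c("Process", "Function", "Component"), length.out = config$nTerms)
  enriched <- termIds[1L]
  rows <- vector("list", config$nTerms)
  for (i in seq_len(config$nTerms)) {
    members <- genes[runif(length(genes)) < config$termBaseRate]
    if (termIds[i] == enriched && length(deGenes) > 0) {
      nIn <- ceiling(config$enrichedRate * length(deGenes))
      members <- union(members, sample(deGenes, nIn))
    }
    if (length(members) == 0L) members <- sample(genes, 1L)
    rows[[i]] <- data.frame(gene_id = members, term_id = termIds[i],
                            term_name = paste0("synthetic term ", i),
                            term_class = classes[i], stringsAsFactors = FALSE)
  }
  annotation <- do.call(rbind, rows)
  annotation <- annotation[!duplicated(annotation[, c("gene_id", "term_id")]), ]
  rownames(annotation) <- NULL
  truth$enrichedTermId <- enriched
  list(annotation = annotation, truth = truth)
}

#' Simulate an interaction edge list with planted hub genes
#'
#' Builds a preferential-attachment backbone over the planted DE genes,
#' forces the designated hub genes to their target degrees by wiring them
#' to additional distinct DE genes, and rewires any other DE gene that
#' exceeds the hub threshold so that the planted hubs are identifiable as
#' exactly the super-threshold nodes of the DE-induced subgraph. Background
#' edges among non-DE genes (and a few crossing edges, removed by
#' induction) are added for realism.
#'
#' @param config a [syntheticConfig()]
#' @param truth truth list from [simulateExpression()]
#' @return list with `edges` (data.frame gene_a, gene_b) and `truth`
#'   extended with `plantedHubIds`
#' @export
simulateEdges <- function(config, truth) {
  stopifnot(inherits(config, "syntheticConfig"))
  set.seed(as.integer(config$seed) + 2L)
  deGenes <- truth$deProbes$probe_id
  allGenes <- sprintf("P%04d", seq_len(config$nProbes))
  nonDe <- setdiff(allGenes, deGenes)
  nDe <- length(deGenes)
  nHub <- length(config$hubTargetDegrees)
  if (nDe < 2 || nHub == 0) {
    truth$plantedHubIds <- character(0)
    return(list(edges = data.frame(gene_a = character(0), gene_b = character(0)),
                truth = truth))
  }
  g <- igraph::sample_pa(nDe, power = 1, m = 1, directed = FALSE)
  igraph::V(g)$name <- sample(deGenes)        # random probe-to-node assignment
  hubs <- sample(deGenes, nHub)
  for (i in seq_len(nHub)) {
    hub <- hubs[i]
    target <- config$hubTargetDegrees[i]
    repeat {
      deg <- igraph::degree(g, hub)
      if (deg >= target) break
      cand <- setdiff(deGenes, c(hub, igraph::V(g)$name[igraph::neighbors(g, hub)]))
      if (length(cand) == 0L) break
      pick <- if (length(cand) == 1L) cand else sample(cand, 1L)
      g <- igraph::add_edges(g, c(hub, pick))
    }
  }
  # keep planted hubs the only super-threshold nodes of the DE subgraph
  repeat {
    deg <- igraph::degree(g)
    over <- setdiff(names(deg)[deg > config$hubThreshold], hubs)
    if (length(over) == 0L) break
    v <- over[1L]
    nb <- igraph::V(g)$name[igraph::neighbors(g, v)]
    nbNonHub <- setdiff(nb, hubs)
    u <- if (length(nbNonHub)) nbNonHub[1L] else nb[1L]
    g <- igraph::delete_edges(g, igraph::get_edge_ids(g, c(v, u)))
  }
  el <- igraph::as_edgelist(g)
  edges <- data.frame(gene_a = el[, 1], gene_b = el[, 2], stringsAsFactors = FALSE)
  # background edges among non-DE genes and a few crossing edges
  if (length(nonDe) >= 2) {
    nBg <- min(length(nonDe), max(10L, config$nProbes %/% 10L))
    bg <- replicate(nBg, sample(nonDe, 2L))
    edges <- rbind(edges, data.frame(gene_a = bg[1, ], gene_b = bg[2, ],
                                     stringsAsFactors = FALSE))
    nCross <- min(10L, nDe, length(nonDe))
    edges <- rbind(edges, data.frame(gene_a = sample(deGenes, nCross),
                                     gene_b = sample(nonDe, nCross),
                                     stringsAsFactors = FALSE))
  }
  edges <- cleanEdgeList(edges)
  truth$plantedHubIds <- hubs
  list(edges = edges, truth = truth)
}

#' Write a complete synthetic study to disk
#'
#' Emits `expression.tsv`, `labels.tsv`, `annotation.tsv`, `edges.tsv` and
#' `truth.json` in the canonical formats read by the package's loaders.
#'
#' @param config a [syntheticConfig()]
#' @param dir output directory (created if absent)
#' @return invisible list with file paths and the ground truth
#' @export
simulateStudy <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sim <- simulateExpression(config)
  ann <- simulateAnnotation(config, sim$truth)
  edg <- simulateEdges(config, ann$truth)
  truth <- edg$truth
  paths <- list(
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "labels.tsv"),
    annotation = file.path(dir, "annotation.tsv"),
    edges = file.path(dir, "edges.tsv"),
    truthFile = file.path(dir, "truth.json")
  )
  writeExpressionMatrix(sim$se, paths$expression)
  write.table(sim$labels[, c("sample_id", "group")], paths$labels,
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(ann$annotation, paths$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(edg$edges, paths$edges, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(truth, paths$truthFile, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(paths, list(truth = truth)))
}
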