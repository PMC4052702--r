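#' Validate a pipeline run configuration
#'
#' Fills defaults for missing keys and rejects unknown ones. Defaults: 3
#' latent components, 10000 permutations, strict FDR cutoff 0.05, exclusive
#' hub degree threshold 10, top 10 enriched terms, patients coded by the
#' group string `"patient"`.
#'
#' @param config named list, or path to a YAML file with the same keys
#' @return validated configuration list with all defaults filled
#' @export
validateRunConfig <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
    if (is.null(config)) config <- list()
  }
  defaults <- list(
    expression = NULL, labels = NULL, annotation = NULL, edges = NULL,
    outdir = NULL, positiveClass = "patient",
    nComponents = 3L, nPermutations = 10000L, fdrThreshold = 0.05,
    hubThreshold = 10L, topKTerms = 10L, scale = TRUE, seed = 1L
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  if (cfg$nComponents < 1) stop("nComponents must be positive")
  if (cfg$nPermutations < 1) stop("nPermutations must be positive")
  if (cfg$fdrThreshold <= 0 || cfg$fdrThreshold > 1) stop("fdrThreshold must be in (0, 1]")
  if (cfg$hubThreshold < 0) stop("hubThreshold must be nonnegative")
  if (cfg$topKTerms < 1) stop("topKTerms must be positive")
  cfg
}

#' Run the full PLS differential-expression pipeline
#'
#' Orchestrates the complete workflow: load and align the expression matrix
#' and labels, autoscale, fit the NIPALS PLS model, score probes by VIP,
#' build the permutation null, compute the empirical FDR, select probes
#' with direction, test term over-representation of the selected genes,
#' and build the selected-gene interaction network with hub calls. Writes
#' the significance, score and enrichment tables, the Cytoscape network
#' files, and a JSON + text run report summarizing sample sizes, selection
#' counts, top terms, hubs, seed and every threshold (including the
#' decided-but-convention choices: pooled tail-ratio FDR estimator,
#' autoscaling, group-mean direction rule). Any stage failure aborts with
#' a stage-named error and removes partial outputs.
#'
#' @param config list or YAML path accepted by [validateRunConfig()]; the
#'   input paths `expression`, `labels`, `annotation`, `edges` and `outdir`
#'   are required
#' @return invisible list with the report, tables and fitted objects
#' @export
runPipeline <- function(config) {
  cfg <- validateRunConfig(config)
  for (key in c("expression", "labels", "annotation", "edges", "outdir"))
    if (is.null(cfg[[key]])) stop("config key '", key, "' is required")
  if (!dir.exists(cfg$outdir)) dir.create(cfg$outdir, recursive = TRUE)
  written <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  out <- function(f) { p <- file.path(cfg$outdir, f); written <<- c(written, p); p }

  se <- stage("load", {
    alignSamples(readExpressionMatrix(cfg$expression),
                 readSampleLabels(cfg$labels, positiveClass = cfg$positiveClass))
  })
  annotation <- stage("load", readAnnotation(cfg$annotation))
  edges <- stage("load", readEdgeList(cfg$edges))

  res <- stage("significance", suppressMessages(
    plsSignificance(se, nComponents = cfg$nComponents,
                    nPermutations = cfg$nPermutations,
                    fdrThreshold = cfg$fdrThreshold,
                    seed = cfg$seed, scale = cfg$scale)))
  tab <- res$table
  stage("write", {
    write.table(as.data.frame(tab), out("significance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(res$scores, out("scores.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  })

  selGenes <- unique(tab$gene_id[tab$selected & !is.na(tab$gene_id)])
  background <- unique(tab$gene_id[!is.na(tab$gene_id)])
  enr <- stage("enrichment", suppressMessages(
    enrichTerms(selGenes, background, annotation)))
  top <- topTerms(enr, K = cfg$topKTerms)
  stage("write", write.table(top, out("enrichment.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE))

  net <- stage("network", buildNetwork(tab, edges, hubThreshold = cfg$hubThreshold))
  stage("write", exportNetwork(net, out("network.sif"), out("network_nodes.tsv")))
  hubs <- hubGenes(net)
  deg <- nodeDegrees(net)

  status <- SummarizedExperiment::colData(se)$status
  report <- list(
    n_probes = nrow(se),
    n_samples = ncol(se),
    n_patients = sum(status == 1L),
    n_controls = sum(status == 0L),
    n_components = cfg$nComponents,
    n_permutations = cfg$nPermutations,
    fdr_threshold = cfg$fdrThreshold,
    hub_threshold = cfg$hubThreshold,
    top_k_terms = cfg$topKTerms,
    seed = cfg$seed,
    n_selected = sum(tab$selected),
    n_up = sum(tab$selected & tab$direction == "up"),
    n_down = sum(tab$selected & tab$direction == "down"),
    top_terms = top$term_id,
    hub_genes = as.list(deg[hubs]),
    conventions = list(
      fdr_estimator = "pooled tail-ratio with per-permutation expectation, closed (>=) tail counts, running-minimum monotonization",
      preprocessing = if (cfg$scale) "column autoscaling (center + unit variance)" else "column centering only",
      direction_rule = "raw log2 group means, patients vs controls; ties labeled down",
      selection_rule = "strict FDR < threshold",
      hub_rule = "degree strictly greater than threshold on the selected-gene induced subgraph"
    )
  )
  stage("report", {
    jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    txt <- c(
      sprintf("Samples: %d (%d patients, %d controls); probes: %d",
              report$n_samples, report$n_patients, report$n_controls, report$n_probes),
      sprintf("PLS components: %d; permutations: %d; seed: %d",
              report$n_components, report$n_permutations, report$seed),
      sprintf("A total of %d probes selected at FDR < %g, including %d depressed and %d overexpressed in patients",
              report$n_selected, report$fdr_threshold, report$n_down, report$n_up),
      sprintf("Top enriched terms: %s", paste(report$top_terms, collapse = ", ")),
      sprintf("Hub genes (degree > %d): %s", report$hub_threshold,
              if (length(hubs)) paste(sprintf("%s (%d)", hubs, deg[hubs]), collapse = ", ")
              else "none")
    )
    writeLines(txt, out("report.txt"))
  })
  invisible(list(report = report, table = tab, enrichment = enr, topTerms = top,
                 network = net, model = res$model, scores = res$scores))
}
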