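# Small fixtures built in code at test time.

writeTsv <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# minimal aligned SummarizedExperiment with a known matrix and 0/1 status
tinySe <- function(m, status) {
  se <- SummarizedExperiment::SummarizedExperiment(assays = list(exprs = m))
  SummarizedExperiment::colData(se)$status <- as.integer(status)
  se
}

randomEdgeFrame <- function(nodes, nEdges) {
  a <- sample(nodes, nEdges, replace = TRUE)
  b <- sample(nodes, nEdges, replace = TRUE)
  data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
}
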