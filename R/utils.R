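# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG
# state afterwards so no global random state leaks out of the package.
withSeed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv(), inherits = FALSE) else NULL
  on.exit(
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv()),
    add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stage-specific 31-bit seed from the scenario seed so the
# stages draw from disjoint streams but all flow from one integer.
# Double arithmetic keeps the product exact (< 2^53) for any 31-bit seed.
deriveSeed <- function(seed, stage) {
  as.integer((abs(as.numeric(seed)) * 7919 + stage * 104729) %% 2147483587)
}

assertScalarCount <- function(x, what) {
  if (length(x) != 1L || is.na(x) || x < 1L)
    stop(what, " must be a single positive count", call. = FALSE)
  invisible(as.integer(x))
}

# Write a TSV with stable quoting/eol so outputs are byte-reproducible.
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, eol = "\n")
  invisible(path)
}

readTsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, colClasses = "character")
}

# igraph handle on the full multiscale network, undirected-collapsed,
# used for neighborhoods, components and BFS.
msnAsIgraphUndirected <- function(network) {
  ed <- unique(edgeTable(network)[c("source", "target")])
  igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = nodeIds(network),
                          stringsAsFactors = FALSE))
}

# Protein-protein subgraph as an undirected igraph (one edge per pair).
msnPpiIgraph <- function(network) {
  ed <- edgeTable(network)
  pp <- ed[ed$edge_class == "pp" & ed$source < ed$target,
           c("source", "target")]
  prot <- network@nodes$id[network@nodes$node_class == "protein"]
  igraph::graph_from_data_frame(
    pp, directed = FALSE,
    vertices = data.frame(name = prot, stringsAsFactors = FALSE))
}
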