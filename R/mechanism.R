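#' Top-k nodes of a diffusion profile
#'
#' Returns the k highest visit-frequency nodes, descending, with ties
#' broken lexicographically by node id. When the network has fewer than
#' k nodes, all nodes are returned.
#'
#' @param profile a [DiffusionProfile-class].
#' @param k number of nodes (default 20, the usual top-k choice that
#'   captures most of the visit frequency mass).
#' @return Ordered character vector of node ids.
#' @export
topKNodes <- function(profile, k = 20L) {
  stopifnot(is(profile, "DiffusionProfile"))
  k <- assertScalarCount(k, "k")
  v <- visitFrequency(profile)
  ord <- order(-v, names(v))
  names(v)[ord][seq_len(min(k, length(v)))]
}

# Dense 1-based rank of every node in a profile (ties broken by id).
profileRanks <- function(profile) {
  v <- visitFrequency(profile)
  ord <- order(-v, names(v))
  stats::setNames(order(ord), names(v))
}

emptyMechanismSubgraph <- function(compound, disease, k) {
  new("MechanismSubgraph",
      nodes = data.frame(id = character(0), node_class = character(0),
                         rank_compound = integer(0),
                         rank_disease = integer(0),
                         freq_compound = numeric(0),
                         freq_disease = numeric(0),
                         is_compound_target = logical(0),
                         is_disease_protein = logical(0),
                         in_top_k_compound = logical(0),
                         in_top_k_disease = logical(0),
                         stringsAsFactors = FALSE),
      edges = data.frame(source = character(0), target = character(0),
                         edge_class = character(0),
                         stringsAsFactors = FALSE),
      compound = compound, disease = disease, k = as.integer(k))
}

#' Extract the mechanism subgraph of a compound-disease pair
#'
#' Builds the induced subnetwork over the union of the top-k nodes of
#' the compound and disease diffusion profiles plus the anchor nodes
#' (compound targets and disease proteins present in the network), then
#' prunes it so that mechanism links remain: compound-side nodes
#' (compound anchors or top-k compound-profile nodes) without a path to
#' any disease-side node within the subgraph are excluded, and vice
#' versa. Connectivity is evaluated ignoring edge direction; since
#' removing a disconnected node can disconnect others, pruning runs to
#' a fixed point, which equals keeping exactly the connected components
#' of the induced subgraph that contain both a compound-side and a
#' disease-side node.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param compoundProfile,diseaseProfile [DiffusionProfile-class]
#'   objects computed on `network`.
#' @param compoundTargets character vector of the compound's target
#'   protein ids.
#' @param diseaseProteins character vector of disease protein ids.
#' @param k per-profile top-k size (default 20).
#' @return A [MechanismSubgraph-class]; empty (with a warning) when no
#'   compound-disease connection survives pruning, signalling the
#'   absence of a mechanism link.
#' @export
extractMechanismSubgraph <- function(network, compoundProfile,
                                     diseaseProfile, compoundTargets,
                                     diseaseProteins, k = 20L) {
  stopifnot(is(network, "MultiscaleNetwork"),
            is(compoundProfile, "DiffusionProfile"),
            is(diseaseProfile, "DiffusionProfile"))
  k <- assertScalarCount(k, "k")
  ids <- nodeIds(network)
  if (!identical(names(visitFrequency(compoundProfile)), ids) ||
      !identical(names(visitFrequency(diseaseProfile)), ids))
    stop("profiles were not computed on this network")
  cAnchor <- intersect(unique(as.character(compoundTargets)), ids)
  dAnchor <- intersect(unique(as.character(diseaseProteins)), ids)
  topC <- topKNodes(compoundProfile, k)
  topD <- topKNodes(diseaseProfile, k)
  compoundSide <- union(cAnchor, topC)
  diseaseSide <- union(dAnchor, topD)
  nodeSet <- sort(union(compoundSide, diseaseSide))

  ed <- edgeTable(network)
  sub <- ed[ed$source %in% nodeSet & ed$target %in% nodeSet, ,
            drop = FALSE]
  g <- igraph::graph_from_data_frame(
    unique(sub[c("source", "target")]), directed = FALSE,
    vertices = data.frame(name = nodeSet, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership
  keepComp <- intersect(
    unique(comp[names(comp) %in% compoundSide]),
    unique(comp[names(comp) %in% diseaseSide]))
  keep <- names(comp)[comp %in% keepComp]
  if (!length(keep)) {
    warning("mechanism subgraph is empty after connectivity pruning: ",
            "no path links the compound side to the disease side",
            call. = FALSE)
    return(emptyMechanismSubgraph(entityLabel(compoundProfile),
                                  entityLabel(diseaseProfile), k))
  }
  keep <- sort(keep)
  sub <- sub[sub$source %in% keep & sub$target %in% keep, , drop = FALSE]
  sub <- sub[order(sub$source, sub$target, sub$edge_class), ,
             drop = FALSE]
  rownames(sub) <- NULL
  cls <- nodeClasses(network)
  rc <- profileRanks(compoundProfile)
  rd <- profileRanks(diseaseProfile)
  vc <- visitFrequency(compoundProfile)
  vd <- visitFrequency(diseaseProfile)
  nodes <- data.frame(
    id = keep,
    node_class = unname(cls[keep]),
    rank_compound = unname(rc[keep]),
    rank_disease = unname(rd[keep]),
    freq_compound = unname(vc[keep]),
    freq_disease = unname(vd[keep]),
    is_compound_target = keep %in% cAnchor,
    is_disease_protein = keep %in% dAnchor,
    in_top_k_compound = keep %in% topC,
    in_top_k_disease = keep %in% topD,
    stringsAsFactors = FALSE)
  new("MechanismSubgraph", nodes = nodes, edges = sub,
      compound = entityLabel(compoundProfile),
      disease = entityLabel(diseaseProfile), k = k)
}

#' Rank the nodes of a mechanism subgraph
#'
#' Sorts nodes by their maximum visit frequency across the compound and
#' disease profiles (the highest-ranking node is the one most affected
#' by either entity), with ties broken by node id, and carries the
#' class and anchor flags.
#'
#' @param subgraph a nonempty [MechanismSubgraph-class].
#' @return data.frame: `id`, `node_class`, `max_visit_frequency`,
#'   `freq_compound`, `freq_disease`, `rank_compound`, `rank_disease`,
#'   `is_compound_target`, `is_disease_protein`.
#' @export
rankMechanismNodes <- function(subgraph) {
  stopifnot(is(subgraph, "MechanismSubgraph"))
  nd <- subgraph@nodes
  if (!nrow(nd)) stop("mechanism subgraph is empty")
  nd$max_visit_frequency <- pmax(nd$freq_compound, nd$freq_disease)
  nd <- nd[order(-nd$max_visit_frequency, nd$id), , drop = FALSE]
  rownames(nd) <- NULL
  nd[c("id", "node_class", "max_visit_frequency", "freq_compound",
       "freq_disease", "rank_compound", "rank_disease",
       "is_compound_target", "is_disease_protein")]
}

#' Export a mechanism subgraph
#'
#' Writes GraphML (node attributes: class, anchor flags, both visit
#' frequencies and ranks, for Cytoscape-style rendering), SIF (edge
#' lines labelled with the edge class), and/or a TSV node table.
#'
#' @param subgraph a [MechanismSubgraph-class].
#' @param graphmlPath,sifPath,tsvPath optional output paths.
#' @return Invisibly, the igraph object written (NULL for an empty
#'   subgraph).
#' @export
exportMechanismSubgraph <- function(subgraph, graphmlPath = NULL,
                                    sifPath = NULL, tsvPath = NULL) {
  stopifnot(is(subgraph, "MechanismSubgraph"))
  nd <- subgraph@nodes
  ed <- subgraph@edges
  if (!is.null(tsvPath)) writeTsv(nd, tsvPath)
  if (!is.null(sifPath))
    writeLines(sprintf("%s\t%s\t%s", ed$source, ed$edge_class, ed$target),
               sifPath)
  g <- NULL
  if (nrow(nd)) {
    vert <- nd
    names(vert)[1] <- "name"
    g <- igraph::graph_from_data_frame(ed, directed = TRUE,
                                       vertices = vert)
    if (!is.null(graphmlPath))
      igraph::write_graph(g, graphmlPath, format = "graphml")
  } else if (!is.null(graphmlPath)) {
    igraph::write_graph(igraph::make_empty_graph(), graphmlPath,
                        format = "graphml")
  }
  invisible(g)
}
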