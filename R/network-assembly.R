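#' Load a compound-target interaction table
#'
#' Reads a TSV with columns `compound_id`, `compound_name`, `target_id`.
#' Duplicate `(compound_id, target_id)` pairs (e.g. the same interaction
#' reported by several source databases) are collapsed to one record and
#' the collapse count is reported. Identifier matching throughout the
#' package is exact, case-sensitive string equality; identifier
#' normalization across vocabularies is a user responsibility performed
#' before loading.
#'
#' @param path TSV file path.
#' @param provenance free-text source label (defaults to the file name).
#' @return A [CompoundTargetTable-class].
#' @export
loadCompoundTargets <- function(path, provenance = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readTsv(path)
  need <- c("compound_id", "compound_name", "target_id")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    stop("schema error: missing column(s): ",
         paste(missingCols, collapse = ", "))
  if (!nrow(df)) stop("empty input: ", path, " has no records")
  dup <- duplicated(df[c("compound_id", "target_id")])
  if (any(dup))
    message(sum(dup), " duplicate compound-target pair(s) collapsed")
  compoundTargetTable(df[!dup, , drop = FALSE], provenance = provenance)
}

#' Load a disease protein list
#'
#' Reads a plain-text file with one protein identifier per line (blank
#' lines ignored).
#'
#' @param path file path.
#' @param label disease name.
#' @param coOccurrenceThreshold optional numeric metadata recording the
#'   selection threshold used upstream.
#' @return A [DiseaseProteinSet-class].
#' @export
loadDiseaseProteins <- function(path, label = "disease",
                                coOccurrenceThreshold = NA_real_) {
  if (!file.exists(path)) stop("no such file: ", path)
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  diseaseProteinSet(trimws(ids), label = label,
                    coOccurrenceThreshold = coOccurrenceThreshold)
}

#' Summarize a compound-target network
#'
#' Counts distinct compounds, distinct targets and unique CPIs, and
#' computes the per-target degree (number of distinct compounds hitting
#' each target). Because records are unique pairs, the degrees sum to
#' the CPI count.
#'
#' @param table a [CompoundTargetTable-class].
#' @return A [NetworkSummary-class].
#' @export
summarizeNetwork <- function(table) {
  stopifnot(is(table, "CompoundTargetTable"))
  r <- cpiRecords(table)
  deg <- if (nrow(r)) {
    t <- table(r$target_id)
    stats::setNames(as.integer(t), names(t))
  } else stats::setNames(integer(0), character(0))
  new("NetworkSummary",
      nCompounds = length(unique(r$compound_id)),
      nTargets = length(deg),
      nCpis = nrow(r),
      targetDegree = deg)
}

#' Filter a compound-target table to key targets
#'
#' Retains exactly the records whose target interacts with at least
#' `minIngredients` distinct compounds ("key targets"). Compounds left
#' with zero targets after filtering are dropped from the roster and
#' reported. The operation is idempotent and its output CPI count is
#' non-increasing in `minIngredients`.
#'
#' @param table a [CompoundTargetTable-class].
#' @param minIngredients minimum distinct-compound degree (default 2,
#'   the usual "two or more ingredients" key-target rule).
#' @return A filtered [CompoundTargetTable-class].
#' @export
filterKeyTargets <- function(table, minIngredients = 2L) {
  stopifnot(is(table, "CompoundTargetTable"))
  minIngredients <- assertScalarCount(minIngredients, "minIngredients")
  r <- cpiRecords(table)
  if (!nrow(r)) return(table)
  deg <- table(r$target_id)
  keep <- names(deg)[as.integer(deg) >= minIngredients]
  out <- r[r$target_id %in% keep, , drop = FALSE]
  lost <- setdiff(unique(r$compound_id), unique(out$compound_id))
  if (length(lost))
    message(length(lost), " compound(s) dropped (no remaining targets): ",
            paste(lost, collapse = ", "))
  compoundTargetTable(out, provenance = table@provenance)
}

#' Export a compound-target network to GraphML / SIF
#'
#' Writes the bipartite compound-target graph with a `node_class` vertex
#' attribute (`"compound"` or `"target"`) plus any user-supplied node
#' attribute maps (e.g. disease or pathway membership flags). The SIF
#' output uses the interaction label `cpi`.
#'
#' @param table a [CompoundTargetTable-class].
#' @param graphmlPath optional GraphML output path.
#' @param sifPath optional SIF output path.
#' @param annotations optional named list; each element is a named
#'   vector mapping node ids to an attribute value (unlisted nodes get
#'   `FALSE` for logical maps, `NA` otherwise).
#' @return Invisibly, the igraph object written.
#' @export
exportNetwork <- function(table, graphmlPath = NULL, sifPath = NULL,
                          annotations = NULL) {
  stopifnot(is(table, "CompoundTargetTable"))
  r <- cpiRecords(table)
  compounds <- sort(unique(r$compound_id))
  targets <- sort(unique(r$target_id))
  vert <- data.frame(
    name = c(compounds, targets),
    node_class = rep(c("compound", "target"),
                     c(length(compounds), length(targets))),
    stringsAsFactors = FALSE)
  nameOf <- stats::setNames(r$compound_name, r$compound_id)
  vert$label <- ifelse(vert$node_class == "compound",
                       unname(nameOf[vert$name]), vert$name)
  if (!is.null(annotations)) {
    if (is.null(names(annotations)))
      stop("annotations must be a named list of node attribute maps")
    for (a in names(annotations)) {
      m <- annotations[[a]]
      v <- m[vert$name]
      if (is.logical(m)) v[is.na(v)] <- FALSE
      vert[[a]] <- unname(v)
    }
  }
  g <- igraph::graph_from_data_frame(
    r[c("compound_id", "target_id")], directed = FALSE, vertices = vert)
  igraph::E(g)$interaction <- "cpi"
  if (!is.null(graphmlPath))
    igraph::write_graph(g, graphmlPath, format = "graphml")
  if (!is.null(sifPath))
    writeLines(sprintf("%s\tcpi\t%s", r$compound_id, r$target_id), sifPath)
  invisible(g)
}

#' Write a network summary as JSON
#'
#' @param summary a [NetworkSummary-class].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeNetworkSummary <- function(summary, path) {
  stopifnot(is(summary, "NetworkSummary"))
  jsonlite::write_json(list(
    n_compounds = summary@nCompounds,
    n_targets = summary@nTargets,
    n_cpis = summary@nCpis,
    target_degree = as.list(summary@targetDegree)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
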