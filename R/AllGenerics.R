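#' Node identifiers of a network-like object
#'
#' @param x object with node structure.
#' @return character vector of node ids (lexicographic order for
#'   [MultiscaleNetwork-class]).
#' @export
setGeneric("nodeIds", function(x) standardGeneric("nodeIds"))

#' Node classes of a network-like object
#'
#' @param x object with node structure.
#' @return named character vector mapping node id to
#'   `"protein"`/`"function"`.
#' @export
setGeneric("nodeClasses", function(x) standardGeneric("nodeClasses"))

#' Edge table of a network-like object
#'
#' @param x object with edges.
#' @return data.frame with columns `source`, `target`, `edge_class`.
#' @export
setGeneric("edgeTable", function(x) standardGeneric("edgeTable"))

#' Interaction records of a compound-target table
#'
#' @param x a [CompoundTargetTable-class].
#' @return data.frame of `(compound_id, compound_name, target_id)` rows.
#' @export
setGeneric("cpiRecords", function(x) standardGeneric("cpiRecords"))

#' Protein identifiers of a disease protein set
#'
#' @param x a [DiseaseProteinSet-class].
#' @return sorted character vector of protein ids.
#' @export
setGeneric("proteinIds", function(x) standardGeneric("proteinIds"))

#' Gene sets of a library
#'
#' @param x a [GeneSetLibrary-class].
#' @return named list of character vectors.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' Visit-frequency vector of a diffusion profile
#'
#' @param x a [DiffusionProfile-class].
#' @return named numeric vector over all network nodes.
#' @export
setGeneric("visitFrequency", function(x) standardGeneric("visitFrequency"))

#' Entity label of a profile or restart vector
#'
#' @param x object with an entity label.
#' @return character scalar.
#' @export
setGeneric("entityLabel", function(x) standardGeneric("entityLabel"))

#' Convergence flag of an iterative computation
#'
#' @param x a [DiffusionProfile-class].
#' @return logical scalar.
#' @export
setGeneric("isConverged", function(x) standardGeneric("isConverged"))

#' @describeIn nodeIds lexicographically ordered node ids.
#' @export
setMethod("nodeIds", "MultiscaleNetwork", function(x) x@nodes$id)

#' @describeIn nodeClasses id-to-class map.
#' @export
setMethod("nodeClasses", "MultiscaleNetwork",
          function(x) stats::setNames(x@nodes$node_class, x@nodes$id))

#' @describeIn edgeTable directed expanded edge list.
#' @export
setMethod("edgeTable", "MultiscaleNetwork", function(x) x@edges)

#' @describeIn cpiRecords the validated record table.
#' @export
setMethod("cpiRecords", "CompoundTargetTable", function(x) x@records)

#' @describeIn proteinIds the sorted id vector.
#' @export
setMethod("proteinIds", "DiseaseProteinSet", function(x) x@ids)

#' @describeIn geneSets the named list of member vectors.
#' @export
setMethod("geneSets", "GeneSetLibrary", function(x) x@sets)

#' @describeIn visitFrequency the named frequency vector.
#' @export
setMethod("visitFrequency", "DiffusionProfile", function(x) x@visitFrequency)

#' @describeIn entityLabel label of a diffusion profile.
#' @export
setMethod("entityLabel", "DiffusionProfile", function(x) x@entity)

#' @describeIn entityLabel label of a restart vector.
#' @export
setMethod("entityLabel", "RestartVector", function(x) x@label)

#' @describeIn isConverged convergence flag of power iteration.
#' @export
setMethod("isConverged", "DiffusionProfile", function(x) x@converged)

setMethod("show", "MultiscaleNetwork", function(object) {
  cls <- table(factor(object@nodes$node_class, levels = NODE_CLASSES))
  ecl <- table(factor(object@edges$edge_class, levels = EDGE_CLASSES))
  cat("MultiscaleNetwork:", cls[["protein"]], "proteins,",
      cls[["function"]], "functions\n")
  cat("  directed edges by class:",
      paste(sprintf("%s=%d", names(ecl), as.integer(ecl)),
            collapse = ", "), "\n")
})

setMethod("show", "CompoundTargetTable", function(object) {
  r <- object@records
  cat("CompoundTargetTable:", nrow(r), "CPIs between",
      length(unique(r$compound_id)), "compounds and",
      length(unique(r$target_id)), "targets\n")
  cat("  provenance:", object@provenance, "\n")
})

setMethod("show", "DiseaseProteinSet", function(object) {
  cat("DiseaseProteinSet '", object@label, "': ", length(object@ids),
      " proteins\n", sep = "")
})

setMethod("show", "GeneSetLibrary", function(object) {
  sz <- vapply(object@sets, length, 1L)
  cat("GeneSetLibrary (", object@source, "): ", length(object@sets),
      " sets", sep = "")
  if (length(sz)) cat(", sizes ", min(sz), "-", max(sz), sep = "")
  cat("\n")
})

setMethod("show", "NetworkSummary", function(object) {
  cat("NetworkSummary:", object@nCpis, "CPIs between", object@nCompounds,
      "compounds and", object@nTargets, "targets\n")
  if (length(object@targetDegree)) {
    top <- sort(object@targetDegree, decreasing = TRUE)
    top <- top[seq_len(min(5L, length(top)))]
    cat("  highest-degree targets:",
        paste(sprintf("%s(%d)", names(top), top), collapse = ", "), "\n")
  }
})

setMethod("show", "EnrichmentResult", function(object) {
  cat("EnrichmentResult '", object@name, "': overlap ", object@overlapK,
      "/", object@setK, " (query ", object@queryN, ", background ",
      object@backgroundN, "), p = ", format(object@pValue, digits = 4),
      "\n", sep = "")
  if (length(object@flags)) cat("  flags:",
                               paste(object@flags, collapse = "; "), "\n")
})

setMethod("show", "DiffusionProfile", function(object) {
  cat("DiffusionProfile '", object@entity, "' over ",
      length(object@visitFrequency), " nodes (",
      object@iterationsUsed, " iterations, ",
      if (object@converged) "converged" else "NOT converged", ")\n",
      sep = "")
})

setMethod("show", "DiffusionConfig", function(object) {
  cat("DiffusionConfig: c =", object@continueProb, ", tol =",
      object@tolerance, ", maxIter =", object@maxIterations,
      ", k =", object@k, "\n")
  cat("  edge class weights:",
      paste(sprintf("%s=%g", names(object@edgeClassWeights),
                    object@edgeClassWeights), collapse = ", "), "\n")
})

setMethod("show", "SyntheticScenario", function(object) {
  cat("SyntheticScenario:", object@nProteins, "proteins,",
      object@nFunctions, "functions,", object@nCompounds,
      "compounds (seed", paste0(object@seed, ")\n"))
})

setMethod("show", "ScenarioBundle", function(object) {
  cat("ScenarioBundle (seed ", object@scenario@seed, ")\n", sep = "")
  show(object@network)
  show(object@compounds)
  show(object@disease)
  show(object@pathways)
  cat("  planted compounds:", paste(object@truth, collapse = ", "), "\n")
})

setMethod("show", "MechanismSubgraph", function(object) {
  cat("MechanismSubgraph '", object@compound, "' vs '", object@disease,
      "' (k = ", object@k, "): ", nrow(object@nodes), " nodes, ",
      nrow(object@edges), " edges\n", sep = "")
})
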