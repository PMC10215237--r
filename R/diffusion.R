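#' Load a multiscale network from an edge-list TSV
#'
#' The file stores each biological association once, with columns
#' `source`, `target`, `edge_class` and classes `pp` (protein-protein),
#' `pf` (protein annotated to a function) and `ff` (function hierarchy,
#' child to parent). Loading expands the undirected layers to reciprocal
#' directed edges (`pp` both ways; the `pf` reverse stored as `fp`) and
#' hierarchy rows to `ff_up` plus reciprocal `ff_down`. Node classes are
#' inferred from edge membership and validated: an id used both as a
#' protein and as a function is a schema violation.
#'
#' @param path TSV file path.
#' @return A [MultiscaleNetwork-class].
#' @export
loadMultiscaleNetwork <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- readTsv(path)
  need <- c("source", "target", "edge_class")
  missingCols <- setdiff(need, names(df))
  if (length(missingCols))
    stop("schema error: missing column(s): ",
         paste(missingCols, collapse = ", "))
  unknown <- setdiff(unique(df$edge_class), FILE_EDGE_CLASSES)
  if (length(unknown))
    stop("schema error: unknown edge_class value(s): ",
         paste(unknown, collapse = ", "),
         " (expected pp, pf or ff)")
  asProtein <- unique(c(df$source[df$edge_class == "pp"],
                        df$target[df$edge_class == "pp"],
                        df$source[df$edge_class == "pf"]))
  asFunction <- unique(c(df$target[df$edge_class == "pf"],
                         df$source[df$edge_class == "ff"],
                         df$target[df$edge_class == "ff"]))
  both <- intersect(asProtein, asFunction)
  if (length(both))
    stop("validation error: id(s) used as both protein and function: ",
         paste(head(both, 10L), collapse = ", "))
  pp <- df[df$edge_class == "pp", , drop = FALSE]
  pf <- df[df$edge_class == "pf", , drop = FALSE]
  ff <- df[df$edge_class == "ff", , drop = FALSE]
  dirEdges <- function(s, t, cls)
    data.frame(source = s, target = t,
               edge_class = rep(cls, length(s)),
               stringsAsFactors = FALSE)
  edges <- rbind(
    dirEdges(pp$source, pp$target, "pp"),
    dirEdges(pp$target, pp$source, "pp"),
    dirEdges(pf$source, pf$target, "pf"),
    dirEdges(pf$target, pf$source, "fp"),
    dirEdges(ff$source, ff$target, "ff_up"),
    dirEdges(ff$target, ff$source, "ff_down"))
  nodes <- data.frame(
    id = c(asProtein, asFunction),
    node_class = rep(c("protein", "function"),
                     c(length(asProtein), length(asFunction))),
    stringsAsFactors = FALSE)
  multiscaleNetwork(nodes, edges)
}

#' Build the restart vector of an entity
#'
#' Places uniform teleport mass over the entity's anchor nodes that are
#' present in the network (a compound anchors on its target proteins, a
#' disease on its protein set). Unmapped ids are dropped with a warning;
#' an entity with no mapped anchor is an error.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param ids anchor node ids.
#' @param label entity name.
#' @return A [RestartVector-class].
#' @export
buildRestartVector <- function(network, ids, label = "entity") {
  ids <- unique(as.character(ids))
  if (!length(ids)) stop("ids must be nonempty")
  mapped <- intersect(ids, nodeIds(network))
  if (!length(mapped))
    stop("entity has no network anchor: none of ", length(ids),
         " id(s) map to network nodes (", label, ")")
  if (length(mapped) < length(ids))
    warning(sprintf("%d of %d anchor id(s) not in network dropped (%s)",
                    length(ids) - length(mapped), length(ids), label),
            call. = FALSE)
  new("RestartVector",
      entries = stats::setNames(rep(1 / length(mapped), length(mapped)),
                                sort(mapped)),
      label = label)
}

#' Build the biased row-stochastic transition matrix
#'
#' For a walker at node `u`, the probability of stepping to `v` is the
#' edge-class weight of `u -> v` divided by the total weight of `u`'s
#' out-edges, so the per-class scalar weights encode the relative
#' likelihood of visiting protein versus biological-function neighbors.
#' Nodes without out-edges are flagged dangling; their walk mass is
#' redirected to the restart vector during propagation.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param weights named positive numeric over the five directed edge
#'   classes (`pp`, `pf`, `fp`, `ff_up`, `ff_down`), or a
#'   [DiffusionConfig-class]; missing classes default to 1.
#' @return A [TransitionModel-class].
#' @examples
#' net <- generateMultiscaleNetwork(syntheticScenario(seed = 7))
#' tm <- buildTransitionMatrix(net, c(pp = 1, pf = 2))
#' @export
buildTransitionMatrix <- function(network, weights = NULL) {
  stopifnot(is(network, "MultiscaleNetwork"))
  if (is(weights, "DiffusionConfig")) weights <- weights@edgeClassWeights
  w <- stats::setNames(rep(1, length(EDGE_CLASSES)), EDGE_CLASSES)
  if (!is.null(weights)) {
    if (is.null(names(weights)) ||
        !all(names(weights) %in% EDGE_CLASSES))
      stop("weights must be named with edge classes among: ",
           paste(EDGE_CLASSES, collapse = ", "))
    if (any(weights <= 0)) stop("edge class weights must be positive")
    w[names(weights)] <- weights
  }
  ids <- nodeIds(network)
  ed <- edgeTable(network)
  i <- match(ed$source, ids)
  j <- match(ed$target, ids)
  x <- unname(w[ed$edge_class])
  W <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(ids), length(ids)))
  rs <- Matrix::rowSums(W)
  dangling <- rs == 0
  if (any(dangling))
    message(sum(dangling), " dangling node(s) flagged (no out-edges)")
  nz <- !dangling
  W[nz, ] <- W[nz, , drop = FALSE] / rs[nz]
  new("TransitionModel", W = W, nodeIds = ids, dangling = dangling)
}

denseRestart <- function(restart, ids) {
  s <- numeric(length(ids))
  names(s) <- ids
  hit <- intersect(names(restart@entries), ids)
  if (length(hit) < length(restart@entries))
    stop("restart vector has support outside the network")
  s[hit] <- restart@entries[hit]
  s
}

#' Compute a diffusion profile by power iteration
#'
#' Iterates the random-walk-with-restart fixed-point update
#' \deqn{r \leftarrow (1 - c)\,s + c\,W^\top r}
#' from `r0 = s`, where `s` is the entity's restart vector, `c` the
#' continue probability, and `W` the biased row-stochastic transition
#' matrix; mass sitting on dangling nodes is redirected to the restart
#' vector at each step. Iteration stops when the L1 change drops below
#' the configured tolerance (the update is a contraction with modulus
#' `c`, so convergence is geometric) or at `maxIterations`, in which
#' case the profile is returned with `converged = FALSE` and a warning.
#'
#' @param network a [MultiscaleNetwork-class].
#' @param restart a [RestartVector-class].
#' @param config a [DiffusionConfig-class].
#' @param transition optional precomputed [TransitionModel-class]
#'   (rebuilt from `config` weights when omitted); pass it when
#'   computing many profiles on one network.
#' @return A [DiffusionProfile-class] over every network node
#'   (lexicographic order), summing to 1 within 1e-9; the per-iteration
#'   L1 changes are recorded in `diagnostics$l1Trace`.
#' @examples
#' net <- generateMultiscaleNetwork(syntheticScenario(seed = 7))
#' s <- buildRestartVector(net, c("P0001", "P0002"), "example")
#' computeDiffusionProfile(net, s, diffusionConfig(tolerance = 1e-10))
#' @export
computeDiffusionProfile <- function(network, restart,
                                    config = diffusionConfig(),
                                    transition = NULL) {
  stopifnot(is(network, "MultiscaleNetwork"), is(restart, "RestartVector"),
            is(config, "DiffusionConfig"))
  validObject(config)
  if (is.null(transition))
    transition <- buildTransitionMatrix(network, config@edgeClassWeights)
  ids <- transition@nodeIds
  s <- denseRestart(restart, ids)
  cc <- config@continueProb
  Wt <- Matrix::t(transition@W)
  dang <- transition@dangling
  r <- s
  trace <- numeric(0)
  converged <- FALSE
  iter <- 0L
  while (iter < config@maxIterations) {
    iter <- iter + 1L
    stepped <- as.numeric(Wt %*% r)
    if (any(dang)) stepped <- stepped + sum(r[dang]) * s
    rNew <- (1 - cc) * s + cc * stepped
    delta <- sum(abs(rNew - r))
    trace <- c(trace, delta)
    r <- rNew
    if (delta < config@tolerance) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("power iteration did not converge within ",
            config@maxIterations, " iterations (last L1 change ",
            format(trace[length(trace)], digits = 3), ")", call. = FALSE)
  r <- r / sum(r)
  new("DiffusionProfile",
      visitFrequency = stats::setNames(as.numeric(r), ids),
      entity = restart@label, iterationsUsed = iter,
      converged = converged, diagnostics = list(l1Trace = trace))
}

#' Solve the stationary diffusion profile exactly
#'
#' Direct sparse linear solve of `(I - c W'^T) r = (1 - c) s`, where
#' `W'` equals the transition matrix with dangling rows replaced by the
#' restart vector. Serves as the independent correctness oracle for
#' [computeDiffusionProfile()] on networks of moderate size.
#'
#' @inheritParams computeDiffusionProfile
#' @return A [DiffusionProfile-class] (`iterationsUsed = 0`,
#'   `converged = TRUE`).
#' @export
solveStationaryExact <- function(network, restart,
                                 config = diffusionConfig(),
                                 transition = NULL) {
  stopifnot(is(network, "MultiscaleNetwork"), is(restart, "RestartVector"),
            is(config, "DiffusionConfig"))
  if (is.null(transition))
    transition <- buildTransitionMatrix(network, config@edgeClassWeights)
  ids <- transition@nodeIds
  n <- length(ids)
  if (n > 2000L)
    stop("direct solve is limited to networks of <= 2000 nodes; ",
         "use computeDiffusionProfile()")
  s <- denseRestart(restart, ids)
  cc <- config@continueProb
  A <- Matrix::Diagonal(n) - cc * Matrix::t(transition@W)
  if (any(transition@dangling)) {
    d <- as.numeric(transition@dangling)
    A <- A - cc * Matrix::Matrix(s, ncol = 1) %*%
      Matrix::Matrix(d, nrow = 1)
  }
  r <- tryCatch(as.numeric(Matrix::solve(A, (1 - cc) * s)),
                error = function(e)
                  stop("stationary system is numerically singular: ",
                       conditionMessage(e), call. = FALSE))
  r <- r / sum(r)
  new("DiffusionProfile",
      visitFrequency = stats::setNames(r, ids),
      entity = restart@label, iterationsUsed = 0L, converged = TRUE,
      diagnostics = list(method = "direct_solve"))
}

#' Simulate a restarting random walker
#'
#' Runs an explicit walker for `nSteps` steps: at each step it restarts
#' with probability `1 - c` (or from a dangling node), otherwise it
#' steps to a neighbor with the biased edge-class probabilities. The
#' empirical visit frequencies converge to the diffusion profile;
#' per-node Monte-Carlo standard errors are estimated by batch means,
#' which accounts for the autocorrelation of consecutive positions.
#' Used as a sampling oracle against the matrix computations.
#'
#' @inheritParams computeDiffusionProfile
#' @param nSteps number of walker steps.
#' @param seed integer seed.
#' @param nBatches number of batches for the batch-means standard
#'   errors.
#' @return A list with `freq` (named empirical visit frequencies), `se`
#'   (named batch-means standard errors), `nSteps` and `nBatches`.
#' @export
simulateWalker <- function(network, restart, config = diffusionConfig(),
                           nSteps = 1e6, seed = 1L, transition = NULL,
                           nBatches = 100L) {
  stopifnot(is(network, "MultiscaleNetwork"), is(restart, "RestartVector"))
  if (is.null(transition))
    transition <- buildTransitionMatrix(network, config@edgeClassWeights)
  ids <- transition@nodeIds
  n <- length(ids)
  W <- transition@W
  cc <- config@continueProb
  ## per-node neighbor index lists and cumulative step probabilities
  Wt <- as(W, "TsparseMatrix")
  ord <- order(Wt@i)
  rowIdx <- Wt@i[ord] + 1L
  colIdx <- Wt@j[ord] + 1L
  vals <- Wt@x[ord]
  nbr <- split(colIdx, factor(rowIdx, levels = seq_len(n)))
  cum <- lapply(split(vals, factor(rowIdx, levels = seq_len(n))), cumsum)
  sIdx <- match(names(restart@entries), ids)
  sCum <- cumsum(unname(restart@entries))
  dang <- transition@dangling
  nSteps <- as.integer(nSteps)
  visits <- integer(nSteps)
  withSeed(seed, {
    uCont <- stats::runif(nSteps)
    uPick <- stats::runif(nSteps)
    cur <- sIdx[findInterval(stats::runif(1), sCum) + 1L]
    for (t in seq_len(nSteps)) {
      if (uCont[t] < cc && !dang[cur]) {
        cv <- cum[[cur]]
        cur <- nbr[[cur]][findInterval(uPick[t] * cv[length(cv)], cv) + 1L]
      } else {
        cur <- sIdx[findInterval(uPick[t], sCum) + 1L]
      }
      visits[t] <- cur
    }
  })
  freq <- tabulate(visits, nbins = n) / nSteps
  nBatches <- as.integer(nBatches)
  batch <- pmin((seq_len(nSteps) - 1L) %/% (nSteps %/% nBatches),
                nBatches - 1L)
  batchFreq <- vapply(split(visits, batch), function(v)
    tabulate(v, nbins = n) / length(v), numeric(n))
  bm <- apply(batchFreq, 1L, stats::sd)
  list(freq = stats::setNames(freq, ids),
       se = stats::setNames(bm / sqrt(nBatches), ids),
       nSteps = nSteps, nBatches = nBatches)
}

#' Pearson correlation of two diffusion profiles
#'
#' Correlates the full visit-frequency vectors of two profiles computed
#' on the same network (all nodes, aligned lexicographic order). A
#' zero-variance profile (e.g. perfectly uniform) has no defined
#' correlation and is an error.
#'
#' @param a,b [DiffusionProfile-class] objects on the same node
#'   universe.
#' @return Pearson correlation coefficient.
#' @export
correlateProfiles <- function(a, b) {
  stopifnot(is(a, "DiffusionProfile"), is(b, "DiffusionProfile"))
  if (!identical(names(visitFrequency(a)), names(visitFrequency(b))))
    stop("profiles are not on the same node universe")
  va <- visitFrequency(a)
  vb <- visitFrequency(b)
  if (stats::sd(va) == 0 || stats::sd(vb) == 0)
    stop("zero-variance profile: correlation undefined (",
         if (stats::sd(va) == 0) a@entity else b@entity, ")")
  stats::cor(va, vb)
}

#' Rank compounds by diffusion-profile correlation with a disease
#'
#' Scores every compound by the Pearson correlation of its diffusion
#' profile with the disease profile and sorts descending (ties broken
#' by compound id). Per-compound overlap test results can be merged in
#' to reproduce the usual prioritization-table shape (name, overlap
#' `k/n`, overlap p, correlation).
#'
#' @param profiles named list of compound [DiffusionProfile-class]
#'   objects.
#' @param diseaseProfile the disease [DiffusionProfile-class].
#' @param overlap optional data.frame with one row per compound
#'   (`compound`, `overlap_k`, `query_n`, `p_value`), e.g. built from
#'   [hypergeomOverlapTest()] results.
#' @return data.frame with columns `compound`, `correlation` (and the
#'   overlap columns when supplied), ordered by decreasing correlation.
#' @export
rankCompounds <- function(profiles, diseaseProfile, overlap = NULL) {
  if (!length(profiles)) stop("at least one compound profile is required")
  if (is.null(names(profiles)) || any(!nzchar(names(profiles))))
    stop("profiles must be a named list")
  out <- data.frame(
    compound = names(profiles),
    correlation = vapply(profiles, correlateProfiles, 1,
                         b = diseaseProfile),
    stringsAsFactors = FALSE)
  if (!is.null(overlap)) {
    out <- merge(out, overlap, by = "compound", all.x = TRUE, sort = FALSE)
  }
  out <- out[order(-out$correlation, out$compound), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a diffusion profile as TSV
#'
#' Columns: `node_id`, `node_class`, `visit_frequency`.
#'
#' @param profile a [DiffusionProfile-class].
#' @param network the [MultiscaleNetwork-class] it was computed on.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeDiffusionProfile <- function(profile, network, path) {
  v <- visitFrequency(profile)
  cls <- nodeClasses(network)
  writeTsv(data.frame(node_id = names(v),
                      node_class = unname(cls[names(v)]),
                      visit_frequency = sprintf("%.12g", unname(v)),
                      stringsAsFactors = FALSE), path)
}

#' Write a ranked-compound table as TSV
#'
#' Mirrors the usual prioritization-table layout: compound name,
#' overlap `k/n` with its hypergeometric p when available, and the
#' diffusion-profile correlation score.
#'
#' @param ranked data.frame from [rankCompounds()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeRankedCompounds <- function(ranked, path) {
  out <- data.frame(name = ranked$compound, stringsAsFactors = FALSE)
  if (all(c("overlap_k", "query_n", "p_value") %in% names(ranked))) {
    out$overlap <- sprintf("%d/%d", ranked$overlap_k, ranked$query_n)
    out$overlap_p <- sprintf("%.6g", ranked$p_value)
  }
  out$correlation <- sprintf("%.6f", ranked$correlation)
  writeTsv(out, path)
}
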