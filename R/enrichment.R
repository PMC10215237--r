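#' Read a GMT gene-set library
#'
#' Standard GMT layout: one set per line, tab-separated
#' `name  description  member1  member2 ...`.
#'
#' @param path GMT file path.
#' @param source label of the library source.
#' @return A [GeneSetLibrary-class].
#' @export
readGMT <- function(path, source = basename(path)) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(parts, length, 1L) < 3L
  if (any(bad))
    stop("malformed GMT line(s) (need name, description, >=1 member): ",
         paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) p[-(1:2)])
  names(sets) <- vapply(parts, `[[`, "", 1L)
  geneSetLibrary(sets, source = source)
}

#' Write a gene-set library as GMT
#'
#' @param library a [GeneSetLibrary-class].
#' @param path output path.
#' @param descriptions optional named character of per-set descriptions
#'   (defaults to the library source label).
#' @return Invisibly, the path.
#' @export
writeGMT <- function(library, path, descriptions = NULL) {
  stopifnot(is(library, "GeneSetLibrary"))
  sets <- geneSets(library)
  desc <- rep(library@source, length(sets))
  names(desc) <- names(sets)
  if (!is.null(descriptions))
    desc[names(descriptions)] <- descriptions
  writeLines(vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), ""), path)
  invisible(path)
}

hypergeomZ <- function(k, n, K, N) {
  mu <- n * K / N
  sigma2 <- n * (K / N) * (1 - K / N) * (N - n) / max(1, N - 1)
  if (sigma2 <= 0) return(NA_real_)
  (k - mu) / sqrt(sigma2)
}

#' Exact hypergeometric overlap test
#'
#' Tests whether the overlap between a query id set and a reference id
#' set is larger than expected when drawing `|query|` ids uniformly
#' without replacement from the background universe. The p-value is the
#' exact upper tail `P(X >= k)` with `N = |background|`,
#' `K = |reference` \eqn{\cap} `background|`, `n = |query|`,
#' `k = |query` \eqn{\cap} `reference|` - no normal approximation. Also
#' reports the hypergeometric z-score `(k - nK/N)/sigma` and the
#' Enrichr-style combined score `-ln(p) * z` (positive for enriched
#' sets).
#'
#' @param query character vector of query ids.
#' @param reference character vector of reference ids (e.g. disease
#'   proteins).
#' @param background character vector: the background universe.
#' @param name test label.
#' @param strict if `TRUE`, query ids outside the background are an
#'   error; otherwise they are dropped with a warning.
#' @return An [EnrichmentResult-class].
#' @examples
#' hypergeomOverlapTest(c("a", "b", "c"), c("a", "b", "d", "e"),
#'                      letters[1:10])
#' @export
hypergeomOverlapTest <- function(query, reference, background,
                                 name = "overlap", strict = FALSE) {
  background <- unique(as.character(background))
  if (!length(background)) stop("background must be nonempty")
  query <- unique(as.character(query))
  reference <- unique(as.character(reference))
  flags <- character(0)
  outside <- setdiff(query, background)
  if (length(outside)) {
    msg <- sprintf("%d query id(s) outside background: %s",
                   length(outside),
                   paste(head(outside, 5L), collapse = ", "))
    if (strict) stop(msg)
    warning(msg, call. = FALSE)
    query <- setdiff(query, outside)
    flags <- c(flags, "query_ids_dropped")
  }
  reference <- intersect(reference, background)
  N <- length(background)
  K <- length(reference)
  n <- length(query)
  members <- sort(intersect(query, reference))
  k <- length(members)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  z <- hypergeomZ(k, n, K, N)
  if (is.na(z)) {
    flags <- c(flags, "zero_variance_z_undefined")
    combined <- 0
  } else combined <- -log(p) * z
  new("EnrichmentResult", name = name, overlapK = k, queryN = n,
      setK = K, backgroundN = N, pValue = p, adjustedP = NA_real_,
      zScore = z, combinedScore = combined,
      foldEnrichment = NA_real_, empiricalP = NA_real_,
      overlapMembers = members, flags = flags)
}

#' Randomized fold-enrichment null for an observed overlap
#'
#' Repeatedly draws `|query|` ids uniformly without replacement from the
#' background and records the overlap with the reference set. Fold
#' enrichment is the observed overlap divided by the mean random
#' overlap; the empirical p-value uses the add-one correction
#' `(1 + #\{random >= observed\}) / (nIter + 1)` so it is never zero.
#' Deterministic under `seed`.
#'
#' @param query,reference,background character id vectors as in
#'   [hypergeomOverlapTest()].
#' @param nIter number of random draws (at least 100).
#' @param seed integer seed.
#' @return A list with `fold`, `empiricalP`, `observedOverlap`,
#'   `meanRandomOverlap`, `nIter` and `flags` (contains
#'   `"infinite_fold"` when the null mean is 0).
#' @export
monteCarloFoldEnrichment <- function(query, reference, background,
                                     nIter = 10000L, seed = 1L) {
  if (nIter < 100L) stop("nIter must be at least 100")
  background <- unique(as.character(background))
  query <- intersect(unique(as.character(query)), background)
  reference <- intersect(unique(as.character(reference)), background)
  N <- length(background)
  n <- length(query)
  observed <- length(intersect(query, reference))
  isRef <- background %in% reference
  draws <- withSeed(seed, vapply(seq_len(nIter), function(i)
    sum(isRef[sample.int(N, n)]), 1L))
  m <- mean(draws)
  flags <- character(0)
  fold <- if (m == 0) {
    flags <- c(flags, "infinite_fold")
    Inf
  } else observed / m
  list(fold = fold,
       empiricalP = (1 + sum(draws >= observed)) / (nIter + 1),
       observedOverlap = observed, meanRandomOverlap = m,
       nIter = as.integer(nIter), flags = flags)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @return Adjusted p-values (monotone, capped at 1, elementwise >= raw).
#' @export
bhAdjust <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pValues, method = "BH")
}

#' Bonferroni adjustment
#'
#' @param pValues numeric vector of raw p-values in (0, 1].
#' @return `min(1, m * p)` per element.
#' @export
bonferroniAdjust <- function(pValues) {
  if (any(is.na(pValues)) || any(pValues <= 0) || any(pValues > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(pValues, method = "bonferroni")
}

#' Pathway over-representation analysis
#'
#' Runs one exact hypergeometric overlap test per library set against
#' the background universe, computes per-set z and combined scores,
#' adjusts p-values for multiplicity, and returns a table sorted by
#' adjusted p then set name.
#'
#' @param query character vector of query ids (e.g. key targets).
#' @param library a [GeneSetLibrary-class].
#' @param background character vector: the background universe.
#' @param correction `"bh"` (Benjamini-Hochberg, default) or
#'   `"bonferroni"`.
#' @return data.frame with columns `name`, `overlap_k`, `set_K`,
#'   `query_n`, `background_N`, `p_value`, `adjusted_p`, `z_score`,
#'   `combined_score`, `overlap_members` (semicolon-joined), `flags`;
#'   the correction used is recorded in the `"correction"` attribute.
#' @export
pathwayORA <- function(query, library, background,
                       correction = c("bh", "bonferroni")) {
  stopifnot(is(library, "GeneSetLibrary"))
  correction <- match.arg(correction)
  sets <- geneSets(library)
  if (!length(sets)) stop("gene-set library is empty")
  background <- unique(as.character(background))
  query <- unique(as.character(query))
  dropped <- setdiff(query, background)
  if (length(dropped)) {
    warning(sprintf("%d query id(s) outside background dropped",
                    length(dropped)), call. = FALSE)
    query <- setdiff(query, dropped)
  }
  res <- lapply(names(sets), function(nm)
    hypergeomOverlapTest(query, sets[[nm]], background, name = nm))
  p <- vapply(res, function(r) r@pValue, 1)
  adj <- switch(correction, bh = bhAdjust(p), bonferroni = bonferroniAdjust(p))
  out <- data.frame(
    name = names(sets),
    overlap_k = vapply(res, function(r) r@overlapK, 1L),
    set_K = vapply(res, function(r) r@setK, 1L),
    query_n = vapply(res, function(r) r@queryN, 1L),
    background_N = vapply(res, function(r) r@backgroundN, 1L),
    p_value = p,
    adjusted_p = adj,
    z_score = vapply(res, function(r) r@zScore, 1),
    combined_score = vapply(res, function(r) r@combinedScore, 1),
    overlap_members = vapply(res, function(r)
      paste(r@overlapMembers, collapse = ";"), ""),
    flags = vapply(res, function(r) paste(r@flags, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  out <- out[order(out$adjusted_p, out$name), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "correction") <- correction
  out
}

#' Write an over-representation result table
#'
#' TSV mirroring the usual enrichment-report layout: term, overlap
#' `k/K`, raw and adjusted p (the header names the correction), combined
#' score and the overlapping genes.
#'
#' @param ora data.frame from [pathwayORA()].
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeEnrichmentTable <- function(ora, path) {
  correction <- attr(ora, "correction")
  label <- switch(correction %||% "bh",
                  bh = "adjusted_p_bh", bonferroni = "adjusted_p_bonferroni")
  out <- data.frame(
    term = ora$name,
    overlap = sprintf("%d/%d", ora$overlap_k, ora$set_K),
    p_value = ora$p_value,
    adjusted = ora$adjusted_p,
    combined_score = ora$combined_score,
    genes = ora$overlap_members,
    stringsAsFactors = FALSE)
  names(out)[4] <- label
  writeTsv(out, path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
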