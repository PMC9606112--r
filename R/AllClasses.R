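#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

.check_canonical_keys <- function(keys, k, max_check = 5000L) {
  if (length(keys) == 0L) return(TRUE)
  if (any(nchar(keys) != k))
    return(sprintf("all k-mers must have length %d", k))
  # full canonicality check is O(total bases); bound it for huge tables
  probe <- if (length(keys) > max_check) keys[seq_len(max_check)] else keys
  canon <- cpp_canonical(probe)
  if (anyNA(canon))
    return("k-mers must contain only A, C, G, T")
  if (!identical(canon, unname(probe)))
    return("k-mers must be canonical (lexicographically <= reverse complement)")
  TRUE
}

#' KmerCountTable: canonical k-mer occurrence counts for one sample
#'
#' Holds the counts of canonical k-mers (each key is the lexicographic
#' minimum of a k-mer and its reverse complement) observed in the reads
#' of one sex/sample, after a minimum-occurrence cutoff. The alphabet is
#' restricted to A, C, G, T; k-mers overlapping any other symbol are
#' never stored.
#'
#' @slot k k-mer length in bp.
#' @slot counts named integer vector, canonical k-mer -> count (>= 1).
#' @slot sourceLabel free-text label (species, sex, file of origin).
#' @slot nSkipped number of k-mer windows skipped because they
#'   overlapped an ambiguous base.
#' @aliases KmerCountTable
#' @exportClass KmerCountTable
setClass("KmerCountTable",
  representation(k = "integer", counts = "integer", sourceLabel = "character",
                 nSkipped = "numeric"),
  prototype(k = 22L, counts = integer(0), sourceLabel = "", nSkipped = 0))

setValidity("KmerCountTable", function(object) {
  msgs <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msgs <- c(msgs, "k must be a single positive integer")
  if (length(object@counts) > 0 && is.null(names(object@counts)))
    msgs <- c(msgs, "counts must be named by k-mer")
  if (any(object@counts < 1L))
    msgs <- c(msgs, "all counts must be >= 1")
  if (anyDuplicated(names(object@counts)))
    msgs <- c(msgs, "k-mer keys must be unique")
  ck <- .check_canonical_keys(names(object@counts), object@k)
  if (!isTRUE(ck)) msgs <- c(msgs, ck)
  if (length(msgs)) msgs else TRUE
})

#' KmerSet: a duplicate-free set of canonical k-mers
#'
#' @slot k k-mer length in bp.
#' @slot members character vector of canonical k-mers (sorted, unique).
#' @slot label free-text label (e.g. "male-specific").
#' @aliases KmerSet
#' @exportClass KmerSet
setClass("KmerSet",
  representation(k = "integer", members = "character", label = "character"),
  prototype(k = 22L, members = character(0), label = ""))

setValidity("KmerSet", function(object) {
  msgs <- character(0)
  if (length(object@k) != 1L || is.na(object@k) || object@k < 1L)
    msgs <- c(msgs, "k must be a single positive integer")
  if (anyDuplicated(object@members))
    msgs <- c(msgs, "members must be duplicate-free")
  ck <- .check_canonical_keys(object@members, object@k)
  if (!isTRUE(ck)) msgs <- c(msgs, ck)
  if (length(msgs)) msgs else TRUE
})

#' ReferenceIndex: exact-position lookup of reference k-mers
#'
#' A hash-style index of every canonical k-mer of a reference assembly,
#' storing the first occurrence (linkage group and 0-based start) and a
#' multiplicity flag for k-mers seen at more than one locus or strand
#' context. Serves as a fast surrogate for a short-read BLAST database.
#'
#' @slot k k-mer length.
#' @slot lgLengths named numeric vector, linkage-group name -> length bp.
#' @slot kmers character vector of canonical k-mers (sorted).
#' @slot lg integer index into `names(lgLengths)` per k-mer.
#' @slot start 0-based start position per k-mer.
#' @slot multi logical; TRUE when the k-mer occurs at >1 locus.
#' @aliases ReferenceIndex
#' @exportClass ReferenceIndex
setClass("ReferenceIndex",
  representation(k = "integer", lgLengths = "numeric", kmers = "character",
                 lg = "integer", start = "integer", multi = "logical"))

setValidity("ReferenceIndex", function(object) {
  msgs <- character(0)
  n <- length(object@kmers)
  if (length(object@lg) != n || length(object@start) != n ||
      length(object@multi) != n)
    msgs <- c(msgs, "kmers, lg, start and multi must be parallel vectors")
  if (is.null(names(object@lgLengths)) && length(object@lgLengths) > 0)
    msgs <- c(msgs, "lgLengths must be named")
  if (n > 0) {
    len <- unname(object@lgLengths[object@lg])
    bad <- object@start < 0 | object@start > len - object@k
    if (any(bad)) msgs <- c(msgs, "k-mer start positions must lie within their linkage group")
  }
  if (length(msgs)) msgs else TRUE
})

#' SexCall: the called sex linkage group and system
#'
#' @slot lg linkage-group name, or NA when no call is made.
#' @slot system "XY", "ZW" or "none".
#' @slot fold enrichment fold (normalized count over the median across
#'   linkage groups) supporting the call.
#' @slot folds per-sex, per-LG fold table used for the call.
#' @aliases SexCall
#' @exportClass SexCall
setClass("SexCall",
  representation(lg = "character", system = "character", fold = "numeric",
                 folds = "data.frame"))

#' SharedKmerTable: cross-species sex-specific k-mer sharing
#'
#' The four intersection sizes between the male- and female-specific
#' k-mer sets of two species, optionally restricted to k-mers placed on
#' one linkage group.
#'
#' @slot speciesA,speciesB species labels.
#' @slot counts named numeric of length 4: `mm` (A male x B male),
#'   `mf` (A male x B female), `fm` (A female x B male),
#'   `ff` (A female x B female).
#' @slot lg restriction linkage group, or NA.
#' @aliases SharedKmerTable
#' @exportClass SharedKmerTable
setClass("SharedKmerTable",
  representation(speciesA = "character", speciesB = "character",
                 counts = "numeric", lg = "character"))

setValidity("SharedKmerTable", function(object) {
  if (!identical(sort(names(object@counts)), sort(c("mm", "mf", "fm", "ff"))))
    return("counts must be named mm, mf, fm, ff")
  if (any(object@counts < 0)) return("intersection sizes must be >= 0")
  TRUE
})

#' PolarityCall: inferred direction of a sex-chromosome turnover
#'
#' @slot ancestralSystem "XY", "ZW" or "indeterminate".
#' @slot narrative human-readable statement of the inferred scenario.
#' @slot maxCell,runnerUp gametolog-pair labels of the largest and
#'   second-largest sharing cells (e.g. "W:X").
#' @slot dominance ratio of the largest to the second-largest cell
#'   (>= 1 whenever defined).
#' @aliases PolarityCall
#' @exportClass PolarityCall
setClass("PolarityCall",
  representation(ancestralSystem = "character", narrative = "character",
                 maxCell = "character", runnerUp = "character",
                 dominance = "numeric"))

#' ChromScreenResult: chromosome-level screen of log2(XY:ZW) windows
#'
#' @slot kw list with the Kruskal-Wallis `H`, `df`, `p` and `pAdj`.
#' @slot dunn data.frame of pairwise Dunn results (group1, group2, z,
#'   p, pAdj), BH-corrected across all pairs.
#' @slot medianRank named numeric, per-LG median of genome-wide window
#'   ranks (ties broken in input order).
#' @slot nWindows total number of windows screened.
#' @aliases ChromScreenResult
#' @exportClass ChromScreenResult
setClass("ChromScreenResult",
  representation(kw = "list", dunn = "data.frame", medianRank = "numeric",
                 nWindows = "integer"))

#' SimTruth: ground truth of a simulated sex-determining region
#'
#' @slot system "XY" or "ZW".
#' @slot lg linkage group carrying the planted region.
#' @slot regionStart,regionEnd 0-based half-open bounds of the region.
#' @slot divergence substitutions per bp between the gametologs.
#' @slot snpPositions 0-based positions of the planted substitutions.
#' @slot seed seed used by the generator.
#' @aliases SimTruth
#' @exportClass SimTruth
setClass("SimTruth",
  representation(system = "character", lg = "character",
                 regionStart = "numeric", regionEnd = "numeric",
                 divergence = "numeric", snpPositions = "numeric",
                 seed = "integer"))

setValidity("SimTruth", function(object) {
  msgs <- character(0)
  if (!object@system %in% c("XY", "ZW"))
    msgs <- c(msgs, "system must be XY or ZW")
  if (object@regionStart >= object@regionEnd)
    msgs <- c(msgs, "region must be non-empty (start < end)")
  if (object@divergence < 0 || object@divergence > 0.2)
    msgs <- c(msgs, "divergence must lie in [0, 0.2]")
  if (length(object@snpPositions) &&
      (min(object@snpPositions) < object@regionStart ||
       max(object@snpPositions) >= object@regionEnd))
    msgs <- c(msgs, "all planted positions must lie inside the region")
  if (length(msgs)) msgs else TRUE
})
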