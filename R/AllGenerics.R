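#' Accessors for k-mer containers
#'
#' `kmerSize()` returns the k-mer length; `kmers()` the canonical k-mer
#' strings; `kmerCounts()` the named count vector of a
#' [KmerCountTable]; `sourceLabel()` the free-text label.
#'
#' @param x a `KmerCountTable`, `KmerSet` or `ReferenceIndex`.
#' @return See the individual descriptions.
#' @name kmer-accessors
#' @examples
#' tab <- countKmers(c("AAAAA"), k = 4, minCount = 2)
#' kmerSize(tab)
#' kmerCounts(tab)
NULL

#' @rdname kmer-accessors
#' @export
setGeneric("kmerSize", function(x) standardGeneric("kmerSize"))

#' @rdname kmer-accessors
#' @export
setGeneric("kmers", function(x) standardGeneric("kmers"))

#' @rdname kmer-accessors
#' @export
setGeneric("kmerCounts", function(x) standardGeneric("kmerCounts"))

#' @rdname kmer-accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))

#' @rdname kmer-accessors
#' @export
setMethod("kmerSize", "KmerCountTable", function(x) x@k)
#' @rdname kmer-accessors
#' @export
setMethod("kmerSize", "KmerSet", function(x) x@k)
#' @rdname kmer-accessors
#' @export
setMethod("kmerSize", "ReferenceIndex", function(x) x@k)

#' @rdname kmer-accessors
#' @export
setMethod("kmers", "KmerCountTable", function(x) names(x@counts))
#' @rdname kmer-accessors
#' @export
setMethod("kmers", "KmerSet", function(x) x@members)
#' @rdname kmer-accessors
#' @export
setMethod("kmers", "ReferenceIndex", function(x) x@kmers)

#' @rdname kmer-accessors
#' @export
setMethod("kmerCounts", "KmerCountTable", function(x) x@counts)

#' @rdname kmer-accessors
#' @export
setMethod("sourceLabel", "KmerCountTable", function(x) x@sourceLabel)
#' @rdname kmer-accessors
#' @export
setMethod("sourceLabel", "KmerSet", function(x) x@label)

#' @describeIn kmer-accessors number of stored k-mers
#' @export
setMethod("length", "KmerSet", function(x) length(x@members))
#' @rdname kmer-accessors
#' @export
setMethod("length", "KmerCountTable", function(x) length(x@counts))

#' Linkage-group lengths of a reference index
#' @param x a `ReferenceIndex`.
#' @return named numeric vector of linkage-group lengths in bp.
#' @export
setGeneric("lgLengths", function(x) standardGeneric("lgLengths"))

#' @rdname lgLengths
#' @export
setMethod("lgLengths", "ReferenceIndex", function(x) x@lgLengths)

setMethod("show", "KmerCountTable", function(object) {
  cat(sprintf("KmerCountTable | k = %d | %s distinct k-mers | label: %s\n",
              object@k, format(length(object@counts), big.mark = ","),
              if (nzchar(object@sourceLabel)) object@sourceLabel else "<none>"))
  if (object@nSkipped > 0)
    cat(sprintf("  (%s ambiguous k-mer windows skipped)\n",
                format(object@nSkipped, big.mark = ",")))
})

setMethod("show", "KmerSet", function(object) {
  cat(sprintf("KmerSet | k = %d | %s members | label: %s\n",
              object@k, format(length(object@members), big.mark = ","),
              if (nzchar(object@label)) object@label else "<none>"))
})

setMethod("show", "ReferenceIndex", function(object) {
  cat(sprintf("ReferenceIndex | k = %d | %d linkage groups (%s bp) | %s k-mers | %s multi-locus\n",
              object@k, length(object@lgLengths),
              format(sum(object@lgLengths), big.mark = ","),
              format(length(object@kmers), big.mark = ","),
              format(sum(object@multi), big.mark = ",")))
})

setMethod("show", "SexCall", function(object) {
  if (object@system == "none") {
    cat("SexCall: no linkage group reaches the enrichment threshold (system: none)\n")
  } else {
    cat(sprintf("SexCall: %s system on %s (enrichment fold %.1f over the LG median)\n",
                object@system, object@lg, object@fold))
  }
})

setMethod("show", "SharedKmerTable", function(object) {
  cat(sprintf("Shared sex-specific k-mers: %s vs %s%s\n", object@speciesA,
              object@speciesB,
              if (!is.na(object@lg)) sprintf(" (restricted to %s)", object@lg) else ""))
  m <- matrix(object@counts[c("mm", "mf", "fm", "ff")][c(1, 2, 3, 4)],
              nrow = 2, byrow = TRUE,
              dimnames = list(paste(object@speciesA, c("male", "female")),
                              paste(object@speciesB, c("male", "female"))))
  print(m)
})

setMethod("show", "PolarityCall", function(object) {
  cat(sprintf("PolarityCall: %s\n  ancestral system: %s\n  largest cell: %s; runner-up: %s; dominance %.2f\n",
              object@narrative, object@ancestralSystem, object@maxCell,
              object@runnerUp, object@dominance))
})

.format_p <- function(p) {
  # conventional floor in printed output; full precision kept in slots/TSV
  ifelse(p < 2.2e-16, "< 2.2e-16", sprintf("= %.4g", p))
}

setMethod("show", "ChromScreenResult", function(object) {
  cat(sprintf("Chromosome screen over %d windows\n", object@nWindows))
  cat(sprintf("  Kruskal-Wallis: H = %.3f, df = %d, p %s\n",
              object@kw$H, object@kw$df, .format_p(object@kw$p)))
  sig <- object@dunn[object@dunn$pAdj < 0.05, , drop = FALSE]
  cat(sprintf("  Dunn's post-hoc: %d of %d pairs significant at BH 0.05\n",
              nrow(sig), nrow(object@dunn)))
  mr <- sort(object@medianRank, decreasing = TRUE)
  top <- utils::head(mr, 3)
  cat("  top median ranks:",
      paste(sprintf("%s (%.1f)", names(top), top), collapse = ", "), "\n")
})

setMethod("show", "SimTruth", function(object) {
  cat(sprintf("SimTruth: %s system on %s, region [%s, %s), d = %g, %d planted SNPs (seed %d)\n",
              object@system, object@lg,
              format(object@regionStart, big.mark = ","),
              format(object@regionEnd, big.mark = ","),
              object@divergence, length(object@snpPositions), object@seed))
})
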