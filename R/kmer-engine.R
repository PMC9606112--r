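#' Canonicalize k-mers
#'
#' Returns, for each input sequence, the lexicographic minimum of the
#' sequence and its reverse complement, uppercased. Canonical k-mers
#' make counting strand-independent: a k-mer and its reverse complement
#' always collapse to the same key.
#'
#' @param seq character vector of DNA strings (A/C/G/T, case
#'   insensitive). Strings containing any other symbol yield `NA` (the
#'   caller is expected to skip them).
#' @return character vector of canonical k-mers; `NA` for rejected
#'   inputs.
#' @examples
#' canonicalKmer(c("AAAC", "TTTT", "ACGT"))
#' @export
canonicalKmer <- function(seq) {
  if (!is.character(seq)) seq <- as.character(seq)
  out <- cpp_canonical(seq)
  if (anyNA(out[!is.na(seq)]))
    warning("sequences with non-ACGT symbols were rejected (NA)")
  out
}

#' Count canonical k-mers in reads
#'
#' Slides a window of `k` bp over every read, canonicalizes each k-mer
#' (so both strands aggregate into one key), and keeps k-mers seen at
#' least `minCount` times. The default cutoff of 2 discards
#' single-occurrence k-mers that are likely sequencing errors; the
#' default `k = 22` suits low-coverage (6-20x) short-read data, where
#' longer k-mers lose too many true k-mers to errors. Windows
#' overlapping an ambiguous base (N etc.) are skipped and tallied in
#' the returned object.
#'
#' @param reads character vector of read sequences, a `DNAStringSet`,
#'   or paths to FASTA/FASTQ files (gzip accepted).
#' @param k k-mer length in bp (1-32). Default 22.
#' @param minCount minimum occurrences for a k-mer to be kept.
#'   Default 2.
#' @param sourceLabel free-text label stored with the table.
#' @return a [KmerCountTable].
#' @examples
#' countKmers("AAAAA", k = 4, minCount = 2)     # both 4-mers canonicalize to AAAA
#' countKmers("ACGTA", k = 4, minCount = 1)
#' @export
countKmers <- function(reads, k = 22L, minCount = 2L, sourceLabel = "") {
  if (length(k) != 1L || is.na(k) || k <= 0)
    stop("k must be a positive integer")
  if (k > 32) stop("k must be <= 32 (k-mers are packed into 64-bit words)")
  .assert_scalar_number(minCount, "minCount", lower = 1)
  reads <- .as_dna_reads(reads)
  k <- as.integer(k)
  if (length(reads) == 0 || all(nchar(reads) < k, na.rm = TRUE)) {
    warning("k exceeds every read length; returning an empty table")
    return(new("KmerCountTable", k = k, counts = integer(0),
               sourceLabel = sourceLabel, nSkipped = 0))
  }
  res <- cpp_count_kmers(reads, k, as.integer(minCount))
  counts <- res$counts
  names(counts) <- res$kmers
  new("KmerCountTable", k = k, counts = counts, sourceLabel = sourceLabel,
      nSkipped = res$n_skipped)
}

#' Read an external k-mer dump
#'
#' Loads k-mer counts produced by an external counter. Two dialects are
#' auto-detected from the first byte: FASTA-style dumps (header line is
#' the count, sequence line is the k-mer; first byte `>`), and
#' two-column text (`KMER COUNT` per line). Keys are canonicalized on
#' load; counts of keys that collide after canonicalization are summed.
#'
#' @param path dump file.
#' @param expectedK optional k; an error is raised on mismatch.
#' @param sourceLabel label stored with the table (defaults to the
#'   file name).
#' @return a [KmerCountTable].
#' @export
readKmerDump <- function(path, expectedK = NULL, sourceLabel = basename(path)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty k-mer dump: ", path)
  if (startsWith(lines[1], ">")) {
    if (length(lines) %% 2 != 0)
      stop("malformed FASTA-style dump (odd number of lines): ", path)
    hdr <- lines[seq(1, length(lines), by = 2)]
    seqs <- lines[seq(2, length(lines), by = 2)]
    counts <- suppressWarnings(as.numeric(sub("^>", "", hdr)))
    if (anyNA(counts)) {
      bad <- which(is.na(counts))[1]
      stop(sprintf("non-numeric count in dump header at line %d", 2L * bad - 1L))
    }
    seq_lines <- seq(2, length(lines), by = 2)
  } else {
    parts <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(parts)
    if (any(nf != 2)) {
      bad <- which(nf != 2)[1]
      stop(sprintf("expected two fields (KMER COUNT) at line %d", bad))
    }
    seqs <- vapply(parts, `[`, "", 1L)
    counts <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
    if (anyNA(counts)) {
      bad <- which(is.na(counts))[1]
      stop(sprintf("non-integer count at line %d", bad))
    }
    seq_lines <- seq_along(lines)
  }
  k <- nchar(seqs[1])
  if (any(nchar(seqs) != k)) {
    bad <- which(nchar(seqs) != k)[1]
    stop(sprintf("mixed k-mer lengths in dump: line %d has length %d, expected %d",
                 seq_lines[bad], nchar(seqs[bad]), k))
  }
  if (!is.null(expectedK) && k != expectedK)
    stop(sprintf("dump contains %d-mers but expectedK = %d", k, expectedK))
  canon <- cpp_canonical(seqs)
  if (anyNA(canon)) {
    bad <- which(is.na(canon))[1]
    stop(sprintf("non-ACGT k-mer at line %d", seq_lines[bad]))
  }
  agg <- rowsum(counts, canon)
  counts <- as.integer(agg[, 1])
  names(counts) <- rownames(agg)
  ord <- order(names(counts), method = "radix")
  new("KmerCountTable", k = as.integer(k), counts = counts[ord],
      sourceLabel = sourceLabel, nSkipped = 0)
}

#' Write a k-mer count table as a two-column dump
#'
#' @param table a [KmerCountTable].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeKmerDump <- function(table, path) {
  stopifnot(is(table, "KmerCountTable"))
  writeLines(paste(names(table@counts), table@counts), path)
  invisible(path)
}

.kmer_keys <- function(x) {
  if (is(x, "KmerCountTable")) names(x@counts)
  else if (is(x, "KmerSet")) x@members
  else stop("expected a KmerCountTable or KmerSet")
}

#' Sex-specific k-mer sets by pairwise subtraction
#'
#' Compares two k-mer tables (or sets) and returns the k-mers private
#' to each: `aOnly` holds keys of `a` absent from `b`, and vice versa.
#' This is the core reference-free step: applied to the per-sex k-mer
#' tables of one species, the private sets are the sex-specific k-mers.
#' Implemented as a merge over lexicographically sorted keys.
#'
#' @param a,b [KmerCountTable] or [KmerSet] objects with equal `k`.
#' @param labels character(2), labels for the two output sets.
#' @return list with [KmerSet] elements `aOnly` and `bOnly`.
#' @examples
#' m <- countKmers("ACGTACCA", k = 4, minCount = 1)
#' f <- countKmers("ACGTAGGA", k = 4, minCount = 1)
#' diffKmerSets(m, f)
#' @export
diffKmerSets <- function(a, b, labels = c("a-only", "b-only")) {
  ka <- kmerSize(a); kb <- kmerSize(b)
  if (ka != kb) stop(sprintf("k mismatch: %d vs %d", ka, kb))
  res <- cpp_kmer_setdiff(.kmer_keys(a), .kmer_keys(b), ka)
  list(aOnly = new("KmerSet", k = ka, members = res$a_only, label = labels[1]),
       bOnly = new("KmerSet", k = ka, members = res$b_only, label = labels[2]))
}

#' Random subsample of a k-mer set
#'
#' Draws a uniform sample without replacement of `min(n, length(s))`
#' members. The draw is a deterministic function of (`seed`, set
#' content, `n`): members are sorted before sampling, so the result
#' does not depend on storage order. Matches the downstream convention
#' of mapping a fixed-size random subset (default one million) of each
#' sex-specific set.
#'
#' @param s a [KmerSet].
#' @param n sample size (>= 0).
#' @param seed integer seed (required, for reproducibility).
#' @return a [KmerSet] with at most `n` members.
#' @export
sampleKmers <- function(s, n = 1e6, seed) {
  stopifnot(is(s, "KmerSet"))
  if (length(n) != 1L || is.na(n) || n < 0) stop("n must be >= 0")
  if (missing(seed)) stop("a seed is required for reproducible sampling")
  members <- sort(s@members, method = "radix")
  take <- min(n, length(members))
  picked <- with_seed(seed, sample.int(length(members), take))
  new("KmerSet", k = s@k, members = sort(members[picked], method = "radix"),
      label = s@label)
}

#' Core k-mers shared by all species with one system
#'
#' Intersects the sex-specific k-mer sets of several species that carry
#' the same sex-chromosome system. The resulting "core" set localizes
#' the shared ancestral differentiated interval once placed on a
#' reference.
#'
#' @param sets list of [KmerSet] objects with equal `k` (length >= 1).
#' @param label label for the output set.
#' @return a [KmerSet].
#' @export
intersectCore <- function(sets, label = "core") {
  if (!is.list(sets) || length(sets) == 0)
    stop("sets must be a non-empty list of KmerSet objects")
  ks <- vapply(sets, kmerSize, integer(1))
  if (length(unique(ks)) != 1) stop("all sets must share the same k")
  members <- Reduce(intersect, lapply(sets, kmers))
  new("KmerSet", k = ks[1],
      members = sort(members, method = "radix"), label = label)
}

#' Write / read a k-mer set as sorted one-per-line text
#'
#' The stable sorted layout makes set files diffable across runs.
#'
#' @param s a [KmerSet].
#' @param path file path.
#' @return `writeKmerSet`: `path` invisibly; `readKmerSet`: a [KmerSet].
#' @export
writeKmerSet <- function(s, path) {
  stopifnot(is(s, "KmerSet"))
  writeLines(sort(s@members, method = "radix"), path)
  invisible(path)
}

#' @rdname writeKmerSet
#' @param label label for the loaded set.
#' @export
readKmerSet <- function(path, label = basename(path)) {
  members <- readLines(path)
  members <- members[nzchar(members)]
  k <- if (length(members)) nchar(members[1]) else 22L
  new("KmerSet", k = as.integer(k),
      members = sort(unique(members), method = "radix"), label = label)
}
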