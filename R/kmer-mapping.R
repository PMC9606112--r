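#' Index a reference assembly for k-mer placement
#'
#' Records every canonical k-mer of the reference with its first
#' occurrence (linkage group, 0-based start) and a multiplicity flag.
#' The index plays the role of a short-read BLAST database: querying it
#' (see [mapKmers]) places 22-mers essentially as a `blastn-short`
#' search with a single best hit per query would. K-mers spanning
#' ambiguous bases are absent from the index.
#'
#' @param reference FASTA path or `DNAStringSet` of linkage-group
#'   sequences.
#' @param k k-mer length (1-32). Default 22.
#' @return a [ReferenceIndex].
#' @export
indexReference <- function(reference, k = 22L) {
  if (is.character(reference)) {
    if (!file.exists(reference)) stop("reference FASTA not found: ", reference)
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (!is(reference, "DNAStringSet"))
    stop("reference must be a FASTA path or a DNAStringSet")
  if (length(reference) == 0) stop("empty reference: no sequences")
  if (k < 1 || k > 32) stop("k must be between 1 and 32")
  k <- as.integer(k)
  nm <- names(reference)
  if (is.null(nm)) nm <- paste0("seq", seq_along(reference))
  nm <- sub("\\s.*$", "", nm)   # FASTA headers: keep the first token
  res <- cpp_index_reference(as.character(reference), k)
  lens <- stats::setNames(as.numeric(Biostrings::width(reference)), nm)
  new("ReferenceIndex", k = k, lgLengths = lens, kmers = res$kmer,
      lg = res$lg, start = res$start, multi = res$multi)
}

.hits_granges <- function(idx, rows, queries, mismatches, excludeMulti) {
  lgn <- names(idx@lgLengths)
  keep <- !is.na(rows)
  if (excludeMulti) keep <- keep & !idx@multi[rows]
  rows <- rows[keep]
  gr <- GenomicRanges::GRanges(
    seqnames = factor(lgn[idx@lg[rows]], levels = lgn),
    ranges = IRanges::IRanges(start = idx@start[rows] + 1L,
                              width = idx@k),
    seqlengths = idx@lgLengths)
  S4Vectors::mcols(gr)$kmer <- queries[keep]
  S4Vectors::mcols(gr)$score <- idx@k - mismatches[keep]
  S4Vectors::mcols(gr)$multi <- idx@multi[rows]
  list(gr = gr, keep = keep)
}

#' Place sex-specific k-mers on a reference
#'
#' Looks every query k-mer up in a [ReferenceIndex], keeping at most
#' one (best) location per query, and counts queries with no placement
#' as unmapped. Unmapped queries correspond to sequence diverged from
#' or absent in the reference. An exact match is tried first; with
#' `maxMismatch = 1` (the default) single-base substitution neighbours
#' are then tried in a fixed order, which recovers k-mers that differ
#' from the reference by the one variant that made them sex-specific
#' (`blastn-short` tolerates such mismatches). `maxMismatch = 0` gives
#' pure exact matching.
#'
#' Multi-locus k-mers are placed once, at their first reference
#' occurrence (mirroring a best-hit-only BLAST search); set
#' `excludeMulti = TRUE` to drop them instead.
#'
#' @param s a [KmerSet] of queries (same `k` as the index).
#' @param idx a [ReferenceIndex].
#' @param maxMismatch 0 or 1 substitutions tolerated. Default 1.
#' @param excludeMulti drop hits whose k-mer occurs at more than one
#'   reference locus. Default FALSE.
#' @return list with `hits` (a `GRanges`; metadata columns `kmer`,
#'   `score` = matching bases, `multi`) and `unmapped` (count of
#'   queries without a placement, including any multi-locus queries
#'   dropped by `excludeMulti`).
#' @export
mapKmers <- function(s, idx, maxMismatch = 1L, excludeMulti = FALSE) {
  stopifnot(is(s, "KmerSet"), is(idx, "ReferenceIndex"))
  if (s@k != idx@k)
    stop(sprintf("k mismatch: query set has k = %d, index k = %d", s@k, idx@k))
  if (!maxMismatch %in% c(0L, 1L))
    stop("maxMismatch must be 0 or 1")
  res <- cpp_lookup_kmers(s@members, idx@kmers, idx@k, as.integer(maxMismatch))
  out <- .hits_granges(idx, res$row, s@members, res$mismatches, excludeMulti)
  list(hits = out$gr, unmapped = length(s@members) - sum(out$keep))
}

#' Import BLAST tabular hits (outfmt 6)
#'
#' Reads a 12-column BLAST tabular file of k-mer queries against a
#' reference, keeps per query the single row with the highest bit-score
#' that passes the identity and alignment-length filters (ties resolved
#' by file order, as BLAST emits the best hit first), and converts the
#' 1-based subject coordinates to plus-strand intervals (sstart/send
#' swapped when the hit is on the minus strand). This is the fidelity
#' path for users who ran real BLAST instead of the built-in lookup.
#'
#' @param path BLAST outfmt 6 file (qseqid sseqid pident length
#'   mismatch gapopen qstart qend sstart send evalue bitscore).
#' @param lgLengths optional named lengths to attach as seqinfo.
#' @param minIdentity minimum percent identity. Default 90.
#' @param minAlignLen minimum alignment length in bp. Default 16.
#' @return a `GRanges` with metadata columns `kmer`, `identity`,
#'   `alignLen`, `bitScore`.
#' @export
importBlastHits <- function(path, lgLengths = NULL, minIdentity = 90,
                            minAlignLen = 16) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12)) {
    bad <- which(nf != 12)[1]
    stop(sprintf("malformed BLAST tabular row at line %d: %d fields (expected 12)",
                 bad, nf[bad]))
  }
  tab <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(tab) <- cols
  num <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
           "sstart", "send", "evalue", "bitscore")
  for (cn in num) {
    v <- suppressWarnings(as.numeric(tab[[cn]]))
    if (anyNA(v))
      stop(sprintf("non-numeric '%s' at line %d", cn, which(is.na(v))[1]))
    tab[[cn]] <- v
  }
  tab <- tab[tab$pident >= minIdentity & tab$length >= minAlignLen, ,
             drop = FALSE]
  if (nrow(tab)) {
    # best bit-score per query; first row wins on ties (file order)
    ord <- order(match(tab$qseqid, unique(tab$qseqid)), -tab$bitscore)
    tab <- tab[ord, , drop = FALSE]
    tab <- tab[!duplicated(tab$qseqid), , drop = FALSE]
  }
  lo <- pmin(tab$sstart, tab$send)
  hi <- pmax(tab$sstart, tab$send)
  gr <- GenomicRanges::GRanges(
    seqnames = tab$sseqid,
    ranges = IRanges::IRanges(start = lo, end = hi),
    seqlengths = if (!is.null(lgLengths)) .as_lg_lengths(lgLengths) else NULL)
  S4Vectors::mcols(gr)$kmer <- tab$qseqid
  S4Vectors::mcols(gr)$identity <- tab$pident
  S4Vectors::mcols(gr)$alignLen <- tab$length
  S4Vectors::mcols(gr)$bitScore <- tab$bitscore
  gr
}

#' Per-linkage-group k-mer enrichment
#'
#' Counts hits per linkage group and normalizes by linkage-group size,
#' reported as hits per Mb. Linkage groups without hits are retained
#' with zero counts, so enrichment tables of the two sexes always align.
#'
#' @param hits `GRanges` of k-mer placements (from [mapKmers] or
#'   [importBlastHits]).
#' @param lgLengths named numeric vector of linkage-group lengths (bp).
#' @param label free-text label (e.g. "male-specific") recorded in the
#'   output.
#' @return a `DataFrame` with columns `lg`, `lengthBp`, `hits`,
#'   `perMb`, `label`.
#' @export
lgEnrichment <- function(hits, lgLengths, label = "") {
  lgLengths <- .as_lg_lengths(lgLengths)
  lg <- as.character(GenomicRanges::seqnames(hits))
  unknown <- setdiff(unique(lg), names(lgLengths))
  if (length(unknown))
    stop("hits on linkage groups absent from lgLengths: ",
         paste(unknown, collapse = ", "))
  raw <- table(factor(lg, levels = names(lgLengths)))
  raw <- stats::setNames(as.numeric(raw), names(lgLengths))
  S4Vectors::DataFrame(lg = names(lgLengths),
                       lengthBp = unname(lgLengths),
                       hits = unname(raw),
                       perMb = unname(raw / (lgLengths / 1e6)),
                       label = label)
}

#' Call the sex chromosome from per-sex k-mer enrichment
#'
#' For each sex, every linkage group's normalized k-mer count is
#' divided by the median normalized count across linkage groups for
#' that sex (a fold of 1 means "looks autosomal"). The call is the
#' linkage group with the maximal fold over both sexes, provided the
#' fold reaches `foldThreshold`; an excess of male-specific k-mers
#' gives an XY call, a female excess a ZW call, and no qualifying
#' linkage group gives "none". A zero median with a positive count
#' yields an infinite fold; among infinite folds the larger normalized
#' count wins.
#'
#' Short unplaced scaffolds inflate fold statistics, so linkage groups
#' shorter than `minLgLength` are excluded from the median (they can
#' still be called). When fewer than two linkage groups pass the floor,
#' all are used.
#'
#' @param maleEnrich,femaleEnrich enrichment tables from
#'   [lgEnrichment] over the same linkage groups.
#' @param foldThreshold minimal fold over the median to make a call.
#'   Default 3.
#' @param minLgLength length floor (bp) for linkage groups entering
#'   the median. Default 1e6.
#' @return a [SexCall].
#' @export
callSexLinkageGroup <- function(maleEnrich, femaleEnrich, foldThreshold = 3,
                                minLgLength = 1e6) {
  m <- as.data.frame(maleEnrich)
  f <- as.data.frame(femaleEnrich)
  if (nrow(m) == 0 || nrow(f) == 0) stop("empty enrichment table")
  if (!identical(m$lg, f$lg))
    stop("male and female enrichment tables must cover the same linkage groups")
  med_of <- function(df) {
    in_med <- df$lengthBp >= minLgLength
    if (sum(in_med) < 2) in_med <- rep(TRUE, nrow(df))
    stats::median(df$perMb[in_med])
  }
  fold_of <- function(df) {
    med <- med_of(df)
    if (med == 0) ifelse(df$perMb > 0, Inf, 0) else df$perMb / med
  }
  foldM <- fold_of(m)
  foldF <- fold_of(f)
  folds <- data.frame(lg = m$lg, maleFold = foldM, femaleFold = foldF,
                      malePerMb = m$perMb, femalePerMb = f$perMb)
  cand <- rbind(
    data.frame(lg = m$lg, system = "XY", fold = foldM, perMb = m$perMb),
    data.frame(lg = f$lg, system = "ZW", fold = foldF, perMb = f$perMb))
  cand <- cand[order(-cand$fold, -cand$perMb), , drop = FALSE]
  best <- cand[1, ]
  if (is.finite(best$fold) && best$fold < foldThreshold)
    return(new("SexCall", lg = NA_character_, system = "none",
               fold = best$fold, folds = folds))
  new("SexCall", lg = best$lg, system = best$system, fold = best$fold,
      folds = folds)
}

#' Delimit differentiated blocks from k-mer placements
#'
#' Tiles the genome into windows, scores each window by the minimum
#' number of point variants explaining its hits (the ceiling of the hit
#' count over `k`, since one isolated variant yields up to `k`
#' clustered hits - this keeps a duplicated sequencing error from
#' marking a window), marks windows whose score reaches `minFold` times
#' the genome-wide median window score (floored at one variant and at
#' `1/minFold` of the peak window score, so sparse noise cannot chain
#' into blocks when the median background is zero), merges
#' marked windows separated by at most `mergeGap` unmarked windows, and
#' reports the merged blocks on the linkage group of interest. A block starts at its first marked window and ends at the
#' start of its last hit plus `k` (clipped to the linkage group). The
#' returned coverage fraction - total block span over linkage-group
#' length - is the statistic behind statements like "the sex
#' determining region covers ~77% of the chromosome".
#'
#' @param hits `GRanges` of k-mer placements (all linkage groups; the
#'   genome-wide median is computed from all of them).
#' @param lgLengths named numeric linkage-group lengths (bp).
#' @param lg linkage group to delimit. Default: the one with most hits.
#' @param k k-mer length used to extend the last hit. Default 22.
#' @param window window size in bp. Default 1e5.
#' @param minFold multiple of the median window count required to mark
#'   a window. Default 5.
#' @param mergeGap number of unmarked windows allowed inside a block.
#'   Default 1.
#' @return list with `blocks` (a `GRanges` with metadata `nKmers` and
#'   `densityPer100kb`) and `coverageFraction`.
#' @export
callBlocks <- function(hits, lgLengths, lg = NULL, k = 22L, window = 1e5,
                       minFold = 5, mergeGap = 1L) {
  lgLengths <- .as_lg_lengths(lgLengths)
  if (is.null(lg)) {
    if (length(hits) == 0) lg <- names(lgLengths)[1]
    else lg <- names(which.max(table(as.character(GenomicRanges::seqnames(hits)))))
  }
  if (!lg %in% names(lgLengths)) stop("unknown linkage group: ", lg)
  lglen <- lgLengths[[lg]]
  empty <- list(blocks = GenomicRanges::GRanges(seqlengths = lgLengths),
                coverageFraction = 0)
  if (length(hits) == 0) return(empty)
  win <- makeWindows(lgLengths, size = window)
  # windows are marked by the number of hit *start* positions they contain,
  # so a k-mer spanning a window boundary is assigned to exactly one window
  hstarts <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(hits),
    ranges = IRanges::IRanges(start = GenomicRanges::start(hits), width = 1L))
  counts <- GenomicRanges::countOverlaps(win, hstarts, ignore.strand = TRUE)
  # an isolated point variant (or a duplicated sequencing error) yields up
  # to k clustered hits, so windows are scored by the minimum number of
  # point variants explaining their hits; a lone artifact then scores 1
  # and cannot clear a multiple-of-median threshold
  score <- ceiling(counts / k)
  medScore <- stats::median(score)
  # the threshold never drops below one variant, nor below 1/minFold of
  # the peak window score: when background occupancy hovers near 50% the
  # median alone is knife-edged between 0 and 1, and a zero median must
  # not let single-variant noise windows chain into blocks
  threshold <- max(1, minFold * medScore, max(score) / minFold)
  onlg <- as.character(GenomicRanges::seqnames(win)) == lg
  widx <- which(onlg)
  marked <- score[widx] >= threshold
  if (!any(marked)) return(empty)
  # merge marked windows across gaps of <= mergeGap unmarked windows
  mpos <- which(marked)
  grp <- cumsum(c(1, diff(mpos) > mergeGap + 1))
  hit_start0 <- GenomicRanges::start(hits) - 1L
  hit_lg <- as.character(GenomicRanges::seqnames(hits))
  starts <- ends <- nk <- numeric(length(unique(grp)))
  for (g in seq_along(starts)) {
    wfirst <- win[widx[mpos[grp == g][1]]]
    wlast <- win[widx[utils::tail(mpos[grp == g], 1)]]
    s0 <- GenomicRanges::start(wfirst) - 1
    e0 <- GenomicRanges::end(wlast)          # half-open end of last window
    inblk <- hit_lg == lg & hit_start0 >= s0 & hit_start0 < e0
    starts[g] <- s0
    ends[g] <- min(max(hit_start0[inblk]) + k, lglen)
    nk[g] <- sum(inblk)
  }
  blocks <- GenomicRanges::GRanges(
    seqnames = factor(rep(lg, length(starts)), levels = names(lgLengths)),
    ranges = IRanges::IRanges(start = starts + 1, end = ends),
    seqlengths = lgLengths)
  S4Vectors::mcols(blocks)$nKmers <- nk
  S4Vectors::mcols(blocks)$densityPer100kb <- nk / ((ends - starts) / 1e5)
  list(blocks = blocks,
       coverageFraction = sum(ends - starts) / lglen)
}
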