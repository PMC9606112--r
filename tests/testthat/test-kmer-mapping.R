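library(GenomicRanges)

test_that("indexReference records first occurrences, multiplicity and ambiguity gaps", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTACGT"))
  idx <- indexReference(ref, k = 4)
  expect_true("ACGT" %in% kmers(idx))
  i <- match("ACGT", kmers(idx))
  expect_identical(idx@start[i], 0L)           # first occurrence kept
  expect_true(idx@multi[i])                    # occurs at 0 and 4
  idx2 <- indexReference(Biostrings::DNAStringSet(c(chr1 = "AAAA")), k = 4)
  expect_identical(kmers(idx2), "AAAA")
  expect_identical(idx2@start, 0L)
  expect_false(idx2@multi)
  # k-mers spanning an N run are absent
  idx3 <- indexReference(Biostrings::DNAStringSet(c(chr1 = "AAAANCCCC")), k = 4)
  expect_setequal(kmers(idx3), c("AAAA", "CCCC"))   # GGGG canonicalizes to CCCC
  expect_error(indexReference(Biostrings::DNAStringSet(), k = 4), "empty")
})

test_that("mapKmers places queries via canonical form and counts the unmapped", {
  ref <- Biostrings::DNAStringSet(c(chrA = "AACCGGTTACGGATCC", chrB = "TTGGCCAATT"))
  idx <- indexReference(ref, k = 6)
  present <- canonicalKmer(substr(as.character(ref[[1]]), 3, 8))
  q <- new("KmerSet", k = 6L,
           members = sort(unique(c(present,
                                   canonicalKmer(rc_oracle(substr(as.character(ref[[1]]), 5, 10))),
                                   canonicalKmer("GTCGTA"))), method = "radix"))
  res <- mapKmers(q, idx, maxMismatch = 0)
  expect_identical(length(res$hits) + res$unmapped, length(q))
  hit_kmers <- mcols(res$hits)$kmer
  expect_true(present %in% hit_kmers)
  # revcomp queries map through their canonical form
  expect_true(canonicalKmer(rc_oracle(substr(as.character(ref[[1]]), 5, 10))) %in% hit_kmers)
  expect_error(mapKmers(new("KmerSet", k = 5L, members = "AAAAA"), idx), "k mismatch")
})

test_that("exact-match mapping agrees with a brute-force reference scan", {
  set.seed(410)
  refseqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 6e4, replace = TRUE), collapse = ""),
               chr2 = paste(sample(c("A", "C", "G", "T"), 4e4, replace = TRUE), collapse = ""))
  idx <- indexReference(Biostrings::DNAStringSet(refseqs), k = 11)
  # queries: a mix of real reference k-mers (fwd and rc) and random ones
  pick <- function(lg, n) {
    at <- sample(nchar(refseqs[[lg]]) - 11, n)
    substring(refseqs[[lg]], at, at + 10)
  }
  q <- unique(canonicalKmer(c(pick("chr1", 120), rc_oracle(pick("chr2", 120)),
                              random_kmers(80, 11))))
  qs <- new("KmerSet", k = 11L, members = sort(q, method = "radix"))
  res <- mapKmers(qs, idx, maxMismatch = 0)
  got <- data.frame(kmer = mcols(res$hits)$kmer,
                    lg = as.character(seqnames(res$hits)),
                    start0 = start(res$hits) - 1L,
                    multi = mcols(res$hits)$multi)
  n_unmapped_oracle <- 0L
  for (kk in kmers(qs)) {
    o <- scan_reference_oracle(kk, refseqs)
    row <- got[got$kmer == kk, , drop = FALSE]
    if (is.null(o)) {
      n_unmapped_oracle <- n_unmapped_oracle + 1L
      expect_identical(nrow(row), 0L)
    } else {
      expect_identical(nrow(row), 1L)
      expect_identical(row$lg, o$lg)
      expect_identical(row$start0, o$start0)
      expect_identical(row$multi, o$multi)
    }
  }
  expect_identical(res$unmapped, n_unmapped_oracle)
})

test_that("single-mismatch lookup recovers variant k-mers at their locus", {
  set.seed(411)
  refseq <- paste(sample(c("A", "C", "G", "T"), 5e3, replace = TRUE), collapse = "")
  idx <- indexReference(Biostrings::DNAStringSet(c(chr1 = refseq)), k = 21)
  at <- 1000L
  wt <- substring(refseq, at + 1, at + 21)
  mid <- 11
  var <- wt
  substr(var, mid, mid) <- setdiff(c("A", "C", "G", "T"), substr(wt, mid, mid))[1]
  qs <- new("KmerSet", k = 21L, members = canonicalKmer(var))
  miss <- mapKmers(qs, idx, maxMismatch = 0)
  expect_identical(length(miss$hits), 0L)      # exact match cannot place it
  hit <- mapKmers(qs, idx, maxMismatch = 1)
  expect_identical(length(hit$hits), 1L)
  expect_identical(start(hit$hits) - 1L, at)
  expect_identical(mcols(hit$hits)$score, 20L)  # one mismatching base
})

test_that("importBlastHits keeps the best filtered hit per query and flips minus-strand coordinates", {
  rows <- c(
    "q1\tLG01\t100.00\t22\t0\t0\t1\t22\t501\t522\t1e-8\t40",
    "q1\tLG02\t100.00\t22\t0\t0\t1\t22\t901\t922\t1e-8\t35",
    "q2\tLG01\t80.00\t22\t4\t0\t1\t22\t101\t122\t1e-3\t20",
    "q3\tLG01\t95.45\t22\t1\t0\t1\t22\t10\t5\t1e-5\t30")
  f <- tempfile(); writeLines(rows, f)
  gr <- importBlastHits(f, minIdentity = 90, minAlignLen = 16)
  expect_setequal(mcols(gr)$kmer, c("q1", "q3"))      # q2 fails identity
  q1 <- gr[mcols(gr)$kmer == "q1"]
  expect_identical(as.character(seqnames(q1)), "LG01") # bit-score 40 beats 35
  expect_identical(mcols(q1)$bitScore, 40)
  q3 <- gr[mcols(gr)$kmer == "q3"]
  # sstart=10, send=5 becomes the 0-based half-open interval [4, 10)
  expect_identical(start(q3) - 1L, 4L)
  expect_identical(end(q3), 10L)
  bad <- tempfile(); writeLines(c(rows[1], "q9\tLG01\tmalformed"), bad)
  expect_error(importBlastHits(bad), "line 2")
})

test_that("importBlastHits resolves bit-score ties by file order", {
  rows <- c("q1\tLG02\t100.00\t22\t0\t0\t1\t22\t201\t222\t1e-8\t40",
            "q1\tLG01\t100.00\t22\t0\t0\t1\t22\t501\t522\t1e-8\t40")
  f <- tempfile(); writeLines(rows, f)
  gr <- importBlastHits(f)
  expect_identical(as.character(seqnames(gr)), "LG02")
})

test_that("lgEnrichment normalizes per Mb and zero-fills missing linkage groups", {
  lgs <- c(LG01 = 1e6, LG02 = 2e6, LG03 = 5e5)
  gr <- GRanges(rep(c("LG01", "LG02"), c(500, 100)),
                IRanges(start = 1:600, width = 22), seqlengths = lgs)
  e <- as.data.frame(lgEnrichment(gr, lgs, label = "male"))
  expect_identical(e$hits, c(500, 100, 0))
  expect_identical(e$perMb, c(500, 50, 0))      # 100 hits / 2 Mb = 50 per Mb
  expect_identical(e$label, rep("male", 3))
  # relabeling invariance: renaming LGs permutes but does not change folds
  lgs2 <- c(B = 1e6, A = 2e6, C = 5e5)
  gr2 <- GRanges(rep(c("B", "A"), c(500, 100)),
                 IRanges(start = 1:600, width = 22), seqlengths = lgs2)
  e2 <- as.data.frame(lgEnrichment(gr2, lgs2))
  expect_identical(e2$perMb, e$perMb)
  # scaling lengths by c divides per-Mb counts by c
  lgs3 <- lgs * 2
  e3 <- as.data.frame(lgEnrichment(gr, lgs3))
  expect_equal(e3$perMb, e$perMb / 2)
  bad <- GRanges("LGxx", IRanges(1, 22))
  expect_error(lgEnrichment(bad, lgs), "absent")
})

test_that("callSexLinkageGroup calls the fold-enriched linkage group and sex system", {
  lgs <- setNames(rep(1e6, 8), paste0("LG", 1:8))
  base <- S4Vectors::DataFrame(lg = names(lgs), lengthBp = unname(lgs),
                               hits = rep(100, 8), perMb = rep(100, 8),
                               label = "x")
  up <- base; up$perMb[5] <- 4000; up$hits[5] <- 4000
  call_xy <- callSexLinkageGroup(up, base, minLgLength = 0)
  expect_identical(call_xy@system, "XY")
  expect_identical(call_xy@lg, "LG5")
  expect_gt(call_xy@fold, 3)
  call_zw <- callSexLinkageGroup(base, up, minLgLength = 0)
  expect_identical(call_zw@system, "ZW")
  expect_identical(call_zw@lg, "LG5")
  flat <- callSexLinkageGroup(base, base, minLgLength = 0)
  expect_identical(flat@system, "none")
  expect_true(is.na(flat@lg))
  expect_error(callSexLinkageGroup(base[0, ], base[0, ]), "empty")
})

test_that("callBlocks delimits hit-dense windows and reports span coverage", {
  lgs <- c(LG1 = 6e6)
  # dense cluster of hits early on, an isolated distant cluster, silence elsewhere
  starts0 <- c(seq(100, 90000, by = 120), seq(5000000, 5020000, by = 150))
  gr <- GRanges("LG1", IRanges(start = starts0 + 1, width = 22), seqlengths = lgs)
  res <- callBlocks(gr, lgs, lg = "LG1", k = 22, window = 1e5)
  expect_identical(length(res$blocks), 2L)
  expect_true(all(start(res$blocks) - 1 >= 0))
  expect_true(all(end(res$blocks) <= 6e6))
  # block 1: starts at window 0, ends at last early hit + k
  b1 <- res$blocks[1]
  expect_identical(start(b1) - 1L, 0L)
  expect_equal(end(b1), max(starts0[starts0 < 1e5]) + 22L)
  b2 <- res$blocks[2]
  expect_identical(start(b2) - 1L, 5000000L)
  expect_equal(end(b2), max(starts0) + 22L)
  expect_equal(res$coverageFraction, sum(width(res$blocks)) / 6e6)
  # blocks are disjoint and sorted
  expect_true(all(start(res$blocks)[-1] > end(res$blocks)[-length(res$blocks)]))
  # no hits: empty result
  none <- callBlocks(GRanges(seqlengths = lgs), lgs, lg = "LG1")
  expect_identical(length(none$blocks), 0L)
  expect_identical(none$coverageFraction, 0)
})

test_that("near-uniform hits collapse into a single near-complete block", {
  # quiet autosomes keep the genome-wide median window score low
  lgs <- c(LG1 = 1e6, LG2 = 1e6, LG3 = 1e6)
  starts0 <- seq(0, 1e6 - 22, by = 50)
  gr <- GRanges("LG1", IRanges(starts0 + 1, width = 22), seqlengths = lgs)
  res <- callBlocks(gr, lgs, lg = "LG1", window = 1e5)
  expect_identical(length(res$blocks), 1L)
  expect_gt(res$coverageFraction, 0.99)
  expect_lte(res$coverageFraction, 1)
})
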