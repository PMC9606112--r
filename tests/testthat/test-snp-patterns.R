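test_that("readSync parses counts per pool and flags malformed lines", {
  f <- tempfile()
  writeLines(c("chr1\t100\tA\t10:0:0:0:0:0\t5:5:0:0:0:0",
               "chr1\t101\tC\t0:0:8:0:1:1\t0:0:9:0:0:0"), f)
  s <- readSync(f)
  expect_identical(s$lg, c("chr1", "chr1"))
  expect_identical(s$pos, c(100, 101))
  expect_identical(s$f_A[1], 10L)
  expect_identical(s$m_A[1], 5L)
  expect_identical(s$m_T[1], 5L)
  expect_identical(s$f_N[2], 1L)
  expect_identical(s$f_del[2], 1L)
  # pool order flag swaps female and male
  s2 <- readSync(f, femaleFirst = FALSE)
  expect_identical(s2$m_A[1], 10L)
  expect_identical(s2$f_T[1], 5L)
  bad <- tempfile(); writeLines("chr1\t100\tA\t10:0:0:0:0\t5:5:0:0:0:0", bad)
  expect_error(readSync(bad), "line 1")
  bad2 <- tempfile()
  writeLines(c("chr1\t100\tA\t10:0:0:0:0:0\t5:5:0:0:0:0", "chr1\t101\tA\tjunk"), bad2)
  expect_error(readSync(bad2), "line 2")
})

test_that("sync round-trips through writeSync and readSync", {
  set.seed(430)
  fm <- matrix(rpois(40, 5), ncol = 4)
  mm <- matrix(rpois(40, 5), ncol = 4)
  s <- sync_frame(fm, mm)
  f <- tempfile()
  writeSync(s, f)
  s2 <- readSync(f)
  expect_equal(s2, s, ignore_attr = TRUE)
})

test_that("pileupToSync counts quality-passing bases and consumes pileup grammar", {
  f <- tempfile()
  q30 <- strrep("?", 5)                     # PHRED 30
  writeLines(paste("chr1", 50, "A", 5, ".....", q30, 5, ".....", q30,
                   sep = "\t"), f)
  s <- pileupToSync(f)
  expect_identical(s$f_A, 5L)
  expect_identical(s$m_A, 5L)
  # low-quality calls are filtered: '.' at Q30 kept, 'T' at Q10 dropped
  f2 <- tempfile()
  writeLines(paste("chr1", 50, "G", 2, ".T", "?+", 2, "..", "??",
                   sep = "\t"), f2)
  s2 <- pileupToSync(f2, minBaseq = 20)
  expect_identical(s2$f_G, 1L)
  expect_identical(s2$f_T, 0L)
  # insertion sub-strings are consumed without touching base counts
  f3 <- tempfile()
  writeLines(paste("chr1", 7, "C", 2, ".+2AT.", "??", 3, ".,^I.", "???",
                   sep = "\t"), f3)
  s3 <- pileupToSync(f3)
  expect_identical(s3$f_C, 2L)
  expect_identical(s3$m_C, 3L)
  # deletions and read starts/ends
  f4 <- tempfile()
  writeLines(paste("chr1", 9, "T", 3, ".*$.", "???", 2, "a,", "??",
                   sep = "\t"), f4)
  s4 <- pileupToSync(f4)
  expect_identical(s4$f_T, 2L)
  expect_identical(s4$f_del, 1L)
  expect_identical(s4$m_A, 1L)
  expect_identical(s4$m_T, 1L)
  # ragged bases/qualities error
  f5 <- tempfile()
  writeLines(paste("chr1", 9, "T", 3, "...", "??", 1, ".", "?",
                   sep = "\t"), f5)
  expect_error(pileupToSync(f5), "ragged")
})

test_that("siteFst evaluates the pooled FST formula", {
  # identical pools: no differentiation
  expect_equal(siteFst(sync_row(c(10, 10, 0, 0), c(10, 10, 0, 0))), 0)
  # fixed difference: complete differentiation
  expect_equal(siteFst(sync_row(c(20, 0, 0, 0), c(0, 20, 0, 0))), 1)
  # hand evaluation: female 10A:10T, male 20A ->
  # HS = (0.5 + 0)/2 = 0.25, pbar = (0.75, 0.25), HT = 0.375, FST = 1/3
  expect_equal(siteFst(sync_row(c(10, 10, 0, 0), c(20, 0, 0, 0))), 1 / 3)
  # zero-depth pool is undefined
  expect_true(is.na(siteFst(sync_row(c(0, 0, 0, 0), c(10, 0, 0, 0)))))
  # N and del counts do not enter denominators
  s <- sync_row(c(10, 10, 0, 0), c(20, 0, 0, 0))
  s$f_N <- 50L; s$m_del <- 50L
  expect_equal(siteFst(s), 1 / 3)
})

test_that("FST stays within [0,1] and is zero iff pool frequencies agree", {
  set.seed(431)
  fm <- matrix(rpois(400, 6), ncol = 4)
  mm <- matrix(rpois(400, 6), ncol = 4)
  keep <- rowSums(fm) > 0 & rowSums(mm) > 0
  fst <- siteFst(sync_frame(fm[keep, ], mm[keep, ]))
  expect_true(all(fst >= 0 & fst <= 1))
  pf <- fm[keep, ] / rowSums(fm[keep, ])
  pm <- mm[keep, ] / rowSums(mm[keep, ])
  same <- rowSums(abs(pf - pm)) < 1e-12
  expect_true(all((fst == 0) == same))
})

test_that("classifySexSnp identifies XY and ZW patterns and the filters around them", {
  # textbook XY: female fixed, male heterozygous
  expect_identical(classifySexSnp(sync_row(c(20, 0, 0, 0), c(10, 10, 0, 0))), "XY")
  # mirrored ZW (female carries the male-absent allele at 0.4)
  expect_identical(classifySexSnp(sync_row(c(12, 8, 0, 0), c(20, 0, 0, 0))), "ZW")
  # male minor frequency 0.1 outside the intermediate range
  expect_identical(classifySexSnp(sync_row(c(20, 0, 0, 0), c(18, 2, 0, 0))), "none")
  # below depth floor
  expect_identical(classifySexSnp(sync_row(c(4, 0, 0, 0), c(2, 2, 0, 0))), "none")
  # more than two segregating alleles across pools
  expect_identical(classifySexSnp(sync_row(c(20, 0, 0, 0), c(6, 8, 6, 0))), "none")
  # a singleton third allele is error floor, not a segregating allele
  expect_identical(classifySexSnp(sync_row(c(20, 0, 0, 0), c(9, 10, 1, 0))), "XY")
})

test_that("pool swap maps XY to ZW exactly", {
  set.seed(432)
  # mixture of sex-patterned shapes (with sampling jitter) and random noise
  n1 <- 1500; n2 <- 2000
  xy_f <- cbind(rpois(n1, 12), 0L, 0L, 0L)
  xy_m <- cbind(rbinom(n1, 12, 0.5), 12 - rbinom(n1, 12, 0.5), 0L, 0L)
  fm <- rbind(xy_f, xy_m, matrix(rpois(4 * n2, 2.5), ncol = 4))
  mm <- rbind(xy_m[sample(n1), ], xy_f[sample(n1), ],
              matrix(rpois(4 * n2, 2.5), ncol = 4))
  s <- sync_frame(fm, mm)
  sw <- sync_frame(mm, fm)
  a <- classifySexSnp(s)
  b <- classifySexSnp(sw)
  expect_identical(b[a == "XY"], rep("ZW", sum(a == "XY")))
  expect_identical(b[a == "ZW"], rep("XY", sum(a == "ZW")))
  expect_identical(b[a == "none"], rep("none", sum(a == "none")))
  expect_gt(sum(a != "none"), 0)   # the random tables do exercise both branches
})

test_that("classification agrees with the enumeration oracle over biallelic tables to depth 12", {
  # all biallelic count tables (A/T) with per-pool depth <= 12, plus a
  # triallelic slice - compared against an independently written
  # single-site transliteration of the rule
  grids <- expand.grid(fa = 0:12, ft = 0:12, ma = 0:12, mt = 0:12)
  grids <- grids[grids$fa + grids$ft <= 12 & grids$ma + grids$mt <= 12, ]
  fm <- cbind(grids$fa, grids$ft, 0L, 0L)
  mm <- cbind(grids$ma, grids$mt, 0L, 0L)
  got <- classifySexSnp(sync_frame(fm, mm))
  want <- vapply(seq_len(nrow(grids)), function(i)
    classify_oracle(fm[i, ], mm[i, ]), "")
  expect_identical(got, want)
  # triallelic slice: a third allele with 0-3 copies in the male pool
  tri <- expand.grid(fa = 0:12, ma = 0:9, mt = 0:9, mc = 0:3)
  tri <- tri[tri$ma + tri$mt + tri$mc <= 12, ]
  fm2 <- cbind(tri$fa, 0L, 0L, 0L)
  mm2 <- cbind(tri$ma, tri$mt, tri$mc, 0L)
  got2 <- classifySexSnp(sync_frame(fm2, mm2))
  want2 <- vapply(seq_len(nrow(tri)), function(i)
    classify_oracle(fm2[i, ], mm2[i, ]), "")
  expect_identical(got2, want2)
})

test_that("planted XY regions are recovered from simulated sync data with few false positives", {
  # depth 20, error 0.002: the bulk of planted sites must classify XY and
  # non-region sites must be almost never called
  reps <- 50
  planted_rate <- numeric(reps)
  fp <- numeric(reps)
  nbg <- numeric(reps)
  for (r in seq_len(reps)) {
    truth <- new("SimTruth", system = "XY", lg = "chr1",
                 regionStart = 200, regionEnd = 1200, divergence = 0.1,
                 snpPositions = seq(200, 1199, by = 10), seed = r)
    sync <- simulateSync(truth, c(chr1 = 2000, chr2 = 1500), depth = 20,
                         err = 0.002, backgroundSnpRate = 0.001, seed = 1000 + r)
    cls <- classifySexSnp(sync)
    inreg <- sync$lg == "chr1" & (sync$pos - 1) %in% truth@snpPositions
    planted_rate[r] <- mean(cls[inreg] == "XY")
    fp[r] <- sum(cls[!inreg] != "none")
    nbg[r] <- sum(!inreg)
  }
  expect_gte(mean(planted_rate), 0.90)
  expect_lte(sum(fp) / sum(nbg), 0.001)
})

test_that("findSexSnps reports positions, patterns, FST and allele frequencies", {
  s <- rbind(sync_row(c(20, 0, 0, 0), c(10, 10, 0, 0), pos = 100),
             sync_row(c(12, 8, 0, 0), c(20, 0, 0, 0), pos = 200),
             sync_row(c(20, 0, 0, 0), c(20, 0, 0, 0), pos = 300))
  res <- findSexSnps(s)
  expect_identical(res$pos, c(100, 200))
  expect_identical(res$pattern, c("XY", "ZW"))
  expect_equal(res$freqM[1], 0.5)   # sex-limited allele in the male pool
  expect_equal(res$freqF[1], 0)
  expect_equal(res$freqF[2], 0.4)
  expect_true(all(res$fst > 0 & res$fst <= 1))
})
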