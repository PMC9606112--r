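library(GenomicRanges)

test_that("makeWindows tiles half-open windows and keeps the partial tail", {
  w <- makeWindows(c(chr1 = 250000), size = 1e5)
  expect_identical(start(w) - 1L, c(0L, 100000L, 200000L))
  expect_identical(end(w), c(100000L, 200000L, 250000L))
  expect_identical(length(makeWindows(c(chr1 = 1e5), 1e5)), 1L)
  tiny <- makeWindows(c(chr1 = 99), 1e5)
  expect_identical(length(tiny), 1L)
  expect_identical(end(tiny), 99L)
  expect_identical(length(makeWindows(c(chr1 = 0, chr2 = 100), 50)), 2L)
})

test_that("windowSnpDensity assigns each SNP to exactly one window and conserves totals", {
  w <- makeWindows(c(chr1 = 250000), 1e5)
  snps <- data.frame(lg = "chr1",
                     pos = c(6, 150006, 100001, 100000),  # 1-based
                     pattern = c("XY", "XY", "XY", "ZW"))
  w2 <- windowSnpDensity(snps, w)
  # 0-based 5 and 150005 land in windows 1 and 2
  expect_identical(mcols(w2)$xy, c(1L, 2L, 0L))
  # 0-based 100000 (= pos 100001) is the first position of window 2;
  # 0-based 99999 (= pos 100000) the last of window 1
  expect_identical(mcols(w2)$zw, c(1L, 0L, 0L))
  expect_identical(sum(mcols(w2)$xy) + sum(mcols(w2)$zw), nrow(snps))
  # no SNPs: all-zero windows with log ratio 0
  w0 <- windowSnpDensity(snps[0, ], w)
  expect_true(all(mcols(w0)$xy == 0) && all(mcols(w0)$logRatio == 0))
  out <- data.frame(lg = "chr1", pos = 250001, pattern = "XY")
  expect_error(windowSnpDensity(out, w), "chr1:250001")
  out2 <- data.frame(lg = "chrX", pos = 5, pattern = "XY")
  expect_error(windowSnpDensity(out2, w), "chrX")
})

test_that("log2Ratio is the pseudocounted log fold with its symmetries", {
  expect_identical(log2Ratio(3, 3), 0)
  expect_identical(log2Ratio(7, 1), 2)
  expect_identical(log2Ratio(1, 7), -2)
  expect_equal(log2Ratio(0, 0), 0)
  expect_identical(log2Ratio(c(7, 1), c(1, 7)), c(2, -2))
  expect_error(log2Ratio(0, 5, pseudocount = 0), "pseudocount")
  expect_error(log2Ratio(-1, 5), ">= 0")
})

test_that("kruskalWallis evaluates the tie-corrected H statistic", {
  kw <- kruskalWallis(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(kw$H, 2.4)
  expect_identical(kw$df, 1L)
  # identical groups: mid-ranks equalize, H = 0
  kw0 <- kruskalWallis(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(kw0$H, 0)
  # all tied values: defined as H = 0, p = 1
  kwt <- kruskalWallis(rep(5, 6), rep(c("a", "b"), 3))
  expect_identical(c(kwt$H, kwt$p), c(0, 1))
  expect_error(kruskalWallis(1:3, rep("a", 3)), "two groups")
})

test_that("kruskalWallis matches stats::kruskal.test to 1e-10 on random data", {
  set.seed(440)
  for (i in 1:100) {
    ng <- sample(2:6, 1)
    sizes <- sample(3:12, ng, replace = TRUE)
    vals <- round(rnorm(sum(sizes)), sample(c(0, 1, 3), 1))  # induce ties
    grp <- rep(letters[seq_len(ng)], sizes)
    kw <- kruskalWallis(vals, grp)
    ref <- stats::kruskal.test(vals, factor(grp))
    expect_equal(kw$H, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
    expect_identical(kw$df, unname(ref$parameter))
  }
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(441)
  vals <- rnorm(60)
  grp <- rep(letters[1:4], each = 15)
  h0 <- kruskalWallis(vals, grp)$H
  expect_equal(kruskalWallis(exp(vals), grp)$H, h0)
  expect_equal(kruskalWallis(vals^3, grp)$H, h0)
  expect_equal(kruskalWallis(rank(vals), grp)$H, h0)
})

test_that("kruskalWallis p agrees with a permutation null", {
  set.seed(442)
  vals <- c(2.1, 0.4, 1.3, 3.9, 2.2, 5.1, 4.4, 3.0, 1.1)
  grp <- rep(c("a", "b", "c"), each = 3)
  kw <- kruskalWallis(vals, grp)
  nperm <- 2e4
  hperm <- numeric(nperm)
  for (i in seq_len(nperm)) {
    hperm[i] <- kruskalWallis(vals, sample(grp))$H
  }
  p_perm <- mean(hperm >= kw$H - 1e-12)
  # chi-square p is asymptotic; agreement within Monte-Carlo + approximation slack
  expect_lt(abs(p_perm - kw$p), 0.05)
})

test_that("dunnPosthoc evaluates pairwise z with tie correction and BH adjustment", {
  d <- dunnPosthoc(c(1, 2, 3, 4), c("a", "a", "b", "b"))
  expect_equal(abs(d$z), 2 / sqrt(20 / 12 * 1), tolerance = 1e-12)
  # identical groups: z = 0, p = 1
  d0 <- dunnPosthoc(c(1, 2, 1, 2), c("a", "a", "b", "b"))
  expect_equal(d0$z, 0)
  expect_equal(d0$p, 1)
  # hand-computed BH on three raw p-values
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"), c(0.03, 0.03, 0.04))
  expect_error(dunnPosthoc(1:3, rep("a", 3)), "two groups")
})

test_that("dunnPosthoc matches an independent implementation to 1e-10 on random data", {
  set.seed(443)
  for (i in 1:100) {
    ng <- sample(3:6, 1)
    sizes <- sample(4:10, ng, replace = TRUE)
    vals <- round(rnorm(sum(sizes)), sample(c(0, 1), 1))
    grp <- rep(letters[seq_len(ng)], sizes)
    got <- dunnPosthoc(vals, grp)
    want <- dunn_oracle(vals, grp)
    expect_equal(got$z, want$z, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$pAdj, p.adjust(want$p, "BH"), tolerance = 1e-10)
  }
})

test_that("BH adjustment is monotone and never below the raw p", {
  set.seed(444)
  vals <- rnorm(80)
  grp <- rep(letters[1:5], each = 16)
  d <- dunnPosthoc(vals, grp)
  expect_true(all(d$pAdj >= d$p - 1e-15))
  ord <- order(d$p)
  expect_true(all(diff(d$pAdj[ord]) >= -1e-15))
  expect_true(all(d$pAdj <= 1))
})

test_that("medianRankByLg ranks genome-wide with first-order tie breaking", {
  lgs <- c(A = 200, B = 200)
  w <- makeWindows(lgs, 100)
  # values in input order 5, 5, 3, 1 -> first-rule ranks 3, 4, 2, 1
  mcols(w)$xy <- 0L; mcols(w)$zw <- 0L
  mcols(w)$logRatio <- c(5, 5, 3, 1)
  mr <- medianRankByLg(w)
  expect_equal(mr[["A"]], 3.5)       # ranks 3 and 4
  expect_equal(mr[["B"]], 1.5)       # ranks 2 and 1
  expect_identical(rank(c(5, 5, 3), ties.method = "first"), c(2L, 3L, 1L))
  # single-LG input of odd n has median (n+1)/2
  w1 <- makeWindows(c(A = 500), 100)
  mcols(w1)$logRatio <- rnorm(5)
  expect_equal(medianRankByLg(w1)[["A"]], 3)
  expect_error(medianRankByLg(w1[0]), "no windows")
})

test_that("a shifted linkage group is detected and the null is calibrated", {
  # 20 LGs x 30 windows of sparse per-window sex-patterned SNP counts
  # (Poisson, 0.5 per window outside a sex region), log-ratios computed by
  # the package; one LG's log-ratios shifted by +1
  n_lg <- 20; n_win <- 30; lambda <- 0.5
  lgs <- paste0("LG", sprintf("%02d", seq_len(n_lg)))
  reps <- 50
  detected <- logical(reps)
  set.seed(445)
  for (r in seq_len(reps)) {
    vals <- log2Ratio(rpois(n_lg * n_win, lambda), rpois(n_lg * n_win, lambda))
    grp <- rep(lgs, each = n_win)
    vals[grp == "LG07"] <- vals[grp == "LG07"] + 1
    d <- dunnPosthoc(vals, grp)
    med <- tapply(rank(vals, ties.method = "first"), grp, median)
    top <- names(which.max(med))
    minp <- min(d$pAdj[d$group1 == "LG07" | d$group2 == "LG07"])
    detected[r] <- (top == "LG07") && (minp < 0.05)
  }
  expect_gte(mean(detected), 0.95)

  # null calibration: no shift, per-LG false-positive rate at BH 0.05 <= 7%
  flagged <- 0L; total <- 0L
  for (r in seq_len(reps)) {
    vals <- log2Ratio(rpois(n_lg * n_win, lambda), rpois(n_lg * n_win, lambda))
    grp <- rep(lgs, each = n_win)
    d <- dunnPosthoc(vals, grp)
    for (lg in lgs) {
      minp <- min(d$pAdj[d$group1 == lg | d$group2 == lg])
      flagged <- flagged + (minp < 0.05)
      total <- total + 1L
    }
  }
  expect_lte(flagged / total, 0.07)
})

test_that("screenChromosomes assembles the KW, Dunn and median-rank screen", {
  set.seed(446)
  lgs <- setNames(rep(1000, 6), paste0("LG", 1:6))
  w <- makeWindows(lgs, 100)     # 60 windows
  snps <- data.frame(
    lg = c(rep("LG3", 40), sample(names(lgs), 25, replace = TRUE)),
    pos = sample(999, 65, replace = TRUE) + 1,
    pattern = c(rep("XY", 40), rep(c("XY", "ZW"), length.out = 25)))
  w <- windowSnpDensity(snps, w)
  scr <- screenChromosomes(w)
  expect_s4_class(scr, "ChromScreenResult")
  expect_identical(scr@nWindows, 60L)
  expect_true(scr@kw$H > 0 && scr@kw$df == 5)
  expect_identical(nrow(scr@dunn), 15L)
  expect_true(all(scr@dunn$pAdj >= scr@dunn$p - 1e-15))
  expect_true(all(scr@medianRank >= 1 & scr@medianRank <= 60))
  expect_identical(names(which.max(scr@medianRank)), "LG3")
  # dropEmpty screens only SNP-bearing windows
  scr2 <- screenChromosomes(w, dropEmpty = TRUE)
  expect_lt(scr2@nWindows, 60L)
  expect_output(show(scr), "Kruskal-Wallis")
})
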