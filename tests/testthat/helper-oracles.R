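# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (Rcpp engine, vectorized classification) so
# that agreement is evidence, not tautology.

# reverse complement via Biostrings (independent of the C++ engine)
rc_oracle <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

canonical_oracle <- function(x) {
  x <- toupper(x)
  rc <- rc_oracle(x)
  # compare base-by-base to stay locale-independent
  ord <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  pick_min <- function(a, b) {
    ca <- ord[strsplit(a, "")[[1]]]
    cb <- ord[strsplit(b, "")[[1]]]
    d <- ca - cb
    nz <- which(d != 0)
    if (length(nz) == 0 || d[nz[1]] < 0) a else b
  }
  mapply(pick_min, x, rc, USE.NAMES = FALSE)
}

# random k-mer generator
random_kmers <- function(n, k) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""), "")
}

# brute-force k-mer placement: scan both strands of every reference
# sequence for the exact query, returning the first occurrence in scan
# order (sequence order, then position) and the total match count
# (used against mapKmers with maxMismatch = 0)
scan_reference_oracle <- function(q, refseqs) {
  pats <- unique(c(q, rc_oracle(q)))
  first <- NULL
  total <- 0L
  for (lg in names(refseqs)) {
    pos <- integer(0)
    for (pat in pats) {
      at <- gregexpr(pat, refseqs[[lg]], fixed = TRUE)[[1]]
      if (at[1] != -1) pos <- c(pos, as.integer(at))
    }
    pos <- sort(unique(pos))
    total <- total + length(pos)
    if (length(pos) && is.null(first))
      first <- list(lg = lg, start0 = pos[1] - 1L)
  }
  if (is.null(first)) return(NULL)
  first$multi <- total > 1L
  first
}

# independent Dunn implementation for cross-checking: written directly
# from the rank-sum definition, no shared helpers with the package
dunn_oracle <- function(values, groups) {
  groups <- as.character(groups)
  N <- length(values)
  r <- rank(values)                     # mid-ranks
  ties <- table(r)
  tie_sum <- sum(ties^3 - ties)
  sigma2 <- (N * (N + 1) / 12) - tie_sum / (12 * (N - 1))
  gl <- sort(unique(groups))
  out <- NULL
  for (i in seq_along(gl)) for (j in seq_along(gl)) if (i < j) {
    gi <- r[groups == gl[i]]; gj <- r[groups == gl[j]]
    z <- (mean(gi) - mean(gj)) / sqrt(sigma2 * (1 / length(gi) + 1 / length(gj)))
    out <- rbind(out, data.frame(group1 = gl[i], group2 = gl[j], z = z,
                                 p = 2 * pnorm(-abs(z))))
  }
  out
}

# direct-rule sex-SNP classifier used by the enumeration oracle: a plain
# transliteration of the classification rule for a single biallelic-ish
# site, independent of the package's vectorized matrix code
classify_oracle <- function(fcounts, mcounts, fixedThreshold = 1.0,
                            hetRange = c(0.3, 0.7), minDepth = 5) {
  stopifnot(length(fcounts) == 4, length(mcounts) == 4)
  df <- sum(fcounts); dm <- sum(mcounts)
  if (df < minDepth || dm < minDepth) return("none")
  if (sum((fcounts + mcounts) >= 2) > 2) return("none")
  dir_test <- function(fixed, het, dfx, dht) {
    majf <- max(fixed) / dfx
    if (majf < fixedThreshold) return(FALSE)
    cand <- which(het > 0 & fixed == 0)
    if (length(cand) == 0) return(FALSE)
    cand <- cand[which.max(het[cand])]
    fr <- het[cand] / dht
    fr >= hetRange[1] && fr <= hetRange[2]
  }
  xy <- dir_test(fcounts, mcounts, df, dm)
  zw <- dir_test(mcounts, fcounts, dm, df)
  if (xy && !zw) "XY" else if (zw && !xy) "ZW" else "none"
}

# build a one-row sync data.frame from two A/T/C/G count vectors
sync_row <- function(fcounts, mcounts, lg = "chr1", pos = 100, ref = "A") {
  df <- data.frame(lg = lg, pos = pos, ref = ref)
  b <- c("A", "T", "C", "G", "N", "del")
  for (i in seq_along(b)) df[[paste0("f_", b[i])]] <- c(fcounts, 0L, 0L)[i]
  for (i in seq_along(b)) df[[paste0("m_", b[i])]] <- c(mcounts, 0L, 0L)[i]
  df
}

# assemble a sync data.frame from matrices of pool counts (rows = sites)
sync_frame <- function(fmat, mmat, lg = "chr1", pos = NULL) {
  n <- nrow(fmat)
  if (is.null(pos)) pos <- seq_len(n)
  df <- data.frame(lg = rep(lg, length.out = n), pos = pos,
                   ref = rep("A", n))
  b <- c("A", "T", "C", "G", "N", "del")
  for (i in 1:4) df[[paste0("f_", b[i])]] <- fmat[, i]
  df$f_N <- 0L; df$f_del <- 0L
  for (i in 1:4) df[[paste0("m_", b[i])]] <- mmat[, i]
  df$m_N <- 0L; df$m_del <- 0L
  df
}
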