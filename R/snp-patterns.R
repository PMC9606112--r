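.SYNC_BASES <- c("A", "T", "C", "G", "N", "del")

.sync_col <- function(pool, base) paste0(pool, "_", base)

#' Read a Popoolation2-style sync file
#'
#' Parses tab-separated lines of the form
#' `LG  POS  REF  A:T:C:G:N:del  A:T:C:G:N:del` (one colon-separated
#' count field per pool; exactly two pools are expected here, female
#' first by convention - set `femaleFirst = FALSE` if the file has the
#' male pool first). `N` and deletion tallies are retained but never
#' enter allele-frequency denominators.
#'
#' @param path sync file.
#' @param femaleFirst is the first pool the female pool? Default TRUE.
#' @return a data.frame with columns `lg`, `pos` (1-based), `ref`, and
#'   per-pool counts `f_A`..`f_del`, `m_A`..`m_del`.
#' @export
readSync <- function(path, femaleFirst = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 5)) {
    bad <- which(nf != 5)[1]
    stop(sprintf("line %d: expected 5 tab-separated fields (lg, pos, ref, pool1, pool2), found %d",
                 bad, nf[bad]))
  }
  m <- do.call(rbind, parts)
  pos <- suppressWarnings(as.numeric(m[, 2]))
  if (anyNA(pos)) stop(sprintf("line %d: non-numeric position", which(is.na(pos))[1]))
  parse_pool <- function(col) {
    sp <- strsplit(m[, col], ":", fixed = TRUE)
    if (any(lengths(sp) != 6)) {
      bad <- which(lengths(sp) != 6)[1]
      stop(sprintf("line %d: pool field must have 6 colon-separated counts (A:T:C:G:N:del)",
                   bad))
    }
    cnt <- suppressWarnings(matrix(as.integer(unlist(sp)), ncol = 6, byrow = TRUE))
    if (anyNA(cnt)) {
      bad <- which(apply(is.na(cnt), 1, any))[1]
      stop(sprintf("line %d: non-integer count", bad))
    }
    colnames(cnt) <- .SYNC_BASES
    cnt
  }
  p1 <- parse_pool(4)
  p2 <- parse_pool(5)
  f <- if (femaleFirst) p1 else p2
  mm <- if (femaleFirst) p2 else p1
  out <- data.frame(lg = m[, 1], pos = pos, ref = toupper(m[, 3]),
                    stringsAsFactors = FALSE)
  for (b in .SYNC_BASES) out[[.sync_col("f", b)]] <- f[, b]
  for (b in .SYNC_BASES) out[[.sync_col("m", b)]] <- mm[, b]
  out
}

#' Write sync-format allele counts
#'
#' @param sync a sync data.frame as returned by [readSync] or
#'   [simulateSync].
#' @param path output file.
#' @param femaleFirst write the female pool first? Default TRUE.
#' @return `path`, invisibly.
#' @export
writeSync <- function(sync, path, femaleFirst = TRUE) {
  fcols <- .sync_col("f", .SYNC_BASES)
  mcols <- .sync_col("m", .SYNC_BASES)
  fstr <- do.call(paste, c(unname(as.list(sync[fcols])), sep = ":"))
  mstr <- do.call(paste, c(unname(as.list(sync[mcols])), sep = ":"))
  p1 <- if (femaleFirst) fstr else mstr
  p2 <- if (femaleFirst) mstr else fstr
  writeLines(paste(sync$lg, sync$pos, sync$ref, p1, p2, sep = "\t"), path)
  invisible(path)
}

# parse one pileup base string into counts of A,T,C,G,N,del given quals
.parse_pileup_bases <- function(bases, quals, ref, minBaseq) {
  counts <- stats::setNames(integer(6), .SYNC_BASES)
  chars <- strsplit(bases, "")[[1]]
  qual <- utf8ToInt(quals) - 33L
  i <- 1L; qi <- 1L
  n <- length(chars)
  while (i <= n) {
    c0 <- chars[i]
    if (c0 == "^") { i <- i + 2L; next }          # read start + mapq char
    if (c0 == "$") { i <- i + 1L; next }          # read end
    if (c0 == "+" || c0 == "-") {                 # indel: consume length + seq
      j <- i + 1L
      while (j <= n && grepl("[0-9]", chars[j])) j <- j + 1L
      len <- as.integer(paste(chars[(i + 1L):(j - 1L)], collapse = ""))
      i <- j + len
      next
    }
    # a base-column symbol: consumes one quality character
    if (qi > length(qual))
      stop("ragged pileup record: more base symbols than quality characters")
    q <- qual[qi]; qi <- qi + 1L
    if (q >= minBaseq) {
      b <- switch(toupper(c0),
                  "." = ref, "," = ref,
                  "A" = "A", "C" = "C", "G" = "G", "T" = "T", "N" = "N",
                  "*" = "del",
                  NA_character_)   # '>'/'<' reference skips etc.
      if (!is.na(b)) counts[b] <- counts[b] + 1L
    }
    i <- i + 1L
  }
  if (qi != length(qual) + 1L)
    stop("ragged pileup record: base and quality columns disagree")
  counts
}

#' Convert samtools-style pileup text to sync counts
#'
#' Parses mpileup text with two pools (columns: lg, pos, ref, then
#' depth/bases/qualities per pool) into per-pool base counts. Base
#' calls below the PHRED cutoff are filtered out; `.`/`,` resolve to
#' the reference base; indel sub-strings and read start/end markers are
#' consumed and skipped; `*` records a deletion.
#'
#' @param path pileup file.
#' @param minBaseq minimum PHRED base quality. Default 20.
#' @param femaleFirst is the first pool the female pool? Default TRUE.
#' @return a sync data.frame (see [readSync]).
#' @export
pileupToSync <- function(path, minBaseq = 20, femaleFirst = TRUE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9)) {
    bad <- which(nf != 9)[1]
    stop(sprintf("line %d: expected 9 tab-separated fields (lg, pos, ref, then depth/bases/quals per pool), found %d",
                 bad, nf[bad]))
  }
  m <- do.call(rbind, parts)
  ref <- toupper(m[, 3])
  pool <- function(bcol, qcol) {
    t(vapply(seq_len(nrow(m)), function(i) {
      .parse_pileup_bases(m[i, bcol], m[i, qcol], ref[i], minBaseq)
    }, stats::setNames(integer(6), .SYNC_BASES)))
  }
  p1 <- pool(5, 6)
  p2 <- pool(8, 9)
  f <- if (femaleFirst) p1 else p2
  mm <- if (femaleFirst) p2 else p1
  out <- data.frame(lg = m[, 1], pos = as.numeric(m[, 2]), ref = ref,
                    stringsAsFactors = FALSE)
  for (b in .SYNC_BASES) out[[.sync_col("f", b)]] <- f[, b]
  for (b in .SYNC_BASES) out[[.sync_col("m", b)]] <- mm[, b]
  out
}

.pool_matrix <- function(sync, pool) {
  as.matrix(sync[, .sync_col(pool, c("A", "T", "C", "G"))])
}

#' Per-site pooled FST between the sexes
#'
#' Computes, for every site, the pooled-sample fixation index between
#' the female and male pools from the A/C/G/T counts (N and deletions
#' never enter the denominators). With per-pool allele frequency
#' vectors \eqn{\hat p_i}, the within-pool heterozygosity is
#' \eqn{H_S = \mathrm{mean}_i(1 - \sum_a \hat p_{i,a}^2)}, the total
#' heterozygosity \eqn{H_T = 1 - \sum_a \bar p_a^2} with
#' \eqn{\bar p} the unweighted mean of the two pool frequency vectors
#' (pools, not read depths, are the sampling units), and
#' \eqn{F_{ST} = (H_T - H_S)/H_T}, defined as 0 when \eqn{H_T = 0}.
#' Sites with zero A/C/G/T depth in either pool are undefined (`NA`).
#'
#' @param sync sync data.frame (one or more rows).
#' @return numeric vector of FST values in \[0, 1\] (`NA` where
#'   undefined).
#' @export
siteFst <- function(sync) {
  f <- .pool_matrix(sync, "f")
  m <- .pool_matrix(sync, "m")
  df <- rowSums(f); dm <- rowSums(m)
  pf <- f / ifelse(df > 0, df, NA)
  pm <- m / ifelse(dm > 0, dm, NA)
  hs <- ((1 - rowSums(pf^2)) + (1 - rowSums(pm^2))) / 2
  pbar <- (pf + pm) / 2
  ht <- 1 - rowSums(pbar^2)
  fst <- ifelse(ht == 0, 0, (ht - hs) / ht)
  # clamp tiny negative rounding noise
  pmin(pmax(fst, 0), 1)
}

#' Classify sites as XY- or ZW-patterned SNPs
#'
#' A site is XY-patterned when the female pool is fixed (its
#' major-allele frequency reaches `fixedThreshold`) while the male pool
#' carries an allele absent from the female pool at intermediate
#' frequency (inside `hetRange`): the male is heterozygous X/Y there.
#' ZW-patterned is the mirror image (male fixed, female carrying the
#' male-absent allele at intermediate frequency). Sites where either
#' pool has A/C/G/T depth below `minDepth`, or where more than two
#' alleles segregate across the pools, are unclassified. Alleles are
#' considered segregating when their pooled count across both pools is
#' at least 2; singleton counts are treated as the sequencing-error
#' floor (they still count toward depths, frequencies and the
#' fixed-pool test).
#'
#' @param sync sync data.frame.
#' @param fixedThreshold major-allele frequency required to call a pool
#'   fixed. Default 1.0.
#' @param hetRange closed frequency interval for the heterogametic
#'   pool's sex-limited allele. Default `c(0.3, 0.7)`.
#' @param minDepth minimum A/C/G/T depth per pool. Default 5.
#' @return character vector: `"XY"`, `"ZW"` or `"none"` per site.
#' @export
classifySexSnp <- function(sync, fixedThreshold = 1.0, hetRange = c(0.3, 0.7),
                           minDepth = 5) {
  f <- .pool_matrix(sync, "f")
  m <- .pool_matrix(sync, "m")
  df <- rowSums(f); dm <- rowSums(m)
  tot <- f + m
  nseg <- rowSums(tot >= 2)
  out <- rep("none", nrow(f))
  usable <- df >= minDepth & dm >= minDepth & nseg <= 2
  if (!any(usable)) return(out)
  one_dir <- function(fixed, het, dfx, dht) {
    # fixed pool's major allele
    maj <- max.col(fixed, ties.method = "first")
    idx <- cbind(seq_len(nrow(fixed)), maj)
    majFreq <- fixed[idx] / dfx
    # candidate sex-limited allele: best-supported het-pool allele that is
    # absent from the fixed pool
    hetOnly <- het
    hetOnly[fixed > 0] <- -1L
    cand <- max.col(hetOnly, ties.method = "first")
    cidx <- cbind(seq_len(nrow(het)), cand)
    candFreq <- ifelse(hetOnly[cidx] > 0, het[cidx] / dht, 0)
    majFreq >= fixedThreshold &
      candFreq >= hetRange[1] & candFreq <= hetRange[2]
  }
  xy <- one_dir(f, m, df, dm)
  zw <- one_dir(m, f, dm, df)
  # a site satisfying both directions is ambiguous, not a sex SNP;
  # this also makes the classification exactly symmetric under pool swap
  out[usable & xy & !zw] <- "XY"
  out[usable & zw & !xy] <- "ZW"
  out
}

#' Classified sex-patterned SNP table
#'
#' Convenience wrapper: classifies every site (see [classifySexSnp]),
#' computes pooled FST (see [siteFst]) and returns the sites that
#' received an XY or ZW call.
#'
#' @inheritParams classifySexSnp
#' @return data.frame with `lg`, `pos` (1-based), `pattern`, `fst`,
#'   `freqF` and `freqM` (frequency of the sex-limited allele in each
#'   pool).
#' @export
findSexSnps <- function(sync, fixedThreshold = 1.0, hetRange = c(0.3, 0.7),
                        minDepth = 5) {
  pattern <- classifySexSnp(sync, fixedThreshold, hetRange, minDepth)
  keep <- pattern != "none"
  if (!any(keep)) {
    return(data.frame(lg = character(0), pos = numeric(0),
                      pattern = character(0), fst = numeric(0),
                      freqF = numeric(0), freqM = numeric(0)))
  }
  sub <- sync[keep, , drop = FALSE]
  f <- .pool_matrix(sub, "f")
  m <- .pool_matrix(sub, "m")
  df <- rowSums(f); dm <- rowSums(m)
  pat <- pattern[keep]
  # the sex-limited allele: the heterogametic pool's strongest allele
  # absent from the fixed pool
  het <- ifelse(pat == "XY", "m", "f")
  hetM <- m; fixM <- f
  hetM[het == "f", ] <- f[het == "f", ]
  fixM[het == "f", ] <- m[het == "f", ]
  hetOnly <- hetM
  hetOnly[fixM > 0] <- -1L
  cand <- max.col(hetOnly, ties.method = "first")
  idx <- cbind(seq_len(nrow(sub)), cand)
  data.frame(lg = sub$lg, pos = sub$pos, pattern = pat,
             fst = siteFst(sub),
             freqF = f[idx] / df, freqM = m[idx] / dm)
}
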