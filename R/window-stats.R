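#' Tile linkage groups into consecutive windows
#'
#' Produces per linkage group the half-open windows
#' `[0, size), [size, 2*size), ...` keeping the final partial window.
#' Zero-length linkage groups yield no windows.
#'
#' @param lgLengths named numeric linkage-group lengths (bp).
#' @param size window size in bp. Default 1e5 (the 100-kb windows used
#'   for sex-patterned SNP densities).
#' @return a `GRanges` of windows (1-based closed internally; BED
#'   export via [exportBed] restores 0-based half-open coordinates).
#' @export
makeWindows <- function(lgLengths, size = 1e5) {
  lgLengths <- .as_lg_lengths(lgLengths)
  .assert_scalar_number(size, "size", lower = 1)
  lgLengths <- lgLengths[lgLengths > 0]
  if (length(lgLengths) == 0)
    return(GenomicRanges::GRanges())
  GenomicRanges::tileGenome(lgLengths, tilewidth = min(size, sum(lgLengths)),
                            cut.last.tile.in.chrom = TRUE)
}

#' Count sex-patterned SNPs per window
#'
#' Assigns each classified SNP to exactly one window (positions are
#' 1-based in the SNP table; windows are half-open, so a SNP at 0-based
#' position `size` falls in the second window) and records per-window
#' XY and ZW counts and the log2(XY:ZW) ratio.
#'
#' @param snps data.frame with `lg`, `pos` (1-based) and `pattern`
#'   (`"XY"`/`"ZW"`), e.g. from [findSexSnps].
#' @param windows `GRanges` from [makeWindows].
#' @param pseudocount added to both counts in the log ratio. Default 1.
#' @return the windows `GRanges` with metadata columns `xy`, `zw` and
#'   `logRatio`.
#' @export
windowSnpDensity <- function(snps, windows, pseudocount = 1) {
  if (nrow(snps) > 0) {
    bad <- !snps$lg %in% GenomeInfoDb::seqlevels(windows)
    if (any(bad))
      stop("SNP outside any window: ", snps$lg[bad][1], ":", snps$pos[bad][1])
    gr <- GenomicRanges::GRanges(snps$lg, IRanges::IRanges(snps$pos, width = 1L))
    hitw <- GenomicRanges::findOverlaps(gr, windows, select = "first")
    if (anyNA(hitw)) {
      i <- which(is.na(hitw))[1]
      stop("SNP outside any window: ", snps$lg[i], ":", snps$pos[i])
    }
    xy <- tabulate(hitw[snps$pattern == "XY"], nbins = length(windows))
    zw <- tabulate(hitw[snps$pattern == "ZW"], nbins = length(windows))
  } else {
    xy <- zw <- integer(length(windows))
  }
  S4Vectors::mcols(windows)$xy <- xy
  S4Vectors::mcols(windows)$zw <- zw
  S4Vectors::mcols(windows)$logRatio <- log2Ratio(xy, zw, pseudocount)
  windows
}

#' log2 ratio of XY to ZW SNP counts
#'
#' `log2((xy + pseudocount) / (zw + pseudocount))`. The pseudocount
#' keeps zero-count windows finite (they are the common case at 100 kb)
#' and maps equal counts to 0; positive values suggest XY
#' differentiation, negative ZW.
#'
#' @param xy,zw non-negative counts (vectorized).
#' @param pseudocount positive constant; a value of 0 is rejected when
#'   any count is zero. Default 1.
#' @return numeric vector of log2 ratios.
#' @examples
#' log2Ratio(7, 1)    # 2
#' log2Ratio(1, 7)    # -2
#' @export
log2Ratio <- function(xy, zw, pseudocount = 1) {
  if (any(xy < 0) || any(zw < 0)) stop("counts must be >= 0")
  if (pseudocount <= 0 && any(xy == 0 | zw == 0))
    stop("zero counts present: use a positive pseudocount")
  log2((xy + pseudocount) / (zw + pseudocount))
}

.rank_ties <- function(r) {
  # sum of t^3 - t over tie groups of the mid-rank vector
  t <- table(r)
  sum(t^3 - t)
}

#' Kruskal-Wallis rank test across linkage groups
#'
#' Mid-rank based Kruskal-Wallis H with tie correction:
#' \deqn{H = \frac{\frac{12}{N(N+1)} \sum_i R_i^2/n_i - 3(N+1)}{1 - \sum(t^3 - t)/(N^3 - N)}}
#' with p from the chi-square distribution on `groups - 1` degrees of
#' freedom. Used to ask whether the per-window log2(XY:ZW) ratio
#' differs among chromosomes. All-tied input gives `H = 0`, `p = 1`.
#'
#' @param values numeric vector (e.g. per-window log ratios).
#' @param groups grouping vector of the same length (linkage groups).
#' @return list with `H`, `df` and `p`.
#' @export
kruskalWallis <- function(values, groups) {
  groups <- as.character(groups)
  if (length(values) != length(groups))
    stop("values and groups must have equal length")
  if (length(unique(groups)) < 2)
    stop("at least two groups are required")
  if (any(tapply(values, groups, length) < 1))
    stop("every group needs at least one value")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  rsum <- tapply(r, groups, sum)
  nsize <- tapply(r, groups, length)
  h0 <- 12 / (n * (n + 1)) * sum(rsum^2 / nsize) - 3 * (n + 1)
  corr <- 1 - .rank_ties(r) / (n^3 - n)
  h <- if (corr == 0) 0 else h0 / corr
  df <- length(unique(groups)) - 1L
  p <- if (corr == 0) 1 else stats::pchisq(h, df, lower.tail = FALSE)
  list(H = h, df = df, p = p)
}

#' Dunn's post-hoc test with Benjamini-Hochberg correction
#'
#' Pairwise follow-up to [kruskalWallis], identifying which
#' chromosomes differ. For groups i and j,
#' \deqn{z_{ij} = \frac{\bar R_i - \bar R_j}{\sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum(t^3-t)}{12(N-1)}\right)\left(\frac{1}{n_i}+\frac{1}{n_j}\right)}}}
#' with mid-ranks over all N values, two-sided p from the standard
#' normal, and BH adjustment across all pairs.
#'
#' @inheritParams kruskalWallis
#' @param adjust multiple-testing method (passed to
#'   [stats::p.adjust]). Default `"BH"`.
#' @return data.frame with `group1`, `group2`, `z`, `p`, `pAdj`.
#' @export
dunnPosthoc <- function(values, groups, adjust = "BH") {
  groups <- as.character(groups)
  if (length(unique(groups)) < 2)
    stop("at least two groups are required")
  nsize <- tapply(values, groups, length)
  if (any(nsize < 1)) stop("every group needs at least one value")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  rmean <- tapply(r, groups, mean)
  tiecorr <- .rank_ties(r) / (12 * (n - 1))
  varterm <- n * (n + 1) / 12 - tiecorr
  gl <- sort(names(rmean))
  pairs <- utils::combn(gl, 2)
  z <- vapply(seq_len(ncol(pairs)), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    se <- sqrt(varterm * (1 / nsize[[g1]] + 1 / nsize[[g2]]))
    if (se == 0) 0 else (rmean[[g1]] - rmean[[g2]]) / se
  }, numeric(1))
  p <- 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             pAdj = stats::p.adjust(p, method = adjust))
}

#' Per-chromosome median of genome-wide window ranks
#'
#' Ranks all windows genome-wide by their log2(XY:ZW) ratio, ascending,
#' breaking ties by input order (the "first" rule), then reports per
#' linkage group the median of its windows' ranks (mean of the middle
#' two when even). A chromosome whose median rank is an outlier - high
#' for XY, low for ZW - is the sex-chromosome candidate; the "first"
#' tie rule keeps the many all-zero windows from collapsing onto one
#' shared mid-rank.
#'
#' @param windows `GRanges` from [windowSnpDensity] (needs `logRatio`).
#' @return named numeric vector, linkage group -> median rank.
#' @export
medianRankByLg <- function(windows) {
  if (length(windows) == 0) stop("no windows")
  lr <- S4Vectors::mcols(windows)$logRatio
  if (is.null(lr)) stop("windows carry no logRatio; run windowSnpDensity first")
  rk <- rank(lr, ties.method = "first")
  lg <- as.character(GenomicRanges::seqnames(windows))
  vapply(split(rk, lg), stats::median, numeric(1))[unique(lg)]
}

#' Chromosome-level screen of log2(XY:ZW) window ratios
#'
#' Runs the full rank screen over annotated windows: Kruskal-Wallis
#' across linkage groups, Dunn's post-hoc with BH correction, and the
#' per-chromosome median-rank diagnostic.
#'
#' @param windows `GRanges` from [windowSnpDensity].
#' @param dropEmpty drop windows with zero SNPs of both patterns before
#'   testing. Default FALSE (all windows retained, carrying log-ratio
#'   0).
#' @param adjust multiple-testing method for Dunn pairs. Default
#'   `"BH"`.
#' @return a [ChromScreenResult].
#' @export
screenChromosomes <- function(windows, dropEmpty = FALSE, adjust = "BH") {
  mc <- S4Vectors::mcols(windows)
  if (is.null(mc$logRatio)) stop("run windowSnpDensity first")
  if (dropEmpty) windows <- windows[mc$xy + mc$zw > 0]
  if (length(windows) == 0) stop("no windows left to screen")
  lr <- S4Vectors::mcols(windows)$logRatio
  lg <- as.character(GenomicRanges::seqnames(windows))
  kw <- kruskalWallis(lr, lg)
  kw$pAdj <- kw$p   # single test per screen; BH across species is external
  dunn <- dunnPosthoc(lr, lg, adjust = adjust)
  new("ChromScreenResult", kw = kw, dunn = dunn,
      medianRank = medianRankByLg(windows), nWindows = length(windows))
}
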