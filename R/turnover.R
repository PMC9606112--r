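#' Cross-species sharing of sex-specific k-mers
#'
#' Intersects the male- and female-specific k-mer sets of two species
#' in all four combinations. Because X and W (and Y and Z) carry the
#' history of the gametologs, the pattern of which cells dominate
#' carries the polarity of a sex-chromosome turnover (see
#' [inferPolarity]). Sharing can be restricted to k-mers placed on one
#' linkage group by passing the k-mers mapped there.
#'
#' @param aMale,aFemale [KmerSet]s of species A (male-/female-specific).
#' @param bMale,bFemale [KmerSet]s of species B.
#' @param restrictTo optional character vector of k-mers (e.g. the
#'   `kmer` column of hits on one linkage group); only k-mers in this
#'   set are counted. Unplaced k-mers are thereby excluded.
#' @param speciesA,speciesB labels.
#' @param lg label of the restriction linkage group (bookkeeping only).
#' @return a [SharedKmerTable].
#' @export
crossShareTable <- function(aMale, aFemale, bMale, bFemale,
                            restrictTo = NULL,
                            speciesA = "speciesA", speciesB = "speciesB",
                            lg = NA_character_) {
  sets <- list(aMale, aFemale, bMale, bFemale)
  ks <- vapply(sets, kmerSize, integer(1))
  if (length(unique(ks)) != 1)
    stop("all four k-mer sets must share the same k")
  keyset <- lapply(sets, kmers)
  if (!is.null(restrictTo))
    keyset <- lapply(keyset, intersect, y = restrictTo)
  counts <- c(
    mm = length(intersect(keyset[[1]], keyset[[3]])),
    mf = length(intersect(keyset[[1]], keyset[[4]])),
    fm = length(intersect(keyset[[2]], keyset[[3]])),
    ff = length(intersect(keyset[[2]], keyset[[4]])))
  new("SharedKmerTable", speciesA = speciesA, speciesB = speciesB,
      counts = as.numeric(counts) |> stats::setNames(names(counts)), lg = lg)
}

#' Infer the polarity of a sex-chromosome turnover
#'
#' Given the shared k-mer table between an XY species and a ZW species,
#' relabels the four cells by gametolog pair (male of a ZW species
#' carries Z/Z; its female-specific k-mers tag the W; the XY species'
#' female-specific k-mers tag the X, its male-specific k-mers the Y)
#' and asks which gametolog is common to the two largest cells. When
#' both of the other species' gametologs share most of their
#' sex-specific k-mers with one chromosome, they both descend from it:
#' that chromosome is the ancestral sex-limited (or sex-shared)
#' gametolog and its system is ancestral. The canonical configuration -
#' (W, X) maximal with (W, Y) second - therefore reads "ZW ancestral;
#' the Y arose on a W haplotype"; the configurations with X, Y or Z as
#' the common gametolog are the corresponding mirrors.
#'
#' The call requires the largest cell to exceed the runner-up, and the
#' runner-up to exceed the remaining cells, by at least
#' `minDominance`; otherwise the polarity is indeterminate.
#'
#' @param t a [SharedKmerTable].
#' @param systemA,systemB "XY" or "ZW" for species A and B (one of
#'   each).
#' @param minDominance minimal ratio between ordered cells. Default 2.
#' @return a [PolarityCall].
#' @export
inferPolarity <- function(t, systemA, systemB, minDominance = 2) {
  stopifnot(is(t, "SharedKmerTable"))
  systems <- c(systemA, systemB)
  if (!setequal(systems, c("XY", "ZW")))
    stop("one species must be XY and the other ZW")
  cnt <- t@counts
  # relabel cells by gametolog pair; cell names are "<ZW-gametolog>:<XY-gametolog>"
  gam_a <- if (systemA == "ZW") c(m = "Z", f = "W") else c(m = "Y", f = "X")
  gam_b <- if (systemB == "ZW") c(m = "Z", f = "W") else c(m = "Y", f = "X")
  pair_name <- function(a, b) {
    g <- c(gam_a[[a]], gam_b[[b]])
    zw <- g[g %in% c("Z", "W")]
    xy <- g[g %in% c("X", "Y")]
    paste(zw, xy, sep = ":")
  }
  cells <- c(pair_name("m", "m"), pair_name("m", "f"),
             pair_name("f", "m"), pair_name("f", "f"))
  byPair <- stats::setNames(as.numeric(cnt[c("mm", "mf", "fm", "ff")]), cells)
  indeterminate <- function(dom, mx = NA_character_, ru = NA_character_) {
    new("PolarityCall", ancestralSystem = "indeterminate",
        narrative = "polarity indeterminate: no gametolog pair dominates",
        maxCell = mx, runnerUp = ru, dominance = dom)
  }
  if (all(byPair == 0)) {
    warning("all four sharing cells are zero; polarity indeterminate")
    return(indeterminate(NA_real_))
  }
  ord <- order(byPair, decreasing = TRUE)
  mx <- names(byPair)[ord[1]]
  ru <- names(byPair)[ord[2]]
  dom1 <- byPair[ord[1]] / byPair[ord[2]]           # max vs runner-up
  dom2 <- byPair[ord[2]] / max(byPair[ord[3]], 1)   # runner-up vs the rest
  ok <- is.finite(dom1) && dom1 >= minDominance && dom2 >= minDominance
  common <- intersect(strsplit(mx, ":")[[1]], strsplit(ru, ":")[[1]])
  if (ok && length(common) == 1) {
    anc_sys <- if (common %in% c("Z", "W")) "ZW" else "XY"
    # the derived species' sex-limited gametolog is the chromosome that
    # "arose" on the ancestral one: Y for a derived XY, W for a derived ZW
    new_lim <- if (anc_sys == "ZW") "Y" else "W"
    return(new("PolarityCall", ancestralSystem = anc_sys,
               narrative = sprintf("%s ancestral; %s arose on a%s %s haplotype",
                                   anc_sys, new_lim,
                                   if (common == "X") "n" else "", common),
               maxCell = mx, runnerUp = ru, dominance = unname(dom1)))
  }
  indeterminate(unname(dom1), mx, ru)
}

#' Convert a sex-specific k-mer count to an estimated SNP count
#'
#' An isolated substitution between gametologs creates `k` overlapping
#' sex-specific k-mers, so the number of underlying SNPs is estimated
#' as `n_kmers / k`. Reported raw (rounded to the nearest integer) and
#' at two significant figures, the convention used when quoting
#' genome-scale totals (one million 22-mers corresponds to roughly
#' 45,000 SNPs).
#'
#' @param nKmers number of sex-specific k-mers (>= 0).
#' @param k k-mer length. Default 22.
#' @return list with `nKmers`, `k`, `raw` (rounded quotient) and
#'   `estimate` (two significant figures).
#' @examples
#' estimateSnpsFromKmers(1e6, 22)   # raw 45455, estimate 45000
#' @export
estimateSnpsFromKmers <- function(nKmers, k = 22) {
  .assert_scalar_number(nKmers, "nKmers", lower = 0)
  .assert_scalar_number(k, "k", lower = 1)
  raw <- round(nKmers / k)
  list(nKmers = nKmers, k = k, raw = raw, estimate = signif(raw, 2))
}

#' Tabular form of a shared-k-mer table
#'
#' @param t a [SharedKmerTable].
#' @return a data.frame with one labeled row per cell.
#' @export
sharedKmerTableAsDf <- function(t) {
  stopifnot(is(t, "SharedKmerTable"))
  data.frame(
    speciesA = t@speciesA, speciesB = t@speciesB,
    sexA = c("male", "male", "female", "female"),
    sexB = c("male", "female", "male", "female"),
    shared = as.numeric(t@counts[c("mm", "mf", "fm", "ff")]),
    lg = t@lg)
}
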