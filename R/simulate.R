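#' Simulate a multi-linkage-group genome
#'
#' Draws i.i.d. bases at a given GC content for each linkage group.
#' Deterministic per seed: the same (`lgLengths`, `gc`, `seed`) always
#' yields the same sequences.
#'
#' @param lgLengths named numeric vector of linkage-group lengths (bp).
#' @param gc GC content in \[0, 1\]. Default 0.4 (typical for teleost
#'   genomes).
#' @param seed integer seed.
#' @return a `DNAStringSet`, one sequence per linkage group.
#' @export
simulateGenome <- function(lgLengths, gc = 0.4, seed) {
  lgLengths <- .as_lg_lengths(lgLengths)
  .assert_scalar_number(gc, "gc", lower = 0, upper = 1)
  if (missing(seed)) stop("a seed is required")
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  seqs <- with_seed(seed, lapply(lgLengths, function(n) {
    paste(sample(names(prob), n, replace = TRUE, prob = prob), collapse = "")
  }))
  out <- Biostrings::DNAStringSet(unlist(seqs))
  names(out) <- names(lgLengths)
  out
}

.mutate_positions <- function(seq_chars, pos1) {
  # substitute each 1-based position with a uniformly drawn different base
  bases <- c("A", "C", "G", "T")
  for (p in pos1) {
    cur <- seq_chars[p]
    seq_chars[p] <- sample(setdiff(bases, cur), 1)
  }
  seq_chars
}

#' Plant a diverged sex-determining region
#'
#' Builds the four haplotypes of a sex system on top of a simulated
#' genome: the sex-limited haplotype (Y for XY, W for ZW) differs from
#' its homolog by substitutions at positions drawn uniformly without
#' replacement within the region at rate `d` (so positions are at
#' least 1 bp apart and the expected SNP count is `d * span`); the
#' homogametic sex carries two identical copies of the unmodified
#' genome. This mirrors the observed architecture of young but
#' extensive sex-determining regions, where the heterogametic
#' chromosome is uniformly diverged over a large fraction of one
#' linkage group.
#'
#' @param genome `DNAStringSet` from [simulateGenome].
#' @param lg linkage group to carry the region.
#' @param region numeric(2), 0-based half-open bounds within `lg`.
#' @param d substitutions per bp between the gametologs, in
#'   \[0, 0.2\].
#' @param system `"XY"` or `"ZW"`.
#' @param seed integer seed.
#' @return list with `haplotypes` (per sex, a list of two genome-wide
#'   `DNAStringSet`s: the heterogametic sex carries the diverged copy)
#'   and `truth` (a [SimTruth]).
#' @export
plantSexSystem <- function(genome, lg, region, d, system = c("XY", "ZW"),
                           seed) {
  system <- match.arg(system)
  stopifnot(is(genome, "DNAStringSet"))
  if (!lg %in% names(genome)) stop("unknown linkage group: ", lg)
  lglen <- Biostrings::width(genome)[names(genome) == lg]
  if (region[1] < 0 || region[2] > lglen || region[1] >= region[2])
    stop("region must be 0-based half-open within the linkage group")
  .assert_scalar_number(d, "d", lower = 0, upper = 0.2)
  if (missing(seed)) stop("a seed is required")
  span <- region[2] - region[1]
  if (d > 0 && d * span < 1)
    warning("d * span < 1: the region may receive zero planted SNPs")
  res <- with_seed(seed, {
    nsnp <- stats::rbinom(1, span, d)
    pos0 <- sort(sample.int(span, nsnp)) - 1L + region[1]  # 0-based
    chars <- strsplit(as.character(genome[[lg]]), "")[[1]]
    chars <- .mutate_positions(chars, pos0 + 1L)
    list(nsnp = nsnp, pos0 = pos0, seq = paste(chars, collapse = ""))
  })
  seqs <- as.character(genome)
  seqs[[lg]] <- res$seq
  diverged <- Biostrings::DNAStringSet(seqs)
  names(diverged) <- names(genome)
  truth <- new("SimTruth", system = system, lg = lg,
               regionStart = region[1], regionEnd = region[2],
               divergence = d, snpPositions = as.numeric(res$pos0),
               seed = as.integer(seed))
  het <- list(genome, diverged)          # X/Y or Z/W
  hom <- list(genome, genome)            # X/X or Z/Z
  haplotypes <- if (system == "XY") list(female = hom, male = het)
                else list(female = het, male = hom)
  list(haplotypes = haplotypes, truth = truth)
}

.sim_reads_one_pool <- function(haps, coverage, readLen, err) {
  # haps: list of genome-wide DNAStringSet haplotypes, drawn uniformly
  glen <- sum(Biostrings::width(haps[[1]]))
  nreads <- round(coverage * glen / readLen)
  hap_id <- sample.int(length(haps), nreads, replace = TRUE)
  lgw <- Biostrings::width(haps[[1]])
  lgn <- names(haps[[1]])
  ok <- lgw >= readLen
  if (!any(ok)) stop("read length exceeds every linkage group")
  lg_id <- sample.int(sum(ok), nreads, replace = TRUE,
                      prob = lgw[ok] / sum(lgw[ok]))
  lg_id <- which(ok)[lg_id]
  start <- as.integer(floor(stats::runif(nreads) * (lgw[lg_id] - readLen))) + 1L
  reads <- character(nreads)
  err_pos <- vector("list", 0)
  for (h in seq_along(haps)) {
    for (l in unique(lg_id[hap_id == h])) {
      sel <- which(hap_id == h & lg_id == l)
      if (!length(sel)) next
      v <- Biostrings::Views(haps[[h]][[lgn[l]]],
                             start = start[sel], width = readLen)
      reads[sel] <- as.character(v)
    }
  }
  nerr <- stats::rbinom(1, nreads * readLen, err)
  err_at <- if (nerr > 0) sample.int(nreads * readLen, nerr) else integer(0)
  if (length(err_at)) {
    ri <- (err_at - 1L) %/% readLen + 1L
    pi <- (err_at - 1L) %% readLen + 1L
    for (j in seq_along(ri)) {
      cur <- substr(reads[ri[j]], pi[j], pi[j])
      sub <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
      substr(reads[ri[j]], pi[j], pi[j]) <- sub
    }
  }
  list(reads = reads, errRead = if (length(err_at)) (err_at - 1L) %/% readLen + 1L else integer(0),
       errPos = if (length(err_at)) (err_at - 1L) %% readLen + 1L else integer(0))
}

#' Simulate pooled short reads per sex
#'
#' Draws single-end reads uniformly from each sex's haplotypes (each
#' read picks one of the individual's two haplotypes at random, which
#' is equivalent to an equal mixture of identical pool members) and
#' injects uniform substitution errors. Emulates the coverage regime
#' of low-pass pool-seq: 6-20x per pool, 150-bp reads.
#'
#' @param haplotypes per-sex haplotype list from [plantSexSystem].
#' @param coverage depth per pool (x). Applied to each sex.
#' @param readLen read length in bp. Default 150.
#' @param err per-base substitution error rate. Default 0.002.
#' @param seed integer seed.
#' @param markErrors when TRUE, bases that received an error get PHRED
#'   quality 10 instead of 30 in the emitted qualities (exercises
#'   downstream base-quality filters).
#' @return list with per-sex elements `female` and `male`, each a list
#'   of `reads` (character vector) and `qualities` (character vector,
#'   constant Q30 except where `markErrors` applies).
#' @export
simulatePoolReads <- function(haplotypes, coverage, readLen = 150,
                              err = 0.002, seed, markErrors = FALSE) {
  .assert_scalar_number(coverage, "coverage", lower = 1e-9)
  if (missing(seed)) stop("a seed is required")
  with_seed(seed, {
    out <- lapply(haplotypes, function(haps) {
      r <- .sim_reads_one_pool(haps, coverage, readLen, err)
      qual <- strrep(rawToChar(as.raw(30 + 33)), readLen)
      quals <- rep(qual, length(r$reads))
      if (markErrors && length(r$errRead)) {
        for (j in seq_along(r$errRead)) {
          substr(quals[r$errRead[j]], r$errPos[j], r$errPos[j]) <-
            rawToChar(as.raw(10 + 33))
        }
      }
      list(reads = r$reads, qualities = quals)
    })
    out
  })
}

#' Write simulated reads as FASTQ
#'
#' @param pool list with `reads` and `qualities` (one sex's element of
#'   [simulatePoolReads] output).
#' @param path output FASTQ path.
#' @param prefix read-name prefix. Default "read".
#' @return `path`, invisibly.
#' @export
writeFastq <- function(pool, path, prefix = "read") {
  dss <- Biostrings::DNAStringSet(pool$reads)
  names(dss) <- paste0(prefix, seq_along(pool$reads))
  qs <- Biostrings::BStringSet(pool$qualities)
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = qs)
  invisible(path)
}

#' Simulate sync-format allele counts with planted truth
#'
#' Generates per-site pooled counts directly (bypassing reads and
#' alignment) for testing the SNP classification and window statistics.
#' At planted sites the heterogametic pool draws its sex-limited allele
#' count from Binomial(depth, 0.5) and the homogametic pool is fixed
#' for the reference allele; background sites are polymorphic in both
#' pools at rate `backgroundSnpRate` with a shared allele frequency
#' drawn from Uniform(0.1, 0.9); all remaining sites are monomorphic.
#' Sequencing error reassigns Binomial(depth, err) reads per pool and
#' site to a uniformly chosen other base.
#'
#' @param truth a [SimTruth].
#' @param lgLengths named numeric linkage-group lengths; sites are
#'   emitted for every position of every linkage group.
#' @param depth pool depth per site. Default 20.
#' @param err per-base error rate. Default 0.002.
#' @param backgroundSnpRate fraction of non-planted sites carrying
#'   shared polymorphism. Default 0.001.
#' @param seed integer seed.
#' @return a sync data.frame (see [readSync]).
#' @export
simulateSync <- function(truth, lgLengths, depth = 20, err = 0.002,
                         backgroundSnpRate = 0.001, seed) {
  stopifnot(is(truth, "SimTruth"))
  lgLengths <- .as_lg_lengths(lgLengths)
  .assert_scalar_number(depth, "depth", lower = 1)
  if (missing(seed)) stop("a seed is required")
  bases <- c("A", "T", "C", "G")
  with_seed(seed, {
    lg <- rep(names(lgLengths), lgLengths)
    pos <- unlist(lapply(lgLengths, seq_len), use.names = FALSE)
    n <- length(pos)
    ref <- sample(bases, n, replace = TRUE)
    fcnt <- matrix(0L, n, 6, dimnames = list(NULL, .SYNC_BASES))
    mcnt <- matrix(0L, n, 6, dimnames = list(NULL, .SYNC_BASES))
    ridx <- cbind(seq_len(n), match(ref, .SYNC_BASES))
    fcnt[ridx] <- depth
    mcnt[ridx] <- depth
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    aidx <- cbind(seq_len(n), match(alt, .SYNC_BASES))
    planted <- lg == truth@lg & (pos - 1) %in% truth@snpPositions
    bg <- !planted & stats::runif(n) < backgroundSnpRate
    # planted: heterogametic pool intermediate, homogametic fixed
    hetm <- if (truth@system == "XY") "m" else "f"
    np <- sum(planted)
    if (np > 0) {
      nalt <- stats::rbinom(np, depth, 0.5)
      tgt <- if (hetm == "m") "mcnt" else "fcnt"
      cntm <- get(tgt)
      cntm[ridx[planted, , drop = FALSE]] <- depth - nalt
      cntm[aidx[planted, , drop = FALSE]] <- nalt
      assign(tgt, cntm)
    }
    # background: shared polymorphism, independent binomial sampling
    nb <- sum(bg)
    if (nb > 0) {
      q <- stats::runif(nb, 0.1, 0.9)
      fa <- stats::rbinom(nb, depth, q)
      ma <- stats::rbinom(nb, depth, q)
      fcnt[ridx[bg, , drop = FALSE]] <- depth - fa
      fcnt[aidx[bg, , drop = FALSE]] <- fa
      mcnt[ridx[bg, , drop = FALSE]] <- depth - ma
      mcnt[aidx[bg, , drop = FALSE]] <- ma
    }
    inject_err <- function(cnt) {
      nerr <- stats::rbinom(n, depth, err)
      for (i in which(nerr > 0)) {
        for (e in seq_len(nerr[i])) {
          have <- which(cnt[i, 1:4] > 0)
          src <- if (length(have) == 1) have else
            sample(have, 1, prob = cnt[i, have])
          dst <- sample(setdiff(1:4, src), 1)
          cnt[i, src] <- cnt[i, src] - 1L
          cnt[i, dst] <- cnt[i, dst] + 1L
        }
      }
      cnt
    }
    if (err > 0) {
      fcnt <- inject_err(fcnt)
      mcnt <- inject_err(mcnt)
    }
    out <- data.frame(lg = lg, pos = pos, ref = ref, stringsAsFactors = FALSE)
    for (b in .SYNC_BASES) out[[.sync_col("f", b)]] <- fcnt[, b]
    for (b in .SYNC_BASES) out[[.sync_col("m", b)]] <- mcnt[, b]
    out
  })
}

#' Simulate a sex-chromosome turnover between two species
#'
#' Builds the haplotypes of an ancestral ZW species and a derived XY
#' species in which the turnover had ZW -> XY polarity: the ancestral W
#' carries divergence `dZW` from the Z/reference over the region; in
#' the derived species both X and Y descend from that W, the Y with
#' additional private substitutions at rate `dY` (the new sex
#' determiner arose on a W haplotype, and the non-recombining Y then
#' degenerates comparatively fast) and the X with slower private drift
#' at rate `dX`. Setting `polarity = "XY"` mirrors every role (an
#' ancestral XY species and a derived ZW species whose Z and W descend
#' from the X).
#'
#' Downstream, the expected sharing pattern (after k-mer extraction at
#' finite coverage) is the diagnostic: the derived species'
#' female-specific k-mers overlap the ancestral female-specific (W)
#' k-mers most, with the derived male-specific (Y) k-mers second.
#'
#' @param lgLengths named numeric linkage-group lengths.
#' @param lg linkage group carrying the system.
#' @param region numeric(2), 0-based half-open region bounds.
#' @param dZW ancestral gametolog divergence. Default 0.03.
#' @param dY private divergence of the derived sex-limited chromosome.
#'   Default 0.02.
#' @param dX private drift of the derived homogametic chromosome.
#'   Default 5e-4.
#' @param polarity simulated true polarity: `"ZW"` (ZW ancestral,
#'   default) or `"XY"` (mirrored).
#' @param gc GC content of the background genome. Default 0.4.
#' @param seed integer seed.
#' @return list with `ancestral` and `derived` haplotype lists (each
#'   with `female` and `male` elements as in [plantSexSystem]) and
#'   `truth` (list with the planted positions of each divergence
#'   layer and the true polarity).
#' @export
simulateTurnover <- function(lgLengths, lg, region, dZW = 0.03, dY = 0.02,
                             dX = 5e-04, polarity = c("ZW", "XY"), gc = 0.4,
                             seed) {
  polarity <- match.arg(polarity)
  if (missing(seed)) stop("a seed is required")
  genome <- simulateGenome(lgLengths, gc = gc, seed = seed)
  anc <- plantSexSystem(genome, lg, region, dZW,
                        system = if (polarity == "ZW") "ZW" else "XY",
                        seed = seed + 1L)
  # the ancestral sex-limited haplotype (W for ZW polarity)
  hetsex <- if (polarity == "ZW") "female" else "male"
  wlike <- anc$haplotypes[[hetsex]][[2]]
  drift <- function(base_genome, d, s) {
    p <- plantSexSystem(base_genome, lg, region, d,
                        system = "XY", seed = s)  # system label irrelevant here
    list(genome = p$haplotypes$male[[2]], pos = p$truth@snpPositions)
  }
  newsex <- drift(wlike, dY, seed + 2L)   # Y (or W') with private divergence
  homdrift <- drift(wlike, dX, seed + 3L) # X (or Z') with slow private drift
  derived_het <- list(homdrift$genome, newsex$genome)
  derived_hom <- list(homdrift$genome, homdrift$genome)
  derived <- if (polarity == "ZW")
    list(female = derived_hom, male = derived_het)   # XX females, XY males
  else
    list(female = derived_het, male = derived_hom)   # ZW females, ZZ males
  list(ancestral = anc$haplotypes, derived = derived,
       truth = list(polarity = polarity, lg = lg, region = region,
                    ancestralSnps = anc$truth@snpPositions,
                    newSexSnps = newsex$pos, homDriftSnps = homdrift$pos,
                    seed = as.integer(seed)))
}

#' Write a SimTruth as JSON and BED
#'
#' @param truth a [SimTruth].
#' @param jsonPath path for the JSON truth record.
#' @param bedPath optional path for a BED interval of the region.
#' @return `jsonPath`, invisibly.
#' @export
writeSimTruth <- function(truth, jsonPath, bedPath = NULL) {
  stopifnot(is(truth, "SimTruth"))
  jsonlite::write_json(
    list(system = truth@system, lg = truth@lg,
         regionStart = truth@regionStart, regionEnd = truth@regionEnd,
         divergence = truth@divergence, snpPositions = truth@snpPositions,
         seed = truth@seed),
    jsonPath, auto_unbox = TRUE, digits = NA)
  if (!is.null(bedPath)) {
    writeLines(paste(truth@lg, format(truth@regionStart, scientific = FALSE),
                     format(truth@regionEnd, scientific = FALSE),
                     paste0("sex_region_", truth@system), sep = "\t"),
               bedPath)
  }
  invisible(jsonPath)
}
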