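#' @useDynLib sexlinker, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.default_config <- function() {
  list(
    k = 22L, minCount = 2L, sampleN = 1e6, seed = 1L,
    window = 1e5, pseudocount = 1,
    foldThreshold = 3, minDominance = 2,
    fixedThreshold = 1.0, hetRangeLow = 0.3, hetRangeHigh = 0.7,
    minDepth = 5, femaleFirst = TRUE, maxMismatch = 1L,
    blockMinFold = 5, blockMergeGap = 1L, minLgLength = 1e6,
    readsFemale = NA_character_, readsMale = NA_character_,
    reference = NA_character_, sync = NA_character_)
}

#' Read a flat key = value run configuration
#'
#' One `key = value` (or `key: value`) pair per line; `#` starts a
#' comment. Unknown keys raise an error; missing keys take the
#' documented defaults. The parsed configuration is echoed verbatim
#' into the run manifest.
#'
#' @param path configuration file.
#' @return a named list (a run configuration).
#' @export
readRunConfig <- function(path) {
  cfg <- .default_config()
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  for (ln in lines) {
    kv <- strsplit(ln, "[=:]", perl = TRUE)[[1]]
    if (length(kv) < 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    if (!key %in% names(cfg)) stop("unknown config key: ", key)
    cur <- cfg[[key]]
    cfg[[key]] <- if (is.logical(cur)) as.logical(val)
      else if (is.numeric(cur) || is.integer(cur)) as.numeric(val)
      else val
  }
  validateRunConfig(cfg)
}

#' Validate a run configuration
#'
#' @param cfg named list as produced by [readRunConfig] or assembled
#'   in code; missing entries are filled with defaults.
#' @return the completed configuration, invisibly usable.
#' @export
validateRunConfig <- function(cfg) {
  full <- .default_config()
  unknown <- setdiff(names(cfg), names(full))
  if (length(unknown)) stop("unknown config keys: ", paste(unknown, collapse = ", "))
  full[names(cfg)] <- cfg
  .assert_scalar_number(full$k, "k", 1, 32)
  .assert_scalar_number(full$minCount, "minCount", 1)
  .assert_scalar_number(full$sampleN, "sampleN", 0)
  .assert_scalar_number(full$window, "window", 1)
  .assert_scalar_number(full$pseudocount, "pseudocount", 0)
  .assert_scalar_number(full$foldThreshold, "foldThreshold", 1)
  .assert_scalar_number(full$minDominance, "minDominance", 1)
  .assert_scalar_number(full$fixedThreshold, "fixedThreshold", 0.5, 1)
  .assert_scalar_number(full$hetRangeLow, "hetRangeLow", 0, 1)
  .assert_scalar_number(full$hetRangeHigh, "hetRangeHigh", 0, 1)
  if (full$hetRangeLow >= full$hetRangeHigh)
    stop("hetRangeLow must be below hetRangeHigh")
  .assert_scalar_number(full$minDepth, "minDepth", 1)
  full
}

.md5_or_na <- function(path) {
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
}

#' Run the full sex-chromosome discovery pipeline
#'
#' Orchestrates the stages end to end and writes every intermediate to
#' a run directory with a JSON manifest: per-sex k-mer counting, sex-
#' specific set subtraction, random subsampling, placement on the
#' reference, per-LG enrichment for both sexes, the sex-linkage-group
#' call, differentiated blocks on the called linkage group, and - when
#' a sync file is provided - SNP classification, window densities and
#' the chromosome-level rank screen. Deterministic given the
#' configuration: all randomness flows from `cfg$seed`, and no
#' timestamps are written, so two runs with identical inputs produce
#' byte-identical outputs.
#'
#' @param cfg run configuration (see [readRunConfig]); `readsFemale`
#'   and `readsMale` are required, `reference` and `sync` optional.
#' @param outDir output directory (created).
#' @return list with the principal results (`sexCall`, `enrichment`,
#'   `blocks`, `screen`, paths of all written files), invisibly.
#' @export
runPipeline <- function(cfg, outDir) {
  cfg <- validateRunConfig(cfg)
  # validate inputs before any computation or output
  inputs <- c(readsFemale = cfg$readsFemale, readsMale = cfg$readsMale)
  if (!is.na(cfg$reference)) inputs <- c(inputs, reference = cfg$reference)
  if (!is.na(cfg$sync)) inputs <- c(inputs, sync = cfg$sync)
  if (anyNA(inputs[c("readsFemale", "readsMale")]))
    stop("readsFemale and readsMale are required")
  missing_in <- inputs[!file.exists(inputs)]
  if (length(missing_in))
    stop("missing input file(s): ", paste(missing_in, collapse = ", "))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  log <- character(0)
  note <- function(stage, msg) {
    log[[length(log) + 1L]] <<- sprintf("[%s] %s", stage, msg)
  }

  tabF <- countKmers(cfg$readsFemale, k = cfg$k, minCount = cfg$minCount,
                     sourceLabel = "female")
  tabM <- countKmers(cfg$readsMale, k = cfg$k, minCount = cfg$minCount,
                     sourceLabel = "male")
  note("count", sprintf("female: %d k-mers; male: %d k-mers (k=%d, minCount=%d)",
                        length(tabF), length(tabM), cfg$k, cfg$minCount))
  paths$dumpFemale <- writeKmerDump(tabF, file.path(outDir, "female.kmers.txt"))
  paths$dumpMale <- writeKmerDump(tabM, file.path(outDir, "male.kmers.txt"))

  dif <- diffKmerSets(tabF, tabM, labels = c("female-specific", "male-specific"))
  note("diff", sprintf("female-specific: %d; male-specific: %d",
                       length(dif$aOnly), length(dif$bOnly)))
  sampF <- sampleKmers(dif$aOnly, cfg$sampleN, seed = cfg$seed)
  sampM <- sampleKmers(dif$bOnly, cfg$sampleN, seed = cfg$seed + 1L)
  paths$setFemale <- writeKmerSet(sampF, file.path(outDir, "female_specific.txt"))
  paths$setMale <- writeKmerSet(sampM, file.path(outDir, "male_specific.txt"))

  res <- list(femaleSpecific = sampF, maleSpecific = sampM, sexCall = NULL,
              enrichment = NULL, blocks = NULL, screen = NULL)

  if (!is.na(cfg$reference)) {
    idx <- indexReference(cfg$reference, k = cfg$k)
    mapF <- mapKmers(sampF, idx, maxMismatch = cfg$maxMismatch)
    mapM <- mapKmers(sampM, idx, maxMismatch = cfg$maxMismatch)
    note("map", sprintf("female: %d placed, %d unmapped; male: %d placed, %d unmapped",
                        length(mapF$hits), mapF$unmapped,
                        length(mapM$hits), mapM$unmapped))
    enrF <- lgEnrichment(mapF$hits, lgLengths(idx), label = "female")
    enrM <- lgEnrichment(mapM$hits, lgLengths(idx), label = "male")
    enr <- rbind(as.data.frame(enrM), as.data.frame(enrF))
    paths$enrichment <- writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    call <- callSexLinkageGroup(enrM, enrF, foldThreshold = cfg$foldThreshold,
                                minLgLength = cfg$minLgLength)
    note("call", sprintf("system %s on %s (fold %.2f)", call@system,
                         ifelse(is.na(call@lg), "-", call@lg), call@fold))
    res$sexCall <- call
    res$enrichment <- enr
    if (call@system != "none") {
      hits <- if (call@system == "XY") mapM$hits else mapF$hits
      blk <- callBlocks(hits, lgLengths(idx), lg = call@lg, k = cfg$k,
                        window = cfg$window, minFold = cfg$blockMinFold,
                        mergeGap = cfg$blockMergeGap)
      res$blocks <- blk
      if (length(blk$blocks)) {
        paths$blocksBed <- exportBed(blk$blocks, file.path(outDir, "blocks.bed"))
        bdf <- as.data.frame(blk$blocks)
        paths$blocksTsv <- writeTsv(bdf, file.path(outDir, "blocks.tsv"))
      }
      note("blocks", sprintf("%d blocks covering %.1f%% of %s",
                             length(blk$blocks), 100 * blk$coverageFraction,
                             call@lg))
    }
  }

  if (!is.na(cfg$sync)) {
    if (is.na(cfg$reference))
      stop("window statistics need linkage-group lengths: provide a reference")
    sync <- readSync(cfg$sync, femaleFirst = cfg$femaleFirst)
    snps <- findSexSnps(sync, fixedThreshold = cfg$fixedThreshold,
                        hetRange = c(cfg$hetRangeLow, cfg$hetRangeHigh),
                        minDepth = cfg$minDepth)
    note("snp", sprintf("%d sex-patterned SNPs (%d XY, %d ZW)", nrow(snps),
                        sum(snps$pattern == "XY"), sum(snps$pattern == "ZW")))
    paths$snps <- writeTsv(snps, file.path(outDir, "sex_snps.tsv"))
    idx <- indexReference(cfg$reference, k = cfg$k)
    win <- makeWindows(lgLengths(idx), size = cfg$window)
    win <- windowSnpDensity(snps, win, pseudocount = cfg$pseudocount)
    paths$windows <- writeTsv(as.data.frame(win), file.path(outDir, "windows.tsv"))
    scr <- screenChromosomes(win)
    res$screen <- scr
    paths$dunn <- writeTsv(scr@dunn, file.path(outDir, "dunn.tsv"))
    paths$medianRank <- writeTsv(
      data.frame(lg = names(scr@medianRank), medianRank = scr@medianRank),
      file.path(outDir, "median_rank.tsv"))
    note("screen", sprintf("KW H = %.2f, p %s over %d windows", scr@kw$H,
                           .format_p(scr@kw$p), scr@nWindows))
  }

  manifest <- list(
    config = cfg[order(names(cfg))],
    stages = log,
    files = lapply(paths, function(p)
      list(path = basename(p), md5 = .md5_or_na(p))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$manifest <- file.path(outDir, "manifest.json")
  res$paths <- paths
  invisible(res)
}
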