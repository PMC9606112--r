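# internal helpers

# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

.assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x < lower || x > upper)
    stop(sprintf("'%s' must be a single number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  invisible(x)
}

.as_lg_lengths <- function(lgLengths) {
  if (is.null(names(lgLengths)) || any(!nzchar(names(lgLengths))))
    stop("linkage-group lengths must be a named vector", call. = FALSE)
  if (any(lgLengths < 0)) stop("linkage-group lengths must be >= 0", call. = FALSE)
  lgLengths
}

# read FASTA/FASTQ (gz accepted) or pass a DNAStringSet / character through
.as_dna_reads <- function(reads) {
  if (is(reads, "DNAStringSet")) return(as.character(reads))
  if (is.character(reads) && length(reads) >= 1 &&
      all(file.exists(reads))) {
    seqs <- unlist(lapply(reads, function(p) {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", p, ignore.case = TRUE))
        "fastq" else "fasta"
      as.character(Biostrings::readDNAStringSet(p, format = fmt))
    }))
    return(unname(seqs))
  }
  if (is.character(reads)) return(reads)
  stop("reads must be a character vector of sequences, file paths, or a DNAStringSet",
       call. = FALSE)
}

#' Write a data frame as tab-separated text
#'
#' Plain TSV writer used for all tabular outputs (no quoting, no row
#' names), so runs diff cleanly.
#'
#' @param x a data.frame or DataFrame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export genomic intervals as BED
#'
#' Writes a `GRanges` as BED (0-based half-open) via rtracklayer.
#'
#' @param gr a `GRanges`.
#' @param path output file (.bed).
#' @return `path`, invisibly.
#' @export
exportBed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
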