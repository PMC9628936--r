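#' Evaluate an expression with a locally scoped RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulators are deterministic without touching
#' global random state.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse-complement DNA strings
#'
#' @param x Character vector of DNA sequences (A/C/G/T).
#' @return Character vector of reverse complements.
#' @examples
#' revcomp("ACGGT")
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Generate random DNA sequences
#'
#' @param n Number of sequences.
#' @param length Length of each sequence (recycled).
#' @param seed Optional integer seed.
#' @return Character vector of `n` sequences.
#' @export
random_dna <- function(n, length, seed = NULL) {
  length <- rep_len(length, n)
  gen <- function() {
    vapply(length, function(l) {
      paste(sample(DNA_BASES, l, replace = TRUE), collapse = "")
    }, character(1))
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGT]", x)
  if (any(bad)) {
    abort(sprintf("%s contains non-ACGT characters (first offender: %s)",
                  what, x[which(bad)[1]]))
  }
  invisible(x)
}

#' Read and write FASTQ as a tibble
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that present reads as a two-column
#' tibble (`read_id`, `sequence`), the exchange format used throughout
#' the package. Written qualities are constant placeholders; the pipeline
#' is quality-agnostic past basecalling.
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: a tibble with columns `read_id`, `sequence`.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble::tibble(read_id = names(set), sequence = as.character(set))
}

#' @rdname read_fastq
#' @param reads Tibble with columns `read_id`, `sequence`.
#' @export
write_fastq <- function(reads, path) {
  set <- Biostrings::DNAStringSet(reads$sequence)
  names(set) <- reads$read_id
  qual <- Biostrings::BStringSet(strrep("I", nchar(reads$sequence)))
  Biostrings::writeXStringSet(set, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read and write TSV tables
#'
#' @param x Data frame to write.
#' @param path File path.
#' @return `read_tsv_file()` returns a tibble.
#' @keywords internal
write_tsv_file <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_file
#' @keywords internal
read_tsv_file <- function(path) {
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}
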