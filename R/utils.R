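#' @importFrom Biostrings DNAStringSet BStringSet readDNAStringSet
#'   writeXStringSet reverseComplement
#' @importFrom S4Vectors mcols
#' @importFrom stats runif
#' @importFrom utils read.table write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character strings
#' (IUPAC codes, including `N`, are handled).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' reverse_complement(c("ACGT", "TTTT"))
reverse_complement <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Reverse a plain string (not complemented).
str_rev <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

# Equal-width strings -> integer matrix (n rows, width columns) of UTF-8
# code points. Workhorse for Hamming computations.
seq_int_matrix <- function(x) {
  if (length(x) == 0L) return(matrix(integer(0), nrow = 0, ncol = 0))
  w <- nchar(x[1L])
  if (any(nchar(x) != w)) stop("sequences must all have equal length")
  if (w == 0L) return(matrix(integer(0), nrow = length(x), ncol = 0))
  t(vapply(x, utf8ToInt, integer(w), USE.NAMES = FALSE))
}

#' Hamming distance between two equal-length strings
#'
#' @param a,b Single character strings of equal length.
#' @return Integer number of mismatching positions. Any character
#'   difference (including `N` vs a base) counts as a mismatch.
#' @export
hamming_dist <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hamming_dist: unequal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# Hamming distances from string `x` to every row of an integer matrix M
# (as produced by seq_int_matrix).
hamming_to_rows <- function(x, M) {
  if (nrow(M) == 0L) return(integer(0))
  v <- utf8ToInt(x)
  if (length(v) != ncol(M)) stop("hamming_to_rows: unequal lengths")
  as.integer(rowSums(M != rep(v, each = nrow(M))))
}

# Phred score(s) -> quality character string(s)
phred_char <- function(q) {
  vapply(q, function(s) intToUtf8(s + 33L), character(1), USE.NAMES = FALSE)
}

# Quality string -> integer Phred scores
qual_ints <- function(qual) utf8ToInt(qual) - 33L

#' Expected number of sequencing errors of a read
#'
#' Sums per-base error probabilities `10^(-Q/10)` from Phred+33 quality
#' strings. `N` bases contribute an error probability of 1 regardless of
#' their quality score.
#'
#' @param seq Character vector of read sequences.
#' @param qual Character vector of Phred+33 quality strings, same lengths.
#' @return Numeric vector of expected error counts.
#' @export
expected_errors <- function(seq, qual) {
  if (length(seq) != length(qual)) stop("seq/qual length mismatch")
  mapply(function(s, q) {
    if (nchar(s) != nchar(q)) stop("sequence/quality width mismatch")
    p <- 10^(-(utf8ToInt(q) - 33L) / 10)
    p[utf8ToInt(s) == utf8ToInt("N")] <- 1
    sum(p)
  }, seq, qual, USE.NAMES = FALSE)
}

# ---- FASTA / FASTQ I/O (Biostrings-backed; gzip transparent) ----

#' Read a FASTQ file into a data frame
#'
#' @param path FASTQ file, optionally gzip-compressed. 4-line records,
#'   Phred+33.
#' @return `data.frame` with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x),
             seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a read data frame to FASTQ
#'
#' @param reads `data.frame` with columns `id`, `seq`, `qual`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file, optionally gzipped.
#' @return Named character vector (names are full header lines).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  out <- as.character(x)
  names(out) <- names(x)
  out
}

#' Write a named character vector as FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path; `.gz` triggers compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}
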