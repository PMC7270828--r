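# Raw-read preprocessing: demultiplexing by inline barcode, fixed-position
# trimming of adapter remnants, joining of the mate pairs around an
# artificial padgap, expected-error quality filtering, wobble-keyed PCR
# clone removal, and bisulfite conversion-rate estimation from the
# common-adapter check cytosine. All operations are order-stable by
# contract: forward and reverse streams stay matched by position.

#' Read a pair of FASTQ files as a read-pair set
#'
#' @param r1_path,r2_path Forward / reverse FASTQ files (optionally `.gz`).
#' @return List with elements `forward` and `reverse`, each a read
#'   `data.frame` (`id`, `seq`, `qual`), matched by position.
#' @export
read_pairs <- function(r1_path, r2_path) {
  fwd <- read_fastq(r1_path)
  rev <- read_fastq(r2_path)
  if (nrow(fwd) != nrow(rev))
    stop("forward and reverse FASTQ have different read counts")
  list(forward = fwd, reverse = rev)
}

n_pairs <- function(pairs) nrow(pairs$forward)

subset_pairs <- function(pairs, idx) {
  list(forward = pairs$forward[idx, , drop = FALSE],
       reverse = pairs$reverse[idx, , drop = FALSE])
}

#' Demultiplex read pairs by inline barcode
#'
#' Read 1 is compared against every barcode as a prefix (longest barcodes
#' first). A pair is assigned to the unique sample whose barcode attains
#' the minimal Hamming distance within `max_mismatches`; equal-best-distance
#' ties go to `unassigned`. The matched barcode prefix is removed from the
#' forward sequence and quality. No restriction-site remnant check is
#' performed.
#'
#' @param pairs Read-pair set from [read_pairs()].
#' @param barcodes Named character vector `sample -> barcode`.
#' @param max_mismatches Maximum Hamming distance inside the barcode
#'   (`N` counts as a mismatch). Default 1.
#' @return List with `samples` (named list of read-pair sets, barcode
#'   stripped), `unassigned` (read-pair set) and `counts`
#'   (`data.frame` sample/n, including an `unassigned` row).
#' @export
demultiplex <- function(pairs, barcodes, max_mismatches = 1L) {
  validate_barcodes(barcodes)
  if (max_mismatches < 0L) stop("max_mismatches must be >= 0")
  ord <- order(nchar(barcodes), decreasing = TRUE)
  barcodes <- barcodes[ord]
  n <- n_pairs(pairs)
  dist <- matrix(NA_integer_, nrow = n, ncol = length(barcodes))
  for (k in seq_along(barcodes)) {
    bc <- barcodes[[k]]
    w <- nchar(bc)
    pre <- substr(pairs$forward$seq, 1L, w)
    ok <- nchar(pre) == w
    d <- rep(NA_integer_, n)
    if (any(ok)) {
      M <- seq_int_matrix(pre[ok])
      d[ok] <- hamming_to_rows(bc, M)
    }
    dist[, k] <- d
  }
  dist[is.na(dist)] <- .Machine$integer.max
  best <- if (n == 0L) integer(0) else apply(dist, 1L, min)
  nbest <- rowSums(dist == best)
  assigned_k <- max.col(-dist, ties.method = "first")
  hit <- best <= max_mismatches & nbest == 1L
  sample_of <- ifelse(hit, names(barcodes)[assigned_k], NA_character_)

  samples <- list()
  for (s in names(barcodes)) {
    idx <- which(!is.na(sample_of) & sample_of == s)
    sub <- subset_pairs(pairs, idx)
    w <- nchar(barcodes[[s]])
    sub$forward$seq <- substring(sub$forward$seq, w + 1L)
    sub$forward$qual <- substring(sub$forward$qual, w + 1L)
    samples[[s]] <- sub
  }
  unassigned <- subset_pairs(pairs, which(is.na(sample_of)))
  counts <- data.frame(
    sample = c(names(barcodes), "unassigned"),
    n = c(vapply(samples, n_pairs, integer(1)), n_pairs(unassigned)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(samples = samples, unassigned = unassigned, counts = counts)
}

#' Trim adapter remnants at fixed positions
#'
#' Removes the first `strip_forward` bases of read 1 (the restriction-site
#' overhang left after barcode removal) and the first `strip_reverse` bases
#' of read 2 (wobble plus common-adapter remnant), then truncates both to
#' `truncate_to` bases so all samples share one read length. Pairs too
#' short for the full trim are dropped and counted.
#'
#' @param pairs Read-pair set (post-demultiplex).
#' @param strip_forward,strip_reverse Bases removed from the 5' ends.
#' @param truncate_to Final length of both mates.
#' @return List with `pairs` (trimmed set) and `dropped` (integer count).
#' @export
trim_pairs <- function(pairs, strip_forward = 4L, strip_reverse = 14L,
                       truncate_to = 86L) {
  need_f <- strip_forward + truncate_to
  need_r <- strip_reverse + truncate_to
  keep <- nchar(pairs$forward$seq) >= need_f &
    nchar(pairs$reverse$seq) >= need_r
  dropped <- sum(!keep)
  if (dropped > 0L)
    warning(dropped, " pair(s) too short for trimming; dropped")
  out <- subset_pairs(pairs, which(keep))
  out$forward$seq <- substr(out$forward$seq, strip_forward + 1L, need_f)
  out$forward$qual <- substr(out$forward$qual, strip_forward + 1L, need_f)
  out$reverse$seq <- substr(out$reverse$seq, strip_reverse + 1L, need_r)
  out$reverse$qual <- substr(out$reverse$qual, strip_reverse + 1L, need_r)
  list(pairs = out, dropped = dropped)
}

#' Join trimmed mates around an artificial padgap
#'
#' Output sequence is `forward + padgap + reverse_complement(reverse)`;
#' the pad positions receive a constant quality score. The layout attribute
#' records the 1-based index ranges of the forward, pad and reverse spans.
#'
#' @param pairs Trimmed read-pair set (both mates equal length).
#' @param padgap Pad sequence inserted between the mates.
#' @param pad_quality Phred score assigned to pad positions (default 40,
#'   i.e. `"I"`).
#' @return Read `data.frame` (`id`, `seq`, `qual`) with attribute
#'   `layout = list(forward = c(from,to), pad = ..., reverse = ...)`.
#' @export
join_pairs <- function(pairs, padgap = "ATATATAT", pad_quality = 40L) {
  lf <- nchar(pairs$forward$seq)
  lr <- nchar(pairs$reverse$seq)
  if (n_pairs(pairs) > 0L && (length(unique(lf)) != 1L ||
                              length(unique(lr)) != 1L || lf[1] != lr[1]))
    stop("join_pairs requires equal-length reads")
  w <- if (n_pairs(pairs) > 0L) lf[1] else 0L
  p <- nchar(padgap)
  padq <- strrep(substr(phred_char(pad_quality), 1, 1), p)
  joined <- data.frame(
    id = pairs$forward$id,
    seq = paste0(pairs$forward$seq, padgap,
                 reverse_complement(pairs$reverse$seq)),
    qual = paste0(pairs$forward$qual, padq, str_rev(pairs$reverse$qual)),
    stringsAsFactors = FALSE)
  attr(joined, "layout") <- list(forward = c(1L, w),
                                 pad = c(w + 1L, w + p),
                                 reverse = c(w + p + 1L, 2L * w + p))
  joined
}

#' Expected-error-rate quality filter
#'
#' A read passes iff its expected error count per base,
#' `sum(10^(-Q/10)) / L`, is strictly below `max_rate`; reads whose rate
#' equals the threshold fail. `N` bases contribute error probability 1.
#'
#' @param joined Read `data.frame` with `seq` and `qual`, or a character
#'   vector of sequences (then `qual` must be given).
#' @param max_rate Maximum tolerated expected errors per base.
#' @param qual Quality strings when `joined` is a character vector.
#' @return Logical vector: `TRUE` = pass.
#' @export
filter_maxee_rate <- function(joined, max_rate = 0.01, qual = NULL) {
  if (is.data.frame(joined)) {
    seqs <- joined$seq
    qual <- joined$qual
  } else seqs <- joined
  if (any(!nzchar(seqs))) stop("empty sequence")
  ee <- expected_errors(seqs, qual)
  ee / nchar(seqs) < max_rate
}

#' Remove PCR clones using the wobble bases
#'
#' Applied to raw (pre-trim) pairs: the dedup key is the first
#' `wobble_length` bases of read 2 together with the full read-1 sequence
#' and the remainder of read 2. The first occurrence of each key is kept;
#' later occurrences are counted as clones.
#'
#' @param pairs Raw read-pair set.
#' @param wobble_length Number of degenerate bases at the start of read 2.
#' @return List with `pairs` (deduplicated set) and `clones`
#'   (integer count removed).
#' @export
clone_filter <- function(pairs, wobble_length = 5L) {
  key <- paste(substr(pairs$reverse$seq, 1L, wobble_length),
               pairs$forward$seq,
               substring(pairs$reverse$seq, wobble_length + 1L),
               sep = "\r")
  dup <- duplicated(key)
  list(pairs = subset_pairs(pairs, which(!dup)), clones = sum(dup))
}

#' Estimate bisulfite conversion efficiency from the adapter check cytosine
#'
#' Tallies the base at `check_index` (0-based) of each raw reverse read.
#' The check position is an unmethylated cytosine of the common adapter, so
#' the conversion rate is `#T / (#T + #C)`. Other bases are counted
#' separately and excluded from the rate.
#'
#' @param reverse_reads Character vector of raw reverse-read sequences, or
#'   a read `data.frame` with a `seq` column.
#' @param check_index 0-based position of the check cytosine (default 12:
#'   five wobble bases + `AACTGTGCA` place it at raw index 12).
#' @return Object of class `conversion_stats`: list with `converted`,
#'   `unconverted`, `other`, `rate` (`NA` and a warning when no C/T
#'   observed).
#' @export
conversion_rate <- function(reverse_reads, check_index = 12L) {
  if (is.data.frame(reverse_reads)) reverse_reads <- reverse_reads$seq
  if (any(nchar(reverse_reads) <= check_index))
    stop("reads shorter than check_index + 1")
  base <- substr(reverse_reads, check_index + 1L, check_index + 1L)
  converted <- sum(base == "T")
  unconverted <- sum(base == "C")
  other <- length(base) - converted - unconverted
  rate <- if (converted + unconverted > 0L)
    converted / (converted + unconverted) else NA_real_
  if (is.na(rate))
    warning("no C or T observed at the check position; rate undefined")
  structure(list(converted = converted, unconverted = unconverted,
                 other = other, rate = rate),
            class = "conversion_stats")
}

#' @export
print.conversion_stats <- function(x, ...) {
  cat("Bisulfite conversion check:",
      x$converted, "T,", x$unconverted, "C,", x$other, "other;",
      "rate =", format(x$rate, digits = 4), "\n")
  invisible(x)
}

#' Full preprocessing of a raw paired library
#'
#' Runs clone filtering (optional), demultiplexing, trimming, joining and
#' expected-error filtering, returning per-sample joined reads and a
#' report table.
#'
#' @param pairs Raw read-pair set from [read_pairs()].
#' @param barcodes Named character vector `sample -> barcode`.
#' @param max_mismatches Barcode mismatch tolerance (default 1).
#' @param strip_forward,strip_reverse,truncate_to Trim parameters, see
#'   [trim_pairs()].
#' @param padgap,pad_quality Join parameters, see [join_pairs()].
#' @param max_rate Expected-error-rate threshold, see
#'   [filter_maxee_rate()].
#' @param use_clone_filter Run [clone_filter()] on the raw pairs first.
#' @return List with `joined` (named list of per-sample joined read data
#'   frames, each with the join layout attribute), `report` (`data.frame`:
#'   sample, input, assigned, trimmed, joined, passed), `clones`,
#'   `unassigned`, and `conversion` (a [conversion_rate()] result computed
#'   on the raw reverse reads).
#' @export
preprocess_pairs <- function(pairs, barcodes, max_mismatches = 1L,
                             strip_forward = 4L, strip_reverse = 14L,
                             truncate_to = 86L, padgap = "ATATATAT",
                             pad_quality = 40L, max_rate = 0.01,
                             use_clone_filter = TRUE) {
  input_n <- n_pairs(pairs)
  conv <- conversion_rate(pairs$reverse$seq)
  clones <- 0L
  if (use_clone_filter) {
    cf <- clone_filter(pairs)
    pairs <- cf$pairs
    clones <- cf$clones
  }
  dm <- demultiplex(pairs, barcodes, max_mismatches)
  joined <- list()
  rows <- list()
  for (s in names(dm$samples)) {
    sub <- dm$samples[[s]]
    tr <- suppressWarnings(
      trim_pairs(sub, strip_forward, strip_reverse, truncate_to))
    jn <- join_pairs(tr$pairs, padgap, pad_quality)
    pass <- if (nrow(jn) > 0L) filter_maxee_rate(jn, max_rate) else logical(0)
    kept <- jn[pass, , drop = FALSE]
    attr(kept, "layout") <- attr(jn, "layout")
    joined[[s]] <- kept
    rows[[s]] <- data.frame(sample = s, input = input_n,
                            assigned = n_pairs(sub),
                            trimmed = n_pairs(tr$pairs),
                            joined = nrow(jn), passed = sum(pass),
                            stringsAsFactors = FALSE)
  }
  list(joined = joined,
       report = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       clones = clones,
       unassigned = n_pairs(dm$unassigned),
       conversion = conv)
}
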