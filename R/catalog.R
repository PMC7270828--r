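# Simplified locus stacking and cross-sample cataloging. This is a
# deliberately reduced functional equivalent of ustacks/cstacks: exact-match
# dereplication, single-linkage merging of primary stacks within a Hamming
# radius, depth-weighted majority consensus, and nearest-entry catalog
# matching. No SNP model, no gapped alignment. Real Stacks v2 catalog FASTA
# files are accepted through read_catalog_fasta() as an alternative entry
# point to reconstruction.

# union-find for single-linkage clustering
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[rj] <- ri
  parent
}

# depth-weighted majority consensus of equal-length sequences;
# ties prefer the base carried by the deepest member stack
consensus_seq <- function(seqs, depths) {
  if (length(seqs) == 1L) return(seqs)
  M <- seq_int_matrix(seqs)
  deep_first <- order(depths, decreasing = TRUE)
  out <- integer(ncol(M))
  for (j in seq_len(ncol(M))) {
    w <- tapply(depths, M[, j], sum)
    top <- as.integer(names(w)[w == max(w)])
    if (length(top) == 1L) out[j] <- top
    else {
      # deepest stack whose base is among the tied candidates
      pick <- M[deep_first, j][M[deep_first, j] %in% top][1]
      out[j] <- pick
    }
  }
  intToUtf8(out)
}

#' Build per-sample loci from joined sequences
#'
#' Dereplicates equal-length sequences into exact-match stacks. Stacks with
#' depth at least `min_depth` are primary; primary stacks within
#' `merge_mismatches` Hamming distance are merged by single linkage into
#' one locus whose consensus is the per-position depth-weighted majority
#' (ties resolved toward the deepest stack). Sub-threshold stacks are
#' absorbed into a unique locus within `merge_mismatches` (adding depth
#' without changing the consensus) or discarded.
#'
#' @param seqs Character vector of joined sequences (equal lengths), or a
#'   read `data.frame` with a `seq` column.
#' @param min_depth Minimum stack depth to seed a locus (default 3).
#' @param merge_mismatches Hamming radius for merging/absorbing (default 2).
#' @return `data.frame` with columns `consensus`, `depth`, ordered by
#'   decreasing depth then consensus.
#' @export
build_stacks <- function(seqs, min_depth = 3L, merge_mismatches = 2L) {
  if (is.data.frame(seqs)) seqs <- seqs$seq
  if (length(seqs) == 0L)
    return(data.frame(consensus = character(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  if (length(unique(nchar(seqs))) != 1L)
    stop("build_stacks requires equal-length sequences")
  tab <- table(seqs)
  stack_seq <- names(tab)
  stack_depth <- as.integer(tab)
  primary <- stack_depth >= min_depth
  pseq <- stack_seq[primary]
  pdepth <- stack_depth[primary]
  if (length(pseq) == 0L)
    return(data.frame(consensus = character(0), depth = integer(0),
                      stringsAsFactors = FALSE))
  # single-linkage merge of primary stacks
  M <- seq_int_matrix(pseq)
  parent <- uf_new(length(pseq))
  for (i in seq_along(pseq)) {
    d <- hamming_to_rows(pseq[i], M)
    for (j in which(d <= merge_mismatches)) {
      if (j > i) parent <- uf_union(parent, i, j)
    }
  }
  roots <- vapply(seq_along(parent), function(i) uf_find(parent, i),
                  integer(1))
  loci <- lapply(split(seq_along(pseq), roots), function(idx) {
    list(consensus = consensus_seq(pseq[idx], pdepth[idx]),
         depth = sum(pdepth[idx]))
  })
  cons <- vapply(loci, `[[`, character(1), "consensus")
  dep <- vapply(loci, `[[`, integer(1), "depth")
  # absorb sub-threshold stacks into a unique locus
  sseq <- stack_seq[!primary]
  sdepth <- stack_depth[!primary]
  if (length(sseq)) {
    CM <- seq_int_matrix(cons)
    for (i in seq_along(sseq)) {
      d <- hamming_to_rows(sseq[i], CM)
      hit <- which(d <= merge_mismatches)
      if (length(hit) == 1L) dep[hit] <- dep[hit] + sdepth[i]
    }
  }
  ord <- order(-dep, cons)
  data.frame(consensus = cons[ord], depth = dep[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

new_catalog <- function(consensus, depth, samples, params = list()) {
  structure(
    data.frame(id = seq_along(consensus),
               consensus = consensus,
               depth = depth,
               n_samples = vapply(samples, length, integer(1)),
               line_index = seq_along(consensus) - 1L,
               stringsAsFactors = FALSE, row.names = NULL),
    samples = samples, params = params, class = c("gbs_catalog", "data.frame"))
}

#' Build a cross-sample catalog of locus consensus sequences
#'
#' Samples are processed in input order. Each sample locus either joins the
#' unique nearest existing catalog entry within `catalog_mismatches`
#' Hamming distance (the entry keeps its consensus and gains the sample) or
#' founds a new entry. Equal-distance ambiguity attaches to the
#' earliest-founded entry (recorded in the `ambiguous` attribute).
#'
#' @param sample_loci Named list of per-sample locus tables from
#'   [build_stacks()].
#' @param catalog_mismatches Hamming tolerance between sample loci
#'   (default 4).
#' @return A `gbs_catalog`: `data.frame` with columns `id`, `consensus`,
#'   `depth`, `n_samples`, `line_index` (0-based record index), plus
#'   attributes `samples` (list of sample-id vectors) and `params`.
#' @export
build_catalog <- function(sample_loci, catalog_mismatches = 4L) {
  if (is.null(names(sample_loci)))
    names(sample_loci) <- paste0("sample", seq_along(sample_loci))
  cons <- character(0)
  dep <- integer(0)
  samp <- list()
  ambiguous <- 0L
  M <- NULL  # integer matrix mirror of `cons`, grown incrementally
  for (s in names(sample_loci)) {
    loci <- sample_loci[[s]]
    for (i in seq_len(nrow(loci))) {
      x <- loci$consensus[i]
      if (length(cons) && nchar(x) != nchar(cons[1]))
        stop("catalog loci must all have equal length")
      hit <- NA_integer_
      if (length(cons)) {
        d <- hamming_to_rows(x, M)
        best <- min(d)
        if (best <= catalog_mismatches) {
          cand <- which(d == best)
          if (length(cand) > 1L) ambiguous <- ambiguous + 1L
          hit <- cand[1]  # earliest-founded entry
        }
      }
      if (is.na(hit)) {
        cons <- c(cons, x)
        dep <- c(dep, loci$depth[i])
        samp <- c(samp, list(s))
        M <- rbind(M, utf8ToInt(x))
      } else {
        dep[hit] <- dep[hit] + loci$depth[i]
        samp[[hit]] <- unique(c(samp[[hit]], s))
      }
    }
  }
  out <- new_catalog(cons, dep, samp,
                     params = list(catalog_mismatches = catalog_mismatches))
  attr(out, "ambiguous") <- ambiguous
  out
}

#' Write a catalog to FASTA
#'
#' One record per locus, headers are the integer locus ids.
#'
#' @param catalog A `gbs_catalog` (or data frame with `id`, `consensus`).
#' @param path Output FASTA path (`.gz` allowed).
#' @return `path`, invisibly.
#' @export
write_catalog_fasta <- function(catalog, path) {
  seqs <- catalog$consensus
  names(seqs) <- as.character(catalog$id)
  write_fasta(seqs, path)
}

#' Read a catalog FASTA (own output or Stacks v2 `catalog.fa[.gz]`)
#'
#' The locus id is the header token before the first whitespace; the
#' 0-based record index is recorded as `line_index`.
#'
#' @param path FASTA path, optionally gzipped.
#' @return A `gbs_catalog` (depths and sample sets unknown: `NA`/empty).
#' @export
read_catalog_fasta <- function(path) {
  seqs <- read_fasta(path)
  if (length(seqs) == 0L) {
    warning("empty catalog file: ", path)
    return(new_catalog(character(0), integer(0), list()))
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) stop("duplicate locus ids in ", path)
  out <- new_catalog(unname(seqs), rep(NA_integer_, length(seqs)),
                     rep(list(character(0)), length(seqs)))
  out$id <- suppressWarnings(as.integer(ids))
  if (anyNA(out$id)) out$id <- ids
  out
}
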