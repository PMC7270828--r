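# The reconstruction core. Bisulfite conversion turns cytosine (pyrimidine)
# into thymine (pyrimidine), so a purine/pyrimidine (RY) image of a
# sequence is invariant under conversion. The two converted strands of one
# genomic fragment therefore have RY images that are exact reverse
# complements of each other; matching catalog entries on that key recovers
# Watson/Crick pairs, and comparing the original bases position by position
# recovers the pre-bisulfite sequence together with the methylation state
# of every cytosine on both strands.

#' Purine/pyrimidine encoding
#'
#' Maps `A,G -> R` and `C,T -> Y`. Sequences containing any other character
#' cannot be encoded and yield `NA` (they are excluded from pairing).
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector over `{R,Y}`, `NA` where invalid.
#' @export
#' @examples
#' ry_encode("GATC")   # "RRYY"
ry_encode <- function(x) {
  ok <- grepl("^[ACGTacgt]*$", x) & nzchar(x)
  out <- rep(NA_character_, length(x))
  out[ok] <- chartr("AGCTagct", "RRYYRRYY", x[ok])
  out
}

#' RY key of the reverse complement
#'
#' Swaps `R` and `Y` at every position and reverses the string — the RY
#' image of reverse complementation. A Watson/Crick candidate pair
#' satisfies `ry_encode(watson) == partner_key(ry_encode(crick))`.
#'
#' @param ry Character vector of RY strings.
#' @return Character vector of partner keys.
#' @export
partner_key <- function(ry) {
  str_rev(chartr("RY", "YR", ry))
}

# decode tables over ordered pairs (watson base, rc-crick base).
# 8 informative combinations; the other 8 cannot arise from any duplex
# under bisulfite chemistry and are conflicts.
.DECODE <- local({
  keys <- c(t(outer(c("A", "C", "G", "T"), c("A", "C", "G", "T"), paste0)))
  base <- rep("N", 16)
  call <- rep("conflict", 16)
  names(base) <- names(call) <- keys
  set <- function(k, b, cl) {
    base[k] <<- b
    call[k] <<- cl
  }
  set("AA", "A", "none")
  set("TT", "T", "none")
  set("CC", "C", "meth-C")
  set("TC", "C", "unmeth-C")
  set("CT", "C", "unmeth-C")
  set("GG", "G", "opp-meth-C")
  set("GA", "G", "opp-unmeth-C")
  set("AG", "G", "opp-unmeth-C")
  list(base = base, call = call)
})

# single-character codes used inside per-fragment call strings
CALL_CODES <- c("meth-C" = "M", "unmeth-C" = "U", "opp-meth-C" = "G",
                "opp-unmeth-C" = "g", "none" = ".", "conflict" = "x")

#' Decode one aligned base pair
#'
#' Given the Watson base `w` and the base `p` of the reverse-complemented
#' Crick sequence at the same position, returns the original base and its
#' methylation call: two cytosines mean a methylated cytosine, C/T an
#' unmethylated cytosine, two guanines a guanine with a methylated cytosine
#' on the opposite strand, G/A a guanine with an unmethylated opposite
#' cytosine, concordant A or T no cytosine, and every other combination a
#' conflict (`N`).
#'
#' @param w,p Single bases in `A,C,G,T`.
#' @return Named character vector `c(base = ..., call = ...)`; call is one
#'   of `meth-C`, `unmeth-C`, `opp-meth-C`, `opp-unmeth-C`, `none`,
#'   `conflict`.
#' @export
#' @examples
#' decode_position("G", "A")  # guanine, unmethylated C opposite
decode_position <- function(w, p) {
  if (!w %in% c("A", "C", "G", "T") || !p %in% c("A", "C", "G", "T"))
    stop("decode_position expects single bases in A,C,G,T")
  k <- paste0(w, p)
  c(base = unname(.DECODE$base[k]), call = unname(.DECODE$call[k]))
}

# vectorised decode of two aligned equal-length strings ->
# list(seq, calls (code string), conflicts)
decode_strings <- function(watson, crick_rc) {
  wb <- strsplit(watson, "")[[1]]
  pb <- strsplit(crick_rc, "")[[1]]
  k <- paste0(wb, pb)
  bad <- !k %in% names(.DECODE$base)
  base <- .DECODE$base[k]
  call <- .DECODE$call[k]
  base[bad] <- "N"
  call[bad] <- "conflict"
  list(sequence = paste(base, collapse = ""),
       calls = paste(CALL_CODES[call], collapse = ""),
       conflicts = sum(call == "conflict"))
}

#' Find Watson/Crick locus pairs in a catalog
#'
#' Loci are bucketed by RY image. In catalog order, each unpaired locus
#' looks up the bucket of its partner key; among candidates the one with
#' the fewest decode conflicts wins (ties to the lowest `line_index`).
#' Self-pairing is disallowed, each locus joins at most one pair, and pairs
#' whose best conflict fraction exceeds `max_conflict_fraction` are
#' rejected with both loci left unpaired.
#'
#' @param catalog A `gbs_catalog` (equal-length loci).
#' @param max_conflict_fraction Maximum tolerated fraction of undecodable
#'   positions (default 0.05).
#' @return List with `pairs` (`data.frame`: `watson`, `crick` row indices
#'   into the catalog, `conflicts`) and `unpaired` (integer row indices).
#' @export
find_pairs <- function(catalog, max_conflict_fraction = 0.05) {
  n <- nrow(catalog)
  ry <- ry_encode(catalog$consensus)
  pkey <- ifelse(is.na(ry), NA, partner_key(ry))
  buckets <- split(seq_len(n), ry)
  paired <- logical(n)
  res <- list()
  unpaired <- integer(0)
  for (i in seq_len(n)) {
    if (paired[i]) next
    if (is.na(ry[i])) {
      unpaired <- c(unpaired, i)
      next
    }
    cand <- setdiff(buckets[[pkey[i]]], i)
    cand <- cand[!paired[cand]]
    if (length(cand) == 0L) {
      unpaired <- c(unpaired, i)
      next
    }
    confl <- vapply(cand, function(j) {
      decode_strings(catalog$consensus[i],
                     reverse_complement(catalog$consensus[j]))$conflicts
    }, integer(1))
    best <- min(confl)
    pickable <- cand[confl == best]
    j <- pickable[which.min(catalog$line_index[pickable])]
    L <- nchar(catalog$consensus[i])
    if (best / L > max_conflict_fraction) {
      unpaired <- c(unpaired, i)
      next
    }
    paired[c(i, j)] <- TRUE
    res[[length(res) + 1L]] <- data.frame(watson = i, crick = j,
                                          conflicts = best)
  }
  # anything not in a pair is unpaired
  in_pair <- if (length(res)) unlist(lapply(res, function(r)
    c(r$watson, r$crick))) else integer(0)
  unpaired <- setdiff(seq_len(n), in_pair)
  list(pairs = if (length(res)) do.call(rbind, res) else
    data.frame(watson = integer(0), crick = integer(0),
               conflicts = integer(0)),
       unpaired = unpaired)
}

#' Decode a Watson/Crick pair into the original sequence
#'
#' Applies [decode_position()] logic at every position of
#' `(watson, reverse_complement(crick))`. Conflict positions become `N`.
#'
#' @param watson,crick Equal-length DNA strings (catalog consensus
#'   sequences of the two converted strands).
#' @param max_conflict_fraction Reject the pair when the conflict fraction
#'   exceeds this value.
#' @return List: `sequence`, `calls` (string of per-position codes:
#'   `M` meth-C, `U` unmeth-C, `G` opp-meth-C, `g` opp-unmeth-C, `.` none,
#'   `x` conflict), `conflicts`, `ok` (`FALSE` when rejected).
#' @export
reconstruct_pair <- function(watson, crick, max_conflict_fraction = 0.05) {
  if (nchar(watson) != nchar(crick)) stop("length mismatch")
  dec <- decode_strings(watson, reverse_complement(crick))
  dec$ok <- dec$conflicts / nchar(watson) <= max_conflict_fraction
  dec
}

#' Remove the padgap and merge overlapping read halves
#'
#' The layout splits a decoded joined sequence into a forward part `F`, the
#' pad, and a tail part `T` (the fragment's 3' read image). The pad is
#' removed; the largest overlap `k` with `min_overlap <= k <= |T|` such
#' that the suffix of `F` matches the prefix of `T` with at most
#' `overlap_mismatches` mismatches is merged out. Without a qualifying
#' overlap the two halves are concatenated unchanged. The call string is
#' spliced identically.
#'
#' @param sequence Decoded joined sequence.
#' @param calls Call-code string of equal length (optional).
#' @param layout List with 1-based spans `forward`, `pad`, `reverse`, as
#'   attached by [join_pairs()].
#' @param min_overlap Smallest overlap accepted (default 10).
#' @param overlap_mismatches Mismatches tolerated inside the overlap
#'   (default 0).
#' @return List: `sequence`, `calls`, `merged` (logical),
#'   `overlap_length`.
#' @export
strip_padgap_and_merge <- function(sequence, calls = NULL, layout,
                                   min_overlap = 10L,
                                   overlap_mismatches = 0L) {
  f <- substr(sequence, layout$forward[1], layout$forward[2])
  t_ <- substr(sequence, layout$reverse[1], layout$reverse[2])
  cf <- if (!is.null(calls)) substr(calls, layout$forward[1],
                                    layout$forward[2]) else NULL
  ct <- if (!is.null(calls)) substr(calls, layout$reverse[1],
                                    layout$reverse[2]) else NULL
  lf <- nchar(f)
  lt <- nchar(t_)
  k_found <- 0L
  if (min(lf, lt) >= min_overlap) {
    for (k in seq(min(lf, lt), min_overlap, by = -1L)) {
      if (hamming_dist(substr(f, lf - k + 1L, lf), substr(t_, 1L, k)) <=
          overlap_mismatches) {
        k_found <- k
        break
      }
    }
  }
  if (k_found > 0L) {
    list(sequence = paste0(f, substring(t_, k_found + 1L)),
         calls = if (!is.null(calls))
           paste0(cf, substring(ct, k_found + 1L)) else NULL,
         merged = TRUE, overlap_length = k_found)
  } else {
    list(sequence = paste0(f, t_),
         calls = if (!is.null(calls)) paste0(cf, ct) else NULL,
         merged = FALSE, overlap_length = 0L)
  }
}

#' Reconstruct all fragments of a catalog
#'
#' Runs [find_pairs()], decodes every accepted pair, strips the padgap and
#' merges overlapping halves. Fragment names are the `line_index` of the
#' pair's lower-indexed (Watson) member, following the convention that the
#' first catalog record that allowed a reconstruction names it.
#'
#' @param catalog A `gbs_catalog`.
#' @param padgap Pad sequence used at joining (locates the layout).
#' @param min_overlap,overlap_mismatches See [strip_padgap_and_merge()].
#' @param max_conflict_fraction See [find_pairs()].
#' @return List: `fragments` (`data.frame`: `name`, `sequence`, `calls`,
#'   `merged`, `overlap_length`, `conflicts`), `unpaired` (catalog row
#'   indices), `n_pairs`.
#' @export
reconstruct_loci <- function(catalog, padgap = "ATATATAT",
                             min_overlap = 10L, overlap_mismatches = 0L,
                             max_conflict_fraction = 0.05) {
  if (nrow(catalog) == 0L)
    return(list(fragments = data.frame(name = character(0),
                                       sequence = character(0),
                                       calls = character(0),
                                       merged = logical(0),
                                       overlap_length = integer(0),
                                       conflicts = integer(0)),
                unpaired = integer(0), n_pairs = 0L))
  J <- nchar(catalog$consensus[1])
  p <- nchar(padgap)
  if ((J - p) %% 2L != 0L)
    stop("joined length minus padgap length must be even")
  w <- (J - p) %/% 2L
  layout <- list(forward = c(1L, w), pad = c(w + 1L, w + p),
                 reverse = c(w + p + 1L, J))
  fp <- find_pairs(catalog, max_conflict_fraction)
  rows <- lapply(seq_len(nrow(fp$pairs)), function(r) {
    i <- fp$pairs$watson[r]
    j <- fp$pairs$crick[r]
    # Watson = lower line_index member; name = its line_index
    if (catalog$line_index[j] < catalog$line_index[i]) {
      tmp <- i; i <- j; j <- tmp
    }
    dec <- reconstruct_pair(catalog$consensus[i], catalog$consensus[j],
                            max_conflict_fraction)
    mg <- strip_padgap_and_merge(dec$sequence, dec$calls, layout,
                                 min_overlap, overlap_mismatches)
    data.frame(name = as.character(catalog$line_index[i]),
               sequence = mg$sequence, calls = mg$calls,
               merged = mg$merged, overlap_length = mg$overlap_length,
               conflicts = dec$conflicts, stringsAsFactors = FALSE)
  })
  frags <- if (length(rows)) do.call(rbind, rows) else
    data.frame(name = character(0), sequence = character(0),
               calls = character(0), merged = logical(0),
               overlap_length = integer(0), conflicts = integer(0))
  list(fragments = frags, unpaired = fp$unpaired,
       n_pairs = nrow(fp$pairs))
}

#' Assemble reconstructed fragments into a mock genome
#'
#' Concatenates fragments in name order (numeric when names are integers)
#' with `spacer_length` `N` bases between consecutive fragments, and
#' records a 1-based inclusive boundary table mapping mock coordinates back
#' to fragments.
#'
#' @param fragments `data.frame` with columns `name` and `sequence`
#'   (e.g. from [reconstruct_loci()]), or a named character vector.
#' @param spacer_length Number of `N` bases between fragments (default 0).
#' @return Object of class `mock_genome`: list with `sequence`,
#'   `boundaries` (`data.frame`: `name`, `start`, `end`), `spacer_length`.
#' @export
build_mock_genome <- function(fragments, spacer_length = 0L) {
  if (is.character(fragments))
    fragments <- data.frame(name = names(fragments),
                            sequence = unname(fragments),
                            stringsAsFactors = FALSE)
  if (nrow(fragments) == 0L) stop("empty fragment list")
  num <- suppressWarnings(as.numeric(fragments$name))
  ord <- if (!anyNA(num)) order(num) else order(fragments$name)
  fragments <- fragments[ord, , drop = FALSE]
  lens <- nchar(fragments$sequence)
  starts <- integer(nrow(fragments))
  pos <- 0L
  for (i in seq_len(nrow(fragments))) {
    if (i > 1L) pos <- pos + spacer_length
    starts[i] <- pos + 1L
    pos <- pos + lens[i]
  }
  spacer <- strrep("N", spacer_length)
  structure(list(
    sequence = paste(fragments$sequence, collapse = spacer),
    boundaries = data.frame(name = fragments$name, start = starts,
                            end = starts + lens - 1L,
                            stringsAsFactors = FALSE),
    spacer_length = as.integer(spacer_length)), class = "mock_genome")
}

#' @export
print.mock_genome <- function(x, ...) {
  cat("Mock genome:", nchar(x$sequence), "bp,",
      nrow(x$boundaries), "fragments, spacer", x$spacer_length, "\n")
  invisible(x)
}

#' Write the reconstruction outputs
#'
#' Writes `mock_genome.fasta` (single record `mock_genome`),
#' `fragments.fasta`, `boundaries.tsv` (name, start, end, merged,
#' overlap_length, conflicts) and `unpaired.txt` into `dir`.
#'
#' @param recon Result of [reconstruct_loci()].
#' @param mock Result of [build_mock_genome()] on `recon$fragments`.
#' @param dir Output directory.
#' @param catalog Optional catalog used, to report unpaired locus ids.
#' @return `dir`, invisibly.
#' @export
write_reconstruction <- function(recon, mock, dir, catalog = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(c(mock_genome = mock$sequence),
              file.path(dir, "mock_genome.fasta"))
  frs <- recon$fragments$sequence
  names(frs) <- recon$fragments$name
  write_fasta(frs, file.path(dir, "fragments.fasta"))
  bt <- merge(mock$boundaries,
              recon$fragments[, c("name", "merged", "overlap_length",
                                  "conflicts")], by = "name", sort = FALSE)
  bt <- bt[order(bt$start), ]
  utils::write.table(bt, file.path(dir, "boundaries.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  unp <- if (!is.null(catalog) && length(recon$unpaired))
    catalog$id[recon$unpaired] else recon$unpaired
  writeLines(as.character(unp), file.path(dir, "unpaired.txt"))
  invisible(dir)
}
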