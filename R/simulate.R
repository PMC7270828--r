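# Forward model of a single-enzyme epiGBS library: restriction digestion,
# context-dependent methylation, strand-wise bisulfite conversion, and
# paired-end reads carrying the inline-barcode P1 adapter remnant on read 1
# and the wobble-bearing common (P2) adapter prefix on read 2. Each genomic
# fragment enters the library in both orientations, so both converted
# strands are sequenced -- the property the reconstruction stage exploits.

#' Built-in GBS barcode table
#'
#' The eight standard inline barcodes shipped with the package
#' (`inst/extdata/barcodes_gbs.tsv`), lengths 5-10 bp, prefix-free.
#'
#' @return Named character vector: `sample -> barcode`.
#' @export
default_barcodes <- function() {
  read_barcode_table(system.file("extdata", "barcodes_gbs.tsv",
                                 package = "epigbsr", mustWork = TRUE))
}

#' Read a headerless sample/barcode TSV
#'
#' @param path Two-column tab-separated file: `sample<TAB>barcode`.
#' @return Named character vector `sample -> barcode` (upper-cased).
#' @export
read_barcode_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("sample", "barcode"),
                           colClasses = "character")
  bc <- toupper(tab$barcode)
  names(bc) <- tab$sample
  validate_barcodes(bc)
  bc
}

validate_barcodes <- function(barcodes) {
  if (length(barcodes) == 0L) stop("empty barcode table")
  if (anyDuplicated(barcodes)) stop("duplicate barcodes in table")
  if (anyDuplicated(names(barcodes))) stop("duplicate sample names in table")
  if (any(!grepl("^[ACGT]+$", barcodes))) stop("barcodes must be A/C/G/T")
  # prefix-freeness: no barcode may be a prefix of a longer one
  for (i in seq_along(barcodes)) for (j in seq_along(barcodes)) {
    if (i != j && startsWith(barcodes[j], barcodes[i]))
      stop("barcode table is not prefix-free: ", barcodes[i], " prefixes ",
           barcodes[j])
  }
  invisible(barcodes)
}

#' Simulation configuration
#'
#' Collects every tunable of the library simulator with validated defaults.
#' Defaults describe a plant-like target: GC fraction 0.38, CpG/CHG/CHH
#' methylation probabilities 0.31 / 0.013 / 0.005, symmetric CpG dyads,
#' bisulfite conversion efficiency 0.98, 100 bp reads, 150-250 bp size
#' selection, depth 5 per insertion orientation.
#'
#' @param genome_length Genome size in bp used when no explicit fragments
#'   are supplied.
#' @param gc_fraction Expected GC content of the random genome, in `[0,1]`.
#' @param recognition_site Restriction recognition sequence
#'   (default `"CTGCAG"`, PstI).
#' @param cut_offset 0-based cut position within the site (PstI cuts
#'   `CTGCA^G`, offset 5).
#' @param size_min,size_max Closed size-selection interval in bp.
#' @param p_cg,p_chg,p_chh Per-context methylation probabilities.
#' @param symmetric_cg If `TRUE`, the two cytosines of a CpG dyad share one
#'   methylation draw.
#' @param conversion_efficiency Probability that an unmethylated cytosine is
#'   converted to thymine.
#' @param failed_conversion_of_methylated Probability that a methylated
#'   cytosine is (wrongly) converted.
#' @param read_length Fixed read length in bp.
#' @param depth_per_orientation Read pairs per fragment, sample and
#'   insertion orientation.
#' @param sequencing_error_rate Per-base substitution error probability.
#' @param base_quality Constant Phred score assigned to every base.
#' @param barcode_table Named character vector `sample -> barcode`.
#' @param seed Integer RNG seed.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(genome_length = 1e6,
                       gc_fraction = 0.38,
                       recognition_site = "CTGCAG",
                       cut_offset = 5L,
                       size_min = 150L,
                       size_max = 250L,
                       p_cg = 0.31,
                       p_chg = 0.013,
                       p_chh = 0.005,
                       symmetric_cg = TRUE,
                       conversion_efficiency = 0.98,
                       failed_conversion_of_methylated = 0,
                       read_length = 100L,
                       depth_per_orientation = 5L,
                       sequencing_error_rate = 0,
                       base_quality = 40L,
                       barcode_table = default_barcodes(),
                       seed = 1L) {
  cfg <- list(genome_length = as.numeric(genome_length),
              gc_fraction = gc_fraction,
              recognition_site = toupper(recognition_site),
              cut_offset = as.integer(cut_offset),
              size_min = as.integer(size_min),
              size_max = as.integer(size_max),
              p_cg = p_cg, p_chg = p_chg, p_chh = p_chh,
              symmetric_cg = isTRUE(symmetric_cg),
              conversion_efficiency = conversion_efficiency,
              failed_conversion_of_methylated = failed_conversion_of_methylated,
              read_length = as.integer(read_length),
              depth_per_orientation = as.integer(depth_per_orientation),
              sequencing_error_rate = sequencing_error_rate,
              base_quality = as.integer(base_quality),
              barcode_table = barcode_table,
              seed = as.integer(seed))
  probs <- c(gc_fraction = cfg$gc_fraction, p_cg = cfg$p_cg,
             p_chg = cfg$p_chg, p_chh = cfg$p_chh,
             conversion_efficiency = cfg$conversion_efficiency,
             failed_conversion_of_methylated =
               cfg$failed_conversion_of_methylated,
             sequencing_error_rate = cfg$sequencing_error_rate)
  bad <- probs < 0 | probs > 1
  if (any(bad)) stop("probabilities outside [0,1]: ",
                     paste(names(probs)[bad], collapse = ", "))
  if (cfg$genome_length <= 0) stop("genome_length must be positive")
  if (cfg$cut_offset < 0L || cfg$cut_offset > nchar(cfg$recognition_site))
    stop("cut_offset outside recognition site")
  if (cfg$size_min > cfg$size_max) stop("size_min > size_max")
  validate_barcodes(cfg$barcode_table)
  # reads must not run into the far adapter for any sample
  floor_len <- cfg$read_length - min(nchar(cfg$barcode_table)) - 4L
  if (cfg$size_min < floor_len)
    stop("size_min (", cfg$size_min, ") below the adapter read-through ",
         "floor read_length - min(barcode) - 4 = ", floor_len)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a random genome of fixed GC content
#'
#' @param length Genome length in bp (> 0).
#' @param gc_fraction Expected GC fraction in `[0,1]`.
#' @param seed Optional integer seed; `NULL` uses the current RNG state.
#' @return A single DNA string over `A,C,G,T`.
#' @export
#' @examples
#' nchar(generate_genome(1000, 0.4, seed = 1))
generate_genome <- function(length, gc_fraction, seed = NULL) {
  if (length <= 0) stop("genome length must be positive")
  if (gc_fraction < 0 || gc_fraction > 1) stop("gc_fraction outside [0,1]")
  if (!is.null(seed)) set.seed(seed)
  p <- c((1 - gc_fraction) / 2, gc_fraction / 2,
         gc_fraction / 2, (1 - gc_fraction) / 2)
  paste(sample(DNA_BASES, length, replace = TRUE, prob = p), collapse = "")
}

#' In-silico restriction digestion of one sequence
#'
#' Scans every position of the top strand for the recognition site
#' (case-insensitive, overlapping occurrences included) and cuts
#' `cut_offset` bases into each occurrence. Fragments partition the
#' sequence; a fragment is `internal` iff both of its flanks are cuts
#' rather than sequence ends.
#'
#' @param sequence DNA string.
#' @param site Recognition sequence (default PstI, `CTGCAG`).
#' @param cut_offset 0-based offset of the cut within the site
#'   (`CTGCA^G` = 5).
#' @param sequence_id Identifier recorded in the output.
#' @return `data.frame` with columns `sequence_id`, `start`, `end`
#'   (0-based, end-exclusive), `length`, `internal`.
#' @export
#' @examples
#' digest("TTCTGCAGAAACTGCAGTT")
digest <- function(sequence, site = "CTGCAG", cut_offset = 5L,
                   sequence_id = "seq1") {
  if (!nzchar(sequence)) stop("empty sequence")
  if (cut_offset < 0L || cut_offset > nchar(site))
    stop("cut_offset outside site")
  L <- nchar(sequence)
  # lookahead regex finds overlapping occurrences at every offset
  hits <- gregexpr(paste0("(?=", site, ")"), toupper(sequence),
                   perl = TRUE)[[1]]
  cuts <- if (hits[1] == -1L) integer(0) else
    as.integer(hits) - 1L + as.integer(cut_offset)
  cuts <- sort(unique(cuts[cuts > 0L & cuts < L]))
  bounds <- c(0L, cuts, L)
  starts <- bounds[-length(bounds)]
  ends <- bounds[-1]
  data.frame(sequence_id = sequence_id,
             start = starts, end = ends, length = ends - starts,
             internal = starts %in% cuts & ends %in% cuts,
             stringsAsFactors = FALSE)
}

#' Count digestion fragments within a size range
#'
#' @param fragments `data.frame` from [digest()] (rows from several source
#'   sequences may be concatenated).
#' @param min_len,max_len Closed length interval in bp.
#' @param internal_only Count only fragments flanked by cuts on both sides.
#' @return Integer count.
#' @export
count_fragments_in_range <- function(fragments, min_len, max_len,
                                     internal_only = TRUE) {
  if (min_len > max_len) stop("empty range: min_len > max_len")
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (internal_only) keep <- keep & fragments$internal
  sum(keep)
}

# Cytosine positions and contexts of one strand. Missing downstream bases
# (cytosines at the fragment edge) are treated as H, so a terminal C is CHH.
cytosine_contexts <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  L <- length(b)
  pos <- which(b == "C")
  if (length(pos) == 0L)
    return(data.frame(pos = integer(0), context = character(0),
                      stringsAsFactors = FALSE))
  nxt1 <- ifelse(pos + 1L <= L, b[pmin(pos + 1L, L)], "")
  nxt2 <- ifelse(pos + 2L <= L, b[pmin(pos + 2L, L)], "")
  context <- ifelse(nxt1 == "G", "CG",
                    ifelse(nxt2 == "G", "CHG", "CHH"))
  data.frame(pos = pos - 1L, context = context, stringsAsFactors = FALSE)
}

#' Assign methylation states to every cytosine of both strands
#'
#' Each cytosine is methylated independently with the probability of its
#' context (`CG`, `CHG`, `CHH`). With `symmetric_cg = TRUE` the two
#' cytosines of a CpG dyad share a single Bernoulli draw.
#'
#' @param fragments Named character vector of fragment sequences
#'   (top strand).
#' @param p_cg,p_chg,p_chh Methylation probabilities per context.
#' @param symmetric_cg Share one draw per CpG dyad.
#' @param seed Optional integer seed.
#' @return `data.frame` with columns `fragment`, `strand`
#'   (`"top"`/`"bottom"`), `pos` (0-based on that strand), `context`,
#'   `state` (`"methylated"`/`"unmethylated"`).
#' @export
assign_methylation <- function(fragments, p_cg = 0.31, p_chg = 0.013,
                               p_chh = 0.005, symmetric_cg = TRUE,
                               seed = NULL) {
  stopifnot(all(c(p_cg, p_chg, p_chh) >= 0), all(c(p_cg, p_chg, p_chh) <= 1))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(names(fragments)))
    names(fragments) <- as.character(seq_along(fragments))
  pvec <- c(CG = p_cg, CHG = p_chg, CHH = p_chh)
  out <- lapply(names(fragments), function(fn) {
    top <- fragments[[fn]]
    bot <- reverse_complement(top)
    L <- nchar(top)
    ct <- cytosine_contexts(top)
    cb <- cytosine_contexts(bot)
    ct$strand <- if (nrow(ct)) "top" else character(0)
    cb$strand <- if (nrow(cb)) "bottom" else character(0)
    df <- rbind(ct, cb)
    if (nrow(df) == 0L)
      return(data.frame(fragment = character(0), strand = character(0),
                        pos = integer(0), context = character(0),
                        state = character(0), stringsAsFactors = FALSE))
    df$state <- ifelse(runif(nrow(df)) < pvec[df$context],
                       "methylated", "unmethylated")
    if (symmetric_cg) {
      # top CpG at top position i pairs the bottom cytosine at L - 2 - i
      is_top_cg <- df$strand == "top" & df$context == "CG"
      for (i in df$pos[is_top_cg]) {
        j <- L - 2L - i
        k_top <- which(df$strand == "top" & df$pos == i)
        k_bot <- which(df$strand == "bottom" & df$pos == j)
        if (length(k_bot) == 1L) df$state[k_bot] <- df$state[k_top]
      }
    }
    df$fragment <- fn
    df[, c("fragment", "strand", "pos", "context", "state")]
  })
  do.call(rbind, out)
}

#' Bisulfite-convert one strand
#'
#' Unmethylated cytosines become thymine with probability `efficiency`;
#' methylated cytosines are converted with probability
#' `failed_conversion_of_methylated` (default 0: fully protected).
#' Non-cytosine bases are never altered.
#'
#' @param strand_sequence DNA string of the strand, 5' to 3'.
#' @param strand_truth `data.frame` with columns `pos` (0-based) and
#'   `state`, covering every cytosine of the strand (e.g. one
#'   strand's rows of [assign_methylation()]).
#' @param efficiency Conversion probability of unmethylated cytosines.
#' @param failed_conversion_of_methylated Conversion probability of
#'   methylated cytosines.
#' @param seed Optional integer seed.
#' @return Converted DNA string of identical length.
#' @export
bisulfite_convert <- function(strand_sequence, strand_truth, efficiency,
                              failed_conversion_of_methylated = 0,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  b <- strsplit(strand_sequence, "")[[1]]
  cpos <- which(b == "C") - 1L
  tpos <- sort(strand_truth$pos)
  if (!identical(as.integer(tpos), as.integer(cpos)))
    stop("strand_truth does not cover exactly the cytosines of the strand")
  if (length(cpos)) {
    st <- strand_truth$state[order(strand_truth$pos)]
    p <- ifelse(st == "methylated", failed_conversion_of_methylated,
                efficiency)
    conv <- runif(length(cpos)) < p
    b[cpos + 1L][conv] <- "T"
  }
  paste(b, collapse = "")
}

# Adapter-derived prefix of raw reverse reads: 5 wobble bases then
# AACTGTGCA. Raw 0-based index 7 is the methylated adapter cytosine (never
# converted); index 12 is the unmethylated check cytosine.
P2_PREFIX <- "AACTGTGCA"
P2_CHECK_INDEX <- 12L
WOBBLE_ALPHABET <- c("A", "G", "T")  # IUPAC D, per the DDDDD wobble design

# introduce iid substitution errors at `rate` into a character vector of
# reads
add_seq_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  vapply(reads, function(s) {
    b <- strsplit(s, "")[[1]]
    hit <- runif(length(b)) < rate
    if (any(hit)) {
      b[hit] <- vapply(b[hit], function(orig) {
        sample(setdiff(DNA_BASES, orig), 1L)
      }, character(1))
    }
    paste(b, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate an epiGBS paired-end library
#'
#' Emits `depth_per_orientation` read pairs per size-selected internal
#' fragment, sample and insertion orientation. Orientation A sequences the
#' bisulfite-converted top strand of the fragment, orientation B the
#' converted bottom strand; each molecule receives an independent
#' conversion draw. Read 1 is `barcode + TGCA + strand`, truncated to
#' `read_length`; read 2 is five wobble bases and the common-adapter
#' remnant `AACTGTGCA` (its check cytosine at raw index 12 converted with
#' probability `conversion_efficiency`) followed by the reverse complement
#' of the same converted strand.
#'
#' @param config A [sim_config()] object.
#' @param fragments Optional named character vector of fragment sequences;
#'   when `NULL`, a random genome is generated, digested and size-selected
#'   according to `config`.
#' @param genome Optional genome string to digest instead of a random one.
#' @return List with elements `r1`, `r2` (read data frames with `id`,
#'   `seq`, `qual`), and `truth` (list: `fragments` named vector,
#'   `methylation` data frame as from [assign_methylation()], `reads`
#'   provenance data frame).
#' @export
simulate_library <- function(config, fragments = NULL, genome = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  if (is.null(fragments)) {
    if (is.null(genome))
      genome <- generate_genome(config$genome_length, config$gc_fraction)
    fr <- digest(genome, config$recognition_site, config$cut_offset)
    fr <- fr[fr$internal & fr$length >= config$size_min &
               fr$length <= config$size_max, , drop = FALSE]
    if (nrow(fr) == 0L)
      stop("no internal fragment passes size selection")
    fragments <- substring(genome, fr$start + 1L, fr$end)
    names(fragments) <- sprintf("frag%04d", seq_len(nrow(fr)))
  } else {
    if (is.null(names(fragments)))
      names(fragments) <- sprintf("frag%04d", seq_along(fragments))
  }
  fragments <- toupper(fragments)
  rl <- config$read_length
  # read 2 needs rl-14 genomic bases; read 1 up to rl-min(barcode)-4
  floor_len <- max(rl - 14L, rl - min(nchar(config$barcode_table)) - 4L)
  short <- nchar(fragments) < floor_len
  if (any(short))
    stop("fragment(s) shorter than the trimmed read span (",
         floor_len, " bp): ", paste(names(fragments)[short], collapse = ", "))

  truth_meth <- assign_methylation(fragments, config$p_cg, config$p_chg,
                                   config$p_chh, config$symmetric_cg)
  samples <- names(config$barcode_table)
  depth <- config$depth_per_orientation
  qual_char <- substr(phred_char(config$base_quality), 1, 1)

  r1_seq <- r2_seq <- ids <- character(0)
  prov <- vector("list", length(fragments) * 2L)
  pi <- 0L
  for (fn in names(fragments)) {
    top <- fragments[[fn]]
    bot <- reverse_complement(top)
    for (ori in c("A", "B")) {
      strand_seq <- if (ori == "A") top else bot
      strand_lab <- if (ori == "A") "top" else "bottom"
      tr <- truth_meth[truth_meth$fragment == fn &
                         truth_meth$strand == strand_lab, , drop = FALSE]
      nmol <- length(samples) * depth
      conv <- vapply(seq_len(nmol), function(i) {
        bisulfite_convert(strand_seq, tr, config$conversion_efficiency,
                          config$failed_conversion_of_methylated)
      }, character(1))
      mol_sample <- rep(samples, each = depth)
      bc <- config$barcode_table[mol_sample]
      geno1 <- substr(conv, 1L, rl - nchar(bc) - 4L)
      read1 <- paste0(bc, "TGCA", geno1)
      wob <- vapply(seq_len(nmol), function(i) {
        paste(sample(WOBBLE_ALPHABET, 5L, replace = TRUE), collapse = "")
      }, character(1))
      adapt <- rep(P2_PREFIX, nmol)
      checked <- runif(nmol) < config$conversion_efficiency
      substr(adapt[checked], 8L, 8L) <- "T"  # check C = raw index 12
      geno2 <- substr(reverse_complement(conv), 1L, rl - 14L)
      read2 <- paste0(wob, adapt, geno2)
      if (any(nchar(read1) != rl) || any(nchar(read2) != rl))
        stop("internal error: read length mismatch for ", fn)
      read1 <- add_seq_errors(read1, config$sequencing_error_rate)
      read2 <- add_seq_errors(read2, config$sequencing_error_rate)
      id <- sprintf("%s:%s:%s:%d", fn, mol_sample, ori,
                    rep(seq_len(depth), times = length(samples)))
      r1_seq <- c(r1_seq, read1)
      r2_seq <- c(r2_seq, read2)
      ids <- c(ids, id)
      pi <- pi + 1L
      prov[[pi]] <- data.frame(id = id, sample = mol_sample, fragment = fn,
                               orientation = ori,
                               replicate = rep(seq_len(depth),
                                               times = length(samples)),
                               stringsAsFactors = FALSE)
    }
  }
  qual <- strrep(qual_char, rl)
  list(r1 = data.frame(id = ids, seq = r1_seq, qual = qual,
                       stringsAsFactors = FALSE),
       r2 = data.frame(id = ids, seq = r2_seq, qual = qual,
                       stringsAsFactors = FALSE),
       truth = list(fragments = fragments,
                    methylation = truth_meth,
                    reads = do.call(rbind, prov[seq_len(pi)])))
}

#' Write a simulated library to disk
#'
#' Writes `R1.fastq.gz`, `R2.fastq.gz`, `truth_fragments.fasta`,
#' `truth_methylation.tsv` (columns fragment, strand, pos_0based, context,
#' state) and `truth_reads.tsv` into `dir`.
#'
#' @param sim Result of [simulate_library()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq(sim$r1, file.path(dir, "R1.fastq.gz"))
  write_fastq(sim$r2, file.path(dir, "R2.fastq.gz"))
  write_fasta(sim$truth$fragments, file.path(dir, "truth_fragments.fasta"))
  meth <- sim$truth$methylation
  names(meth)[names(meth) == "pos"] <- "pos_0based"
  utils::write.table(meth, file.path(dir, "truth_methylation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$reads, file.path(dir, "truth_reads.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Fragment-count statistics of an in-silico digestion
#'
#' @param sequences Named character vector of genome sequences, or a path
#'   to a FASTA file.
#' @param site,cut_offset Restriction site and cut offset (PstI defaults).
#' @param ranges List of `c(min, max)` closed bp intervals.
#' @param internal_only Count only internal (cut-to-cut) fragments.
#' @return `data.frame` with columns `min_len`, `max_len`, `count`.
#' @export
digest_stats <- function(sequences,
                         site = "CTGCAG", cut_offset = 5L,
                         ranges = list(c(150L, 250L), c(100L, 300L),
                                       c(100L, 400L)),
                         internal_only = TRUE) {
  if (is.character(sequences) && length(sequences) == 1L &&
      file.exists(sequences))
    sequences <- read_fasta(sequences)
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  frags <- do.call(rbind, lapply(names(sequences), function(nm)
    digest(sequences[[nm]], site, cut_offset, sequence_id = nm)))
  data.frame(
    min_len = vapply(ranges, `[`, integer(1), 1L),
    max_len = vapply(ranges, `[`, integer(1), 2L),
    count = vapply(ranges, function(r)
      count_fragments_in_range(frags, r[1], r[2], internal_only),
      integer(1)))
}
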