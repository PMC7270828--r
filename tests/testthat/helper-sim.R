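# shared fixtures and small independent oracles, built in code

random_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

make_fragments <- function(lens) {
  out <- vapply(lens, random_dna, character(1))
  names(out) <- sprintf("frag%04d", seq_along(out))
  out
}

# insert sizes that avoid the ambiguous short-overlap zone (161-171 bp)
roundtrip_lengths <- function(n) {
  sample(c(100:160, 172:300), n, replace = TRUE)
}

# the image the pipeline can reconstruct from two 86-bp read halves:
# full sequence when the halves overlap by >= min_overlap or abut exactly,
# 5'86 + 3'86 concatenation otherwise
expected_image <- function(s, w = 86L, min_overlap = 10L) {
  L <- nchar(s)
  k <- 2L * w - L
  if (k == 0L || k >= min_overlap) s
  else paste0(substr(s, 1L, w), substr(s, L - w + 1L, L))
}

# strand-agnostic canonical form
canon <- function(x) pmin(x, reverse_complement(x))

# brute-force cut-position oracle: test a site match at every offset
naive_cuts <- function(sequence, site, cut_offset) {
  L <- nchar(sequence)
  w <- nchar(site)
  cuts <- integer(0)
  for (i in seq_len(max(L - w + 1L, 0L))) {
    if (toupper(substr(sequence, i, i + w - 1L)) == toupper(site))
      cuts <- c(cuts, i - 1L + cut_offset)
  }
  cuts[cuts > 0L & cuts < L]
}

# per-base expected-error oracle, written independently of the package
naive_maxee_pass <- function(seq, qual, max_rate) {
  b <- strsplit(seq, "")[[1]]
  q <- strsplit(qual, "")[[1]]
  e <- 0
  for (i in seq_along(b)) {
    e <- e + if (b[i] == "N") 1 else 10^(-(utf8ToInt(q[i]) - 33) / 10)
  }
  e / length(b) < max_rate
}

# default 4-sample subset of the packaged barcode table
four_barcodes <- function() default_barcodes()[1:4]

sim_pairs <- function(sim) list(forward = sim$r1, reverse = sim$r2)

# a catalog with exactly the given records (identical records preserved),
# built through the FASTA reader
toy_catalog <- function(seqs) {
  tmp <- tempfile(fileext = ".fa")
  on.exit(unlink(tmp))
  writeLines(c(rbind(paste0(">", seq_along(seqs) - 1L), seqs)), tmp)
  read_catalog_fasta(tmp)
}
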