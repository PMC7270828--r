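test_that("generate_genome respects length, GC and determinism", {
  expect_error(generate_genome(0, 0.5), "positive")
  expect_error(generate_genome(100, 1.5), "\\[0,1\\]")

  g <- generate_genome(10000, 0.5, seed = 1)
  expect_equal(nchar(g), 10000)
  gc <- sum(strsplit(g, "")[[1]] %in% c("G", "C")) / 10000
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / 10000))

  g2 <- generate_genome(100, 1.0, seed = 7)
  expect_true(grepl("^[GC]+$", g2))

  expect_identical(generate_genome(500, 0.4, seed = 3),
                   generate_genome(500, 0.4, seed = 3))
})

test_that("digest matches the hand-traced toy example", {
  fr <- digest("TTCTGCAGAAACTGCAGTT", "CTGCAG", 5L)
  cuts <- setdiff(unique(c(fr$start, fr$end)), c(0, 19))
  expect_equal(sort(cuts), c(7, 16))
  int <- fr[fr$internal, ]
  expect_equal(nrow(int), 1)
  expect_equal(int$start, 7)
  expect_equal(int$end, 16)
  expect_equal(int$length, 9)
  expect_equal(substr("TTCTGCAGAAACTGCAGTT", 8, 16), "GAAACTGCA")
})

test_that("digest degenerate cases", {
  fr <- digest("AAAA")
  expect_equal(nrow(fr), 1)
  expect_false(any(fr$internal))
  # one site -> two terminal fragments, none internal
  one <- digest(paste0(random_dna(50), "CTGCAG", random_dna(50)))
  expect_equal(sum(one$internal), 0)
  expect_equal(nrow(one), 2)
  expect_error(digest(""), "empty")
})

test_that("digest agrees with the naive all-offsets oracle and partitions", {
  set.seed(11)
  for (rep in 1:25) {
    L <- sample(50:400, 1)
    site <- random_dna(sample(3:6, 1))
    off <- sample(0:nchar(site), 1)
    s <- random_dna(L, bases = c("A", "C", "G", "T"))
    fr <- digest(s, site, off)
    cuts <- setdiff(unique(c(fr$start, fr$end)), c(0L, L))
    expect_equal(sort(cuts), sort(naive_cuts(s, site, off)))
    expect_equal(sum(fr$length), L)
    expect_identical(paste(substring(s, fr$start + 1, fr$end),
                           collapse = ""), s)
  }
})

test_that("overlapping site occurrences are all cut", {
  # AAA with site AA and offset 1 -> overlapping matches at 0 and 1
  fr <- digest("CAAAC", "AA", 1L)
  cuts <- setdiff(unique(c(fr$start, fr$end)), c(0, 5))
  expect_equal(sort(cuts), c(2, 3))
})

test_that("count_fragments_in_range filters on closed interval", {
  fr <- digest("TTCTGCAGAAACTGCAGTT")
  expect_equal(count_fragments_in_range(fr, 1, 100, TRUE), 1)
  expect_equal(count_fragments_in_range(fr, 10, 100, TRUE), 0)
  expect_equal(count_fragments_in_range(fr, 9, 9, TRUE), 1)
  expect_equal(count_fragments_in_range(fr, 1, 100, FALSE), 3)
  expect_error(count_fragments_in_range(fr, 5, 4), "range")
})

test_that("assign_methylation respects degenerate probabilities", {
  frags <- make_fragments(c(120, 150))
  all_cg <- assign_methylation(frags, 1, 0, 0, symmetric_cg = FALSE,
                               seed = 2)
  expect_true(all(all_cg$state[all_cg$context == "CG"] == "methylated"))
  expect_true(all(all_cg$state[all_cg$context != "CG"] == "unmethylated"))

  none <- assign_methylation(frags, 0, 0, 0, seed = 2)
  expect_true(all(none$state == "unmethylated"))
})

test_that("assign_methylation CG rate is binomial around p_cg", {
  set.seed(5)
  frags <- make_fragments(rep(300, 40))
  tr <- assign_methylation(frags, 0.3, 0, 0, symmetric_cg = FALSE)
  cg <- tr[tr$context == "CG", ]
  n <- nrow(cg)
  expect_gt(n, 1000)
  frac <- mean(cg$state == "methylated")
  expect_lt(abs(frac - 0.3), 3 * sqrt(0.3 * 0.7 / n))
})

test_that("symmetric CpG dyads share one methylation draw", {
  set.seed(9)
  frags <- make_fragments(rep(200, 10))
  tr <- assign_methylation(frags, 0.5, 0, 0, symmetric_cg = TRUE)
  for (fn in names(frags)) {
    s <- frags[[fn]]
    L <- nchar(s)
    b <- strsplit(s, "")[[1]]
    dyads <- which(b[-L] == "C" & b[-1] == "G")  # 1-based top C position
    sub <- tr[tr$fragment == fn, ]
    for (i in dyads) {
      top <- sub$state[sub$strand == "top" & sub$pos == i - 1L]
      bot <- sub$state[sub$strand == "bottom" & sub$pos == L - 1L - i]
      expect_identical(top, bot)
    }
  }
})

test_that("bisulfite_convert converts per state and preserves non-C bases", {
  tr <- data.frame(pos = 1L, state = "unmethylated")
  expect_identical(bisulfite_convert("ACGT", tr, 1), "ATGT")
  tr$state <- "methylated"
  expect_identical(bisulfite_convert("ACGT", tr, 1, 0), "ACGT")
  expect_error(bisulfite_convert("ACGT", data.frame(pos = 2L,
                                                    state = "methylated"), 1),
               "cover")

  # binomial bound on conversion count at efficiency 0.95
  s <- strrep("CA", 1000)
  truth <- data.frame(pos = seq(0, 1998, by = 2), state = "unmethylated")
  conv <- bisulfite_convert(s, truth, 0.95, seed = 4)
  n_t <- sum(strsplit(conv, "")[[1]] == "T")
  expect_lt(abs(n_t - 950), 3 * sqrt(1000 * 0.95 * 0.05))
  # A positions untouched
  expect_true(all(strsplit(conv, "")[[1]][seq(2, 2000, 2)] == "A"))
})

test_that("sim_config validates probabilities and the size floor", {
  expect_error(sim_config(p_cg = 1.2), "probabilities")
  expect_error(sim_config(size_min = 80), "floor")
  expect_error(sim_config(size_min = 200, size_max = 150), "size_min")
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$cut_offset, 5L)
})

test_that("simulate_library emits the documented read structure", {
  set.seed(1)
  frags <- make_fragments(c(150))
  bc <- default_barcodes()["AlDA1"]
  cfg <- sim_config(conversion_efficiency = 1, depth_per_orientation = 1,
                    barcode_table = bc, seed = 5)
  sim <- simulate_library(cfg, fragments = frags)
  # 1 fragment x 1 sample x 2 orientations x depth 1 = 2 pairs
  expect_equal(nrow(sim$r1), 2)
  expect_true(all(startsWith(sim$r1$seq, paste0(bc, "TGCA"))))
  expect_true(all(nchar(sim$r1$seq) == 100))
  expect_true(all(nchar(sim$r2$seq) == 100))
  # read 2: wobble over IUPAC D then the adapter remnant with index-7 C
  # intact and index-12 check C converted (efficiency 1)
  expect_true(all(grepl("^[AGT]{5}AACTGTGTA", sim$r2$seq)))

  # full conversion + no methylation: no C at genomic C positions of read 1
  cfg0 <- sim_config(conversion_efficiency = 1, p_cg = 0, p_chg = 0,
                     p_chh = 0, depth_per_orientation = 1,
                     barcode_table = bc, seed = 5)
  sim0 <- simulate_library(cfg0, fragments = frags)
  genomic <- substring(sim0$r1$seq, nchar(bc) + 5L)
  expect_false(any(grepl("C", genomic)))
})

test_that("read-structure invariant: trimmed reads are strand substrings", {
  set.seed(3)
  frags <- make_fragments(c(120, 200, 250))
  bc <- four_barcodes()
  cfg <- sim_config(depth_per_orientation = 2, barcode_table = bc,
                    seed = 11)
  sim <- simulate_library(cfg, fragments = frags)
  prov <- sim$truth$reads
  for (r in sample(nrow(sim$r1), 20)) {
    b <- bc[prov$sample[r]]
    core1 <- substr(sim$r1$seq[r], nchar(b) + 5L, nchar(b) + 4L + 86L)
    core2 <- substr(sim$r2$seq[r], 15L, 100L)
    frag <- sim$truth$fragments[prov$fragment[r]]
    strand <- if (prov$orientation[r] == "A") frag
              else reverse_complement(frag)
    # conversion only turns C into T: RY image must match the strand
    expect_identical(ry_encode(core1),
                     ry_encode(substr(strand, 1, 86)))
    expect_identical(ry_encode(reverse_complement(core2)),
                     ry_encode(substr(strand, nchar(strand) - 85,
                                      nchar(strand))))
  }
})

test_that("simulate_library rejects fragments below the read span", {
  cfg <- sim_config(barcode_table = default_barcodes()["AlPB1"], seed = 1)
  expect_error(simulate_library(cfg, fragments = c(f1 = random_dna(80))),
               "shorter")
})

test_that("identical config and seed give byte-identical FASTQ", {
  frags <- withr::with_seed(8, make_fragments(c(150, 210)))
  cfg <- sim_config(depth_per_orientation = 2,
                    barcode_table = four_barcodes(), seed = 99,
                    sequencing_error_rate = 0.01)
  s1 <- simulate_library(cfg, fragments = frags)
  s2 <- simulate_library(cfg, fragments = frags)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("R1.fastq.gz", "R2.fastq.gz"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("digest_stats counts ranges over a multi-record input", {
  set.seed(21)
  g1 <- paste0(random_dna(100), "CTGCAG", random_dna(194), "CTGCAG",
               random_dna(100))
  g2 <- paste0(random_dna(50), "CTGCAG", random_dna(45), "CTGCAG",
               random_dna(50))
  st <- digest_stats(c(a = g1, b = g2),
                     ranges = list(c(150L, 250L), c(40L, 60L)))
  # internal fragment of g1: 194 + 11 site-derived bases = 200 bp
  expect_equal(st$count[1], 1)
  expect_equal(st$count[2], 1)
})
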