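test_that("ry_encode maps purines to R and pyrimidines to Y", {
  expect_identical(ry_encode("GATC"), "RRYY")
  expect_identical(ry_encode("ACGT"), "RYRY")
  expect_true(is.na(ry_encode("ANGT")))
  expect_identical(ry_encode(c("AG", "CT", "NN")), c("RR", "YY", NA))
})

test_that("partner_key is the RY image of reverse complementation", {
  expect_identical(partner_key("RYRY"), "RYRY")
  expect_identical(partner_key("RRRR"), "YYYY")
  set.seed(47)
  for (i in 1:100) {
    s <- random_dna(sample(5:60, 1))
    expect_identical(partner_key(ry_encode(s)),
                     ry_encode(reverse_complement(s)))
  }
})

test_that("RY encoding is invariant under bisulfite conversion", {
  set.seed(53)
  for (i in 1:100) {
    s <- random_dna(sample(20:100, 1))
    cpos <- which(strsplit(s, "")[[1]] == "C") - 1L
    truth <- data.frame(pos = cpos,
                        state = sample(c("methylated", "unmethylated"),
                                       length(cpos), replace = TRUE))
    conv <- bisulfite_convert(s, truth, efficiency = runif(1),
                              failed_conversion_of_methylated = runif(1))
    expect_identical(ry_encode(conv), ry_encode(s))
  }
})

test_that("decode_position is total: 8 informative outcomes, 8 conflicts", {
  bases <- c("A", "C", "G", "T")
  expected <- list(
    AA = c("A", "none"),       TT = c("T", "none"),
    CC = c("C", "meth-C"),     TC = c("C", "unmeth-C"),
    CT = c("C", "unmeth-C"),   GG = c("G", "opp-meth-C"),
    GA = c("G", "opp-unmeth-C"), AG = c("G", "opp-unmeth-C"))
  n_conflict <- 0L
  for (w in bases) for (p in bases) {
    out <- decode_position(w, p)
    key <- paste0(w, p)
    if (key %in% names(expected)) {
      expect_identical(unname(out), expected[[key]])
    } else {
      expect_identical(unname(out), c("N", "conflict"))
      n_conflict <- n_conflict + 1L
    }
  }
  expect_equal(n_conflict, 8L)
  expect_error(decode_position("A", "N"), "single bases")
})

test_that("reconstruct_pair decodes the hand-traced duplex", {
  # original duplex ACGT: converted top = ATGT, converted bottom = ATGT
  dec <- reconstruct_pair("ATGT", "ATGT")
  expect_identical(dec$sequence, "ACGT")
  expect_identical(dec$calls, ".Ug.")  # none, unmeth-C, opp-unmeth-C, none
  expect_equal(dec$conflicts, 0)
  expect_true(dec$ok)

  # no cytosine on either strand: watson == rc(crick), zero C-related calls
  w <- "ATTATA"
  dec2 <- reconstruct_pair(w, reverse_complement(w))
  expect_identical(dec2$sequence, w)
  expect_identical(dec2$calls, "......")

  # all-conflict input is rejected
  dec3 <- reconstruct_pair("AAAA", "AAAA")  # rc = TTTT: (A,T) x4
  expect_equal(dec3$conflicts, 4)
  expect_false(dec3$ok)
  expect_identical(dec3$sequence, "NNNN")

  expect_error(reconstruct_pair("AAA", "AAAA"), "length")
})

test_that("find_pairs pairs the two strand images of one fragment", {
  cat_ <- toy_catalog(c("ATGT", "ATGT"))
  fp <- find_pairs(cat_)
  expect_equal(nrow(fp$pairs), 1)
  expect_equal(length(fp$unpaired), 0)

  fp1 <- find_pairs(toy_catalog("ATGT"))
  expect_equal(nrow(fp1$pairs), 0)
  expect_equal(fp1$unpaired, 1L)
})

test_that("find_pairs rejects pairs above the conflict budget", {
  # RY-compatible but chemically impossible pair: many conflicts
  cat_ <- toy_catalog(c("AAAAAAAAAA", "AAAAAAAAAA"))
  fp <- find_pairs(cat_, max_conflict_fraction = 0.05)
  expect_equal(nrow(fp$pairs), 0)
  expect_setequal(fp$unpaired, c(1L, 2L))
})

test_that("strip_padgap_and_merge finds the maximal qualifying overlap", {
  layout <- list(forward = c(1L, 10L), pad = c(11L, 14L),
                 reverse = c(15L, 24L))
  joined <- paste0("ACGTACGTAC", "ATAT", "GTACGTACGT")
  m <- strip_padgap_and_merge(joined, layout = layout, min_overlap = 8L)
  expect_true(m$merged)
  expect_equal(m$overlap_length, 8)
  expect_identical(m$sequence, "ACGTACGTACGT")
  expect_equal(nchar(m$sequence), 12)

  # brute-force overlap oracle on random true fragments
  set.seed(59)
  for (i in 1:30) {
    L <- sample(12:19, 1)  # halves of 10 overlap by 1..8
    frag <- random_dna(L)
    f <- substr(frag, 1, 10)
    t_ <- substr(frag, L - 9, L)
    true_k <- 20 - L
    # oracle: largest k >= min_overlap with exact suffix/prefix match
    ks <- which(vapply(1:10, function(k)
      substr(f, 11 - k, 10) == substr(t_, 1, k), logical(1)))
    best <- max(c(0, ks[ks >= 2]))
    m2 <- strip_padgap_and_merge(paste0(f, "ATAT", t_),
                                 layout = layout, min_overlap = 2L)
    expect_equal(m2$overlap_length, best)
    if (true_k >= 2) expect_gte(m2$overlap_length, true_k)
  }
})

test_that("non-overlapping halves concatenate unmerged, pad removed", {
  layout <- list(forward = c(1L, 10L), pad = c(11L, 14L),
                 reverse = c(15L, 24L))
  f <- "AAAAACCCCC"
  t_ <- "GGGGGTTTTT"
  m <- strip_padgap_and_merge(paste0(f, "ATAT", t_), layout = layout,
                              min_overlap = 10L)
  expect_false(m$merged)
  expect_equal(m$overlap_length, 0)
  expect_identical(m$sequence, paste0(f, t_))
  expect_false(grepl("ATAT", substr(m$sequence, 8, 14)))
})

test_that("calls are spliced identically to bases", {
  layout <- list(forward = c(1L, 4L), pad = c(5L, 6L), reverse = c(7L, 10L))
  m <- strip_padgap_and_merge("ACGTATGTAC", calls = "MUg.??.Ug.",
                              layout = layout, min_overlap = 2L)
  expect_equal(nchar(m$calls), nchar(m$sequence))
})

test_that("build_mock_genome tiles fragments with correct boundaries", {
  frs <- data.frame(name = c("0", "1", "2"),
                    sequence = c(strrep("A", 100), strrep("C", 120),
                                 strrep("G", 80)))
  mg <- build_mock_genome(frs, spacer_length = 0)
  expect_equal(nchar(mg$sequence), 300)
  expect_equal(mg$boundaries$start, c(1, 101, 221))
  expect_equal(mg$boundaries$end, c(100, 220, 300))

  mg10 <- build_mock_genome(frs[1:2, ], spacer_length = 10)
  expect_equal(nchar(mg10$sequence), 230)
  expect_equal(mg10$boundaries$start[2], 111)
  expect_equal(mg10$boundaries$end[2], 230)
  expect_identical(substr(mg10$sequence, 101, 110), strrep("N", 10))

  single <- build_mock_genome(data.frame(name = "7", sequence = "ACGT"))
  expect_identical(single$sequence, "ACGT")
  expect_equal(single$boundaries$end, 4)
  expect_error(build_mock_genome(frs[0, ]), "empty")
})

test_that("boundary intervals reproduce fragments byte-exactly", {
  set.seed(61)
  frs <- data.frame(name = as.character(sample(0:99, 20)),
                    sequence = vapply(1:20, function(i)
                      random_dna(sample(50:150, 1)), character(1)))
  for (sp in c(0L, 5L)) {
    mg <- build_mock_genome(frs, spacer_length = sp)
    for (i in seq_len(nrow(mg$boundaries))) {
      b <- mg$boundaries[i, ]
      expect_identical(substr(mg$sequence, b$start, b$end),
                       frs$sequence[frs$name == b$name])
    }
  }
})

test_that("fragments are named by the lower line_index of the pair", {
  cat_ <- toy_catalog(c("TTTT", "ATGT", "ATGT"))
  recon <- reconstruct_loci(cat_, padgap = "", min_overlap = 3L)
  expect_equal(recon$n_pairs, 1)
  expect_identical(recon$fragments$name, "1")  # records 1 and 2 paired
  expect_equal(recon$unpaired, 1L)
})

test_that("reconstruction output files round-trip through the readers", {
  frags <- withr::with_seed(67, make_fragments(c(150, 210)))
  bc <- four_barcodes()
  cfg <- sim_config(conversion_efficiency = 1, barcode_table = bc,
                    seed = 71)
  sim <- simulate_library(cfg, fragments = frags)
  res <- run_pipeline(sim_pairs(sim), bc)
  dir <- withr::local_tempdir()
  write_reconstruction(res$reconstruction, res$mock, dir, res$catalog)
  mock_back <- read_fasta(file.path(dir, "mock_genome.fasta"))
  expect_identical(unname(mock_back), res$mock$sequence)
  bt <- load_boundaries(file.path(dir, "boundaries.tsv"))
  expect_equal(nrow(bt), nrow(res$mock$boundaries))
  frs <- read_fasta(file.path(dir, "fragments.fasta"))
  expect_setequal(unname(frs), res$reconstruction$fragments$sequence)
})
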