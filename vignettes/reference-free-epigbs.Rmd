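---
title: "Reconstructing pre-bisulfite GBS fragments without a reference genome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing pre-bisulfite GBS fragments without a reference genome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epigbsr)
```

## The measurement problem

Reduced-representation bisulfite sequencing cuts the genome with a
restriction enzyme (here PstI, `CTGCA^G`), ligates adapters, treats with
sodium bisulfite and sequences. Bisulfite deaminates unmethylated cytosine
to uracil, read as thymine after PCR, while 5-methylcytosine is protected.
Methylation is then called by comparing each read against the *untreated*
sequence — which non-model organisms do not have.

In the library design this package models, fragments are inserted in both
orientations between a barcoded P1 adapter and a single hemimethylated
common (P2) adapter; after nick translation with 5-methyl-dCTP only the
top P1 adapter strand remains unmethylated, so PCR amplifies the bottom
chains of both orientations. The practical consequence: for every fragment
the library contains the converted image of its top strand *and* of its
bottom strand, as two separate locus sequences. Those two images jointly
determine the original sequence — the reference is in the data.

## The model and its key invariant

Bisulfite conversion maps C to T, a pyrimidine to a pyrimidine. Under the
purine/pyrimidine encoding (`A,G -> R`, `C,T -> Y`) conversion is the
identity:

```{r}
s <- "ACGGTCAC"
truth <- data.frame(pos = c(1L, 5L, 7L),
                    state = c("unmethylated", "methylated", "unmethylated"))
identical(ry_encode(bisulfite_convert(s, truth, efficiency = 1)),
          ry_encode(s))
```

Since the two strands of a duplex are reverse complements, the two
converted strand images of one fragment satisfy
`ry_encode(watson) == partner_key(ry_encode(crick))` *exactly*, whatever
the methylation pattern or conversion efficiency. Pair search therefore
buckets catalog entries by RY string and looks up each entry's partner
key; within a bucket the candidate minimizing decode conflicts wins (ties
to the lowest record index). The RY key lookup is hash-bucketed because a
naive all-pairs search grows quadratically with catalog size.

Decoding compares the Watson sequence with the reverse complement of the
Crick sequence position by position. Only 8 of the 16 ordered base pairs
can arise from a real duplex; the informative outcomes are C/C = methylated
C, T/C or C/T = unmethylated C, G/G and G/A (or A/G) = the mirrored calls
for the cytosine on the opposite strand, and concordant A or T =
no cytosine. Everything else is a conflict and decodes to `N`.

```{r}
decode_position("G", "A")
reconstruct_pair("ATGT", "ATGT")$sequence   # both strands of "ACGT"
```

## Pipeline stages and their parameters

* **Demultiplexing** (`demultiplex()`): read 1 carries an inline barcode
  (5–10 bp, prefix-free table shipped in `inst/extdata/barcodes_gbs.tsv`)
  directly followed by the `TGCA` restriction-overhang remnant. Default
  mismatch tolerance is 1 (the tool this step emulates allows one by
  default; exact matching via `max_mismatches = 0`). Equal-best-distance
  ties are conservatively unassigned. No restriction-site check is done:
  bisulfite conversion corrupts the site.
* **Trimming** (`trim_pairs()`): fixed-position, not adapter-scanning —
  strip 4 bases from read 1 (the overhang) and 14 from read 2 (5 wobble
  bases + 9 adapter bases), truncate both to 86 bp. With 100 bp reads and
  barcodes up to 10 bp this makes every sample's joined sequence the same
  length, which the exact-match stacking requires.
* **Joining** (`join_pairs()`): forward + `ATATATAT` + reverse complement
  of reverse, pad quality Phred 40 (`I`). The pad keeps the two read
  images in one record while marking the unsequenced middle.
* **Quality filter** (`filter_maxee_rate()`): expected errors
  `sum(10^(-Q/10))` per base strictly below 0.01; a read at exactly the
  threshold fails, `N` bases count as error probability 1.
* **Clone filter** (`clone_filter()`): the P2 adapter starts with five
  degenerate wobble bases (IUPAC D = A/G/T), so identical inserts with
  identical wobbles are PCR clones; the first occurrence is kept. Applied
  before trimming, which would destroy the wobbles.
* **Conversion QC** (`conversion_rate()`): the P2 bottom strand is fully
  methylated except one deliberate cytosine in the PstI overlap, landing
  at raw read-2 index 12 (0-based). Its T:C ratio estimates conversion
  efficiency without touching genomic cytosines.
* **Stacking/catalog** (`build_stacks()`, `build_catalog()`): exact-match
  dereplication; stacks of depth >= 3 seed loci, single-linkage merging
  within 2 mismatches, depth-weighted majority consensus; the cross-sample
  catalog merges sample loci within 4 mismatches (the value balances
  tolerating methylation-state differences between samples against merging
  paralogs — raising it merges more paralogous loci, lowering it splits
  methylation variants into separate loci). Stacks v2 `catalog.fa` files
  are read directly for users who prefer the original tools.
* **Reconstruction** (`reconstruct_loci()`): pad removed; if the two 86 bp
  halves overlap by at least `min_overlap = 10` (0 mismatches by default)
  the overlap is collapsed, otherwise the halves are concatenated
  unchanged. The maximal qualifying overlap is taken to avoid spurious
  short matches; 10 bp makes a chance exact match unlikely
  (about `86 * 4^-10` per pair). Fragments are named by the 0-based
  catalog record index of the pair's first member, so every mock-genome
  fragment traces back to its catalog line.
* **Mock genome** (`build_mock_genome()`): fragments concatenated in name
  order; boundary table in 1-based inclusive coordinates to match the
  conventions of standard methylation callers. The default spacer is 0
  because all downstream reads are fixed-length and map within one read
  image; a configurable `N` spacer is available for soft-clipping
  aligners. `seek_fragments()` resolves caller coordinates by binary
  search (positions inside spacers return no fragment rather than the
  nearest one).

## What the simulator emulates — and what it does not

`simulate_library()` implements the forward model: in-silico digestion
(overlapping site occurrences included; fragment length is cut-to-cut),
context-dependent methylation (CpG/CHG/CHH; CpG dyads symmetric by
default), independent per-molecule bisulfite conversion at a configurable
efficiency, both insertion orientations at a configurable depth, inline
barcodes + `TGCA` on read 1, wobble + adapter remnant (with the check
cytosine behaving as designed) on read 2, constant base qualities and
optional iid substitution errors.

Defaults state a plant-like world: GC 0.38 and methylation levels
31% (CpG) / 1.3% (CHG) / 0.5% (CHH), matching what this protocol family
reports for PstI libraries of a small plant genome; conversion efficiency
0.98 (typical kit performance and the design point of the adapter check);
150–250 bp size selection (the usual ~200 bp insert target); depth 5 per
orientation per sample.

Not simulated (deliberately): nick-translation failure, adapter dimers,
chimeras, indel errors, quality decay along the read, two-enzyme
libraries, and adapter read-through — fragments shorter than the trimmed
read span are rejected, as the fixed trim/truncate scheme assumes inserts
of at least 90 bp. A green round-trip test therefore establishes the
correctness of the decoding logic and the pipeline contracts, not
robustness to library artifacts the model excludes.

## Numerical and degenerate-input choices

* Digest cut convention: 0-based cut coordinate `site_start + 5` for
  `CTGCA^G`; fragments partition the source, so terminal (non-internal)
  fragments are reported too and concatenating all fragments restores the
  input.
* Cytosine context at fragment edges: missing downstream bases are treated
  as H, so a terminal cytosine is CHH.
* Decode conflicts become `N` rather than discarding the pair, up to a
  conflict fraction of 0.05 per pair (beyond that the pairing itself is
  suspect and both loci are reported unpaired).
* Unpaired catalog loci are excluded from the mock genome: reconstruction
  requires both strand images. Counts are reported and ids written to
  `unpaired.txt`.
* Fragment polarity is unknowable without a reference: the Watson member
  of a pair is simply the lower catalog index, so about half the
  fragments are emitted as the bottom strand. Downstream mapping should
  be non-directional. Tests compare strand-agnostically.
* Inserts longer than 172 bp cannot be fully covered by two 86 bp read
  images; they are reconstructed as the 5'86 + 3'86 concatenation
  (`merged = FALSE`). Inserts of 161–171 bp overlap by fewer than
  `min_overlap` bases and are likewise concatenated, duplicating up to
  9 middle bases — the simulator's round-trip tests draw insert sizes
  outside this ambiguous zone.
* Order stability: all stages are single-threaded and preserve stream
  order, keeping forward/reverse files matched by position.

## Known limitations

* The stacking/catalog stage is a simplified stand-in for the original
  tools (no SNP model, no gapped alignment); heterozygous loci may split.
  Users can substitute a real Stacks v2 catalog.
* Near-identical paralogs within the catalog mismatch radius are merged
  into one mock-genome fragment, exactly as in the original pipeline.
* Methylation *extraction* from sample reads against the mock genome is
  out of scope by design — use a bisulfite aligner and caller; this
  package supplies the reference and maps the results back
  (`load_positions()`, `seek_fragments()`).
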