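# epigbsr

Reference-free analysis of single-enzyme **epiGBS** libraries
(epi-genotyping-by-sequencing): reduced-representation bisulfite
sequencing for non-model organisms, where restriction fragments are
ligated between a barcoded adapter and one hemimethylated common adapter
and enter the library in **both orientations**. After bisulfite treatment
and PCR, each genomic fragment is therefore represented by the converted
images of *both* of its strands — and that redundancy is enough to
reconstruct the original, pre-bisulfite fragment sequence and the
methylation state of every cytosine **without any reference genome**.

## Who this is for

Groups studying DNA methylation in natural populations of plants or other
non-model organisms who sequence PstI (or similar) epiGBS libraries and
need a mapping reference built from the reads themselves, plus the
supporting plumbing: demultiplexing, overhang trimming, read joining,
quality filtering, PCR-clone removal, conversion-rate QC, and a simulator
to design and validate experiments.

## The core idea

Bisulfite converts unmethylated cytosine to (ultimately) thymine — a
pyrimidine to a pyrimidine. Encode every base as purine or pyrimidine
(`A,G → R`; `C,T → Y`) and conversion becomes invisible:

```
ry_encode(bisulfite(s)) == ry_encode(s)          for any methylation state
```

The two converted strands of one fragment are reverse complements in RY
space, so locus consensus sequences can be paired by the key

```
partner_key(ry) = reverse(swap_RY(ry)) = ry_encode(reverse_complement(s))
```

Decoding a paired Watson sequence `w` against the reverse complement `p`
of its Crick partner recovers sequence and methylation at every position:

| (w, p)     | original base | interpretation                    |
|------------|---------------|-----------------------------------|
| C, C       | C             | methylated cytosine               |
| T, C / C, T| C             | unmethylated cytosine             |
| G, G       | G             | methylated C on opposite strand   |
| G, A / A, G| G             | unmethylated C on opposite strand |
| A, A / T, T| A / T         | no cytosine                       |
| anything else | N          | conflict                          |

Reconstructed fragments are concatenated into a **mock genome** with a
boundary table, so standard bisulfite aligners and methylation callers can
be used downstream; `seek_fragments()` maps caller coordinates back to
fragments.

## Worked example

Simulate a small library from a random genome (3 internal PstI fragments
of 175, 192 and 129 bp survive 100–300 bp size selection), run the whole
pipeline in memory, and check the result:

```r
library(epigbsr)

bc  <- default_barcodes()[1:4]            # 4 samples, Table-style barcodes
cfg <- sim_config(genome_length = 4e5, gc_fraction = 0.5,
                  size_min = 100, size_max = 300,
                  depth_per_orientation = 20,
                  conversion_efficiency = 0.98,
                  barcode_table = bc, seed = 2026)
sim <- simulate_library(cfg)
res <- run_pipeline(list(forward = sim$r1, reverse = sim$r2), bc)

res$preprocess$report
#>   sample input assigned trimmed joined passed
#> 1  AlDA1   480      120     120    120    120
#> 2  AlDB2   480      119     119    119    119
#> 3  AlDA2   480      120     120    120    120
#> 4  AlDB1   480      120     120    120    120

res$preprocess$conversion
#> Bisulfite conversion check: 468 T, 12 C, 0 other; rate = 0.975

nrow(res$catalog)                         # 6: one locus per strand image
res$reconstruction$n_pairs                # 3 Watson/Crick pairs found
res$mock
#> Mock genome: 473 bp, 3 fragments, spacer 0
res$mock$boundaries
#>   name start end
#> 1    0     1 172
#> 2    1   173 344
#> 3    4   345 473

seek_fragments(c(100L, 400L), res$mock$boundaries)
#>   position fragment offset
#> 1      100        0    100
#> 2      400        4     56
```

The 129 bp fragment is recovered base-exactly at full length (its two
86 bp read halves overlap and are merged); the 175 and 192 bp fragments
are recovered as the 172 bp image covered by the reads (5' 86 bp + 3'
86 bp). The estimated conversion rate (0.975) tracks the simulated
efficiency (0.98) from the adapter check cytosine alone. Per-position
methylation calls come back as a compact string per fragment
(`M`/`U` = methylated/unmethylated C, `G`/`g` = the same for the opposite
strand's C, `.` = no cytosine, `x` = conflict):

```r
substr(res$reconstruction$fragments$calls[1], 1, 60)
#> ".gU.gg..gggU......gU.gUU.gg...UUUgUgUU.MGg..U...U...MGgUgg.."
```

Note that fragment polarity is arbitrary without a reference: roughly half
the fragments are reported as the bottom strand (map with a
non-directional bisulfite aligner downstream).

## Command line

Every stage is also exposed as a subcommand (see `inst/scripts/epigbsr`):

```sh
Rscript -e 'epigbsr::run_cli()' simulate    --out sim --seed 1
Rscript -e 'epigbsr::run_cli()' preprocess  --r1 sim/R1.fastq.gz --r2 sim/R2.fastq.gz --out pp
Rscript -e 'epigbsr::run_cli()' catalog     --joined-dir pp --out catalog.fa
Rscript -e 'epigbsr::run_cli()' reconstruct --catalog catalog.fa --out rec
Rscript -e 'epigbsr::run_cli()' seek        --positions dmc.tsv --boundaries rec/boundaries.tsv
Rscript -e 'epigbsr::run_cli()' convrate    --r2 sim/R2.fastq.gz
Rscript -e 'epigbsr::run_cli()' digest-stats --genome genome.fasta
```

`reconstruct` also accepts a Stacks v2 `catalog.fa[.gz]` directly.

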