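# End-to-end convenience wrapper: raw paired reads -> per-sample joined
# sequences -> per-sample loci -> cross-sample catalog -> reconstructed
# fragments -> mock genome.

#' Run the full reference-free pipeline in memory
#'
#' @param pairs Raw read-pair set from [read_pairs()] (or
#'   `simulate_library()` output via `list(forward = sim$r1,
#'   reverse = sim$r2)`).
#' @param barcodes Named character vector `sample -> barcode`.
#' @param max_mismatches,strip_forward,strip_reverse,truncate_to,padgap,pad_quality,max_rate,use_clone_filter
#'   Preprocessing parameters, see [preprocess_pairs()].
#' @param min_depth,merge_mismatches Stacking parameters, see
#'   [build_stacks()].
#' @param catalog_mismatches Catalog parameter, see [build_catalog()].
#' @param min_overlap,overlap_mismatches,max_conflict_fraction
#'   Reconstruction parameters, see [reconstruct_loci()].
#' @param spacer_length Mock-genome spacer, see [build_mock_genome()].
#' @return List: `preprocess` (report, conversion stats, clone count),
#'   `catalog`, `reconstruction`, `mock`.
#' @export
run_pipeline <- function(pairs, barcodes,
                         max_mismatches = 1L, strip_forward = 4L,
                         strip_reverse = 14L, truncate_to = 86L,
                         padgap = "ATATATAT", pad_quality = 40L,
                         max_rate = 0.01, use_clone_filter = TRUE,
                         min_depth = 3L, merge_mismatches = 2L,
                         catalog_mismatches = 4L,
                         min_overlap = 10L, overlap_mismatches = 0L,
                         max_conflict_fraction = 0.05,
                         spacer_length = 0L) {
  pp <- preprocess_pairs(pairs, barcodes, max_mismatches, strip_forward,
                         strip_reverse, truncate_to, padgap, pad_quality,
                         max_rate, use_clone_filter)
  loci <- lapply(pp$joined, build_stacks, min_depth = min_depth,
                 merge_mismatches = merge_mismatches)
  cat <- build_catalog(loci, catalog_mismatches)
  recon <- reconstruct_loci(cat, padgap, min_overlap, overlap_mismatches,
                            max_conflict_fraction)
  mock <- if (nrow(recon$fragments) > 0L)
    build_mock_genome(recon$fragments, spacer_length) else NULL
  list(preprocess = pp, catalog = cat, reconstruction = recon, mock = mock)
}
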