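# Published clade composition of the Streptomyces reference species tree.

#' Clade sizes of the Streptomyces reference species tree
#'
#' Species counts of the eight major clades (C1-C8) into which 373
#' *Streptomyces* type-strain genomes fall on the re-rooted reference
#' species tree. The re-rooted tree's two deepest branches hold C1-C4
#' (180 species) and C5-C8 (193 species). These counts are the standard
#' worked input for the clade-proportional resampling design.
#'
#' @return a named integer vector of length 8.
#' @examples
#' sizes <- streptomyces_clade_sizes()
#' sum(sizes[1:4])  # 180, the C1-C4 deep branch
#' sum(sizes[5:8])  # 193, the C5-C8 deep branch
#' allocate_clade_counts(sizes, 64)
#' @export
streptomyces_clade_sizes <- function() {
  c(C1 = 1L, C2 = 2L, C3 = 18L, C4 = 159L,
    C5 = 36L, C6 = 56L, C7 = 15L, C8 = 86L)
}

#' Synthetic clade partition with the published clade sizes
#'
#' Builds a `clade_partition` whose clade sizes match
#' [streptomyces_clade_sizes()], with synthetic species identifiers
#' (`C4_017`, ...). Species identity does not matter for resampling
#' statistics, only the clade size structure does, so this stand-in
#' reproduces the design's resampling behaviour exactly.
#'
#' @return a `clade_partition` over 373 synthetic species IDs.
#' @export
streptomyces_clade_partition <- function() {
  sizes <- streptomyces_clade_sizes()
  clade_partition(
    species_id = unlist(lapply(names(sizes), function(cl)
      sprintf("%s_%03d", cl, seq_len(sizes[[cl]]))), use.names = FALSE),
    clade_label = rep(names(sizes), sizes))
}
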