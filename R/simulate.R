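# Synthetic data with the statistical structure the concordance analysis
# assumes: a Yule species tree, gene trees at controlled topological
# distances from it (random NNI walks), and protein alignments whose
# parsimony-informative-site counts span orders of magnitude.

#' Simulation configuration
#'
#' Defaults emulate one random genome dataset of the resampling design:
#' 64 species, a small low-discordance focal gene set ("DG", 10 genes at
#' 2 NNI moves) against a large background set ("sOG", 500 genes at 8
#' NNI moves), mirroring the per-dataset scale of roughly 10
#' development-related gene trees versus roughly 500 strict-orthogroup
#' trees. Per-gene alignment lengths and substitution rates are drawn
#' log-uniformly from `alignment_length_range` columns and `rate_range`
#' expected substitutions per site per branch, wide enough that realized
#' PIS counts span from around ten to around a thousand.
#'
#' @param n_species number of tips of the species tree (default 64).
#' @param genes_per_set named integer vector: genes per gene set.
#' @param nni_per_set named integer vector (same names): NNI moves
#'   applied to each gene tree of the set; 0 means perfectly concordant.
#' @param alignment_length_range min/max alignment columns.
#' @param rate_range min/max per-branch substitution probability scale
#'   (expected substitutions per site on a unit branch).
#' @param seed master RNG seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_species = 64L,
                       genes_per_set = c(DG = 10L, sOG = 500L),
                       nni_per_set = c(DG = 2L, sOG = 8L),
                       alignment_length_range = c(50L, 2000L),
                       rate_range = c(0.003, 0.3),
                       seed = 1L) {
  stopifnot(n_species >= 4L,
            length(genes_per_set) >= 1L, all(genes_per_set >= 1L),
            !is.null(names(genes_per_set)),
            setequal(names(genes_per_set), names(nni_per_set)),
            all(nni_per_set >= 0L),
            length(alignment_length_range) == 2L,
            alignment_length_range[1L] >= 1L,
            diff(alignment_length_range) >= 0,
            length(rate_range) == 2L, all(rate_range > 0),
            diff(rate_range) >= 0)
  structure(list(n_species = as.integer(n_species),
                 genes_per_set = genes_per_set,
                 nni_per_set = nni_per_set[names(genes_per_set)],
                 alignment_length_range = alignment_length_range,
                 rate_range = rate_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a species tree under a Yule process
#'
#' Pure-birth tree with `n` tips labelled `sp0001`, `sp0002`, ... and
#' unit branch lengths (all downstream statistics are topological; the
#' alignment simulator treats every branch as one unit of time).
#'
#' @param n number of tips (at least 4).
#' @param seed optional integer seed; the tree is deterministic per
#'   seed.
#' @return a binary rooted `phylo`.
#' @export
simulate_species_tree <- function(n, seed = NULL) {
  n <- as.integer(assert_scalar_number(n, "n", 4))
  tr <- with_seed_if(seed, ape::rphylo(n, birth = 1, death = 0))
  tr$tip.label <- sprintf("sp%04d", seq_len(n))
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

#' Perturb a gene tree by random NNI moves
#'
#' Applies `n_moves` random nearest-neighbour interchanges to a copy of
#' the species tree, producing a gene tree at a controlled topological
#' distance: each move changes at most one bipartition, so discordance
#' grows (stochastically) with the number of moves.
#'
#' @param species_tree a binary `phylo`.
#' @param n_moves number of NNI moves (0 returns the tree unchanged).
#' @param seed optional integer seed.
#' @return a `phylo` with the same tips.
#' @export
perturb_gene_tree <- function(species_tree, n_moves, seed = NULL) {
  validate_phylo(species_tree)
  n_moves <- as.integer(assert_scalar_number(n_moves, "n_moves", 0))
  if (n_moves == 0L) return(species_tree)
  with_seed_if(seed, phangorn::rNNI(species_tree, moves = n_moves, n = 1L))
}

#' Evolve a protein alignment down a tree
#'
#' Simple Poisson-style simulator: the root sequence is uniform over the
#' 20 amino acids; along every branch (treated as unit length) each site
#' substitutes with probability `1 - exp(-rate)`, to a residue chosen
#' uniformly among the 19 alternatives. No rate heterogeneity, no
#' indels; this controls the number of parsimony-informative sites,
#' which is all downstream stages consume.
#'
#' @param tree a `phylo`; one alignment row is produced per tip.
#' @param n_columns number of sites.
#' @param rate expected substitutions per site per branch.
#' @param seed optional integer seed.
#' @return a character matrix (tips x sites).
#' @export
evolve_alignment <- function(tree, n_columns, rate, seed = NULL) {
  validate_phylo(tree)
  n_columns <- as.integer(assert_scalar_number(n_columns, "n_columns", 1))
  assert_scalar_number(rate, "rate", 0)
  with_seed_if(seed, {
    tr <- stats::reorder(tree, "cladewise")  # parents before children
    n <- length(tr$tip.label)
    p_sub <- 1 - exp(-rate)
    seqs <- matrix(NA_integer_, nrow = n + tr$Nnode, ncol = n_columns)
    root <- tr$edge[1L, 1L]
    seqs[root, ] <- sample.int(20L, n_columns, replace = TRUE)
    for (i in seq_len(nrow(tr$edge))) {
      s <- seqs[tr$edge[i, 1L], ]
      hit <- which(stats::runif(n_columns) < p_sub)
      if (length(hit))
        s[hit] <- 1L + (s[hit] - 1L +
                          sample.int(19L, length(hit), replace = TRUE)) %% 20L
      seqs[tr$edge[i, 2L], ] <- s
    }
    aln <- matrix(AA20[seqs[seq_len(n), , drop = FALSE]], nrow = n)
    rownames(aln) <- tr$tip.label
    aln
  })
}

#' Simulate one synthetic concordance dataset in memory
#'
#' Draws a Yule species tree and, for each configured gene set, gene
#' trees perturbed by the set's NNI budget, optionally with protein
#' alignments evolved on each gene tree (length and rate drawn
#' log-uniformly per gene from the configured ranges). Fully
#' reproducible for a given `config$seed`.
#'
#' @param config a [sim_config()].
#' @param alignments simulate alignments too? (default TRUE; trees-only
#'   runs are much faster when PIS counts are not needed).
#' @return a list with `species_tree`, `genes` (data.frame: `gene_id`,
#'   `set_label`, `n_moves`, `n_columns`, `rate`), `trees` (named list
#'   of `phylo`), `alignments` (named list of matrices, or NULL).
#' @export
simulate_dataset <- function(config = sim_config(), alignments = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  with_seed_if(config$seed, {
    species_tree <- ape::rphylo(config$n_species, birth = 1, death = 0)
    species_tree$tip.label <- sprintf("sp%04d", seq_len(config$n_species))
    species_tree$edge.length <- rep(1, nrow(species_tree$edge))

    llr <- log10(as.numeric(config$alignment_length_range))
    lrr <- log10(config$rate_range)
    genes <- list(); trees <- list(); alns <- list()
    for (set in names(config$genes_per_set)) {
      n_genes <- config$genes_per_set[[set]]
      moves <- config$nni_per_set[[set]]
      for (g in seq_len(n_genes)) {
        id <- sprintf("%s_%04d", set, g)
        tr <- if (moves == 0L) species_tree
              else phangorn::rNNI(species_tree, moves = moves, n = 1L)
        len <- as.integer(round(10^stats::runif(1L, llr[1L], llr[2L])))
        rate <- 10^stats::runif(1L, lrr[1L], lrr[2L])
        genes[[id]] <- data.frame(gene_id = id, set_label = set,
                                  n_moves = moves, n_columns = len,
                                  rate = rate, stringsAsFactors = FALSE)
        trees[[id]] <- tr
        if (alignments) alns[[id]] <- evolve_alignment(tr, len, rate)
      }
    }
    list(species_tree = species_tree,
         genes = do.call(rbind, c(genes, list(make.row.names = FALSE))),
         trees = trees,
         alignments = if (alignments) alns else NULL)
  })
}

#' Write a synthetic concordance fixture to disk
#'
#' Materializes [simulate_dataset()] in the on-disk layout the pipeline
#' consumes: `species_tree.nwk`, one Newick per gene under `trees/`, one
#' FASTA per gene under `alignments/`, and `manifest.tsv` with columns
#' `gene_id`, `tree_path`, `alignment_path`, `set_label` (paths relative
#' to `out_dir`). Regenerating with the same config yields identical
#' files.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with `out_dir`, `reference_tree` and
#'   `manifest` paths.
#' @export
generate_fixture <- function(config = sim_config(), out_dir) {
  stopifnot(is.character(out_dir), length(out_dir) == 1L)
  d <- simulate_dataset(config, alignments = TRUE)
  dir.create(file.path(out_dir, "trees"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)

  ref_path <- file.path(out_dir, "species_tree.nwk")
  writeLines(write_newick(d$species_tree), ref_path)

  tree_rel <- file.path("trees", paste0(d$genes$gene_id, ".nwk"))
  aln_rel <- file.path("alignments", paste0(d$genes$gene_id, ".fasta"))
  for (i in seq_len(nrow(d$genes))) {
    id <- d$genes$gene_id[i]
    writeLines(write_newick(d$trees[[id]]), file.path(out_dir, tree_rel[i]))
    write_alignment(d$alignments[[id]], file.path(out_dir, aln_rel[i]))
  }
  manifest <- data.frame(gene_id = d$genes$gene_id, tree_path = tree_rel,
                         alignment_path = aln_rel,
                         set_label = d$genes$set_label,
                         stringsAsFactors = FALSE)
  man_path <- file.path(out_dir, "manifest.tsv")
  write.table(manifest, man_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(list(out_dir = out_dir, reference_tree = ref_path,
                 manifest = man_path))
}
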