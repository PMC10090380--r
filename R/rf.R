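# Robinson-Foulds concordance between gene trees and a reference tree.
#
# An RF record is a one-row data.frame; batch functions rbind them into a
# per-gene table, the package's central result object.

# Canonical string keys for the non-trivial unrooted bipartitions of a
# tree. Each split is oriented away from the lexicographically smallest
# tip label so that keys are comparable across trees on the same tip set.
split_keys <- function(tree) {
  n <- length(tree$tip.label)
  if (n < 4L) return(character(0))
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  # rank tips by label so keys are comparable across trees on one tip set
  rank <- match(tree$tip.label, sort(tree$tip.label))
  parts <- ape::prop.part(tree)
  keys <- vapply(parts, function(p) {
    s <- length(p)
    if (s < 2L || s > n - 2L) return(NA_character_)
    side <- rank[p]
    if (1L %in% side) side <- seq_len(n)[-side]  # orient away from rank 1
    paste(sort.int(side), collapse = ",")
  }, character(1L))
  unique(keys[!is.na(keys)])
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' One bipartition per internal edge of the unrooted tree; trivial splits
#' (one tip versus the rest) are omitted. Each element is the sorted
#' vector of tip labels on the side *not* containing the
#' lexicographically smallest tip, a canonical orientation under which
#' two splits are equal iff their label vectors are identical.
#'
#' @param tree a `phylo` object with at least 4 tips.
#' @return a list of character vectors of tip labels.
#' @examples
#' bipartitions(parse_newick("((A,B),(C,D));"))  # list(c("C","D"))
#' bipartitions(parse_newick("(A,B,C,D,E);"))    # empty: star tree
#' @export
bipartitions <- function(tree) {
  validate_phylo(tree)
  if (length(tree$tip.label) < 4L)
    stop("bipartitions are defined for trees with at least 4 tips",
         call. = FALSE)
  labs_sorted <- sort(tree$tip.label)
  lapply(split_keys(tree), function(k)
    labs_sorted[as.integer(strsplit(k, ",", fixed = TRUE)[[1L]])])
}

rf_record_row <- function(gene_id = NA_character_, raw_rf = NA_integer_,
                          max_rf = NA_integer_, norm_rf = NA_real_,
                          n_shared_tips = NA_integer_,
                          polytomy_fraction = NA_real_,
                          excluded = FALSE, reason = NA_character_,
                          degenerate = FALSE, n_pis = NA_integer_) {
  data.frame(gene_id = gene_id, raw_rf = as.integer(raw_rf),
             max_rf = as.integer(max_rf), norm_rf = norm_rf,
             n_shared_tips = as.integer(n_shared_tips),
             polytomy_fraction = polytomy_fraction,
             excluded = excluded, reason = reason,
             degenerate = degenerate, n_pis = as.integer(n_pis),
             stringsAsFactors = FALSE)
}

#' Robinson-Foulds distance between a gene tree and a reference tree
#'
#' Prunes both trees to their shared tips, extracts the non-trivial
#' unrooted bipartitions of each, and counts the symmetric difference.
#' The normalized distance divides by the total number of non-trivial
#' splits in both trees, `|S_gene| + |S_ref|`, which keeps the value in
#' `[0, 1]` for polytomous as well as binary trees (for two binary trees
#' on n tips this denominator equals the classical maximum 2(n-3)).
#'
#' @param t_gene,t_ref `phylo` objects; they need not share all tips but
#'   must share at least 4.
#' @param gene_id optional identifier stored in the record.
#' @return a one-row data.frame (an "RF record") with columns `gene_id`,
#'   `raw_rf`, `max_rf`, `norm_rf`, `n_shared_tips`, `polytomy_fraction`
#'   (of the pruned gene tree), `excluded`, `reason`, `degenerate`,
#'   `n_pis`.
#' @details If both pruned trees are stars (`max_rf == 0`) the normalized
#'   distance is defined as 0 and the record is flagged `degenerate` with
#'   a warning.
#' @examples
#' rf_distance(parse_newick("((A,B),(C,D));"),
#'             parse_newick("((A,C),(B,D));"))$norm_rf  # 1
#' @export
rf_distance <- function(t_gene, t_ref, gene_id = NA_character_) {
  pr <- prune_to_common_tips(t_gene, t_ref)
  s_gene <- split_keys(pr$t1)
  s_ref <- split_keys(pr$t2)
  raw <- length(setdiff(s_gene, s_ref)) + length(setdiff(s_ref, s_gene))
  mx <- length(s_gene) + length(s_ref)
  degen <- mx == 0L
  if (degen)
    warning("both trees are stars after pruning; norm_rf set to 0",
            call. = FALSE)
  rf_record_row(gene_id = gene_id, raw_rf = raw, max_rf = mx,
                norm_rf = if (degen) 0 else raw / mx,
                n_shared_tips = length(pr$t1$tip.label),
                polytomy_fraction = polytomy_tip_fraction(pr$t1),
                degenerate = degen)
}

#' RF distances of many gene trees against one reference
#'
#' Equivalent to calling [rf_distance()] per tree, but when a gene tree
#' has exactly the reference's tip set the reference split set is reused
#' instead of being re-extracted, which makes large batches (hundreds of
#' gene trees per dataset) much faster.
#'
#' @param trees a list of `phylo` objects.
#' @param t_ref the reference `phylo`.
#' @param gene_ids optional identifiers (defaults to `names(trees)`).
#' @return an RF record data.frame with one row per tree.
#' @export
rf_distance_batch <- function(trees, t_ref, gene_ids = names(trees)) {
  stopifnot(is.list(trees), length(trees) >= 1L)
  if (is.null(gene_ids)) gene_ids <- rep(NA_character_, length(trees))
  validate_phylo(t_ref)
  ref_labs <- sort(t_ref$tip.label)
  ref_keys <- split_keys(t_ref)
  rows <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    if (identical(sort(tr$tip.label), ref_labs)) {
      s_gene <- split_keys(tr)
      raw <- length(setdiff(s_gene, ref_keys)) +
        length(setdiff(ref_keys, s_gene))
      mx <- length(s_gene) + length(ref_keys)
      degen <- mx == 0L
      rf_record_row(gene_id = gene_ids[i], raw_rf = raw, max_rf = mx,
                    norm_rf = if (degen) 0 else raw / mx,
                    n_shared_tips = length(ref_labs),
                    polytomy_fraction = polytomy_tip_fraction(tr),
                    degenerate = degen)
    } else {
      rf_distance(tr, t_ref, gene_id = gene_ids[i])
    }
  })
  do.call(rbind, rows)
}

#' Apply the polytomy exclusion rule
#'
#' Marks records whose gene tree has multifurcations involving at least
#' `threshold` of the species as excluded; excluded records never enter
#' gene-set summaries or baseline fits. The rule is inclusive: a fraction
#' exactly equal to the threshold is excluded.
#'
#' @param records an RF record data.frame (see [rf_distance()]).
#' @param threshold exclusion threshold on `polytomy_fraction`
#'   (default 0.5).
#' @param boundary_margin records with `|polytomy_fraction - threshold|`
#'   at or below this margin are flagged `near_boundary` so borderline
#'   decisions are visible downstream (default 0.05).
#' @return `records` with updated `excluded`/`reason` columns and an
#'   added logical `near_boundary` column.
#' @export
apply_exclusion <- function(records, threshold = 0.5, boundary_margin = 0.05) {
  stopifnot(is.data.frame(records), "polytomy_fraction" %in% names(records))
  assert_scalar_number(threshold, "threshold", 0, 1)
  hit <- !is.na(records$polytomy_fraction) &
    records$polytomy_fraction >= threshold
  records$excluded <- records$excluded | hit
  records$reason[hit & is.na(records$reason)] <- "polytomy"
  records$near_boundary <- !is.na(records$polytomy_fraction) &
    abs(records$polytomy_fraction - threshold) <= boundary_margin
  records
}

#' Summarize the concordance of a gene set
#'
#' Mean and sample standard deviation of a distance column over the
#' non-excluded records of one gene set.
#'
#' @param records an RF record data.frame for the genes of one set.
#' @param set_label label stored in the summary row.
#' @param value column to summarize (default `"norm_rf"`; use
#'   `"rf_prime"` after baseline normalization).
#' @return a one-row data.frame with `set_label`, `n_trees`, `mean_rf`,
#'   `sd_rf`, `sd_undefined` (TRUE when only one record contributed, in
#'   which case `sd_rf` is reported as 0).
#' @export
summarize_gene_set <- function(records, set_label, value = "norm_rf") {
  stopifnot(is.data.frame(records), value %in% names(records))
  keep <- !records$excluded & !is.na(records[[value]])
  x <- records[[value]][keep]
  if (length(x) == 0L)
    stop("gene set \"", set_label, "\": no included records to summarize",
         call. = FALSE)
  one <- length(x) == 1L
  data.frame(set_label = set_label, n_trees = length(x),
             mean_rf = mean(x), sd_rf = if (one) 0 else sd(x),
             sd_undefined = one, stringsAsFactors = FALSE)
}

#' Relative RF distance of a gene set versus a reference set
#'
#' `(set_mean - ref_mean) / ref_mean`: the signed fractional shift of a
#' gene set's mean distance relative to the background set (e.g. the
#' strict orthogroups). Negative values mean the set is more concordant
#' with the species tree than the background.
#'
#' @param set_mean mean (normalized) RF distance of the gene set.
#' @param ref_mean mean of the reference set; must be positive.
#' @return a signed fraction.
#' @export
relative_rf <- function(set_mean, ref_mean) {
  assert_scalar_number(set_mean, "set_mean")
  assert_scalar_number(ref_mean, "ref_mean")
  if (ref_mean <= 0)
    stop("`ref_mean` must be positive", call. = FALSE)
  (set_mean - ref_mean) / ref_mean
}
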