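# Tree input/output and topology manipulation.
#
# All trees are ape "phylo" objects. Branch lengths and node support values
# are carried along when present but every statistic in this package is
# purely topological and ignores them.

#' Validate a phylogenetic tree
#'
#' Checks the invariants every tree used by this package must satisfy:
#' an ape `phylo` object with at least two uniquely and non-emptily
#' labelled tips.
#'
#' @param tree an object to validate.
#' @return `tree`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo"))
    stop("not a \"phylo\" object", call. = FALSE)
  labs <- tree$tip.label
  if (length(labs) < 2L)
    stop("tree must have at least 2 tips", call. = FALSE)
  if (anyNA(labs) || any(!nzchar(labs)))
    stop("tip labels must be non-empty", call. = FALSE)
  if (anyDuplicated(labs)) {
    dup <- unique(labs[duplicated(labs)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  invisible(tree)
}

#' Parse a Newick string
#'
#' Parses a single Newick statement into an ape `phylo` object and
#' validates it (unique, non-empty tip labels). Internal nodes of
#' out-degree one (created e.g. by redundant parentheses) are collapsed,
#' so that every internal node has at least two children.
#'
#' @param text a single Newick string terminated by `";"`.
#' @return a validated `phylo` object.
#' @seealso [write_newick()], [ape::read.tree()]
#' @examples
#' tr <- parse_newick("((A,B),(C,D));")
#' tr$tip.label
#' @export
parse_newick <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text)))
    stop("`text` must be a single non-empty Newick string", call. = FALSE)
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr))
    stop("malformed Newick string", call. = FALSE)
  if (inherits(tr, "multiPhylo")) {
    if (length(tr) != 1L)
      stop("expected a single Newick statement, found ", length(tr),
           call. = FALSE)
    tr <- tr[[1L]]
  }
  tr <- ape::collapse.singles(tr)
  validate_phylo(tr)
  tr
}

#' Serialize a tree to Newick
#'
#' Round-trip guarantee: `parse_newick(write_newick(t))` has the same
#' unrooted bipartition set as `t`.
#'
#' @param tree a `phylo` object.
#' @return a single Newick string.
#' @export
write_newick <- function(tree) {
  validate_phylo(tree)
  ape::write.tree(tree)
}

#' Read one or more Newick trees from a file
#'
#' Accepts files with one tree per line. Returns a list of validated
#' `phylo` objects.
#'
#' @param path path to a Newick file.
#' @return a list of `phylo` objects.
#' @export
read_newick_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("no trees in file: ", path, call. = FALSE)
  if (inherits(tr, "phylo")) tr <- list(tr) else tr <- unclass(tr)
  lapply(tr, function(t) validate_phylo(ape::collapse.singles(t)))
}

#' Prune two trees to their common tip set
#'
#' Both trees are restricted to the intersection of their tip labels, the
#' preliminary step for any topological comparison of trees inferred from
#' different taxon samples. Degree-two nodes created by pruning are
#' suppressed.
#'
#' @param t1,t2 `phylo` objects.
#' @return a list with elements `t1` and `t2`, both on the shared tip set.
#' @details At least 4 shared tips are required: with fewer there is no
#'   non-trivial unrooted bipartition and the RF distance is undefined.
#' @export
prune_to_common_tips <- function(t1, t2) {
  validate_phylo(t1); validate_phylo(t2)
  common <- intersect(t1$tip.label, t2$tip.label)
  if (length(common) < 4L)
    stop("trees share only ", length(common),
         " tips; at least 4 are required", call. = FALSE)
  list(t1 = ape::keep.tip(t1, common), t2 = ape::keep.tip(t2, common))
}

#' Re-root a tree on its most balanced edge
#'
#' Places the root on the edge whose induced bipartition minimizes the
#' absolute difference between the numbers of tips on its two sides, so
#' that the two deepest branches of the re-rooted tree contain close
#' numbers of species. Ties are broken deterministically by the
#' lexicographically smallest tip label on the smaller side (then by the
#' full sorted label list of that side).
#'
#' @param tree a `phylo` object with at least 4 tips.
#' @return a rooted `phylo` whose root has exactly two children.
#' @details Only the root position changes: the unrooted bipartition set
#'   of the result equals that of the input.
#' @export
reroot_balanced <- function(tree) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  if (n < 4L) stop("balanced re-rooting needs at least 4 tips", call. = FALSE)
  un <- if (ape::is.rooted(tree)) ape::unroot(tree) else tree
  labs <- un$tip.label

  edge <- un$edge
  best <- NULL
  for (i in seq_len(nrow(edge))) {
    child <- edge[i, 2L]
    side <- if (child <= n) labs[child]
            else labs[phangorn::Descendants(un, child, "tips")[[1L]]]
    s <- length(side)
    if (s == 0L || s == n) next
    other <- setdiff(labs, side)
    smaller <- if (s < n - s) side
               else if (s > n - s) other
               else if (min(side) <= min(other)) side else other
    cand <- list(imbalance = abs(n - 2L * s),
                 key1 = min(smaller),
                 key2 = paste(sort(smaller), collapse = "\x1f"),
                 outgroup = side)
    if (is.null(best) ||
        cand$imbalance < best$imbalance ||
        (cand$imbalance == best$imbalance &&
         (cand$key1 < best$key1 ||
          (cand$key1 == best$key1 && cand$key2 < best$key2)))) {
      best <- cand
    }
  }
  rooted <- ape::root(un, outgroup = best$outgroup, resolve.root = TRUE)
  validate_phylo(rooted)
  rooted
}

# Tip indices (1..n) descending from each flagged multifurcating node.
multifurcation_nodes <- function(tree) {
  n <- length(tree$tip.label)
  root <- n + 1L
  nchild <- tabulate(tree$edge[, 1L], nbins = max(tree$edge))
  nodes <- which(nchild > 0L)
  # Unrooted sense: a non-root node with c children has unrooted degree
  # c + 1, the root has degree c. True polytomy <=> unrooted degree >= 4.
  nodes[(nodes == root & nchild[nodes] >= 4L) |
        (nodes != root & nchild[nodes] >= 3L)]
}

#' Fraction of tips involved in multifurcations
#'
#' Returns the proportion of tips that descend from at least one
#' multifurcating (polytomous) node. Used by the exclusion rule that
#' removes gene trees whose unresolved regions involve at least half of
#' the species.
#'
#' @param tree a `phylo` object.
#' @return a fraction in `[0, 1]`.
#' @details Polytomies are judged in the unrooted sense: a node is
#'   multifurcating when its unrooted degree is at least 4, i.e. a
#'   non-root node with more than two children, or the (stored) root with
#'   more than three. A bifurcating root is therefore never counted, and
#'   neither is the basal trichotomy of a fully resolved unrooted tree.
#'   "Involved" tips are the descendant tips of the multifurcating node
#'   in the orientation the tree was supplied in.
#' @examples
#' polytomy_tip_fraction(parse_newick("((A,B),(C,D));"))   # 0
#' polytomy_tip_fraction(parse_newick("(A,B,C,D,E);"))     # 1
#' polytomy_tip_fraction(parse_newick("((A,B,C),(D,(E,F)));")) # 0.5
#' @export
polytomy_tip_fraction <- function(tree) {
  validate_phylo(tree)
  n <- length(tree$tip.label)
  poly <- multifurcation_nodes(tree)
  if (length(poly) == 0L) return(0)
  covered <- unique(unlist(phangorn::Descendants(tree, poly, "tips")))
  length(covered) / n
}
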