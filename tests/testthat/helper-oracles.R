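# Independent brute-force oracles, deliberately implemented by literal
# enumeration rather than through the package's canonical-key machinery.

# All non-trivial unrooted splits of a tree as explicit two-sided label
# sets, found by recursing over the edge table.
oracle_splits <- function(tree) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  n <- length(tree$tip.label)
  edge <- tree$edge
  tips_below <- function(node) {
    if (node <= n) return(tree$tip.label[node])
    unlist(lapply(edge[edge[, 1] == node, 2], tips_below))
  }
  out <- list()
  for (i in seq_len(nrow(edge))) {
    ch <- edge[i, 2]
    if (ch <= n) next
    a <- sort(tips_below(ch))
    b <- sort(setdiff(tree$tip.label, a))
    if (length(a) >= 2 && length(b) >= 2)
      out[[length(out) + 1]] <- list(a = a, b = b)
  }
  out
}

oracle_split_in <- function(s, set) {
  any(vapply(set, function(t)
    (identical(s$a, t$a) && identical(s$b, t$b)) ||
    (identical(s$a, t$b) && identical(s$b, t$a)), logical(1)))
}

# Raw RF by counting, one split at a time, membership in the other
# tree's split list (both directions).
oracle_rf <- function(t1, t2) {
  common <- intersect(t1$tip.label, t2$tip.label)
  s1 <- oracle_splits(ape::keep.tip(t1, common))
  s2 <- oracle_splits(ape::keep.tip(t2, common))
  in2 <- vapply(s1, oracle_split_in, logical(1), set = s2)
  in1 <- vapply(s2, oracle_split_in, logical(1), set = s1)
  sum(!in2) + sum(!in1)
}

# Naive per-column parsimony-informative-site counter using table().
oracle_pis <- function(aln) {
  sum(vapply(seq_len(ncol(aln)), function(j) {
    v <- aln[, j]
    v <- v[v %in% LETTERS & v != "X" & v != "B" & v != "Z" &
             v != "J" & v != "U" & v != "O"]
    tb <- table(v)
    sum(tb >= 2) >= 2
  }, logical(1)))
}

# Random unrooted-ish test topology on n tips labelled A, B, C, ...
rand_tree <- function(n, labels = NULL) {
  tr <- ape::rtree(n)
  tr$tip.label <- if (is.null(labels)) make.unique(rep(LETTERS, length.out = n))
                  else labels
  tr
}

# Random protein alignment with gaps and ambiguity codes mixed in.
rand_alignment <- function(nrow, ncol) {
  matrix(sample(c("A", "C", "D", "E", "F", "G", "R", "K", "-", "X"),
                nrow * ncol, replace = TRUE,
                prob = c(rep(0.11, 8), 0.07, 0.05)),
         nrow = nrow,
         dimnames = list(sprintf("s%02d", seq_len(nrow)), NULL))
}
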