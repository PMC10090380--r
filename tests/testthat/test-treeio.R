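test_that("parse_newick builds validated trees and rejects bad input", {
  tr <- parse_newick("((A,B),(C,D));")
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_equal(bipartitions(tr), list(c("C", "D")))

  star <- parse_newick("(A,B,C,D,E);")
  expect_length(star$tip.label, 5)
  expect_length(bipartitions(star), 0)

  expect_error(parse_newick("((A,B),(A,C));"), "duplicate")
  expect_error(parse_newick("((A,B),(C,D)"), "malformed")
  expect_error(parse_newick(c("(A,B);", "(C,D);")), "single")
})

test_that("branch lengths are carried but do not change topology results", {
  t_bl <- parse_newick("((A:1.5,B:0.2):0.9,(C:3,D:0.1):0.4);")
  t_plain <- parse_newick("((A,B),(C,D));")
  expect_false(is.null(t_bl$edge.length))
  expect_equal(rf_distance(t_bl, t_plain)$raw_rf, 0L)
})

test_that("write_newick round-trips the bipartition set", {
  for (txt in c("((A,B),(C,D));", "(A,B,C,D,E);",
                "(((A,B),C),((D,E),(F,G)));")) {
    tr <- parse_newick(txt)
    back <- parse_newick(write_newick(tr))
    expect_equal(suppressWarnings(rf_distance(back, tr))$raw_rf, 0L,
                 info = txt)
  }
})

test_that("parse/write round-trip preserves splits on random trees", {
  set.seed(42)
  for (i in 1:500) {
    n <- sample(4:64, 1)
    tr <- rand_tree(n, labels = sprintf("t%03d", seq_len(n)))
    back <- parse_newick(write_newick(tr))
    rec <- rf_distance(back, tr)
    expect_equal(rec$raw_rf, 0L)
    # idempotence: a second round trip changes nothing
    expect_identical(write_newick(parse_newick(write_newick(back))),
                     write_newick(back))
  }
})

test_that("prune_to_common_tips restricts both trees to the intersection", {
  t1 <- parse_newick("((A,B),((C,D),E));")
  t2 <- parse_newick("((A,C),((B,D),F));")
  pr <- prune_to_common_tips(t1, t2)
  expect_setequal(pr$t1$tip.label, c("A", "B", "C", "D"))
  expect_setequal(pr$t2$tip.label, c("A", "B", "C", "D"))

  # identical tip sets: split sets preserved
  t3 <- parse_newick("(((A,B),C),(D,E));")
  pr2 <- prune_to_common_tips(t3, t3)
  expect_equal(rf_distance(pr2$t1, t3)$raw_rf, 0L)

  t4 <- parse_newick("((A,B),(C,G));")
  t5 <- parse_newick("((A,B),(C,H));")
  expect_error(prune_to_common_tips(t4, t5), "at least 4")
})

test_that("reroot_balanced finds the most balanced edge deterministically", {
  cat6 <- parse_newick("(((((A,B),C),D),E),F);")
  r <- reroot_balanced(cat6)
  root_children <- r$edge[r$edge[, 1] == length(r$tip.label) + 1L, 2L]
  expect_length(root_children, 2L)
  sides <- lapply(root_children, function(ch) {
    if (ch <= length(r$tip.label)) r$tip.label[ch]
    else r$tip.label[phangorn::Descendants(r, ch, "tips")[[1]]]
  })
  expect_equal(sort(lengths(sides)), c(3L, 3L))
  expect_true(setequal(sides[[1]], c("A", "B", "C")) ||
              setequal(sides[[2]], c("A", "B", "C")))

  bal4 <- parse_newick("((A,B),(C,D));")
  r4 <- reroot_balanced(bal4)
  rc <- r4$edge[r4$edge[, 1] == 5L, 2L]
  expect_length(rc, 2L)
  expect_equal(rf_distance(r4, bal4)$raw_rf, 0L)
})

test_that("reroot_balanced never changes the unrooted bipartition set", {
  set.seed(7)
  for (i in 1:50) {
    tr <- rand_tree(sample(4:40, 1))
    expect_equal(rf_distance(reroot_balanced(tr), tr)$raw_rf, 0L)
  }
})

test_that("polytomy_tip_fraction measures tips under multifurcations", {
  expect_equal(polytomy_tip_fraction(parse_newick("((A,B),(C,D));")), 0)
  # unrooted-stored binary tree: basal trichotomy is not a polytomy
  expect_equal(polytomy_tip_fraction(parse_newick("((A,B),(C,D),(E,F));")), 0)
  expect_equal(polytomy_tip_fraction(parse_newick("(A,B,C,D,E);")), 1)
  expect_equal(
    polytomy_tip_fraction(parse_newick("((A,B,C),(D,(E,F)));")), 0.5)
})

test_that("polytomy fraction is zero iff the tree is binary (unrooted)", {
  set.seed(11)
  for (i in 1:40) {
    tr <- rand_tree(sample(5:30, 1))
    if (i %% 2 == 0) tr <- ape::di2multi(tr, tol = 0.4)  # collapse some edges
    frac <- polytomy_tip_fraction(tr)
    expect_equal(frac == 0, ape::is.binary(ape::unroot(tr)))
  }
})
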