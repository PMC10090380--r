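test_that("bipartitions enumerates non-trivial unrooted splits", {
  expect_equal(bipartitions(parse_newick("((A,B),(C,D));")),
               list(c("C", "D")))
  expect_length(bipartitions(parse_newick("(A,B,C,D,E,F);")), 0)
  set.seed(3)
  for (i in 1:10) {
    tr <- rand_tree(8)
    expect_length(bipartitions(tr), 5)  # n - 3 internal edges
  }
  expect_error(bipartitions(parse_newick("(A,(B,C));")), "at least 4")
})

test_that("rf_distance matches hand-computed cases", {
  tA <- parse_newick("((A,B),(C,D));")
  expect_equal(rf_distance(tA, tA)[, c("raw_rf", "norm_rf")],
               data.frame(raw_rf = 0L, norm_rf = 0))

  rec <- rf_distance(tA, parse_newick("((A,C),(B,D));"))
  expect_equal(rec$raw_rf, 2L)
  expect_equal(rec$max_rf, 2L)
  expect_equal(rec$norm_rf, 1)

  # 6-tip trees sharing exactly one of their three splits each
  t1 <- parse_newick("((A,B),((C,D),(E,F)));")   # AB, CD, EF
  t2 <- parse_newick("((A,B),((C,E),(D,F)));")   # AB, CE, DF
  rec2 <- rf_distance(t1, t2)
  expect_equal(rec2$raw_rf, 4L)
  expect_equal(rec2$max_rf, 6L)
  expect_equal(rec2$norm_rf, 4 / 6)
})

test_that("rf_distance flags the degenerate star-vs-star case", {
  s1 <- parse_newick("(A,B,C,D);")
  s2 <- parse_newick("(A,B,D,C);")
  expect_warning(rec <- rf_distance(s1, s2), "star")
  expect_equal(rec$norm_rf, 0)
  expect_true(rec$degenerate)
})

test_that("rf_distance agrees with the brute-force split oracle", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(4:8, 1)
    t1 <- rand_tree(n)
    t2 <- rand_tree(n)
    expect_equal(rf_distance(t1, t2)$raw_rf, oracle_rf(t1, t2))
  }
})

test_that("rf_distance agrees with phangorn on binary trees", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    t1 <- rand_tree(n)
    t2 <- rand_tree(n)
    expect_equal(rf_distance(t1, t2)$raw_rf,
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
})

test_that("rf_distance is symmetric and norm_rf stays in [0, 1]", {
  set.seed(13)
  for (i in 1:30) {
    n <- sample(4:20, 1)
    t1 <- rand_tree(n)
    t2 <- rand_tree(n)
    if (i %% 3 == 0) t2 <- ape::di2multi(t2, tol = 0.3)
    a <- suppressWarnings(rf_distance(t1, t2))
    b <- suppressWarnings(rf_distance(t2, t1))
    expect_equal(a$raw_rf, b$raw_rf)
    expect_gte(a$norm_rf, 0)
    expect_lte(a$norm_rf, 1)
  }
})

test_that("rf_distance_batch equals per-pair rf_distance", {
  set.seed(77)
  ref <- rand_tree(12, labels = sprintf("x%02d", 1:12))
  trees <- replicate(15, rand_tree(12, labels = sprintf("x%02d", 1:12)),
                     simplify = FALSE)
  trees[[16]] <- ape::keep.tip(trees[[1]], sprintf("x%02d", 1:8))
  names(trees) <- sprintf("g%02d", seq_along(trees))
  batch <- rf_distance_batch(trees, ref)
  for (i in seq_along(trees)) {
    one <- rf_distance(trees[[i]], ref, gene_id = names(trees)[i])
    expect_equal(batch[i, ], one, ignore_attr = "row.names")
  }
})

test_that("the exclusion rule removes heavily multifurcating gene trees", {
  recs <- rbind(
    rf_distance(parse_newick("((A,B),(C,D));"),
                parse_newick("((A,B),(C,D));"), gene_id = "binary"),
    suppressWarnings(rf_distance(parse_newick("(A,B,C,D);"),
                                 parse_newick("((A,B),(C,D));"),
                                 gene_id = "star")),
    rf_distance(parse_newick("((A,B,C),(D,(E,F)));"),
                parse_newick("((A,B),((C,D),(E,F)));"),
                gene_id = "half"))
  out <- apply_exclusion(recs, threshold = 0.5)
  expect_equal(out$excluded, c(FALSE, TRUE, TRUE))  # 0.5 is excluded (>=)
  expect_equal(out$reason[2:3], c("polytomy", "polytomy"))
  expect_true(out$near_boundary[3])
  expect_false(out$near_boundary[1])

  lax <- apply_exclusion(recs, threshold = 0.9)
  expect_equal(lax$excluded, c(FALSE, TRUE, FALSE))
})

test_that("summarize_gene_set averages included records only", {
  recs <- data.frame(gene_id = c("a", "b", "c"),
                     norm_rf = c(0.2, 0.4, 0.9),
                     excluded = c(FALSE, FALSE, TRUE))
  s <- summarize_gene_set(recs, "demo")
  expect_equal(s$n_trees, 2L)
  expect_equal(s$mean_rf, 0.3)
  expect_equal(s$sd_rf, sd(c(0.2, 0.4)))
  expect_false(s$sd_undefined)

  one <- summarize_gene_set(
    data.frame(gene_id = "a", norm_rf = 0.5, excluded = FALSE), "solo")
  expect_equal(one$mean_rf, 0.5)
  expect_equal(one$sd_rf, 0)
  expect_true(one$sd_undefined)

  expect_error(summarize_gene_set(
    data.frame(gene_id = "a", norm_rf = 0.5, excluded = TRUE), "gone"),
    "gone")
})

test_that("gene-set mean is consistent with its sampling distribution", {
  set.seed(202)
  x <- rbeta(1000, 2, 3)  # known mean 0.4
  recs <- data.frame(gene_id = sprintf("g%04d", 1:1000), norm_rf = x,
                     excluded = FALSE)
  s <- summarize_gene_set(recs, "mc")
  se <- sqrt(2 / 5 * 3 / 5 / 6) / sqrt(1000)  # beta(2,3) sd / sqrt(n)
  expect_lt(abs(s$mean_rf - 0.4), 3 * se)
})

test_that("relative_rf is the signed fractional shift versus the reference", {
  expect_equal(relative_rf(0.2, 0.2), 0)
  expect_equal(relative_rf(0.25, 0.20), 0.25)
  expect_equal(relative_rf(0.15, 0.20), -0.25)
  expect_error(relative_rf(0.1, 0), "positive")
})
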