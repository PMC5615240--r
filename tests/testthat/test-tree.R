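test_that("newick parsing assigns branch lengths, defaults and conversions", {
  tr <- parse_newick("((a:1,b:2):0.5,c:3);")
  expect_equal(tr$s, 3L)
  expect_equal(sort(tr$brlen[!is.na(tr$brlen)]), c(0.5, 1, 2, 3))
  expect_equal(tr$brlen[match("c", tr$labels)], 3)

  # trifurcating root -> rooted binary with a zero-length stub, round trips
  tr3 <- parse_newick("((a,b),(c,d),e);")
  expect_equal(tr3$s, 5L)
  expect_true(same_topology(tr3, parse_newick(write_newick(tr3))))
  expect_true("a|b" %in% names(bipartitions(tr3)) ||
                "c|d|e" %in% names(bipartitions(tr3)))

  # missing lengths default to 0.1
  trd <- parse_newick("((a,b),c);")
  expect_equal(unique(trd$brlen[-(2L * trd$s - 1L)]), 0.1)

  expect_error(parse_newick("((a,b);"), "unclosed")
  expect_error(parse_newick("((a,b)),c;"), "parse error")
  expect_error(parse_newick("((a,a),b);"), "duplicate")
  expect_error(parse_newick("((a,b,c),(d,e),f);"), "polytomy")
})

test_that("write/parse round trip preserves topology, labels and lengths", {
  set.seed(17)
  for (i in 1:50) {
    tr <- rand_tree(sample(3:8, 1))
    back <- parse_newick(write_newick(tr))
    expect_true(same_topology(tr, back, rooted = TRUE))
    expect_equal(sort(back$brlen), sort(tr$brlen), tolerance = 1e-9)
  }
  expect_equal(write_newick(parse_newick("(a:1,b:1);")), "(a:1,b:1);")
})

test_that("bipartitions are canonical, deduplicated and root-invariant", {
  expect_equal(names(bipartitions(parse_newick("((a,b),(c,d));"))), "c|d")
  cat5 <- parse_newick("((((a,b),c),d),e);")
  expect_setequal(names(bipartitions(cat5)), c("c|d|e", "d|e"))
  # same unrooted topology, different rootings
  r1 <- parse_newick("((a,b),(c,(d,e)));")
  r2 <- parse_newick("((((a,b),c),d),e);")
  expect_setequal(names(bipartitions(r1)), names(bipartitions(r2)))
})

test_that("topology comparison respects rooting and child order", {
  t1 <- parse_newick("((a,b),(c,d));")
  expect_true(same_topology(t1, t1))
  expect_true(same_topology(t1, parse_newick("((c,d),(a,b));"),
                            rooted = TRUE))
  expect_false(same_topology(t1, parse_newick("((a,c),(b,d));")))
  expect_true(same_topology(t1, parse_newick("(((c,d),a),b);")))   # unrooted
  expect_false(same_topology(t1, parse_newick("(((c,d),a),b);"),
                             rooted = TRUE))
  expect_error(same_topology(t1, parse_newick("((a,b),(c,e));")),
               "taxon sets")
})

test_that("majority consensus keeps exactly the splits above threshold", {
  t1 <- parse_newick("((a,b),(c,d));")
  cons <- majority_consensus(list(t1, t1, t1))
  expect_equal(unname(cons$support), 1)
  expect_true(grepl("1", cons$newick))

  t2 <- parse_newick("((a,c),(b,d));")
  cons2 <- majority_consensus(list(t1, t1, t2), threshold = 0.5)
  expect_equal(unname(cons2$support[["c|d"]]), 2 / 3)
  expect_false("b|d" %in% names(cons2$support))

  # strict ">" at threshold 1 with any disagreement gives a star
  cons3 <- majority_consensus(list(t1, t2), threshold = 1)
  expect_length(cons3$support, 0)

  # retained splits agree with ape's majority-rule consensus
  set.seed(3)
  trees <- replicate(20, rand_tree(6), simplify = FALSE)
  cons4 <- majority_consensus(trees)
  phys <- lapply(trees, function(t) ape::unroot(phylohet:::as_ape_phylo(t)))
  ape_cons <- ape::consensus(phys, p = 0.5, rooted = FALSE)
  ape_splits <- ape::prop.part(ape_cons)
  labs <- attr(ape_splits, "labels")
  ape_keys <- setdiff(vapply(ape_splits, function(idx)
    phylohet:::split_key(labs[idx], labs), character(1)), "")
  expect_setequal(names(cons4$support), ape_keys)
})

test_that("topology enumeration matches the double factorials without duplicates", {
  expect_length(enumerate_topologies(letters[1:3]), 3L)
  expect_length(enumerate_topologies(letters[1:4], rooted = FALSE), 3L)
  expect_length(enumerate_topologies(letters[1:4]), 15L)
  expect_length(enumerate_topologies(letters[1:5]), 105L)
  expect_error(enumerate_topologies(letters[1:8]), "3..7")

  r4 <- enumerate_topologies(letters[1:4])
  keys <- vapply(r4, phylohet:::canonical_topology, character(1))
  expect_equal(anyDuplicated(keys), 0L)

  # every unrooted 5-taxon topology admits exactly 7 rooted placements
  r5 <- enumerate_topologies(letters[1:5])
  ukeys <- vapply(r5, phylohet:::unrooted_key, character(1))
  expect_equal(sort(unname(table(ukeys))), rep(7L, 15L), ignore_attr = TRUE)
})

test_that("NNI produces the two alternative resolutions and connects tree space", {
  tr <- parse_newick("((a,b),(c,d));")
  nb <- nni_neighbors(tr, c("a", "b"))
  got <- vapply(nb, phylohet:::canonical_topology, character(1))
  expect_setequal(
    vapply(list(parse_newick("((a,c),(b,d));"),
                parse_newick("((a,d),(b,c));")),
           phylohet:::canonical_topology, character(1)), got)
  expect_error(nni_neighbors(tr, "a"), "trivial")
  expect_error(nni_neighbors(parse_newick("((a,b),(c,d));"),
                             c("a", "c")), "no internal branch")

  # 2(s-3) distinct unrooted neighbours at s=5, taxa preserved
  t5 <- parse_newick("((((a,b),c),d),e);")
  nbs <- unlist(lapply(names(bipartitions(t5)), function(k)
    nni_neighbors(t5, k)), recursive = FALSE)
  expect_length(nbs, 4L)
  expect_equal(anyDuplicated(vapply(nbs, phylohet:::unrooted_key,
                                    character(1))), 0L)
  for (nb1 in nbs) expect_setequal(nb1$labels, t5$labels)

  # rooted-NNI graph reaches all 15 rooted 4-taxon topologies
  seen <- character(0)
  frontier <- list(parse_newick("((a,b),(c,d));"))
  while (length(frontier)) {
    tr0 <- frontier[[1L]]; frontier <- frontier[-1L]
    key <- phylohet:::canonical_topology(tr0)
    if (key %in% seen) next
    seen <- c(seen, key)
    ch <- phylohet:::nni_choices(tr0)
    for (r in seq_len(nrow(ch)))
      frontier <- c(frontier,
                    list(phylohet:::rooted_nni(tr0, ch[r, 1L], ch[r, 2L])))
  }
  expect_length(seen, 15L)
})
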