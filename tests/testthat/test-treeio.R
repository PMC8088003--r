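test_that("newick parsing produces the expected unrooted structure", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  expect_s3_class(tr, "nr_tree")
  expect_equal(tr$ntips, 4L)
  expect_equal(n_edges(tr), 5L)
  expect_equal(tr$nnode, 6L)

  # rooted input: the two basal branches merge into one edge of summed length
  tr2 <- parse_newick("((A:1,B:1):0.5,(C:1,D:1):0.5);")
  expect_equal(n_edges(tr2), 5L)
  expect_equal(sort(tr2$length), c(1, 1, 1, 1, 1))

  expect_error(parse_newick("(A:1,B:1);"), "at least 3")
  expect_error(parse_newick("((A:1,B:1):1,C:1,D:1,E:1);"), "binary")
  expect_error(parse_newick("((A:1,B),C:1,D:1);"), "branch lengths")
  expect_error(parse_newick("not a tree"), "invalid newick")
})

test_that("parse/write round trip preserves topology and lengths", {
  txt <- "((A:0.12,B:0.5):0.33,(C:1.5,D:0.01):0.2,E:0.77);"
  tr <- parse_newick(txt)
  tr2 <- parse_newick(write_newick(tr))
  expect_equal(tr2$labels, tr$labels)
  expect_equal(sort(tr2$length), sort(tr$length), tolerance = 1e-9)
  # tip-to-tip distances are a topology+length invariant
  d1 <- ape::cophenetic.phylo(ape::read.tree(text = txt))
  d2 <- ape::cophenetic.phylo(ape::read.tree(text = write_newick(tr)))
  expect_equal(d2[rownames(d1), colnames(d1)], d1, tolerance = 1e-9)
})

test_that("place_root splits a branch without changing path lengths", {
  tr <- parse_newick("((A:1,B:1):1,C:1,D:1);")
  r <- place_root(tr, 3, 0.5)
  expect_equal(root_branch_lengths(r), c(0.5, 0.5))
  r0 <- place_root(tr, 3, 0)
  expect_equal(root_branch_lengths(r0), c(0, 1))
  for (beta in c(0, 0.17, 0.5, 0.99, 1)) {
    r <- place_root(tr, 2, beta)
    expect_equal(sum(root_branch_lengths(r)), tr$length[2])
  }
  expect_error(place_root(tr, 99, 0.5), "unknown edge")
  expect_error(place_root(tr, 1, 1.5), "beta")
})

test_that("annotated newick honors suppression and re-parses", {
  tr <- ultrametric4()
  rooted <- place_root(tr, 1, 0.5)
  # no annotations: plain newick
  plain <- write_newick_annotated(rooted)
  expect_false(grepl("\\[", plain))
  # one annotated branch
  ann <- list("2" = c(LWR = 1.0, alpha = 0.25, LL = -12.5))
  nwk <- write_newick_annotated(rooted, ann)
  expect_equal(lengths(regmatches(nwk, gregexpr("LWR=", nwk))), 1L)
  reparsed <- parse_newick(nwk)
  expect_equal(sort(reparsed$labels), sort(tr$labels))
  expect_equal(sort(reparsed$length), sort(tr$length), tolerance = 1e-6)
})

test_that("approximate MAD ranking identifies the clock root", {
  tr <- ultrametric4()
  rk <- mad_rank_edges(tr)
  expect_setequal(rk, seq_len(n_edges(tr)))
  # the central edge (connecting the two cherries) must rank first
  internal_edge <- which(apply(tr$edge, 1, function(e) all(e > tr$ntips)))
  expect_equal(rk[1], internal_edge)

  # caterpillar clock tree: root on the edge above the deepest split
  tr2 <- parse_newick("(((A:1,B:1):1,C:2):1,D:3,E:3);")
  rk2 <- mad_rank_edges(tr2)
  expect_setequal(rk2, seq_len(n_edges(tr2)))
})

test_that("normalized root distance counts path nodes", {
  tr <- ultrametric4()  # 6 nodes
  internal_edge <- which(apply(tr$edge, 1, function(e) all(e > tr$ntips)))
  tip_edges <- setdiff(seq_len(n_edges(tr)), internal_edge)
  expect_equal(root_distance(tr, 1, 1), 0)
  # tip edge adjacent to the central edge: one shared node on the path
  expect_equal(root_distance(tr, internal_edge, tip_edges[1]), 1 / 6)
  # symmetry
  for (e1 in seq_len(5)) for (e2 in seq_len(5))
    expect_equal(root_distance(tr, e1, e2), root_distance(tr, e2, e1))
  expect_error(root_distance(tr, 1, 42), "unknown edge")
})

test_that("tip-to-tip path lengths are preserved by rooting at any beta", {
  fx <- sim_fixture(6, 10, 3)
  tr <- fx$tree
  base <- ape::cophenetic.phylo(ape::read.tree(text = write_newick(tr)))
  for (e in c(1, 4, n_edges(tr))) {
    nwk <- write_newick_annotated(place_root(tr, e, 0.3))
    d <- ape::cophenetic.phylo(ape::read.tree(text = nwk))
    expect_equal(d[rownames(base), colnames(base)], base, tolerance = 1e-6)
  }
})
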