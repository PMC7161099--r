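test_that("gene tree parsing reads, validates and orders loci", {
  gts <- parse_gene_trees("((A,(B,C)),D);\n(A,((B,C),D));")
  expect_length(gts, 2)
  expect_setequal(gts[[1]]$tip.label, c("A", "B", "C", "D"))
  expect_setequal(gts[[2]]$tip.label, c("A", "B", "C", "D"))
  g <- parse_gene_trees("((A,B),C);")[[1]]
  expect_equal(length(g$tip.label), 3)
  expect_equal(g$Nnode, 2)

  expect_error(parse_gene_trees("((A,B,C),D);"), "binary")
  expect_error(parse_gene_trees("((A,B),C);\n((A,B),A);"), "line 2")
  expect_error(parse_gene_trees("((A,B),C"), "line 1")
})

test_that("branch lengths in gene tree input are ignored", {
  a <- parse_gene_trees("((A:0.1,B:0.2):0.3,C:0.4);")[[1]]
  b <- parse_gene_trees("((A,B),C);")[[1]]
  expect_null(a$edge.length)
  expect_equal(canonical_topology(a), canonical_topology(b))
})

test_that("network parser reads reticulations, gamma and trees", {
  net <- parse_network("((A,(B)#H1:::0.3),(C,#H1));")
  expect_s3_class(net, "phylo_network")
  expect_length(reticulations(net), 1)
  expect_equal(sum(!is.na(net$labels)), 3)
  r <- reticulations(net)
  rows <- which(net$edges$child == r)
  expect_equal(sum(net$edges$is_b1[rows]), 1)
  expect_equal(net$edges$gamma[rows][net$edges$is_b1[rows]], 0.3)

  tr <- parse_network("((A,B),C);")
  expect_length(reticulations(tr), 0)
})

test_that("network validator rejects structural violations", {
  # reticulation with out-degree 2
  expect_error(parse_network("((A,(B,C)#H1),(#H1,D));"), "out-degree")
  # gamma outside [0,1]
  expect_error(parse_network("((A,(B)#H1:::1.5),(C,#H1));"), "\\[0,1\\]")
  # both parent edges of a reticulation annotated but not summing to 1
  expect_error(parse_network("((A,(B)#H1:::0.3),(C,#H1:::0.4));"),
               "sum to 1")
  # direct degree checks on hand-built edge tables
  edges <- data.frame(parent = c(4, 4, 5, 5), child = c(1, 5, 2, 3))
  expect_silent(phylo_network(edges, c("A", "B", "C", NA, NA), 4))
  # unlabeled degree-1/1 node is not a valid tree node
  bad <- data.frame(parent = c(4, 4, 5, 5, 6, 1), child = c(1, 5, 2, 6, 3, 6))
  expect_error(phylo_network(bad, c(NA, "B", "C", NA, NA, NA), 4))
})

test_that("parallel reticulation parent edges sharing head and tail parse", {
  net <- parse_network("(((A)#H1,#H1),B);")
  r <- reticulations(net)
  expect_length(r, 1)
  rows <- which(net$edges$child == r)
  expect_equal(net$edges$parent[rows][1], net$edges$parent[rows][2])
  rt <- parse_network(write_network(net))
  expect_true(networks_isomorphic(net, rt))
})

test_that("canonical serialization is order-invariant and round-trips", {
  a <- parse_network("((C,B),A);")
  b <- parse_network("(A,(B,C));")
  expect_identical(canonical_network(a), canonical_network(b))
  expect_identical(canonical_network(a), "(A,(B,C));")

  n1 <- parse_network("((A,(B)#H1:::0.3),(C,#H1));")
  n2 <- parse_network("((#H1,C),((B)#H1:::0.3,A));")
  expect_identical(write_network(n1), write_network(n2))
})

test_that("parse/write round-trips across enumerated small networks", {
  nets4 <- enumerate_topologies(LETTERS[1:4], max_ret = 1L)
  expect_gt(length(nets4), 15)
  for (net in nets4) {
    rt <- parse_network(write_network(net))
    expect_identical(canonical_network(rt), canonical_network(net))
  }
  # seeded subset of the 5-taxon, 1-reticulation space
  nets5 <- enumerate_topologies(LETTERS[1:5], max_ret = 1L)
  set.seed(101)
  for (net in sample(nets5, 150)) {
    rt <- parse_network(write_network(net))
    expect_identical(canonical_network(rt), canonical_network(net))
  }
})

test_that("gamma and lengths survive a full-parameter round trip", {
  net <- net3_retic(gamma = 0.25)
  rt <- parse_network(write_network(net))
  expect_true(networks_isomorphic(net, rt, params = TRUE))
})
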