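test_that("history counts match small hand-derived cases", {
  tr <- parse_network("((A,B),C);")
  g_match <- parse_gene_trees("((A,B),C);")[[1]]
  g_mis <- parse_gene_trees("((A,C),B);")[[1]]
  expect_length(enumerate_histories(g_match, tr), 2)
  expect_length(enumerate_histories(g_mis, tr), 1)
  # two taxa: the single coalescence can only happen above the root
  two <- parse_network("(A,B);")
  g2 <- parse_gene_trees("(A,B);")[[1]]
  expect_length(enumerate_histories(g2, two), 1)
  expect_error(enumerate_histories(g_match, two), "labels differ")
})

test_that("enumeration equals the brute-force map-filter oracle on trees", {
  for (s in topos3) for (gnk in topos3) {
    g <- parse_gene_trees(gnk)[[1]]
    expect_equal(length(enumerate_histories(g, parse_network(s))),
                 brute_force_history_count(gnk, s),
                 info = paste(gnk, "in", s))
  }
  topos4 <- all_topo_strings(LETTERS[1:4])
  set.seed(7)
  pairs <- expand.grid(g = topos4, s = topos4, stringsAsFactors = FALSE)
  pairs <- pairs[sample.int(nrow(pairs), 60), ]
  for (i in seq_len(nrow(pairs))) {
    g <- parse_gene_trees(pairs$g[i])[[1]]
    expect_equal(length(enumerate_histories(g, parse_network(pairs$s[i]))),
                 brute_force_history_count(pairs$g[i], pairs$s[i]),
                 info = paste(pairs$g[i], "in", pairs$s[i]))
  }
})

test_that("caterpillar history counts grow like the known tree sequence", {
  # matching caterpillar gene tree in its own species tree: 2, 5, 14
  # histories for 3, 4, 5 taxa (verified against the brute-force oracle,
  # not assumed from a formula)
  cat_nwk <- function(n) {
    s <- paste0("(", LETTERS[1], ",", LETTERS[2], ")")
    for (k in 3:n) s <- paste0("(", s, ",", LETTERS[k], ")")
    paste0(s, ";")
  }
  for (n in 3:5) {
    nwk <- cat_nwk(n)
    g <- parse_gene_trees(nwk)[[1]]
    cnt <- length(enumerate_histories(g, parse_network(nwk)))
    expect_equal(cnt, brute_force_history_count(nwk, nwk))
    expect_equal(cnt, c(2, 5, 14)[n - 2])
  }
})

test_that("network histories distinguish reticulation routings", {
  net <- net3_retic()
  g <- parse_gene_trees("((A,B),C);")[[1]]
  hs <- enumerate_histories(g, net)
  # B's lineage can take either parent edge: u1 + u2 = 1 for every history
  r <- reticulations(net)
  rows <- which(net$edges$child == r)
  b1 <- rows[net$edges$is_b1[rows]]
  b2 <- rows[!net$edges$is_b1[rows]]
  u1 <- vapply(hs, function(h) h$u[b1], integer(1))
  u2 <- vapply(hs, function(h) h$u[b2], integer(1))
  expect_true(all(u1 + u2 == 1L))
  expect_true(any(u1 == 1L) && any(u2 == 1L))
  # routing-only variants are distinct histories
  key <- vapply(hs, function(h) paste(h$map, collapse = ","), character(1))
  expect_true(any(duplicated(key)))
})

test_that("per-edge counts satisfy the flow invariants", {
  nets <- list(parse_network("(((A,B),C),D);"), net3_retic(),
               net4_indist_a())
  gts <- list("((A,(B,C)),D);", "((A,C),B);", "(((A,B),C),D);")
  for (k in seq_along(nets)) {
    labs <- sort(nets[[k]]$labels[!is.na(nets[[k]]$labels)])
    g <- parse_gene_trees(gts[[k]])[[1]]
    if (!setequal(g$tip.label, labs)) next
    for (h in enumerate_histories(g, nets[[k]])) {
      cnt <- tabulate(h$map, nbins = length(h$u))
      expect_equal(h$v, h$u - cnt)
      expect_true(all(h$v[h$u >= 1L] >= 1L))
      expect_true(all(h$w >= 1 & h$w <= h$d))
      # the root edge absorbs everything down to one lineage
      rho <- length(h$u)
      expect_equal(h$v[rho], 1L)
    }
  }
})

test_that("within-edge event-order terms match brute-force enumeration", {
  tr <- parse_network("((A,B),C);")
  g <- parse_gene_trees("((A,B),C);")[[1]]
  hs <- enumerate_histories(g, tr)
  rho <- nrow(tr$edges) + 1L
  # history with both coalescences at the root: 3 first-event orders, 1 ok
  all_root <- Filter(function(h) all(h$map == rho), hs)
  expect_length(all_root, 1)
  expect_equal(unname(wd_edge_terms(all_root[[1]], rho)), c(1, 3))
  # history with AB on the internal edge: forced orders everywhere
  split_h <- Filter(function(h) !all(h$map == rho), hs)[[1]]
  expect_equal(unname(wd_edge_terms(split_h, rho)), c(1, 1))
  # u=3, v=2 with an assigned pair: 1 agreeing of choose(3,2) sequences
  g4 <- parse_gene_trees("((A,B),(C,D));")[[1]]
  tr4 <- parse_network("((A,B),(C,D));")
  hs4 <- enumerate_histories(g4, tr4)
  rho4 <- nrow(tr4$edges) + 1L
  for (h in hs4) {
    if (h$u[rho4] == 3L && h$v[rho4] == 2L)
      expect_equal(unname(wd_edge_terms(h, rho4)), c(1, 3))
    if (h$u[rho4] == 4L && h$v[rho4] == 1L) {
      # 2 cherries coalescing fully at the root: d = 6*3*1, w = orderings
      # of {AB, CD, ABCD} with ABCD last = 2
      expect_equal(unname(wd_edge_terms(h, rho4)), c(2, 18))
    }
  }
})

test_that("enumeration guards refuse oversize inputs", {
  s <- "(t1,t2)"
  for (k in 3:12) s <- paste0("(", s, ",t", k, ")")
  nwk <- paste0(s, ";")
  g <- parse_gene_trees(nwk)[[1]]
  net <- parse_network(nwk)
  expect_error(enumerate_histories(g, net, max_leaves = 10), "capped")
})
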