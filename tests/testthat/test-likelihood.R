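test_that("lineage-count transition probability matches the pure-death oracle", {
  for (u in 2:8) for (v in 1:u) for (t in c(0.1, 1, 5)) {
    expect_equal(p_uv(u, v, t), p_uv_expm(u, v, t), tolerance = 1e-10,
                 info = sprintf("u=%d v=%d t=%g", u, v, t))
  }
})

test_that("p_uv closed forms, row sums and domain errors", {
  expect_equal(p_uv(1, 1, 3.7), 1)
  expect_equal(p_uv(2, 2, 1), exp(-1))
  expect_equal(p_uv(2, 1, 1), 1 - exp(-1))
  expect_equal(p_uv(5, 5, 0), 1)
  for (u in 2:8) for (t in c(0, 0.3, 2)) {
    expect_equal(sum(vapply(1:u, function(v) p_uv(u, v, t), numeric(1))), 1,
                 tolerance = 1e-12)
  }
  expect_error(p_uv(2, 3, 1), "v <= u")
  expect_error(p_uv(2, 0, 1), "v <= u")
  expect_error(p_uv(2, 1, -1), "nonnegative")
})

test_that("integrated transition probability agrees with quadrature", {
  quad <- function(u, v, cfg) {
    r <- cfg$exp_rate; tau <- cfg$tau
    norm <- if (is.infinite(tau)) 1 else 1 - exp(-r * tau)
    stats::integrate(function(t) p_uv(u, v, t) * r * exp(-r * t) / norm,
                     0, min(tau, 300),
                     rel.tol = 1e-11, abs.tol = 1e-12)$value
  }
  for (cfg in list(likelihood_config(tau = Inf),
                   likelihood_config(tau = 1),
                   likelihood_config(tau = 2, exp_rate = 0.5))) {
    for (u in 1:6) for (v in 1:u) {
      expect_equal(p_uv_integrated(u, v, cfg), quad(u, v, cfg),
                   tolerance = 1e-8,
                   info = sprintf("u=%d v=%d tau=%g", u, v, cfg$tau))
    }
  }
  # closed-form anchors
  expect_equal(p_uv_integrated(1, 1, likelihood_config(tau = 0.7)), 1)
  expect_equal(p_uv_integrated(2, 2), 0.5)
  expect_equal(p_uv_integrated(2, 2, likelihood_config(tau = 1)),
               (1 - exp(-2)) / (2 * (1 - exp(-1))))
})

test_that("truncated prior converges to the untruncated limit", {
  inf_cfg <- likelihood_config(tau = Inf)
  t50 <- likelihood_config(tau = 50)
  for (u in 1:6) for (v in 1:u) {
    expect_equal(p_uv_integrated(u, v, t50), p_uv_integrated(u, v, inf_cfg),
                 tolerance = 1e-12)
  }
})

test_that("history and gene-tree probabilities reproduce the 3-taxon MSC", {
  tr <- tree3_param(t = 1)
  g <- parse_gene_trees("((A,B),C);")[[1]]
  hs <- enumerate_histories(g, tr)
  probs <- sort(vapply(hs, history_prob, numeric(1), net = tr))
  expect_equal(probs, sort(c(1 - exp(-1), exp(-1) / 3)))
  expect_equal(gene_tree_prob(g, tr), 1 - 2 / 3 * exp(-1))
  for (mis in c("((A,C),B);", "((B,C),A);")) {
    expect_equal(gene_tree_prob(parse_gene_trees(mis)[[1]], tr), exp(-1) / 3)
  }
  tot <- sum(vapply(topos3, function(s)
    gene_tree_prob(parse_gene_trees(s)[[1]], tr), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-12)
})

test_that("integrated 3-taxon probabilities match hand integration", {
  tr <- parse_network("((A,B),C);")
  g <- parse_gene_trees("((A,B),C);")[[1]]
  hs <- enumerate_histories(g, tr)
  ip <- sort(vapply(hs, history_prob_integrated, numeric(1), net = tr))
  expect_equal(ip, sort(c(1 / 2, 1 / 6)))  # p21^inf and p22^inf / 3
  expect_equal(gene_tree_prob_integrated(g, tr), 2 / 3)
  expect_equal(
    gene_tree_prob_integrated(parse_gene_trees("((A,C),B);")[[1]], tr),
    1 / 6)
  expect_equal(
    gene_tree_prob_integrated(parse_gene_trees("((B,C),A);")[[1]], tr),
    1 / 6)
})

test_that("reticulation prior factors integrate the Beta(2,2) correctly", {
  # closed factorial forms for small lineage splits
  bterm <- function(u1, u2) beta(2 + u1, 2 + u2) / beta(2, 2)
  expect_equal(bterm(0, 0), 1)
  expect_equal(bterm(1, 0), 1 / 2)
  expect_equal(bterm(0, 1), 1 / 2)
  expect_equal(bterm(1, 1), 6 * factorial(2) * factorial(2) / factorial(5))
  # quadrature of 6 * integral gamma^(u1+1) (1-gamma)^(u2+1)
  for (u1 in 0:2) for (u2 in 0:2) {
    q <- stats::integrate(function(x) 6 * x^(u1 + 1) * (1 - x)^(u2 + 1),
                          0, 1, rel.tol = 1e-10)$value
    expect_equal(bterm(u1, u2), q, tolerance = 1e-8)
  }
})

test_that("gene-tree pmf sums to one over all topologies", {
  # fixed-parameter and integrated, trees and a 1-reticulation network
  topos4 <- all_topo_strings(LETTERS[1:4])
  st <- parse_network("(((A:1,B:1):1,C:2):0.5,D:3);")
  tot <- sum(vapply(topos4, function(s)
    gene_tree_prob(parse_gene_trees(s)[[1]], st), numeric(1)))
  expect_equal(tot, 1, tolerance = 1e-8)
  for (tau in c(0.5, 1, 2, Inf)) {
    cfg <- likelihood_config(tau = tau)
    tot_i <- sum(vapply(topos4, function(s)
      gene_tree_prob_integrated(parse_gene_trees(s)[[1]],
                                parse_network("(((A,B),C),D);"), cfg),
      numeric(1)))
    expect_equal(tot_i, 1, tolerance = 1e-8, info = paste("tau =", tau))
  }
  net <- net3_retic(gamma = 0.3)
  tot_net <- sum(vapply(topos3, function(s)
    gene_tree_prob(parse_gene_trees(s)[[1]], net), numeric(1)))
  expect_equal(tot_net, 1, tolerance = 1e-8)
  for (tau in c(0.5, 1, 2, Inf)) {
    cfg <- likelihood_config(tau = tau)
    tot_neti <- sum(vapply(topos3, function(s)
      gene_tree_prob_integrated(parse_gene_trees(s)[[1]], net, cfg),
      numeric(1)))
    expect_equal(tot_neti, 1, tolerance = 1e-8, info = paste("tau =", tau))
  }
})

test_that("integrated probability equals quadrature of the pmf x priors", {
  # 3-taxon species tree: one effective branch, 1D quadrature
  g <- parse_gene_trees("((A,B),C);")[[1]]
  tr <- parse_network("((A,B),C);")
  f <- function(t) vapply(t, function(tt)
    gene_tree_prob(g, tree3_param(t = tt)) * exp(-tt), numeric(1))
  q <- stats::integrate(f, 0, 40, rel.tol = 1e-9)$value
  expect_equal(gene_tree_prob_integrated(g, tr), q, tolerance = 1e-6)

  # 1-reticulation network: the only edges that can hold two lineages are
  # the two root edges; nested quadrature over them and gamma
  net <- net3_retic()
  hs <- enumerate_histories(g, net)
  e <- net$edges
  root_edges <- which(e$parent == net$root)
  set_params <- function(t1, t2, gam) {
    e2 <- e
    e2$length[] <- 1
    e2$length[root_edges] <- c(t1, t2)
    e2$gamma[e2$is_b1] <- gam
    net2 <- net
    net2$edges <- e2
    net2
  }
  integrand <- function(t1, t2, gam) {
    n2 <- set_params(t1, t2, gam)
    p <- sum(vapply(hs, history_prob, numeric(1), net = n2))
    p * exp(-t1) * exp(-t2) * 6 * gam * (1 - gam)
  }
  outer_q <- stats::integrate(function(t1v) vapply(t1v, function(t1) {
    stats::integrate(function(t2v) vapply(t2v, function(t2) {
      stats::integrate(function(gv) vapply(gv, function(gam)
        integrand(t1, t2, gam), numeric(1)), 0, 1, rel.tol = 1e-9)$value
    }, numeric(1)), 0, 40, rel.tol = 1e-8)$value
  }, numeric(1)), 0, 40, rel.tol = 1e-7)$value
  expect_equal(gene_tree_prob_integrated(g, net), outer_q, tolerance = 1e-6)
})

test_that("multi-locus log-likelihood sums, caches and validates", {
  tr <- parse_network("((A,B),C);")
  G1 <- parse_gene_trees("((A,B),C);")
  expect_equal(multilocus_loglik(c(G1, G1), tr),
               2 * multilocus_loglik(G1, tr))
  expect_equal(multilocus_loglik(unlist(topos3), tr), log(1 / 54))
  expect_equal(multilocus_loglik(list(), tr), 0)
  expect_error(multilocus_loglik("((A,B),X);", tr), "locus 1")
  pl <- per_locus_loglik(c("((A,B),C);", "((B,A),C);", "((A,C),B);"), tr)
  expect_equal(pl$log_prob, c(log(2 / 3), log(2 / 3), log(1 / 6)))
})

test_that("species trees give identical results through both code paths", {
  phy <- parse_gene_trees("(((A,B),C),D);")[[1]]
  net_a <- as_phylo_network(phy)
  net_b <- parse_network("(((A,B),C),D);")
  g <- parse_gene_trees("((A,(B,C)),D);")[[1]]
  expect_identical(canonical_network(net_a), canonical_network(net_b))
  expect_equal(gene_tree_prob_integrated(g, net_a),
               gene_tree_prob_integrated(g, net_b))
  # a network object with a reticulation added and removed again behaves
  # like the plain tree
  with_ret <- add_reticulation(net_b, 0L, 1L)
  net_c <- delete_reticulation_edge(with_ret, nrow(with_ret$edges))
  expect_equal(gene_tree_prob_integrated(g, net_c),
               gene_tree_prob_integrated(g, net_b))
})
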