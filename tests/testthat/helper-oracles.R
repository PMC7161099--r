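# Shared fixtures and independent oracles used across the suite.
# Oracles deliberately use different algorithms from the package code.

topos3 <- c("((A,B),C);", "((A,C),B);", "(A,(B,C));")

all_topo_strings <- function(taxa) {
  vapply(enumerate_topologies(taxa, 0L), canonical_network, character(1))
}

# --- pure-death-chain transition probability by matrix exponential -------
# States v = 1..u; rate k(k-1)/2 from k to k-1.  Independent of the
# closed-form series in the package.
p_uv_expm <- function(u, v, t) {
  Q <- matrix(0, u, u)
  for (k in 2:u) {
    Q[k, k] <- -k * (k - 1) / 2
    Q[k, k - 1] <- k * (k - 1) / 2
  }
  P <- as.matrix(Matrix::expm(Q * t))
  P[u, v]
}

# --- brute-force coalescent-history counter for species trees ------------
# Enumerates every map from gene-tree internal nodes to network edges
# (plus the virtual root edge) and keeps those satisfying the two
# conditions: leaves sit on their pendant edges, and the image of a node
# is ancestral-or-equal to the images of all nodes in its subtree.
brute_force_history_count <- function(g_newick, s_newick) {
  net <- parse_network(s_newick)
  g <- parse_gene_trees(g_newick)[[1]]
  e <- net$edges
  ne <- nrow(e)
  rho <- ne + 1L
  # edge b "sits at or below" edge a if a is on every... (for trees: the
  # head of b is a descendant-or-equal of the head of a)
  desc <- function(node) {
    out <- node
    kids <- e$child[e$parent == node]
    for (k in kids) out <- c(out, desc(k))
    out
  }
  head_of <- c(e$child, net$root)  # rho's head is the root
  below <- lapply(seq_len(rho), function(a) {
    d <- desc(head_of[a])
    which(head_of[seq_len(rho)] %in% d)
  })
  # ancestral-or-equal: edge a is at/above edge b  <=>  b in below[[a]]
  n <- length(g$tip.label)
  nnode <- g$Nnode
  internal <- (n + 1):(n + nnode)
  kids_g <- split(g$edge[, 2], factor(g$edge[, 1], levels = 1:(n + nnode)))
  # image of a leaf = its pendant edge
  pend <- integer(n)
  for (row in seq_len(ne)) {
    lab <- net$labels[e$child[row]]
    if (!is.na(lab)) pend[match(lab, g$tip.label)] <- row
  }
  count <- 0L
  grid <- as.matrix(expand.grid(rep(list(seq_len(rho)), nnode)))
  img <- integer(n + nnode)
  img[1:n] <- pend
  for (r in seq_len(nrow(grid))) {
    img[internal] <- grid[r, ]
    ok <- TRUE
    for (v in internal) {
      for (c in kids_g[[v]]) {
        if (!(img[c] %in% below[[img[v]]])) { ok <- FALSE; break }
      }
      if (!ok) break
    }
    if (ok) count <- count + 1L
  }
  count
}

# --- independent recursive-deletion displayed-tree oracle ----------------
displayed_trees_recursive <- function(net) {
  rets <- reticulations(net)
  if (length(rets) == 0L) return(sort(unique(canonical_network(net))))
  rows <- which(net$edges$child == rets[1])
  out <- character(0)
  for (row in rows) {
    sub <- delete_reticulation_edge(net, row)
    out <- c(out, displayed_trees_recursive(sub))
  }
  sort(unique(out))
}

# fully parameterized 3-taxon / 4-taxon fixtures
tree3_param <- function(t = 1) {
  parse_network(sprintf("((A:1,B:1):%g,C:2);", t))
}

net3_retic <- function(gamma = 0.3) {
  parse_network(sprintf(
    "((A:1,(B:1)#H1:1::%g):1,(C:1,#H1:1):1);", gamma))
}

net4_indist_a <- function() parse_network("((A,((B,C))#H1),(#H1,D));")
net4_indist_b <- function() parse_network("((A,((B,C),(D)#H1)),#H1);")
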