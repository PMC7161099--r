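#' Displayed trees of a phylogenetic network
#'
#' For each of the 2^l ways of keeping exactly one parent edge per
#' reticulation, deletes the unselected parent edges, suppresses the
#' resulting degree-2 nodes and unreachable parts, and collects the rooted
#' tree that remains.  The deduplicated set has at most 2^l members.
#'
#' @param net A \code{phylo_network} with l reticulations.
#' @return Character vector of canonical topology strings (sorted).
#' @examples
#' displayed_trees(parse_network("((A,(B)#H1),(C,#H1));"))
#' @export
displayed_trees <- function(net) {
  rets <- reticulations(net)
  l <- length(rets)
  if (l == 0L) return(canonical_network(net))
  e <- net$edges
  out <- character(0)
  for (mask in 0:(2^l - 1)) {
    drop_rows <- integer(0)
    for (k in seq_len(l)) {
      rows <- which(e$child == rets[k])
      keep_first <- bitwAnd(mask, bitwShiftL(1L, k - 1L)) == 0L
      drop_rows <- c(drop_rows, if (keep_first) rows[2] else rows[1])
    }
    parts <- .pn_cleanup(e[-drop_rows, , drop = FALSE], net$labels, net$root)
    tr <- tryCatch(phylo_network(parts$edges, parts$labels, parts$root),
                   error = function(err) NULL)
    if (is.null(tr)) next
    if (length(reticulations(tr)) > 0L) next
    # a selection can orphan taxa (e.g. a leaf only reachable through a
    # removed edge); such selections do not display a tree on the full set
    if (length(net_leaves(tr)) != length(net_leaves(net))) next
    out <- c(out, canonical_network(tr))
  }
  sort(unique(out))
}

#' Do two networks display the same set of trees?
#'
#' Networks with equal displayed-tree sets are indistinguishable from gene
#' tree topologies sampled with one allele per species, in the sense that
#' no amount of topology-frequency data can separate them when they also
#' induce the same topology distribution; equality of displayed trees is
#' the first-order check used here.
#'
#' @param net1,net2 \code{phylo_network} objects.
#' @return Logical; \code{FALSE} with a warning when the leaf sets differ.
#' @export
same_displayed_set <- function(net1, net2) {
  l1 <- sort(net1$labels[!is.na(net1$labels)])
  l2 <- sort(net2$labels[!is.na(net2$labels)])
  if (length(l1) != length(l2) || any(l1 != l2)) {
    warning("networks have different leaf sets")
    return(FALSE)
  }
  identical(displayed_trees(net1), displayed_trees(net2))
}

#' Topological distance between two networks (hardwired-cluster surrogate)
#'
#' A simple symmetric dissimilarity: each edge of a network determines a
#' hardwired cluster, the set of leaves reachable from its head; the
#' distance is the size of the symmetric difference of the two cluster
#' multisets, normalized by their total size.  It is 0 exactly when the
#' multisets coincide and is symmetric in its arguments.  This is a
#' deliberate surrogate for heavier reduction-based network metrics; it is
#' used here only to score whether an inferred network matches the truth.
#'
#' @param net1,net2 \code{phylo_network} objects on the same leaf set.
#' @return Nonnegative real in [0, 1].
#' @export
network_distance <- function(net1, net2) {
  l1 <- sort(net1$labels[!is.na(net1$labels)])
  l2 <- sort(net2$labels[!is.na(net2$labels)])
  if (length(l1) != length(l2) || any(l1 != l2))
    stop("networks must share a leaf set")
  c1 <- .hardwired_clusters(net1)
  c2 <- .hardwired_clusters(net2)
  tab1 <- table(c1); tab2 <- table(c2)
  all_k <- union(names(tab1), names(tab2))
  n1 <- as.numeric(tab1[all_k]); n1[is.na(n1)] <- 0
  n2 <- as.numeric(tab2[all_k]); n2[is.na(n2)] <- 0
  sum(abs(n1 - n2)) / (length(c1) + length(c2))
}

# multiset of descendant-leaf sets, one per edge, as sorted strings
.hardwired_clusters <- function(net) {
  e <- net$edges
  nn <- n_nodes(net)
  below <- vector("list", nn)
  for (v in rev(.pn_topo_order(net))) {
    ch <- e$child[e$parent == v]
    below[[v]] <- if (length(ch) == 0L) net$labels[v]
                  else sort(unique(unlist(below[ch])))
  }
  vapply(seq_len(nrow(e)),
         function(row) paste(below[[e$child[row]]], collapse = ","),
         character(1))
}
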