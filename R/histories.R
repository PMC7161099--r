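#' Coalescent histories of a gene tree within a species network
#'
#' A coalescent history maps every coalescence (internal node) of a gene
#' tree to the network edge in which it occurs, and routes each gene
#' lineage through the network: wherever a lineage passes a reticulation
#' node on its way toward the root it follows one of the two parent edges.
#' Two histories that differ only in routing are distinct, because their
#' inheritance-probability exponents differ.  Coalescences not placed on
#' any network edge occur above the network root, which is treated as a
#' virtual edge of unbounded duration (edge id \code{nrow(net$edges) + 1}).
#'
#' Each returned history carries, per network edge b, the number of
#' lineages entering at its bottom (\code{u}), the number exiting at its
#' top (\code{v}), and the combinatorial pair \code{w}/\code{d}: \code{d}
#' counts all distinct sequences of \code{u - v} pairwise coalescent events
#' among \code{u} lineages, and \code{w} counts those sequences compatible
#' with the gene-tree topology (the number of linear orderings of the
#' coalescences assigned to b that respect gene-tree ancestry).
#'
#' @param g A gene tree (\code{"phylo"}) whose leaf labels equal the
#'   network's leaf labels.
#' @param net A \code{phylo_network}.
#' @param max_leaves,max_retics Guards against super-exponential
#'   enumeration; exceeding either is an error.
#' @return A list of \code{coal_history} objects, in a deterministic order.
#'   Each has components \code{map} (gene internal node id -> edge id),
#'   \code{segments} (the routed lineage paths), and the per-edge vectors
#'   \code{u}, \code{v}, \code{w}, \code{d} (indexed by edge id, with the
#'   virtual root edge last).
#' @examples
#' net <- parse_network("((A,B),C);")
#' g <- parse_gene_trees("((A,B),C);")[[1]]
#' length(enumerate_histories(g, net))  # 2
#' @export
enumerate_histories <- function(g, net, max_leaves = 10L, max_retics = 3L) {
  gs <- gt_struct(g)
  net_labs <- net$labels[!is.na(net$labels)]
  if (!setequal(gs$labels, net_labs) || length(gs$labels) != length(net_labs))
    stop("gene tree and network leaf labels differ")
  if (gs$n > max_leaves)
    stop("gene tree has ", gs$n, " leaves; enumeration capped at ",
         max_leaves, " (raise max_leaves to override)")
  nret <- length(reticulations(net))
  if (nret > max_retics)
    stop("network has ", nret, " reticulations; enumeration capped at ",
         max_retics, " (raise max_retics to override)")

  e <- net$edges
  ne <- nrow(e)
  rho <- ne + 1L  # virtual root edge

  # pendant edge of each taxon
  pend <- integer(0)
  for (row in seq_len(ne)) {
    lab <- net$labels[e$child[row]]
    if (!is.na(lab)) pend[lab] <- row
  }

  # next edges up from each edge (rho above edges whose tail is the root)
  up <- vector("list", rho)
  for (row in seq_len(ne)) {
    p <- e$parent[row]
    up[[row]] <- if (p == net$root) rho else which(e$child == p)
  }
  up[[rho]] <- integer(0)

  # edges reachable upward from each edge (inclusive)
  reach <- vector("list", rho)
  reach_up <- function(a) {
    if (!is.null(reach[[a]])) return(reach[[a]])
    r <- a
    for (pe in up[[a]]) r <- union(r, reach_up(pe))
    reach[[a]] <<- sort(r)
    r
  }
  for (a in seq_len(rho)) reach_up(a)

  # all upward edge paths from a ending exactly at b
  path_memo <- new.env(parent = emptyenv())
  paths_to <- function(a, b) {
    key <- paste0(a, ".", b)
    got <- path_memo[[key]]
    if (!is.null(got)) return(got)
    res <- list()
    if (a == b) {
      res <- list(a)
    } else if (b %in% reach[[a]]) {
      for (pe in up[[a]]) {
        for (p in paths_to(pe, b)) res[[length(res) + 1L]] <- c(a, p)
      }
    }
    path_memo[[key]] <- res
    res
  }

  # recursive enumeration over the gene tree; a partial record is
  # list(e = edge holding the subtree-root lineage, segs, coal)
  enum <- function(v) {
    ch <- gs$children[[v]]
    if (length(ch) == 0L) {
      return(list(list(e = pend[[gs$labels[v]]], segs = list(),
                       coal = integer(0))))
    }
    r1 <- enum(ch[1]); r2 <- enum(ch[2])
    out <- list()
    for (a in r1) for (b in r2) {
      meet <- intersect(reach[[a$e]], reach[[b$e]])
      for (estar in meet) {
        p1s <- paths_to(a$e, estar)
        p2s <- paths_to(b$e, estar)
        for (p1 in p1s) for (p2 in p2s) {
          coal <- c(a$coal, b$coal, structure(estar, names = as.character(v)))
          segs <- c(a$segs, b$segs,
                    list(list(path = p1, leaf = length(gs$children[[ch[1]]]) == 0L),
                         list(path = p2, leaf = length(gs$children[[ch[2]]]) == 0L)))
          out[[length(out) + 1L]] <- list(e = estar, segs = segs, coal = coal)
        }
      }
    }
    out
  }

  partials <- enum(gs$root)
  hists <- list()
  for (rec in partials) {
    for (p in paths_to(rec$e, rho)) {
      segs <- c(rec$segs, list(list(path = p, leaf = FALSE)))
      hists[[length(hists) + 1L]] <-
        .history_finalize(rec$coal, segs, gs, ne, rho)
    }
  }
  hists
}

# derive per-edge u, v, w, d for a completed routing
.history_finalize <- function(coal, segs, gs, ne, rho) {
  u <- integer(rho)
  for (s in segs) {
    entered <- if (s$leaf) s$path else s$path[-1L]
    if (length(entered)) u[entered] <- u[entered] + 1L
  }
  nodes_by_edge <- split(as.integer(names(coal)),
                         factor(coal, levels = seq_len(rho)))
  cnt <- unname(lengths(nodes_by_edge))
  v <- u - cnt
  if (any(v < 0L) || any(u >= 1L & v < 1L))
    stop("internal error: inconsistent lineage counts in history")
  w <- rep(1, rho); d <- rep(1, rho)
  for (b in seq_len(rho)) {
    if (cnt[b] == 0L) next
    ks <- seq.int(v[b] + 1L, u[b])
    d[b] <- prod(choose(ks, 2))
    w[b] <- .linear_extensions(nodes_by_edge[[b]], gs$anc)
  }
  structure(list(map = coal, segments = segs, u = u, v = v, w = w, d = d),
            class = "coal_history")
}

# number of linear orderings of the coalescences in `nodes` respecting
# child-before-parent gene-tree ancestry (anc[a, b]: a strict ancestor of b)
.linear_extensions <- function(nodes, anc) {
  k <- length(nodes)
  if (k <= 1L) return(1)
  count <- function(S) {
    if (length(S) == 1L) return(1)
    tot <- 0
    for (i in seq_along(S)) {
      m <- S[i]
      if (!any(anc[m, S])) tot <- tot + count(S[-i])
    }
    tot
  }
  count(nodes)
}

#' Combinatorial event-order terms of a history on one edge
#'
#' @param h A \code{coal_history}.
#' @param edge Edge id (row of \code{net$edges}, or one past the last row
#'   for the virtual root edge).
#' @return Named numeric vector \code{c(w = ..., d = ...)}.
#' @export
wd_edge_terms <- function(h, edge) {
  if (edge < 1L || edge > length(h$w)) stop("edge id out of range")
  c(w = h$w[edge], d = h$d[edge])
}

#' @export
print.coal_history <- function(x, ...) {
  cat("coal_history:", length(x$map), "coalescences;",
      "map:", paste(names(x$map), "->", x$map, collapse = ", "), "\n")
  invisible(x)
}
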