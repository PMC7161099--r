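#' Rooted phylogenetic networks
#'
#' A \code{phylo_network} is a rooted directed acyclic graph whose nodes are
#' partitioned into a root (in-degree 0), leaves (in-degree 1, out-degree 0,
#' bijectively labeled by taxa), internal tree nodes (in-degree 1,
#' out-degree >= 2) and reticulation nodes (in-degree 2, out-degree 1).
#' Each edge may carry a length in coalescent units; each reticulation node
#' carries an inheritance probability gamma attached to its designated first
#' parent edge (the other parent edge carries 1 - gamma).  A species tree is
#' the special case with no reticulation nodes.
#'
#' Internally the network is a list with components \code{edges} (a data
#' frame with columns \code{parent}, \code{child}, \code{length},
#' \code{gamma}, \code{is_b1}), \code{labels} (character, \code{NA} for
#' non-leaves) and \code{root} (integer node id).
#'
#' @param edges Data frame with integer columns \code{parent} and
#'   \code{child}, and optionally \code{length}, \code{gamma},
#'   \code{is_b1}.
#' @param labels Character vector of node labels (\code{NA} for internal
#'   nodes), indexed by node id.
#' @param root Integer id of the root node.
#' @param validate Check structural invariants (default \code{TRUE}).
#' @return An object of class \code{"phylo_network"}.
#' @export
phylo_network <- function(edges, labels, root, validate = TRUE) {
  edges <- as.data.frame(edges)
  if (is.null(edges$length)) edges$length <- NA_real_
  if (is.null(edges$gamma)) edges$gamma <- NA_real_
  if (is.null(edges$is_b1)) edges$is_b1 <- FALSE
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  net <- structure(list(edges = edges, labels = as.character(labels),
                        root = as.integer(root)),
                   class = "phylo_network")
  if (validate) validate_network(net)
  net
}

n_nodes <- function(net) length(net$labels)

net_leaves <- function(net) which(!is.na(net$labels))

#' @export
print.phylo_network <- function(x, ...) {
  nl <- length(net_leaves(x))
  nr <- length(reticulations(x))
  cat("phylo_network with", nl, "leaves and", nr,
      if (nr == 1) "reticulation\n" else "reticulations\n")
  cat(" ", write_network(x), "\n")
  invisible(x)
}

#' Reticulation nodes of a network
#'
#' @param net A \code{phylo_network}.
#' @return Integer vector of node ids with in-degree 2.
#' @export
reticulations <- function(net) {
  indeg <- tabulate(net$edges$child, nbins = n_nodes(net))
  which(indeg == 2L)
}

#' Validate the structural invariants of a phylogenetic network
#'
#' Checks the degree conditions (root in-degree 0; leaves in/out 1/0;
#' internal tree nodes in/out 1/>=2; reticulations in/out 2/1), acyclicity,
#' reachability of every node from the root, unique leaf labels, and that
#' inheritance probabilities lie in [0,1] with exactly one designated
#' primary parent edge per reticulation.
#'
#' @param net A \code{phylo_network}.
#' @return The network, invisibly, if valid; otherwise an error.
#' @export
validate_network <- function(net) {
  e <- net$edges
  nn <- n_nodes(net)
  if (nrow(e) == 0L) stop("network has no edges")
  if (any(e$parent < 1L | e$parent > nn | e$child < 1L | e$child > nn))
    stop("edge endpoint out of range")
  indeg <- tabulate(e$child, nbins = nn)
  outdeg <- tabulate(e$parent, nbins = nn)
  r <- net$root
  if (indeg[r] != 0L) stop("root must have in-degree 0")
  if (outdeg[r] < 2L) stop("root must have out-degree >= 2")
  for (v in seq_len(nn)) {
    if (v == r) next
    if (indeg[v] == 0L) stop("node ", v, " is not reachable from the root")
    if (indeg[v] == 1L && outdeg[v] == 0L) {
      if (is.na(net$labels[v])) stop("unlabeled leaf node ", v)
    } else if (indeg[v] == 1L) {
      if (outdeg[v] < 2L) stop("internal tree node ", v,
                               " must have out-degree >= 2")
    } else if (indeg[v] == 2L) {
      if (outdeg[v] != 1L)
        stop("reticulation node ", v, " must have out-degree 1 (has ",
             outdeg[v], ")")
    } else {
      stop("node ", v, " has in-degree ", indeg[v], " > 2")
    }
  }
  labs <- net$labels[!is.na(net$labels)]
  if (anyDuplicated(labs))
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "))
  lv <- which(!is.na(net$labels))
  if (any(outdeg[lv] > 0L)) stop("labeled node with out-degree > 0")
  # acyclicity by Kahn's algorithm
  deg <- indeg
  queue <- r
  seen <- 0L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    seen <- seen + 1L
    for (c in e$child[e$parent == v]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0L) queue <- c(queue, c)
    }
  }
  if (seen != nn) stop("network contains a cycle or unreachable nodes")
  g <- e$gamma[!is.na(e$gamma)]
  if (any(g < 0 | g > 1)) stop("inheritance probability outside [0,1]")
  for (v in which(indeg == 2L)) {
    rows <- which(e$child == v)
    if (sum(e$is_b1[rows]) != 1L)
      stop("reticulation node ", v,
           " must have exactly one designated primary parent edge")
  }
  if (any(e$is_b1[indeg[e$child] != 2L]))
    stop("primary-parent designation on a non-reticulation edge")
  if (any(!is.na(e$gamma) & !e$is_b1))
    stop("inheritance probability on a non-primary parent edge")
  invisible(net)
}

## ---------------------------------------------------------------------------
## Extended Newick parser (Rich Newick dialect: #H-tagged hybrid nodes,
## per-edge fields name:length:support:probability; the probability field on
## a reticulation parent edge is the inheritance probability gamma and marks
## that edge as the designated primary parent edge b1).
## ---------------------------------------------------------------------------

#' Parse a rooted phylogenetic network from extended Newick
#'
#' Accepts the #H-tagged extended Newick dialect used by the PhyloNet
#' family of tools: a reticulation node appears once with its subtree and
#' once (or more) as a bare \code{#H} reference; each occurrence carries the
#' fields of its own parent edge, \code{:length:support:probability}, all
#' optional.  A probability annotation on a reticulation parent edge is its
#' inheritance probability and designates that edge as the primary parent
#' edge; the sibling parent edge implicitly carries one minus it.  A plain
#' Newick tree parses to a species tree (no reticulations).
#'
#' @param text A single extended Newick string terminated by a semicolon.
#' @return A validated \code{phylo_network}.
#' @examples
#' net <- parse_network("((A,(B)#H1:::0.3),(C,#H1));")
#' reticulations(net)
#' @export
parse_network <- function(text) {
  s <- gsub("[[:space:]]", "", paste(text, collapse = ""))
  if (!nzchar(s)) stop("empty network string")
  if (!endsWith(s, ";")) stop("network string must end with ';'")
  s <- substr(s, 1L, nchar(s) - 1L)
  env <- new.env(parent = emptyenv())
  env$s <- s; env$pos <- 1L; env$n <- nchar(s); env$occ <- list()
  root_occ <- .pn_clade(env)
  if (env$pos <= env$n)
    stop("trailing characters at position ", env$pos, ": '",
         substr(env$s, env$pos, env$n), "'")
  .pn_build(env$occ, root_occ)
}

.pn_peek <- function(env) {
  if (env$pos > env$n) "" else substr(env$s, env$pos, env$pos)
}

.pn_scan_name <- function(env) {
  start <- env$pos
  while (env$pos <= env$n &&
         !substr(env$s, env$pos, env$pos) %in% c("(", ")", ",", ":", ";", "#"))
    env$pos <- env$pos + 1L
  if (env$pos > start) substr(env$s, start, env$pos - 1L) else ""
}

.pn_scan_number <- function(env) {
  start <- env$pos
  while (env$pos <= env$n &&
         grepl("[0-9eE.+-]", substr(env$s, env$pos, env$pos)))
    env$pos <- env$pos + 1L
  if (env$pos == start) return(NA_real_)
  x <- suppressWarnings(as.numeric(substr(env$s, start, env$pos - 1L)))
  if (is.na(x)) stop("invalid numeric field at position ", start)
  x
}

.pn_clade <- function(env) {
  children <- integer(0)
  if (.pn_peek(env) == "(") {
    env$pos <- env$pos + 1L
    repeat {
      children <- c(children, .pn_clade(env))
      ch <- .pn_peek(env)
      if (ch == ",") { env$pos <- env$pos + 1L; next }
      if (ch == ")") { env$pos <- env$pos + 1L; break }
      stop("expected ',' or ')' at position ", env$pos)
    }
  }
  label <- .pn_scan_name(env)
  hybrid <- NA_character_
  if (.pn_peek(env) == "#") {
    env$pos <- env$pos + 1L
    hybrid <- .pn_scan_name(env)
    if (!nzchar(hybrid)) stop("empty hybrid tag at position ", env$pos)
  }
  if (length(children) == 0L && !nzchar(label) && is.na(hybrid))
    stop("expected a leaf label at position ", env$pos)
  fields <- rep(NA_real_, 3L)
  k <- 0L
  while (.pn_peek(env) == ":") {
    env$pos <- env$pos + 1L
    k <- k + 1L
    if (k > 3L) stop("too many ':' fields at position ", env$pos)
    fields[k] <- .pn_scan_number(env)
  }
  id <- length(env$occ) + 1L
  env$occ[[id]] <- list(children = children,
                        label = if (nzchar(label)) label else NA_character_,
                        hybrid = hybrid,
                        length = fields[1], gamma = fields[3])
  id
}

.pn_build <- function(occ, root_occ) {
  # map occurrences to node ids, merging occurrences that share a hybrid tag
  tags <- vapply(occ, function(o) o$hybrid, character(1))
  node_of <- integer(length(occ))
  tag_node <- list()
  nid <- 0L
  for (i in seq_along(occ)) {
    tg <- tags[i]
    if (is.na(tg)) {
      nid <- nid + 1L
      node_of[i] <- nid
    } else if (!is.null(tag_node[[tg]])) {
      node_of[i] <- tag_node[[tg]]
    } else {
      nid <- nid + 1L
      tag_node[[tg]] <- nid
      node_of[i] <- nid
    }
  }
  labels <- rep(NA_character_, nid)
  parent <- integer(0); child <- integer(0)
  len <- numeric(0); gam <- numeric(0)
  has_children <- logical(nid)
  for (i in seq_along(occ)) {
    o <- occ[[i]]
    v <- node_of[i]
    if (length(o$children)) has_children[v] <- TRUE
    for (cocc in o$children) {
      parent <- c(parent, v); child <- c(child, node_of[cocc])
      len <- c(len, occ[[cocc]]$length); gam <- c(gam, occ[[cocc]]$gamma)
    }
  }
  for (i in seq_along(occ)) {
    o <- occ[[i]]
    v <- node_of[i]
    if (!has_children[v] && !is.na(o$label)) labels[v] <- o$label
  }
  edges <- data.frame(parent = parent, child = child, length = len,
                      gamma = gam, is_b1 = FALSE)
  indeg <- tabulate(edges$child, nbins = nid)
  for (v in which(indeg == 2L)) {
    rows <- which(edges$child == v)
    ann <- rows[!is.na(edges$gamma[rows])]
    if (length(ann) == 2L) {
      if (abs(sum(edges$gamma[ann]) - 1) > 1e-6)
        stop("inheritance probabilities on the two parent edges of a ",
             "reticulation must sum to 1")
      edges$gamma[ann[2]] <- NA_real_
      ann <- ann[1]
    }
    b1 <- if (length(ann) == 1L) ann else rows[1]
    edges$is_b1[b1] <- TRUE
  }
  if (any(!is.na(edges$gamma) & !edges$is_b1))
    stop("inheritance probability annotation on a non-reticulation edge")
  phylo_network(edges, labels, node_of[root_occ])
}

## ---------------------------------------------------------------------------
## Canonical serialization
## ---------------------------------------------------------------------------

# Per-node structural signature and smallest descendant leaf label, used to
# order children deterministically.  Reticulation nodes are flagged in the
# signature so tree-like and reticulate sharing never collide.
.pn_signatures <- function(net) {
  e <- net$edges
  nn <- n_nodes(net)
  indeg <- tabulate(e$child, nbins = nn)
  kids <- split(e$child, factor(e$parent, levels = seq_len(nn)))
  sig <- character(nn); minleaf <- character(nn)
  done <- logical(nn)
  # process in reverse topological order (leaves first)
  order_nodes <- .pn_topo_order(net)
  for (v in rev(order_nodes)) {
    ch <- kids[[v]]
    if (length(ch) == 0L) {
      sig[v] <- net$labels[v]
      minleaf[v] <- net$labels[v]
    } else {
      o <- order(minleaf[ch], sig[ch])
      body <- paste0("(", paste(sig[ch][o], collapse = ","), ")")
      if (indeg[v] == 2L) body <- paste0(body, "#")
      sig[v] <- body
      minleaf[v] <- min(minleaf[ch])
    }
    done[v] <- TRUE
  }
  list(sig = sig, minleaf = minleaf)
}

# topological order from root (parents before children)
.pn_topo_order <- function(net) {
  e <- net$edges
  nn <- n_nodes(net)
  indeg <- tabulate(e$child, nbins = nn)
  queue <- net$root
  out <- integer(0)
  deg <- indeg
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    out <- c(out, v)
    for (c in e$child[e$parent == v]) {
      deg[c] <- deg[c] - 1L
      if (deg[c] == 0L) queue <- c(queue, c)
    }
  }
  out
}

#' Serialize a phylogenetic network to canonical extended Newick
#'
#' Children are ordered by their smallest descendant leaf label (ties broken
#' by a structural signature), hybrid tags are renumbered in emission order,
#' and each reticulation subtree is expanded at its first occurrence, so
#' isomorphic networks serialize to identical strings.  With
#' \code{lengths = FALSE, gammas = FALSE} the result is the canonical
#' topology string used for deduplication throughout the package.
#'
#' @param net A \code{phylo_network}.
#' @param lengths Emit branch lengths where present.
#' @param gammas Emit inheritance probabilities where present (on the
#'   designated primary parent edge, as the third \code{:} field).
#' @return A single extended Newick string with trailing semicolon.
#' @examples
#' write_network(parse_network("((C,B),A);"))
#' @export
write_network <- function(net, lengths = TRUE, gammas = TRUE) {
  e <- net$edges
  nn <- n_nodes(net)
  sg <- .pn_signatures(net)
  indeg <- tabulate(e$child, nbins = nn)
  env <- new.env(parent = emptyenv())
  env$htag <- integer(nn)   # 0 = not yet emitted
  env$next_h <- 0L
  fields <- function(row) {
    l <- if (lengths && !is.na(e$length[row])) sprintf("%.10g", e$length[row]) else ""
    g <- if (gammas && isTRUE(e$is_b1[row]) && !is.na(e$gamma[row]))
      sprintf("%.10g", e$gamma[row]) else ""
    if (nzchar(g)) paste0(":", l, "::", g)
    else if (nzchar(l)) paste0(":", l)
    else ""
  }
  emit <- function(v) {
    rows <- which(e$parent == v)
    if (length(rows) == 0L) return(net$labels[v])
    o <- order(sg$minleaf[e$child[rows]], sg$sig[e$child[rows]],
               !e$is_b1[rows])
    parts <- character(length(rows))
    for (k in seq_along(rows)) {
      row <- rows[o[k]]
      c <- e$child[row]
      if (indeg[c] == 2L) {
        if (env$htag[c] == 0L) {
          env$next_h <- env$next_h + 1L
          env$htag[c] <- env$next_h
          parts[k] <- paste0(emit(c), "#H", env$htag[c], fields(row))
        } else {
          parts[k] <- paste0("#H", env$htag[c], fields(row))
        }
      } else {
        parts[k] <- paste0(emit(c), fields(row))
      }
    }
    paste0("(", paste(parts, collapse = ","), ")")
  }
  body <- emit(net$root)
  # a leaf-only "network" cannot occur (validator requires outdeg(root) >= 2)
  paste0(body, ";")
}

#' Canonical topology string of a network
#'
#' @param net A \code{phylo_network}.
#' @return \code{write_network(net, lengths = FALSE, gammas = FALSE)}.
#' @export
canonical_network <- function(net) write_network(net, lengths = FALSE, gammas = FALSE)

#' Test whether two networks are isomorphic as leaf-labeled DAGs
#'
#' @param net1,net2 \code{phylo_network} objects.
#' @param params If \code{TRUE}, branch lengths and inheritance
#'   probabilities must match as well.
#' @return Logical.
#' @export
networks_isomorphic <- function(net1, net2, params = FALSE) {
  if (params) write_network(net1) == write_network(net2)
  else canonical_network(net1) == canonical_network(net2)
}

## ---------------------------------------------------------------------------
## Conversions and surgery
## ---------------------------------------------------------------------------

#' Convert a rooted tree to a species-tree network
#'
#' @param phy A rooted \code{"phylo"} object (or Newick string).
#' @return A \code{phylo_network} with no reticulations.
#' @export
as_phylo_network <- function(phy) {
  if (is.character(phy)) return(parse_network(phy))
  if (inherits(phy, "phylo_network")) return(phy)
  stopifnot(inherits(phy, "phylo"))
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  labels <- rep(NA_character_, nn)
  labels[seq_len(n)] <- phy$tip.label
  len <- if (is.null(phy$edge.length)) rep(NA_real_, nrow(phy$edge)) else phy$edge.length
  edges <- data.frame(parent = phy$edge[, 1], child = phy$edge[, 2],
                      length = len, gamma = NA_real_, is_b1 = FALSE)
  phylo_network(edges, labels, n + 1L)
}

#' Convert a reticulation-free network to an ape tree
#'
#' @param net A \code{phylo_network} with no reticulation nodes.
#' @return A \code{"phylo"} object.
#' @export
net_to_phylo <- function(net) {
  if (length(reticulations(net)) > 0L)
    stop("network has reticulations; extract displayed trees first")
  phy <- ape::read.tree(text = write_network(net, gammas = FALSE))
  phy
}

# Remove unreachable nodes, splice out in/out-degree 1/1 nodes (summing
# lengths where both are set), drop childless unlabeled nodes, and re-root
# below out-degree-1 roots.  Gamma/b1 marks survive only on edges whose head
# still has in-degree 2.  Used after displayed-tree extraction and
# reticulation-edge deletion.
.pn_cleanup <- function(edges, labels, root) {
  repeat {
    nn <- length(labels)
    keep_node <- rep(FALSE, nn)
    # reachability from root
    queue <- root
    keep_node[root] <- TRUE
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (c in edges$child[edges$parent == v]) {
        if (!keep_node[c]) { keep_node[c] <- TRUE; queue <- c(queue, c) }
      }
    }
    edges <- edges[keep_node[edges$parent] & keep_node[edges$child], , drop = FALSE]
    indeg <- tabulate(edges$child, nbins = nn)
    outdeg <- tabulate(edges$parent, nbins = nn)
    changed <- FALSE
    # drop unlabeled childless non-root nodes
    dead <- which(keep_node & outdeg == 0L & is.na(labels) & seq_len(nn) != root)
    if (length(dead)) {
      edges <- edges[!(edges$child %in% dead), , drop = FALSE]
      keep_node[dead] <- FALSE
      changed <- TRUE
    } else {
      # splice one 1/1 node
      mid <- which(keep_node & indeg == 1L & outdeg == 1L & is.na(labels))
      if (length(mid)) {
        v <- mid[1]
        up <- which(edges$child == v)
        dn <- which(edges$parent == v)
        l1 <- edges$length[up]; l2 <- edges$length[dn]
        edges$parent[dn] <- edges$parent[up]
        edges$length[dn] <- if (is.na(l1) || is.na(l2)) NA_real_ else l1 + l2
        edges <- edges[-up, , drop = FALSE]
        keep_node[v] <- FALSE
        changed <- TRUE
      } else if (sum(edges$parent == root) == 1L) {
        dn <- which(edges$parent == root)
        keep_node[root] <- FALSE
        root <- edges$child[dn]
        edges <- edges[-dn, , drop = FALSE]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # clear stale gamma marks on edges no longer entering a reticulation
  indeg <- tabulate(edges$child, nbins = length(labels))
  stale <- indeg[edges$child] != 2L
  edges$gamma[stale] <- NA_real_
  edges$is_b1[stale] <- FALSE
  # ensure surviving reticulations keep exactly one b1 mark
  for (v in which(indeg == 2L)) {
    rows <- which(edges$child == v)
    if (sum(edges$is_b1[rows]) != 1L) {
      edges$is_b1[rows] <- FALSE
      edges$is_b1[rows[1]] <- TRUE
      edges$gamma[rows] <- NA_real_
    }
  }
  # compact node ids
  used <- sort(unique(c(edges$parent, edges$child, root)))
  remap <- integer(length(labels)); remap[used] <- seq_along(used)
  edges$parent <- remap[edges$parent]; edges$child <- remap[edges$child]
  list(edges = edges, labels = labels[used], root = remap[root])
}

#' Add a reticulation edge between two edges of a network
#'
#' Subdivides \code{tail_edge} with a new tree node x and \code{head_edge}
#' with a new reticulation node y, and adds the edge x -> y.  With
#' \code{tail_edge = 0} the new tail is a new root placed above the current
#' root.  Returns \code{NULL} when the result would be cyclic or otherwise
#' invalid.
#'
#' @param net A \code{phylo_network}.
#' @param tail_edge,head_edge Row indices into \code{net$edges} (distinct),
#'   or \code{tail_edge = 0} for the root position.
#' @return A \code{phylo_network}, or \code{NULL} if invalid.
#' @export
add_reticulation <- function(net, tail_edge, head_edge) {
  if (tail_edge == head_edge) return(NULL)
  e <- net$edges
  nn <- n_nodes(net)
  x <- nn + 1L; y <- nn + 2L
  labels <- c(net$labels, NA_character_, NA_character_)
  root <- net$root
  if (tail_edge == 0L) {
    # new root above the current root
    e <- rbind(e, data.frame(parent = x, child = root, length = NA_real_,
                             gamma = NA_real_, is_b1 = FALSE))
    root <- x
  } else {
    tc <- e$child[tail_edge]
    e$child[tail_edge] <- x
    e <- rbind(e, data.frame(parent = x, child = tc, length = NA_real_,
                             gamma = NA_real_, is_b1 = FALSE))
  }
  hc <- e$child[head_edge]
  hb1 <- e$is_b1[head_edge]; hg <- e$gamma[head_edge]
  e$child[head_edge] <- y
  e <- rbind(e,
             data.frame(parent = y, child = hc, length = NA_real_,
                        gamma = hg, is_b1 = hb1),
             data.frame(parent = x, child = y, length = NA_real_,
                        gamma = NA_real_, is_b1 = FALSE))
  e$gamma[head_edge] <- NA_real_
  # the subdivided original edge into y is the designated primary parent
  e$is_b1[head_edge] <- TRUE
  out <- tryCatch(phylo_network(e, labels, root), error = function(err) NULL)
  out
}

#' Delete one parent edge of a reticulation and simplify
#'
#' Removes the given reticulation parent edge, then suppresses the two
#' resulting degree-2 nodes (and any unreachable parts).  Deleting the only
#' reticulation of a 1-reticulation network yields one of its displayed
#' trees.
#'
#' @param net A \code{phylo_network}.
#' @param edge Row index into \code{net$edges}; its head must be a
#'   reticulation node.
#' @return A \code{phylo_network}.
#' @export
delete_reticulation_edge <- function(net, edge) {
  e <- net$edges
  indeg <- tabulate(e$child, nbins = n_nodes(net))
  if (indeg[e$child[edge]] != 2L)
    stop("edge ", edge, " does not enter a reticulation node")
  e <- e[-edge, , drop = FALSE]
  parts <- .pn_cleanup(e, net$labels, net$root)
  phylo_network(parts$edges, parts$labels, parts$root)
}
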