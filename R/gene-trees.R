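#' Parse rooted binary gene trees from Newick text
#'
#' Reads one rooted binary gene tree per non-empty line.  Branch lengths,
#' if present, are silently dropped: the coalescent model implemented here
#' is defined on gene-tree topologies only.
#'
#' @param text Character scalar (possibly multi-line) or character vector of
#'   Newick strings, one tree per line, each terminated by a semicolon.
#' @return A list of \code{"phylo"} objects (see \pkg{ape}), validated to be
#'   rooted, binary, and uniquely leaf-labeled.
#' @examples
#' gts <- parse_gene_trees("((A,B),C);\n((A,C),B);")
#' length(gts)
#' @export
parse_gene_trees <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- trimws(lines)
  keep <- nzchar(lines)
  idx <- which(keep)
  out <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    phy <- tryCatch(
      suppressWarnings(ape::read.tree(text = lines[i])),
      error = function(e) stop("line ", i, ": malformed Newick: ",
                               conditionMessage(e), call. = FALSE)
    )
    if (is.null(phy))
      stop("line ", i, ": malformed Newick", call. = FALSE)
    phy$edge.length <- NULL
    phy$node.label <- NULL
    tryCatch(validate_gene_tree(phy),
             error = function(e) stop("line ", i, ": ", conditionMessage(e),
                                      call. = FALSE))
    out[[k]] <- phy
  }
  out
}

#' Validate a rooted binary gene tree
#'
#' @param phy A \code{"phylo"} object.
#' @return The tree, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_gene_tree <- function(phy) {
  if (!inherits(phy, "phylo")) stop("not a \"phylo\" object")
  n <- length(phy$tip.label)
  if (n < 2) stop("gene tree must have at least 2 leaves")
  if (anyDuplicated(phy$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy)) stop("gene tree must be rooted")
  deg <- tabulate(phy$edge[, 1], nbins = n + phy$Nnode)
  if (any(deg[(n + 1):(n + phy$Nnode)] != 2L))
    stop("gene tree must be binary (every internal node has exactly 2 children)")
  if (phy$Nnode != n - 1L)
    stop("a rooted binary tree on ", n, " leaves must have ", n - 1L,
         " internal nodes")
  invisible(phy)
}

# Compact structural view of a phylo object used by the enumeration code:
# children list indexed by node id (ape numbering: tips 1..n, root n+1),
# internal nodes in post order, and the set of internal descendants of each
# internal node (for the within-edge event-order computation).
gt_struct <- function(phy) {
  n <- length(phy$tip.label)
  nn <- n + phy$Nnode
  children <- vector("list", nn)
  parent <- integer(nn)
  for (i in seq_len(nrow(phy$edge))) {
    p <- phy$edge[i, 1]; c <- phy$edge[i, 2]
    children[[p]] <- c(children[[p]], c)
    parent[c] <- p
  }
  root <- n + 1L
  # post order over all nodes
  po <- integer(0)
  stack <- root
  visit <- integer(0)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    visit <- c(visit, v)
    stack <- c(stack, children[[v]])
  }
  po <- rev(visit)
  # is_anc[a, b]: node a is a strict ancestor of node b (internal nodes only)
  anc <- matrix(FALSE, nn, nn)
  for (v in po) {
    for (ch in children[[v]]) {
      anc[v, ch] <- TRUE
      anc[v, ] <- anc[v, ] | anc[ch, ]
    }
  }
  list(n = n, nnode = nn, children = children, parent = parent,
       root = root, postorder = po, labels = phy$tip.label, anc = anc)
}

#' Canonical topology string of a rooted tree
#'
#' Serializes a rooted tree with children ordered by their smallest
#' descendant leaf label, so that topologically identical trees map to
#' identical strings.  Branch lengths are ignored.
#'
#' @param phy A \code{"phylo"} object, or a Newick string.
#' @return A canonical Newick string (with trailing semicolon).
#' @examples
#' canonical_topology("((C,B),A);")  # "((B,C),A);"
#' @export
canonical_topology <- function(phy) {
  if (is.character(phy)) phy <- parse_gene_trees(phy)[[1]]
  s <- gt_struct(phy)
  sig <- character(s$nnode)
  minleaf <- character(s$nnode)
  for (v in s$postorder) {
    ch <- s$children[[v]]
    if (length(ch) == 0L) {
      sig[v] <- s$labels[v]
      minleaf[v] <- s$labels[v]
    } else {
      o <- order(minleaf[ch], sig[ch])
      sig[v] <- paste0("(", paste(sig[ch][o], collapse = ","), ")")
      minleaf[v] <- min(minleaf[ch])
    }
  }
  paste0(sig[s$root], ";")
}
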