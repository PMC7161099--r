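#' Minimum number of extra lineages of one gene tree
#'
#' The deep-coalescence cost of fitting a gene tree into a species tree or
#' network: the minimum, over all coalescent histories (including lineage
#' routing at reticulations), of the total number of lineages beyond one
#' exiting each network edge.  Inheritance probabilities play no role.
#'
#' @param g A gene tree (\code{"phylo"}).
#' @param net A \code{phylo_network} (topology only is needed).
#' @return Nonnegative integer.
#' @examples
#' net <- parse_network("((A,B),C);")
#' extra_lineages(parse_gene_trees("((A,C),B);")[[1]], net)  # 1
#' @export
extra_lineages <- function(g, net) {
  key <- paste("xl", canonical_topology(g), canonical_network(net), sep = "|")
  got <- .ncm_cache[[key]]
  if (!is.null(got)) return(got)
  hs <- enumerate_histories(g, net)
  ne <- nrow(net$edges)
  xl <- vapply(hs, function(h) sum(pmax(h$v[seq_len(ne)] - 1L, 0L)),
               numeric(1))
  out <- as.integer(min(xl))
  .ncm_cache[[key]] <- out
  out
}

#' Minimize-deep-coalescences score of a topology over many loci
#'
#' Sum of \code{\link{extra_lineages}} over all loci, with caching on the
#' canonical gene-tree topology so repeated topologies are scored once.
#'
#' @param G List of gene trees or character vector of Newick strings.
#' @param net A \code{phylo_network}.
#' @return Nonnegative integer; the MDC-optimal topology minimizes it.
#' @export
mdc_score <- function(G, net) {
  if (is.character(G)) G <- parse_gene_trees(G)
  if (length(G) == 0L) return(0L)
  keys <- vapply(G, canonical_topology, character(1))
  tab <- table(keys)
  tot <- 0L
  for (k in seq_along(tab)) {
    g <- parse_gene_trees(names(tab)[k])[[1]]
    tot <- tot + as.integer(tab[k]) * extra_lineages(g, net)
  }
  tot
}

#' Per-locus extra-lineage table
#'
#' @inheritParams mdc_score
#' @return Data frame with columns \code{locus}, \code{topology},
#'   \code{extra_lineages}.
#' @export
per_locus_mdc <- function(G, net) {
  if (is.character(G)) G <- parse_gene_trees(G)
  keys <- vapply(G, canonical_topology, character(1))
  uk <- unique(keys)
  xl <- vapply(uk, function(k)
    extra_lineages(parse_gene_trees(k)[[1]], net), integer(1))
  data.frame(locus = seq_along(G), topology = keys,
             extra_lineages = xl[match(keys, uk)], row.names = NULL)
}
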