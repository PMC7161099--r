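#' Simulation regime for multi-locus gene-tree data
#'
#' Two sampling laws for the per-locus continuous parameters of a species
#' network topology.  Under \code{mode = "common"} one fixed setting of all
#' branch lengths and inheritance probabilities is shared by every locus
#' (the classical common-mechanism assumption).  Under \code{mode = "ncm"}
#' every locus draws its own branch lengths, uniformly on
#' (0, \code{branch_length_upper}), and its own inheritance probabilities,
#' uniformly on (0, 1).
#'
#' @param mode \code{"common"} or \code{"ncm"}.
#' @param n_loci Number of loci to simulate.
#' @param branch_length_value Common-mode branch length (coalescent units)
#'   applied to every edge without a length of its own.
#' @param gamma_value Common-mode inheritance probability applied to every
#'   reticulation without a gamma of its own.
#' @param branch_length_upper NCM-mode upper bound of the uniform
#'   branch-length law.
#' @return An object of class \code{"sim_regime"}.
#' @export
sim_regime <- function(mode = c("common", "ncm"), n_loci = 100L,
                       branch_length_value = 1, gamma_value = 0.5,
                       branch_length_upper = 2) {
  mode <- match.arg(mode)
  stopifnot(n_loci >= 1L, branch_length_value > 0, branch_length_upper > 0,
            gamma_value >= 0, gamma_value <= 1)
  structure(list(mode = mode, n_loci = as.integer(n_loci),
                 branch_length_value = branch_length_value,
                 gamma_value = gamma_value,
                 branch_length_upper = branch_length_upper),
            class = "sim_regime")
}

#' Simulate one gene tree under the multispecies network coalescent
#'
#' One lineage starts at each leaf.  Within an edge of length lambda each
#' pair of extant lineages coalesces at rate 1 (exact exponential waiting
#' times, uniformly chosen pairs).  At a reticulation node each lineage
#' independently follows the designated primary parent edge with its
#' inheritance probability.  Above the network root coalescence continues
#' until a single lineage remains.  The returned tree is the topology in
#' canonical Newick form (children ordered by smallest descendant leaf).
#'
#' @param net A \code{phylo_network} whose edges all have lengths and whose
#'   reticulations all have gamma (unless supplied via \code{lengths} /
#'   \code{gammas}).
#' @param lengths Optional numeric vector overriding the edge lengths
#'   (indexed like \code{net$edges} rows).
#' @param gammas Optional numeric vector of inheritance probabilities, one
#'   per reticulation in the order of \code{reticulations(net)}.
#' @param as_phylo Return a \code{"phylo"} object instead of the canonical
#'   Newick string.
#' @return Canonical Newick string, or a \code{"phylo"} if
#'   \code{as_phylo = TRUE}.  Uses R's global random number stream.
#' @export
simulate_gene_tree <- function(net, lengths = NULL, gammas = NULL,
                               as_phylo = FALSE) {
  e <- net$edges
  ne <- nrow(e)
  len <- if (is.null(lengths)) e$length else lengths
  if (length(len) != ne || any(is.na(len)) || any(len < 0))
    stop("all edge lengths must be set and nonnegative")
  rets <- reticulations(net)
  gam <- numeric(0)
  if (length(rets)) {
    gam <- if (is.null(gammas)) {
      vapply(rets, function(v) {
        rows <- which(e$child == v)
        e$gamma[rows[e$is_b1[rows]]]
      }, numeric(1))
    } else gammas
    if (length(gam) != length(rets) || any(is.na(gam)))
      stop("all inheritance probabilities must be set")
  }
  nn <- n_nodes(net)
  kids_edges <- split(seq_len(ne), factor(e$parent, levels = seq_len(nn)))
  # lineage = list(str = canonical newick fragment, min = smallest leaf)
  coalesce_in <- function(lin, tmax) {
    k <- length(lin)
    t <- 0
    while (k > 1L) {
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
      if (t > tmax) break
      ij <- sample.int(k, 2L)
      a <- lin[[ij[1]]]; b <- lin[[ij[2]]]
      mrg <- if (a$min <= b$min)
        list(str = paste0("(", a$str, ",", b$str, ")"), min = a$min)
      else
        list(str = paste0("(", b$str, ",", a$str, ")"), min = b$min)
      lin <- c(lin[-ij], list(mrg))
      k <- k - 1L
    }
    lin
  }
  # lineages sitting at the top of each edge, filled leaves-up
  at_top <- vector("list", ne)
  for (v in rev(.pn_topo_order(net))) {
    if (v == net$root) next
    below <- kids_edges[[v]]
    lin <- if (length(below) == 0L) {
      list(list(str = net$labels[v], min = net$labels[v]))
    } else {
      do.call(c, at_top[below])
    }
    rows <- which(e$child == v)
    if (length(rows) == 2L) {
      # reticulation: route each lineage independently
      b1 <- rows[e$is_b1[rows]]; b2 <- rows[!e$is_b1[rows]]
      g <- gam[match(v, rets)]
      go1 <- stats::runif(length(lin)) < g
      # single-bracket assignment: a branch may carry zero lineages and a
      # NULL result must not delete the list slot
      at_top[b1] <- list(coalesce_in(lin[go1], len[b1]))
      at_top[b2] <- list(coalesce_in(lin[!go1], len[b2]))
    } else {
      at_top[rows] <- list(coalesce_in(lin, len[rows]))
    }
  }
  lin <- do.call(c, at_top[kids_edges[[net$root]]])
  lin <- coalesce_in(lin, Inf)
  nwk <- paste0(lin[[1]]$str, ";")
  if (as_phylo) parse_gene_trees(nwk)[[1]] else nwk
}

#' Simulate a multi-locus gene-tree data set
#'
#' Under the common regime one fixed parameter setting is reused for every
#' locus; under the NCM regime every branch length and every inheritance
#' probability is drawn afresh per locus.  Fully determined by the seed.
#'
#' @param net A \code{phylo_network}; edges may be topology-only (lengths
#'   are then taken from the regime) or carry lengths used as the
#'   common-mode values.
#' @param regime A \code{\link{sim_regime}}.
#' @param seed Optional integer seed (set via \code{set.seed}).
#' @param as_phylo Return \code{"phylo"} objects instead of Newick strings.
#' @return A list with components \code{trees} (character vector of
#'   canonical Newick strings, or list of \code{"phylo"}) and \code{params}
#'   (data frame logging the per-locus branch lengths \code{len_<edge>} and
#'   inheritance probabilities \code{gamma_<k>}; one row under the common
#'   regime, one row per locus under NCM).
#' @export
simulate_dataset <- function(net, regime, seed = NULL, as_phylo = FALSE) {
  stopifnot(inherits(regime, "sim_regime"))
  if (!is.null(seed)) set.seed(seed)
  e <- net$edges
  ne <- nrow(e)
  rets <- reticulations(net)
  nr <- length(rets)
  m <- regime$n_loci
  base_len <- ifelse(is.na(e$length), regime$branch_length_value, e$length)
  base_gam <- if (nr) vapply(rets, function(v) {
    rows <- which(e$child == v)
    g <- e$gamma[rows[e$is_b1[rows]]]
    if (is.na(g)) regime$gamma_value else g
  }, numeric(1)) else numeric(0)
  trees <- character(m)
  if (regime$mode == "common") {
    for (i in seq_len(m))
      trees[i] <- simulate_gene_tree(net, lengths = base_len,
                                     gammas = base_gam)
    params <- data.frame(locus = NA_integer_,
                         t(c(base_len, base_gam)))
  } else {
    pl <- matrix(0, m, ne + nr)
    for (i in seq_len(m)) {
      len <- stats::runif(ne, 0, regime$branch_length_upper)
      gam <- if (nr) stats::runif(nr) else numeric(0)
      pl[i, ] <- c(len, gam)
      trees[i] <- simulate_gene_tree(net, lengths = len, gammas = gam)
    }
    params <- data.frame(locus = seq_len(m), pl)
  }
  names(params) <- c("locus", paste0("len_", seq_len(ne)),
                     if (nr) paste0("gamma_", seq_len(nr)))
  if (as_phylo) trees <- parse_gene_trees(paste(trees, collapse = "\n"))
  list(trees = trees, params = params)
}
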