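#' Search configuration for topology inference
#'
#' @param max_reticulations Maximum number of reticulations in candidate
#'   networks (0 searches species trees only).
#' @param criterion \code{"ncm"} (maximize the integrated likelihood) or
#'   \code{"mdc"} (minimize deep coalescences).
#' @param mode \code{"exhaustive"} (guarded to <= 6 taxa and <= 1
#'   reticulation) or \code{"hill_climb"}.
#' @param seed Integer seed for random restarts.
#' @param max_iterations Cap on hill-climbing steps per restart.
#' @param num_restarts Number of random restarts for hill climbing.
#' @param tabu Never re-evaluate a previously scored canonical topology.
#' @return An object of class \code{"search_config"}.
#' @export
search_config <- function(max_reticulations = 0L,
                          criterion = c("ncm", "mdc"),
                          mode = c("exhaustive", "hill_climb"),
                          seed = 1L, max_iterations = 100L,
                          num_restarts = 3L, tabu = TRUE) {
  structure(list(max_reticulations = as.integer(max_reticulations),
                 criterion = match.arg(criterion),
                 mode = match.arg(mode),
                 seed = as.integer(seed),
                 max_iterations = as.integer(max_iterations),
                 num_restarts = as.integer(num_restarts),
                 tabu = isTRUE(tabu)),
            class = "search_config")
}

#' Enumerate all rooted topologies on a taxon set
#'
#' All rooted binary species-tree topologies on the given taxa
#' (\code{max_ret = 0}; there are (2n-3)!! of them), optionally extended by
#' every distinct one-reticulation network obtainable by adding a
#' reticulation edge between two edges (including a tail above the root),
#' deduplicated by canonical form.
#'
#' @param taxa Character vector of 2 to 6 taxon labels.
#' @param max_ret 0 or 1 reticulations.
#' @return List of \code{phylo_network} objects.
#' @examples
#' length(enumerate_topologies(c("A", "B", "C")))       # 3
#' length(enumerate_topologies(c("A", "B", "C", "D")))  # 15
#' @export
enumerate_topologies <- function(taxa, max_ret = 0L) {
  taxa <- as.character(taxa)
  n <- length(taxa)
  if (n < 2L || n > 6L)
    stop("exhaustive enumeration supports 2 to 6 taxa")
  if (!max_ret %in% c(0L, 1L))
    stop("exhaustive enumeration supports at most 1 reticulation")
  trees <- .all_rooted_tree_newicks(taxa)
  nets <- lapply(trees, parse_network)
  if (max_ret == 0L) return(nets)
  seen <- new.env(parent = emptyenv())
  out <- list()
  add <- function(net) {
    key <- canonical_network(net)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      out[[length(out) + 1L]] <<- net
    }
  }
  for (net in nets) add(net)
  for (net in nets) {
    ne <- nrow(net$edges)
    for (ti in c(0L, seq_len(ne))) {
      for (hi in seq_len(ne)) {
        if (ti == hi) next
        cand <- add_reticulation(net, ti, hi)
        if (!is.null(cand)) add(cand)
      }
    }
  }
  out
}

# all rooted binary tree topologies by leaf insertion on every edge
# (including above the root); returns Newick strings
.all_rooted_tree_newicks <- function(taxa) {
  taxa <- sort(taxa)
  grow <- function(tr, leaf) {
    # tr is a nested list; leaves are character scalars
    res <- list(list(tr, leaf))  # above the root
    insert <- function(node) {
      # returns list of variants of `node` with the leaf attached inside
      outs <- list()
      if (is.character(node)) return(outs)
      for (k in 1:2) {
        # attach on the edge above child k
        v <- node; v[[k]] <- list(node[[k]], leaf)
        outs[[length(outs) + 1L]] <- v
        for (sub in insert(node[[k]])) {
          v <- node; v[[k]] <- sub
          outs[[length(outs) + 1L]] <- v
        }
      }
      outs
    }
    c(res, insert(tr))
  }
  trees <- list(list(taxa[1], taxa[2]))
  for (i in seq_along(taxa)[-(1:2)]) {
    trees <- do.call(c, lapply(trees, grow, leaf = taxa[i]))
  }
  to_newick <- function(tr) {
    f <- function(x) if (is.character(x)) x else
      paste0("(", f(x[[1]]), ",", f(x[[2]]), ")")
    paste0(f(tr), ";")
  }
  vapply(trees, to_newick, character(1))
}

# criterion score: larger is better for both criteria
.search_score <- function(net, G, cfg, lik_cfg, cache) {
  key <- canonical_network(net)
  got <- cache$scores[[key]]
  if (!is.null(got)) return(got)
  s <- if (cfg$criterion == "ncm") multilocus_loglik(G, net, lik_cfg)
       else -as.numeric(mdc_score(G, net))
  cache$scores[[key]] <- s
  cache$trace <- rbind(cache$trace,
                       data.frame(topology = key, score = s))
  s
}

#' Exhaustive topology search
#'
#' Scores every topology from \code{\link{enumerate_topologies}} under the
#' chosen criterion and returns the optimum (ties broken by the
#' lexicographically smallest canonical serialization).
#'
#' @param G Gene trees (list of \code{"phylo"} or Newick character vector).
#' @param config A \code{\link{search_config}}.
#' @param lik_config A \code{\link{likelihood_config}}.
#' @return List with \code{network}, \code{score} (log-likelihood for
#'   \code{"ncm"}, minus the MDC cost for \code{"mdc"}), \code{optima}
#'   (canonical strings of all score-tied optima) and \code{trace} (every
#'   topology scored).
#' @export
exhaustive_search <- function(G, config = search_config(),
                              lik_config = likelihood_config()) {
  if (is.character(G)) G <- parse_gene_trees(G)
  taxa <- sort(G[[1]]$tip.label)
  nets <- enumerate_topologies(taxa, config$max_reticulations)
  cache <- new.env(parent = emptyenv())
  cache$scores <- list(); cache$trace <- NULL
  scores <- vapply(nets, .search_score, numeric(1), G = G, cfg = config,
                   lik_cfg = lik_config, cache = cache)
  best <- max(scores)
  tol <- 1e-9 * max(1, abs(best))
  tied <- which(scores >= best - tol)
  keys <- vapply(nets[tied], canonical_network, character(1))
  pick <- tied[order(keys)[1]]
  list(network = nets[[pick]], score = scores[pick],
       optima = sort(keys), trace = cache$trace)
}

# neighborhood move set: rooted NNI on tree edges, reticulation-edge
# addition (up to the cap), deletion, and relocation (delete + re-add)
.neighbors <- function(net, max_ret) {
  out <- list()
  add <- function(x) if (!is.null(x)) out[[length(out) + 1L]] <<- x
  e <- net$edges
  ne <- nrow(e)
  indeg <- tabulate(e$child, nbins = n_nodes(net))
  # rooted NNI: for an edge (u, v) with v an internal tree node, swap a
  # child subtree of v with a sibling edge of v
  for (row in seq_len(ne)) {
    v <- e$child[row]; u <- e$parent[row]
    if (indeg[v] != 1L) next
    vkids <- which(e$parent == v)
    if (length(vkids) < 2L) next
    sibs <- setdiff(which(e$parent == u), row)
    for (s in sibs) for (k in vkids) {
      e2 <- e
      cs <- e2$child[s]; ck <- e2$child[k]
      e2$child[s] <- ck; e2$child[k] <- cs
      # swap gamma marks along with the subtrees
      tmp <- e2[s, c("gamma", "is_b1")]
      e2[s, c("gamma", "is_b1")] <- e2[k, c("gamma", "is_b1")]
      e2[k, c("gamma", "is_b1")] <- tmp
      cand <- tryCatch(phylo_network(e2, net$labels, net$root),
                       error = function(err) NULL)
      add(cand)
    }
  }
  rets <- reticulations(net)
  # reticulation addition
  if (length(rets) < max_ret) {
    for (ti in c(0L, seq_len(ne))) for (hi in seq_len(ne)) {
      if (ti != hi) add(add_reticulation(net, ti, hi))
    }
  }
  # deletion and relocation
  for (r in rets) {
    rows <- which(e$child == r)
    for (row in rows) {
      del <- tryCatch(delete_reticulation_edge(net, row),
                      error = function(err) NULL)
      if (is.null(del)) next
      if (length(reticulations(del)) <= max_ret) add(del)
      nd <- nrow(del$edges)
      for (ti in c(0L, seq_len(nd))) for (hi in seq_len(nd)) {
        if (ti != hi) add(add_reticulation(del, ti, hi))
      }
    }
  }
  # dedup by canonical form, deterministic order
  keys <- vapply(out, canonical_network, character(1))
  keep <- !duplicated(keys)
  out <- out[keep]
  out[order(keys[keep])]
}

# seeded random rooted tree by sequential joining
.random_start_tree <- function(taxa) {
  lin <- as.list(sort(taxa))
  while (length(lin) > 1L) {
    ij <- sample.int(length(lin), 2L)
    mrg <- paste0("(", lin[[ij[1]]], ",", lin[[ij[2]]], ")")
    lin <- c(lin[-ij], list(mrg))
  }
  parse_network(paste0(lin[[1]], ";"))
}

#' Hill-climbing topology search
#'
#' Greedy ascent over tree/network topologies from seeded random starting
#' trees: at each step all neighbors under the move set (rooted
#' nearest-neighbor interchange, reticulation-edge addition, deletion and
#' relocation) are scored and the best strictly improving one is taken.
#' With \code{tabu = TRUE} a canonical topology is never scored twice
#' across the whole run.  Deterministic given the seed.
#'
#' @inheritParams exhaustive_search
#' @return List with \code{network}, \code{score}, \code{trace} (every
#'   topology evaluated, in evaluation order), \code{path} (the accepted
#'   topology/score sequence per restart) and \code{n_evaluated}.
#' @export
hill_climb <- function(G, config = search_config(mode = "hill_climb"),
                       lik_config = likelihood_config()) {
  if (is.character(G)) G <- parse_gene_trees(G)
  taxa <- sort(G[[1]]$tip.label)
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  cache$scores <- list(); cache$trace <- NULL
  best_net <- NULL; best_score <- -Inf
  path <- NULL
  for (rs in seq_len(max(1L, config$num_restarts))) {
    cur <- .random_start_tree(taxa)
    cur_score <- .search_score(cur, G, config, lik_config, cache)
    path <- rbind(path, data.frame(restart = rs, step = 0L,
                                   topology = canonical_network(cur),
                                   score = cur_score))
    iter <- 0L
    repeat {
      iter <- iter + 1L
      if (iter > config$max_iterations) break
      nbs <- .neighbors(cur, config$max_reticulations)
      if (config$tabu) {
        keys <- vapply(nbs, canonical_network, character(1))
        nbs <- nbs[is.na(match(keys, names(cache$scores)))]
      }
      if (length(nbs) == 0L) break
      sc <- vapply(nbs, .search_score, numeric(1), G = G, cfg = config,
                   lik_cfg = lik_config, cache = cache)
      mx <- max(sc)
      if (mx <= cur_score) break
      tied <- which(sc >= mx)
      keys <- vapply(nbs[tied], canonical_network, character(1))
      cur <- nbs[[tied[order(keys)[1]]]]
      cur_score <- mx
      path <- rbind(path, data.frame(restart = rs, step = iter,
                                     topology = canonical_network(cur),
                                     score = cur_score))
    }
    if (cur_score > best_score ||
        (cur_score == best_score &&
         canonical_network(cur) < canonical_network(best_net))) {
      best_net <- cur; best_score <- cur_score
    }
  }
  list(network = best_net, score = best_score, trace = cache$trace,
       path = path, n_evaluated = length(cache$scores))
}

#' Infer a species phylogeny topology from gene trees
#'
#' Front end dispatching on \code{config$mode} to
#' \code{\link{exhaustive_search}} or \code{\link{hill_climb}}.
#'
#' @inheritParams exhaustive_search
#' @return The result list of the dispatched search.
#' @export
infer_network <- function(G, config = search_config(),
                          lik_config = likelihood_config()) {
  if (config$mode == "exhaustive") exhaustive_search(G, config, lik_config)
  else hill_climb(G, config, lik_config)
}
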