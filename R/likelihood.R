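#' Prior configuration for the integrated likelihood
#'
#' Branch lengths of the species phylogeny receive independent exponential
#' priors with rate \code{exp_rate}, truncated to (0, \code{tau}] when
#' \code{tau} is finite; \code{tau = Inf} (the default, used throughout the
#' package's inference functions) is the untruncated exponential.
#' Inheritance probabilities receive independent Beta(\code{beta_shape[1]},
#' \code{beta_shape[2]}) priors; the default Beta(2,2) keeps the posterior
#' terms in closed factorial form while down-weighting extreme gamma.
#'
#' @param tau Truncation bound of the exponential prior; positive real or
#'   \code{Inf}.
#' @param exp_rate Rate of the exponential prior (default 1).
#' @param beta_shape Length-2 positive numeric, the Beta shape parameters
#'   (default \code{c(2, 2)}).
#' @return An object of class \code{"likelihood_config"}.
#' @export
likelihood_config <- function(tau = Inf, exp_rate = 1, beta_shape = c(2, 2)) {
  stopifnot(is.numeric(tau), length(tau) == 1L, tau > 0,
            is.numeric(exp_rate), length(exp_rate) == 1L, exp_rate > 0,
            is.finite(exp_rate),
            is.numeric(beta_shape), length(beta_shape) == 2L,
            all(beta_shape > 0), all(is.finite(beta_shape)))
  structure(list(tau = tau, exp_rate = exp_rate, beta_shape = beta_shape),
            class = "likelihood_config")
}

# coefficients of the classic lineage-count transition density
# p_uv(t) = sum_{j=v}^{u} exp(-j(j-1)t/2) f(u,v,j), with
# f(u,v,j) = (2j-1)(-1)^(j-v) / (v! (j-v)! (v+j-1)) *
#            prod_{y=0}^{j-1} (v+y)(u-y)/(u+y)
.f_uvj <- function(u, v, j) {
  y <- seq.int(0L, j - 1L)
  pr <- prod((v + y) * (u - y) / (u + y))
  (2 * j - 1) * (-1)^(j - v) /
    (factorial(v) * factorial(j - v) * (v + j - 1)) * pr
}

#' Probability that u lineages coalesce to v within time t
#'
#' The lineage-count transition probability of the coalescent: starting
#' from \code{u} lineages, each pair coalesces at rate 1, and
#' \code{p_uv(u, v, t)} is the probability that exactly \code{v} lineages
#' remain after \code{t} coalescent time units.
#'
#' @param u Integer >= 1, lineages entering.
#' @param v Integer in [1, u], lineages remaining.
#' @param t Nonnegative time in coalescent units (vectorized).
#' @return Probability (same length as \code{t}).
#' @examples
#' p_uv(2, 2, 1)          # exp(-1)
#' p_uv(2, 1, 1)          # 1 - exp(-1)
#' @export
p_uv <- function(u, v, t) {
  .check_uv(u, v)
  if (any(t < 0)) stop("t must be nonnegative")
  js <- seq.int(v, u)
  f <- vapply(js, function(j) .f_uvj(u, v, j), numeric(1))
  out <- vapply(t, function(tt) sum(f * exp(-js * (js - 1) / 2 * tt)),
                numeric(1))
  pmin(pmax(out, 0), 1)
}

.check_uv <- function(u, v) {
  if (!is.numeric(u) || !is.numeric(v) || length(u) != 1L || length(v) != 1L)
    stop("u and v must be scalars")
  if (u < 1 || v < 1 || v > u || u != round(u) || v != round(v))
    stop("require integers 1 <= v <= u")
  invisible(TRUE)
}

#' Lineage transition probability integrated over a branch-length prior
#'
#' Integrates \code{p_uv(u, v, t)} against the (possibly truncated)
#' exponential prior on t: with rate r and truncation tau,
#' \deqn{p^\tau_{uv} = \frac{1}{1-e^{-r\tau}} \sum_{j=v}^{u} f(u,v,j)\,
#'   \frac{r}{j(j-1)/2 + r}\left(1 - e^{-(j(j-1)/2 + r)\tau}\right),}
#' and for \code{tau = Inf} the limit \eqn{\sum_j f(u,v,j)\, r/(j(j-1)/2+r)}.
#'
#' @param u,v Integers with 1 <= v <= u.
#' @param config A \code{\link{likelihood_config}}.
#' @return Probability.
#' @examples
#' p_uv_integrated(2, 2, likelihood_config(tau = Inf))  # 1/2
#' @export
p_uv_integrated <- function(u, v, config = likelihood_config()) {
  .check_uv(u, v)
  stopifnot(inherits(config, "likelihood_config"))
  r <- config$exp_rate
  tau <- config$tau
  js <- seq.int(v, u)
  f <- vapply(js, function(j) .f_uvj(u, v, j), numeric(1))
  rate_j <- js * (js - 1) / 2 + r
  if (is.infinite(tau)) {
    val <- sum(f * r / rate_j)
  } else {
    val <- sum(f * r / rate_j * (1 - exp(-rate_j * tau))) / (1 - exp(-r * tau))
  }
  min(max(val, 0), 1)
}

# per-reticulation u-exponents of a history: entries into b1 and b2 edges
.retic_exponents <- function(h, net) {
  e <- net$edges
  rets <- reticulations(net)
  if (length(rets) == 0L)
    return(data.frame(node = integer(0), u1 = integer(0), u2 = integer(0),
                      b1 = integer(0), b2 = integer(0)))
  u1 <- u2 <- b1 <- b2 <- integer(length(rets))
  for (k in seq_along(rets)) {
    rows <- which(e$child == rets[k])
    b1[k] <- rows[e$is_b1[rows]]
    b2[k] <- rows[!e$is_b1[rows]]
    u1[k] <- h$u[b1[k]]
    u2[k] <- h$u[b2[k]]
  }
  data.frame(node = rets, u1 = u1, u2 = u2, b1 = b1, b2 = b2)
}

#' Probability of one coalescent history given full parameters
#'
#' The probability of a coalescent history on a network with known branch
#' lengths and inheritance probabilities: the product over edges of
#' (w_b/d_b) p_{u_b v_b}(lambda_b), times the root event-order factor
#' w/d, times, for each reticulation i, gamma_i^{u_{b1_i}}
#' (1-gamma_i)^{u_{b2_i}}.  For a species tree the reticulation product is
#' empty.  Accumulated in log space.
#'
#' @param h A \code{coal_history} from \code{\link{enumerate_histories}}.
#' @param net The network it was enumerated on, with all edge lengths set
#'   and, if reticulate, all gamma set.
#' @param log Return the log probability.
#' @return Probability (or its log).
#' @export
history_prob <- function(h, net, log = FALSE) {
  e <- net$edges
  ne <- nrow(e)
  rho <- ne + 1L
  if (any(h$u[seq_len(ne)] > 0 & is.na(e$length)))
    stop("all branch lengths must be set for the fixed-parameter likelihood")
  lp <- 0
  for (b in seq_len(ne)) {
    if (h$u[b] == 0L) next
    lp <- lp + log(h$w[b] / h$d[b]) + log(p_uv(h$u[b], h$v[b], e$length[b]))
  }
  lp <- lp + log(h$w[rho] / h$d[rho])
  rx <- .retic_exponents(h, net)
  if (nrow(rx)) {
    gam <- e$gamma[rx$b1]
    if (any(is.na(gam)))
      stop("all inheritance probabilities must be set for the ",
           "fixed-parameter likelihood")
    lp <- lp + sum(rx$u1 * log(gam) + rx$u2 * log1p(-gam))
    if (any(rx$u1 > 0 & gam == 0) || any(rx$u2 > 0 & gam == 1))
      lp <- -Inf
  }
  if (log) lp else exp(lp)
}

#' Probability of one coalescent history with parameters integrated out
#'
#' Replaces each within-edge factor p_{u_b v_b}(lambda_b) by its integral
#' against the exponential branch-length prior, and each reticulation's
#' gamma factor by its integral against the Beta prior:
#' \eqn{B(a + u_{b1}, b + u_{b2}) / B(a, b)}, which for the default
#' Beta(2,2) is \eqn{6\,(u_{b1}+1)!\,(u_{b2}+1)!/(u_{b1}+u_{b2}+3)!}.
#'
#' @inheritParams history_prob
#' @param config A \code{\link{likelihood_config}}.
#' @return Probability (or its log).
#' @export
history_prob_integrated <- function(h, net, config = likelihood_config(),
                                    log = FALSE) {
  e <- net$edges
  ne <- nrow(e)
  rho <- ne + 1L
  lp <- 0
  for (b in seq_len(ne)) {
    if (h$u[b] == 0L) next
    lp <- lp + log(h$w[b] / h$d[b]) +
      log(p_uv_integrated(h$u[b], h$v[b], config))
  }
  lp <- lp + log(h$w[rho] / h$d[rho])
  rx <- .retic_exponents(h, net)
  if (nrow(rx)) {
    a <- config$beta_shape[1]; bb <- config$beta_shape[2]
    lp <- lp + sum(lbeta(a + rx$u1, bb + rx$u2) - lbeta(a, bb))
  }
  if (log) lp else exp(lp)
}

#' Gene-tree topology probability under the multispecies network coalescent
#'
#' Sums \code{\link{history_prob}} over all coalescent histories of
#' \code{g} within \code{net}.
#'
#' @param g A gene tree (\code{"phylo"}).
#' @param net A fully parameterized \code{phylo_network}.
#' @param log Return the log probability.
#' @return Probability in (0, 1].
#' @examples
#' net <- parse_network("((A:1,B:1):1,C:2);")
#' g <- parse_gene_trees("((A,B),C);")[[1]]
#' gene_tree_prob(g, net)  # 1 - (2/3) * exp(-1)
#' @export
gene_tree_prob <- function(g, net, log = FALSE) {
  hs <- enumerate_histories(g, net)
  lps <- vapply(hs, history_prob, numeric(1), net = net, log = TRUE)
  out <- .logsumexp(lps)
  if (log) out else exp(out)
}

#' Integrated gene-tree topology probability given a topology alone
#'
#' The probability of a gene-tree topology given only the species
#' phylogeny's topology, with branch lengths and inheritance probabilities
#' integrated against their priors: the sum of
#' \code{\link{history_prob_integrated}} over all coalescent histories.
#'
#' @inheritParams gene_tree_prob
#' @param config A \code{\link{likelihood_config}}.
#' @examples
#' net <- parse_network("((A,B),C);")
#' g <- parse_gene_trees("((A,B),C);")[[1]]
#' gene_tree_prob_integrated(g, net)  # 2/3
#' @export
gene_tree_prob_integrated <- function(g, net, config = likelihood_config(),
                                      log = FALSE) {
  key <- paste(canonical_topology(g), canonical_network(net),
               config$tau, config$exp_rate,
               config$beta_shape[1], config$beta_shape[2], sep = "|")
  out <- .ncm_cache[[key]]
  if (is.null(out)) {
    hs <- enumerate_histories(g, net)
    lps <- vapply(hs, history_prob_integrated, numeric(1), net = net,
                  config = config, log = TRUE)
    out <- .logsumexp(lps)
    .ncm_cache[[key]] <- out
  }
  if (log) out else exp(out)
}

# memo cache for topology-keyed quantities (integrated probabilities and
# deep-coalescence costs are pure functions of canonical topologies)
.ncm_cache <- new.env(parent = emptyenv())

.logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Multi-locus integrated log-likelihood of a topology
#'
#' The no-common-mechanism integrated log-likelihood of a species tree or
#' network topology given gene trees for m independent loci: the sum over
#' loci of the log integrated gene-tree probability.  Every locus carries
#' its own (integrated-out) branch lengths and inheritance probabilities,
#' so only the topology of \code{net} matters.  Loci with identical
#' topologies are computed once.
#'
#' @param G List of gene trees (\code{"phylo"} objects), or a character
#'   vector of Newick strings.
#' @param net A \code{phylo_network} (topology only is sufficient).
#' @param config A \code{\link{likelihood_config}}.
#' @return The log-likelihood (<= 0).
#' @examples
#' net <- parse_network("((A,B),C);")
#' G <- parse_gene_trees("((A,B),C);\n((A,C),B);\n((B,C),A);")
#' multilocus_loglik(G, net)  # log(2/3 * 1/6 * 1/6)
#' @export
multilocus_loglik <- function(G, net, config = likelihood_config()) {
  if (is.character(G)) G <- parse_gene_trees(G)
  if (length(G) == 0L) return(0)
  net_labs <- sort(net$labels[!is.na(net$labels)])
  keys <- character(length(G))
  for (i in seq_along(G)) {
    labs <- sort(G[[i]]$tip.label)
    if (length(labs) != length(net_labs) || any(labs != net_labs))
      stop("locus ", i, ": gene-tree leaf labels do not match the network")
    keys[i] <- canonical_topology(G[[i]])
  }
  tab <- table(keys)
  ll <- 0
  for (k in seq_along(tab)) {
    g <- parse_gene_trees(names(tab)[k])[[1]]
    ll <- ll + as.numeric(tab[k]) *
      gene_tree_prob_integrated(g, net, config, log = TRUE)
  }
  ll
}

#' Per-locus integrated log-probabilities
#'
#' @inheritParams multilocus_loglik
#' @return Data frame with columns \code{locus}, \code{topology}
#'   (canonical string) and \code{log_prob}.
#' @export
per_locus_loglik <- function(G, net, config = likelihood_config()) {
  if (is.character(G)) G <- parse_gene_trees(G)
  keys <- vapply(G, canonical_topology, character(1))
  uk <- unique(keys)
  lp <- vapply(uk, function(k)
    gene_tree_prob_integrated(parse_gene_trees(k)[[1]], net, config,
                              log = TRUE), numeric(1))
  data.frame(locus = seq_along(G), topology = keys,
             log_prob = lp[match(keys, uk)], row.names = NULL)
}
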