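# Network-level statistics: the absolute degree difference per edge, the
# selective-constraint edge weight |omega_n - omega_m|, the average network
# weight w, and its two null models (node-weight permutation; degree-
# preserving rewiring).

#' Absolute degree difference of an interacting pair
#'
#' \eqn{\Delta k = |k_1 - k_2|}, the absolute difference of the two
#' members' interaction degrees.
#'
#' @param pair Character vector of two gene identifiers in the network.
#' @param net A [ppi_network()].
#' @return Nonnegative integer.
#' @export
degree_difference <- function(pair, net) {
  stopifnot(length(pair) == 2L)
  k <- net_degree(net, pair)
  abs(k[[1]] - k[[2]])
}

#' Selective-constraint edge weight
#'
#' The edge weight of an interaction is the absolute difference of its two
#' members' whole-alignment \eqn{\omega} values,
#' \eqn{e_{\Delta\omega} = |\omega_n - \omega_m|}: small weights mean
#' similar selective constraint across the interaction.
#'
#' @param pair Character vector of two gene identifiers.
#' @param omegas A [gene_omega()] table containing both genes.
#' @return Nonnegative numeric.
#' @export
edge_constraint_weight <- function(pair, omegas) {
  stopifnot(length(pair) == 2L)
  miss <- setdiff(pair, names(omegas))
  if (length(miss)) stop("gene(s) missing omega: ",
                         paste(miss, collapse = ", "))
  abs(omegas[[pair[1]]] - omegas[[pair[2]]])
}

# rank-sum p; fully tied samples carry no evidence against the null
.np_ranksum_p <- function(x, y) {
  if (length(unique(c(x, y))) < 2L) return(1)
  suppressWarnings(stats::wilcox.test(x, y)$p.value)
}

# edges scorable under a node weight vector; returns index + weight parts
.np_scorable <- function(net, weights) {
  a <- net$edges$a; b <- net$edges$b
  ok <- a %in% names(weights) & b %in% names(weights)
  list(a = a[ok], b = b[ok], n_skipped = sum(!ok))
}

#' Average edge weight of the network
#'
#' \eqn{w = \sum_{e \in E} e / n_E}, the mean of per-edge weights over all
#' scorable edges (edges whose two members both carry a node weight);
#' skipped edges are counted and logged.
#'
#' @param net A [ppi_network()].
#' @param weights Named numeric node weights (e.g. a [gene_omega()] table),
#'   or `NULL` to use node degrees (the degree-difference weighting).
#' @param quiet Suppress the skipped-edge log message.
#' @return List with `w`, `n_edges` (scorable), `n_skipped`.
#' @export
network_weight <- function(net, weights = NULL, quiet = TRUE) {
  if (is.null(weights)) {
    weights <- as.numeric(net$degree)
    names(weights) <- names(net$degree)
  }
  sc <- .np_scorable(net, weights)
  if (length(sc$a) == 0L) stop("no scorable edges")
  if (!quiet && sc$n_skipped > 0L) {
    .np_log("network weight: %d edge(s) skipped for missing node weight",
            sc$n_skipped)
  }
  w <- mean(abs(as.numeric(weights[sc$a]) - as.numeric(weights[sc$b])))
  list(w = w, n_edges = length(sc$a), n_skipped = sc$n_skipped)
}

#' Constraint assortativity of the interaction network
#'
#' Tests whether interacting proteins have more similar selective
#' constraints than expected: the observed average edge weight
#' \eqn{w} (mean \eqn{|\omega_n - \omega_m|} over scorable edges) is
#' compared against `n_perm` random reassignments of the node-weight
#' multiset over the scorable nodes, one-sided for w smaller than null
#' (similar-constraint partners). The scorable subgraph is fixed before
#' permutation so observed and null are computed on the same edge set.
#'
#' @param net A [ppi_network()].
#' @param omegas A [gene_omega()] table.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed; permutation i uses seed + i.
#' @return Object of class `network_weight_test`: list with `weight_id`,
#'   `w`, `null_w`, `null_mean`, `test` ([perm_result()]), `n_edges`,
#'   `n_skipped`.
#' @export
constraint_assortativity_test <- function(net, omegas, n_perm = 10000,
                                          seed = 1L) {
  sc <- .np_scorable(net, omegas)
  if (length(sc$a) == 0L) stop("no scorable edges")
  nodes <- unique(c(sc$a, sc$b))
  wts <- as.numeric(omegas[nodes]); names(wts) <- nodes
  if (length(unique(wts)) < 2L) stop("need at least two distinct omega values")
  ia <- match(sc$a, nodes); ib <- match(sc$b, nodes)
  w_obs <- mean(abs(wts[ia] - wts[ib]))
  null_w <- vapply(seq_len(n_perm), function(i) {
    p <- permute_node_weights(wts, seed = seed + i)
    mean(abs(p[ia] - p[ib]))
  }, numeric(1))
  test <- perm_result(w_obs, null_w, "less", seed,
                      "average |omega| edge weight")
  structure(list(weight_id = "omega-difference", w = w_obs, null_w = null_w,
                 null_mean = mean(null_w), test = test,
                 n_edges = length(sc$a), n_skipped = sc$n_skipped,
                 n_perm = n_perm, seed = seed),
            class = "network_weight_test")
}

#' Degree assortativity against degree-preserving rewiring
#'
#' The network weight with degree-difference edge weights
#' (\eqn{e = |k_n - k_m|}) compared to `n_rewire` degree-preserving
#' rewirings of the network. Reported two-sided with the direction of the
#' deviation: an observed w above the null mean means the real network
#' pairs up nodes of dissimilar degree more than chance (interaction with
#' similar-degree nodes is less likely than null).
#'
#' @param net A [ppi_network()].
#' @param n_rewire Number of rewired replicate networks (default 1000).
#' @param n_swaps_per_edge Attempted swaps per edge per replicate.
#' @param seed Integer seed; replicate i uses seed + i.
#' @return A `network_weight_test` (see
#'   [constraint_assortativity_test()]) with an added `direction_observed`
#'   field (`"above null"` / `"below null"`).
#' @export
degree_assortativity_test <- function(net, n_rewire = 1000,
                                      n_swaps_per_edge = 10, seed = 1L) {
  if (n_edges(net) < 2L) stop("network too small to rewire")
  kw <- as.numeric(net$degree); names(kw) <- names(net$degree)
  w_obs <- network_weight(net, kw)$w
  null_w <- vapply(seq_len(n_rewire), function(i) {
    rn <- rewire_degree_preserving(net, n_swaps_per_edge, seed = seed + i)
    # degrees are preserved, so node weights carry over unchanged
    network_weight(rn, kw)$w
  }, numeric(1))
  test <- perm_result(w_obs, null_w, "two-sided", seed,
                      "average |degree| edge weight")
  structure(list(weight_id = "degree-difference", w = w_obs, null_w = null_w,
                 null_mean = mean(null_w), test = test,
                 n_edges = n_edges(net), n_skipped = 0L,
                 n_perm = n_rewire, seed = seed,
                 direction_observed = if (w_obs >= mean(null_w)) "above null"
                                      else "below null"),
            class = "network_weight_test")
}

#' @export
print.network_weight_test <- function(x, ...) {
  cat(sprintf("Network weight test (%s)\n", x$weight_id))
  cat(sprintf("  observed w = %.4g vs null mean %.4g (n = %d)\n",
              x$w, x$null_mean, x$n_perm))
  cat(sprintf("  empirical P %s (%s)\n", format_p(x$test),
              x$test$direction))
  invisible(x)
}

#' Compare degree distributions of two gene sets
#'
#' Per-set connectivity summaries (min, max, mean degree) and a two-sample
#' Wilcoxon rank-sum test. The sets must be nonempty and disjoint.
#'
#' @param genesA,genesB Character vectors of genes in the network.
#' @param net A [ppi_network()].
#' @return List with `summary` (data frame) and `p` (rank-sum p-value).
#' @export
compare_degree_sets <- function(genesA, genesB, net) {
  if (!length(genesA) || !length(genesB)) stop("empty gene set")
  if (length(intersect(genesA, genesB))) stop("gene sets must be disjoint")
  kA <- as.numeric(net_degree(net, genesA))
  kB <- as.numeric(net_degree(net, genesB))
  p <- .np_ranksum_p(kA, kB)
  list(summary = data.frame(
    set = c("A", "B"), n = c(length(kA), length(kB)),
    k_min = c(min(kA), min(kB)), k_max = c(max(kA), max(kB)),
    k_mean = c(mean(kA), mean(kB)), stringsAsFactors = FALSE), p = p)
}

#' Compare degree-difference distributions of two interaction sets
#'
#' Computes \eqn{\Delta k} for every interaction in each set and compares
#' the distributions with a two-sample Wilcoxon rank-sum test.
#'
#' @param ppisA,ppisB Data frames with columns `a`, `b` (gene pairs).
#' @param net A [ppi_network()] providing the degrees.
#' @return List with `dkA`, `dkB`, `mean_dkA`, `mean_dkB`, `p`.
#' @export
compare_degree_difference_sets <- function(ppisA, ppisB, net) {
  if (!nrow(ppisA) || !nrow(ppisB)) stop("empty interaction set")
  dk <- function(df) {
    abs(as.numeric(net_degree(net, df$a)) - as.numeric(net_degree(net, df$b)))
  }
  dkA <- dk(ppisA); dkB <- dk(ppisB)
  p <- .np_ranksum_p(dkA, dkB)
  list(dkA = dkA, dkB = dkB, mean_dkA = mean(dkA), mean_dkB = mean(dkB),
       p = p)
}
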