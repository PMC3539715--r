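# The three randomization engines behind every hypothesis test in the
# package: degree-proportional pseudo-pair sampling, node-weight
# permutation, and degree-preserving double-edge-swap rewiring. Each takes
# an explicit seed; callers running replicated nulls seed replicate i as
# seed + i, giving replicate-level reproducibility.

#' Sample degree-proportional pseudo-interactions
#'
#' Draws `n_pairs` unordered gene pairs from the network's gene set, each
#' member drawn independently with probability proportional to its degree.
#' Self-pairs, true edges of the network and duplicates within the set are
#' rejected and redrawn, so the result is a set of unique non-interacting
#' pairs mirroring the degree profile of the real edges (the "pseudo-PPI"
#' null used throughout).
#'
#' @param net A [ppi_network()].
#' @param n_pairs Number of pairs required (>= 1).
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param accept Optional vectorized predicate `function(a, b)` returning
#'   which candidate pairs are admissible (used to impose analysis-specific
#'   eligibility such as a minimum number of shared omega branches).
#' @param max_tries Safety cap on rejection-sampling rounds.
#' @return Object of class `pseudo_pairs`: list with `a`, `b` (canonically
#'   ordered members), `n`, `seed`.
#' @export
sample_pseudo_pairs <- function(net, n_pairs, seed = NULL, accept = NULL,
                                max_tries = 2000L) {
  stopifnot(n_pairs >= 1)
  if (!is.null(seed)) set.seed(seed)
  deg <- net$degree
  genes <- names(deg)[deg > 0L]
  w <- as.numeric(deg[genes])
  if (length(genes) < 2L) stop("need at least two connected genes")
  n_avail <- choose(length(genes), 2) - n_edges(net)
  if (is.null(accept) && n_pairs > n_avail) {
    stop(sprintf("requested %d pseudo-pairs but only %d non-edges exist",
                 n_pairs, n_avail))
  }
  edge_keys <- .np_edge_keys(net)
  got_a <- character(0); got_b <- character(0); got_keys <- character(0)
  tries <- 0L
  while (length(got_a) < n_pairs) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("could not assemble the requested pseudo-pair set ",
           "(constraints too tight)")
    }
    need <- n_pairs - length(got_a)
    m <- max(2L * need, 16L)
    ca <- sample(genes, m, replace = TRUE, prob = w)
    cb <- sample(genes, m, replace = TRUE, prob = w)
    ok <- ca != cb
    cp <- .np_canon_pairs(ca[ok], cb[ok])
    key <- .np_pair_key(cp$a, cp$b)
    keep <- !(key %in% edge_keys) & !(key %in% got_keys) & !duplicated(key)
    if (!is.null(accept) && any(keep)) {
      keep[keep] <- accept(cp$a[keep], cp$b[keep])
    }
    if (any(keep)) {
      take <- utils::head(which(keep), need)
      got_a <- c(got_a, cp$a[take])
      got_b <- c(got_b, cp$b[take])
      got_keys <- c(got_keys, key[take])
    }
  }
  structure(list(a = got_a, b = got_b, n = n_pairs,
                 seed = if (is.null(seed)) NA_integer_ else seed),
            class = "pseudo_pairs")
}

#' @export
print.pseudo_pairs <- function(x, ...) {
  cat(sprintf("Pseudo-pair set: %d unique non-interacting pairs\n", x$n))
  invisible(x)
}

#' Permute node weights
#'
#' Uniformly random permutation of a node-weight multiset over the same
#' gene set; the multiset of values is preserved exactly.
#'
#' @param weights Named numeric vector (gene -> value), length >= 2.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @return Named numeric vector over the same genes.
#' @export
permute_node_weights <- function(weights, seed = NULL) {
  if (length(weights) < 2L) stop("need at least two genes to permute")
  if (is.null(names(weights))) stop("weights must be named by gene")
  if (!is.null(seed)) set.seed(seed)
  out <- sample(as.numeric(weights))
  names(out) <- names(weights)
  out
}

#' Degree-preserving network rewiring
#'
#' Randomizes interaction identities by repeated double-edge swaps
#' (edges (a,b),(c,d) become (a,d),(c,b)), rejecting any swap that would
#' create a self-loop or a multi-edge. The per-node degree sequence of the
#' output is identical to the input.
#'
#' @param net A [ppi_network()] with at least 2 edges.
#' @param n_swaps_per_edge Attempted swaps per edge (default 10, a
#'   conventional mixing heuristic); 0 returns the input edge set.
#' @param seed Integer seed (`NULL` to use the current RNG state).
#' @param quiet Suppress the rejection-count log message.
#' @return A rewired `ppi_network`.
#' @export
rewire_degree_preserving <- function(net, n_swaps_per_edge = 10,
                                     seed = NULL, quiet = TRUE) {
  m <- n_edges(net)
  if (m < 2L) stop("need at least two edges to rewire")
  if (!is.null(seed)) set.seed(seed)
  nodes <- net$nodes
  n <- length(nodes)
  # integer-encoded edges with an O(1) membership set keyed (i-1)*n + j
  a <- match(net$edges$a, nodes); b <- match(net$edges$b, nodes)
  swap <- a > b; tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  in_set <- raw(n * n)   # 1 byte per potential edge
  in_set[(a - 1L) * n + b] <- as.raw(1)
  n_attempt <- as.integer(round(n_swaps_per_edge * m))
  rejected <- 0L
  if (n_attempt > 0L) {
    e1s <- sample.int(m, n_attempt, replace = TRUE)
    e2s <- sample.int(m, n_attempt, replace = TRUE)
    flip <- stats::runif(n_attempt) < 0.5
    for (i in seq_len(n_attempt)) {
      e1 <- e1s[i]; e2 <- e2s[i]
      if (e1 == e2) { rejected <- rejected + 1L; next }
      x1 <- a[e1]; y1 <- b[e1]; x2 <- a[e2]; y2 <- b[e2]
      # two possible reconnections; pick one at random
      if (flip[i]) { p1 <- x1; q1 <- y2; p2 <- x2; q2 <- y1 }
      else         { p1 <- x1; q1 <- x2; p2 <- y1; q2 <- y2 }
      if (p1 == q1 || p2 == q2) { rejected <- rejected + 1L; next }
      if (p1 > q1) { t <- p1; p1 <- q1; q1 <- t }
      if (p2 > q2) { t <- p2; p2 <- q2; q2 <- t }
      k1 <- (p1 - 1L) * n + q1; k2 <- (p2 - 1L) * n + q2
      if (k1 == k2 || in_set[k1] != as.raw(0) || in_set[k2] != as.raw(0)) {
        rejected <- rejected + 1L; next
      }
      in_set[(a[e1] - 1L) * n + b[e1]] <- as.raw(0)
      in_set[(a[e2] - 1L) * n + b[e2]] <- as.raw(0)
      in_set[k1] <- as.raw(1); in_set[k2] <- as.raw(1)
      a[e1] <- p1; b[e1] <- q1; a[e2] <- p2; b[e2] <- q2
    }
  }
  if (!quiet) {
    .np_log("rewiring: %d attempted swaps, %d rejected", n_attempt, rejected)
  }
  out <- ppi_network(nodes[a], nodes[b], quiet = TRUE)
  stopifnot(identical(out$degree[names(net$degree)], net$degree))
  out
}
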