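# Gene-set construction and hypergeometric over/under-representation
# analysis against a flat gene -> annotation-term table, with Bonferroni
# correction. Each contrast defines its own universe (members plus the
# explicit complement), not the whole genome.

#' Define the three analysis gene sets
#'
#' * `PrimPresI`: genes in at least one primate-specific interaction
#'   (origin in the primates, human-chimp or human class); complement =
#'   network genes never in such an interaction.
#' * `PrimUniqI`: genes all of whose interactions are primate-specific;
#'   complement = all other network genes.
#' * `AdaptI`: genes in at least one interaction having some branch where
#'   both members' \eqn{\omega} exceeds `threshold`; universe = genes of
#'   interactions for which mirrortrees could be built (both members in
#'   the omega table).
#'
#' @param census An [origin_census()].
#' @param net A [ppi_network()].
#' @param table A [branch_omega()] table (for `AdaptI`).
#' @param threshold Omega threshold for `AdaptI` (default 0.5).
#' @return Named list of three `gene_set` objects, each a list with `id`,
#'   `members`, `complement`.
#' @export
define_gene_sets <- function(census, net, table = NULL, threshold = 0.5) {
  po <- census$pair_origins
  prim_classes <- c("primates", "human-chimp", "human")
  is_prim <- po$origin %in% prim_classes
  prim_genes <- unique(c(po$a[is_prim], po$b[is_prim]))
  nonprim_genes <- unique(c(po$a[!is_prim], po$b[!is_prim]))
  all_genes <- net$nodes
  primpres <- list(id = "PrimPresI", members = sort(prim_genes),
                   complement = sort(setdiff(all_genes, prim_genes)))
  uniq <- sort(setdiff(prim_genes, nonprim_genes))
  primuniq <- list(id = "PrimUniqI", members = uniq,
                   complement = sort(setdiff(all_genes, uniq)))
  out <- list(PrimPresI = structure(primpres, class = "gene_set"),
              PrimUniqI = structure(primuniq, class = "gene_set"))
  if (!is.null(table)) {
    O <- unclass(table)
    a <- po$a; b <- po$b
    in_tab <- a %in% rownames(O) & b %in% rownames(O)
    a <- a[in_tab]; b <- b[in_tab]
    shared <- rowSums(O[a, , drop = FALSE] > threshold &
                        O[b, , drop = FALSE] > threshold, na.rm = TRUE) > 0
    adapt_genes <- unique(c(a[shared], b[shared]))
    universe <- unique(c(a, b))
    out$AdaptI <- structure(
      list(id = "AdaptI", members = sort(adapt_genes),
           complement = sort(setdiff(universe, adapt_genes))),
      class = "gene_set")
  }
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("Gene set %s: %d members vs %d complement genes\n",
              x$id, length(x$members), length(x$complement)))
  invisible(x)
}

#' Read a flat gene-to-term annotation table
#'
#' Two-column TSV (`gene`, `term`); a gene may carry any number of terms.
#'
#' @param path TSV path.
#' @return Data frame with columns `gene`, `term`.
#' @export
read_annotations <- function(path) {
  df <- .np_read_tsv_df(path, c("gene", "term"))
  unique(df)
}

#' Hypergeometric over/under-representation of annotation terms
#'
#' For each term annotating at least one universe gene, computes the
#' observed member count, the universe-proportional expectation and the
#' smaller hypergeometric tail (over- vs under-representation), with an
#' optional Bonferroni correction across the terms tested. Terms
#' annotating zero universe genes are skipped.
#'
#' @param set A `gene_set` (see [define_gene_sets()]); universe = members
#'   plus complement.
#' @param annotations Data frame `gene`, `term` (see [read_annotations()]).
#' @param bonferroni Apply the Bonferroni correction (default `TRUE`;
#'   uncorrected p-values are also reported).
#' @return Data frame of class `enrichment_result`, one row per term:
#'   `term`, `n_annotated`, `observed`, `expected`, `fold`, `direction`,
#'   `p`, `p_adjusted`, sorted by adjusted p.
#' @export
hypergeometric_enrichment <- function(set, annotations, bonferroni = TRUE) {
  if (!length(set$members)) stop("empty study set")
  universe <- c(set$members, set$complement)
  if (anyDuplicated(universe)) stop("members and complement overlap")
  ann <- annotations[annotations$gene %in% universe, , drop = FALSE]
  if (!nrow(ann)) stop("no annotation overlaps the universe")
  N <- length(universe)
  n_set <- length(set$members)
  terms <- sort(unique(ann$term))
  rows <- lapply(terms, function(tm) {
    g <- unique(ann$gene[ann$term == tm])
    K <- length(g)
    x <- sum(g %in% set$members)
    p_over <- stats::phyper(x - 1, K, N - K, n_set, lower.tail = FALSE)
    p_under <- stats::phyper(x, K, N - K, n_set)
    expected <- n_set * K / N
    data.frame(term = tm, n_annotated = K, observed = x,
               expected = expected, fold = x / expected,
               direction = if (p_over <= p_under) "over" else "under",
               p = min(p_over, p_under), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- if (bonferroni) pmin(1, out$p * nrow(out)) else out$p
  out <- out[order(out$p_adjusted, out$p, out$term), ]
  rownames(out) <- NULL
  attr(out, "bonferroni") <- bonferroni
  attr(out, "n_terms") <- nrow(out)
  attr(out, "tail") <- "smaller hypergeometric tail (two-sided assessment)"
  class(out) <- c("enrichment_result", class(out))
  out
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment: %d terms tested (Bonferroni %s)\n",
              attr(x, "n_terms"),
              if (isTRUE(attr(x, "bonferroni"))) "on" else "off"))
  NextMethod()
}
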