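# Constrained-parsimony dating of genes and interactions. The model: a gene
# is defined from the human gene set, appears exactly once on the tree, and
# can only be lost thereafter; the latest branch on the root-to-human path
# consistent with the observed ortholog pattern is its origin. A pair's
# origin is the more recent of its two members' origins.

#' Latest-possible origin branch of a gene
#'
#' Under the single-appearance model the origin is the origin-eligible
#' branch immediately ancestral to the most recent common ancestor of the
#' species carrying the ortholog; an MRCA at (or above) the basal split
#' maps to the root class.
#'
#' @param gene Gene identifier (must be present in human).
#' @param presence A [presence_matrix()].
#' @param phylo A [mammal_phylogeny()] (fixed topology; kept for interface
#'   symmetry).
#' @return One of `np_branches("origin")`.
#' @export
gene_origin_branch <- function(gene, presence, phylo = NULL) {
  unname(gene_origins(presence, gene))
}

#' Vectorized gene origin classes
#'
#' @param presence A [presence_matrix()].
#' @param genes Optional subset of genes (default all).
#' @return Named character vector of origin classes.
#' @export
gene_origins <- function(presence, genes = NULL) {
  if (is.null(genes)) genes <- rownames(presence)
  miss <- setdiff(genes, rownames(presence))
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  m <- unclass(presence)[genes, , drop = FALSE]
  out_euarch <- rowSums(m[, c("horse", "dog", "cow"), drop = FALSE]) > 0
  rodent <- rowSums(m[, c("mouse", "rat"), drop = FALSE]) > 0
  cls <- ifelse(out_euarch, "root",
         ifelse(rodent, "euarchontoglires",
         ifelse(m[, "macaque"] == 1L, "primates",
         ifelse(m[, "chimpanzee"] == 1L, "human-chimp", "human"))))
  names(cls) <- genes
  cls
}

#' Latest-possible origin branch of an interacting pair
#'
#' The younger (closer to human) of the two member genes' origin classes:
#' the pair cannot predate its younger member.
#'
#' @param pair Character vector of two gene identifiers.
#' @inheritParams gene_origin_branch
#' @return One of `np_branches("origin")`.
#' @export
ppi_origin_branch <- function(pair, presence, phylo = NULL) {
  stopifnot(length(pair) == 2L)
  o <- gene_origins(presence, pair)
  np_branches("origin")[max(.np_origin_rank(o))]
}

# vectorized pair origins for an edge list
.np_pair_origins <- function(a, b, presence) {
  genes <- unique(c(a, b))
  o <- .np_origin_rank(gene_origins(presence, genes))
  names(o) <- genes
  np_branches("origin")[pmax(o[a], o[b])]
}

#' Census of interaction origins over the human lineage
#'
#' Places every edge of the network on its latest-possible origin branch
#' and accumulates, for each node on the root-to-human path, the fraction
#' of present-day interactions already present there (necessarily 100% at
#' the human tip).
#'
#' @param net A [ppi_network()].
#' @param presence A [presence_matrix()] covering all network genes.
#' @param phylo A [mammal_phylogeny()].
#' @return Object of class `origin_census`: list with `pair_origins` (data
#'   frame `a`, `b`, `origin`), `counts` (per origin class), `fractions`
#'   (cumulative presence fraction at each lineage node, root to human) and
#'   `n_pairs`.
#' @export
origin_census <- function(net, presence, phylo) {
  if (n_edges(net) == 0L) stop("network has no edges")
  org <- .np_pair_origins(net$edges$a, net$edges$b, presence)
  classes <- np_branches("origin")
  counts <- vapply(classes, function(cl) sum(org == cl), integer(1))
  fr <- cumsum(counts) / n_edges(net)
  structure(list(
    pair_origins = data.frame(a = net$edges$a, b = net$edges$b,
                              origin = org, stringsAsFactors = FALSE),
    counts = counts, fractions = fr, n_pairs = n_edges(net)),
    class = "origin_census")
}

#' @export
print.origin_census <- function(x, ...) {
  cat(sprintf("Origin census of %d interactions\n", x$n_pairs))
  for (cl in names(x$counts)) {
    cat(sprintf("  %-18s %6d new  (%5.1f%% present at node)\n",
                cl, x$counts[[cl]], 100 * x$fractions[[cl]]))
  }
  invisible(x)
}

#' Concerted presence/absence of interaction partners
#'
#' For each non-reference species, counts interactions whose two members
#' are both present (status 4) or both absent (status 0), and tests whether
#' this concordant count exceeds that of degree-matched pseudo-pair sets.
#' An excess indicates that pair membership is linked to gene retention,
#' i.e. that the pairings are selectively meaningful.
#'
#' @param net A [ppi_network()].
#' @param presence A [presence_matrix()].
#' @param n_null Number of pseudo-pair replicate sets (>= 1).
#' @param seed Integer seed; replicate i uses seed + i.
#' @return Object of class `concerted_test`: list with `status_counts`
#'   (species x code matrix for the real pairs), `per_species` (named list
#'   of [perm_result()]), `pooled` ([perm_result()] on the summed
#'   concordant count).
#' @export
concerted_presence_test <- function(net, presence, n_null = 100,
                                    seed = 1L) {
  if (n_null < 1) stop("n_null must be >= 1")
  if (n_edges(net) == 0L) stop("network has no edges")
  species <- setdiff(np_species(), "human")
  obs <- .np_status_table(net$edges$a, net$edges$b, presence, species)
  obs_conc <- obs[, "4"] + obs[, "0"]
  null_conc <- matrix(0, n_null, length(species),
                      dimnames = list(NULL, species))
  for (i in seq_len(n_null)) {
    pp <- sample_pseudo_pairs(net, n_edges(net), seed = seed + i)
    tab <- .np_status_table(pp$a, pp$b, presence, species)
    null_conc[i, ] <- tab[, "4"] + tab[, "0"]
  }
  per_species <- lapply(species, function(s) {
    perm_result(obs_conc[[s]], null_conc[, s], "greater", seed,
                paste0("concordant count (", s, ")"))
  })
  names(per_species) <- species
  pooled <- perm_result(sum(obs_conc), rowSums(null_conc), "greater", seed,
                        "concordant count (pooled)")
  structure(list(status_counts = obs, per_species = per_species,
                 pooled = pooled, n_null = n_null, seed = seed),
            class = "concerted_test")
}

#' @export
print.concerted_test <- function(x, ...) {
  cat("Concerted presence/absence test\n")
  cat(sprintf("  pooled concordant count %d, empirical P %s (n = %d)\n",
              as.integer(x$pooled$observed), format_p(x$pooled), x$n_null))
  invisible(x)
}

.np_status_table <- function(a, b, presence, species) {
  codes <- c("4", "2", "1", "0")
  out <- matrix(0L, length(species), 4, dimnames = list(species, codes))
  m <- unclass(presence)
  for (s in species) {
    p1 <- m[a, s] == 1L
    p2 <- m[b, s] == 1L
    st <- .np_status_code(p1, p2)
    out[s, ] <- c(sum(st == 4L), sum(st == 2L), sum(st == 1L), sum(st == 0L))
  }
  out
}

#' Association between interaction age and partner degree
#'
#' For each origin class, takes the mean present-day degree of all proteins
#' participating in interactions first appearing there (note: not the
#' degree of the genes appearing at that node -- an old hub counts toward a
#' young class if it gained a young partner), and correlates it (Pearson)
#' with branch age measured as cumulative Ks from the human tip to the
#' branch midpoint. Significance comes from re-running the analysis on
#' degree-proportional pseudo-pair networks.
#'
#' @inheritParams concerted_presence_test
#' @param phylo A [mammal_phylogeny()] providing branch ages.
#' @return Object of class `degree_age_test`: list with `table` (class,
#'   age, n pairs, mean degree), `test` (a [perm_result()] on Pearson's r,
#'   direction-aware).
#' @export
degree_age_correlation <- function(net, presence, phylo, n_null = 100,
                                   seed = 1L) {
  obs <- .np_degree_age_stat(net$edges$a, net$edges$b, presence, phylo)
  if (is.na(obs$r)) stop("fewer than 3 origin classes with pairs")
  nulls <- vapply(seq_len(n_null), function(i) {
    pp <- sample_pseudo_pairs(net, n_edges(net), seed = seed + i)
    .np_degree_age_stat(pp$a, pp$b, presence, phylo)$r
  }, numeric(1))
  nulls <- nulls[!is.na(nulls)]
  dir <- if (obs$r >= 0) "greater" else "less"
  test <- perm_result(obs$r, nulls, dir, seed, "degree-age Pearson r")
  structure(list(table = obs$table, test = test), class = "degree_age_test")
}

#' @export
print.degree_age_test <- function(x, ...) {
  cat("Degree vs interaction age\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  Pearson r = %.3f, empirical P %s\n",
              x$test$observed, format_p(x$test)))
  invisible(x)
}

# mean degree per origin class + Pearson r against branch age; degrees are
# computed within the supplied pair set (the analysis is re-run as-is on
# null pair sets)
.np_degree_age_stat <- function(a, b, presence, phylo) {
  org <- .np_pair_origins(a, b, presence)
  deg <- table(c(a, b))
  classes <- np_branches("origin")
  mean_deg <- rep(NA_real_, length(classes)); names(mean_deg) <- classes
  n_pairs <- integer(length(classes)); names(n_pairs) <- classes
  for (cl in classes) {
    sel <- org == cl
    n_pairs[cl] <- sum(sel)
    if (any(sel)) {
      genes <- unique(c(a[sel], b[sel]))
      mean_deg[cl] <- mean(as.numeric(deg[genes]))
    }
  }
  ok <- !is.na(mean_deg)
  r <- if (sum(ok) >= 3) stats::cor(phylo$ages[classes][ok], mean_deg[ok])
       else NA_real_
  list(r = r,
       table = data.frame(class = classes, age = unname(phylo$ages[classes]),
                          n_pairs = unname(n_pairs),
                          mean_degree = unname(mean_deg),
                          stringsAsFactors = FALSE))
}

#' Ks-calibrated interaction loss rate on a calibration stem
#'
#' Loss rates are estimated on shared branches not containing direct
#' ancestors of humans (the mouse-rat and horse-dog stems). A pair is
#' exposed if both members are inferred present at the stem's parent node;
#' a loss event is an exposed pair with at least one member absent from
#' both descendants of the stem (minimal-loss reading: one loss on the
#' stem). The rate is events / exposure / Ks, per interaction per unit Ks.
#'
#' @param branch One of `np_branches("loss")`.
#' @param net A [ppi_network()].
#' @param presence A [presence_matrix()].
#' @param phylo A [mammal_phylogeny()].
#' @return Object of class `rate_estimate`: list with `branch`, `type`,
#'   `events`, `exposure`, `ks`, `rate`.
#' @export
loss_rate <- function(branch, net, presence, phylo) {
  branch <- match.arg(branch, np_branches("loss"))
  ks <- phylo$ks[[branch]]
  if (ks <= 0) stop("loss-calibration branch has zero Ks")
  m <- unclass(presence)
  if (branch == "mouse-rat") {
    # present at the euarchontoglires ancestor: ortholog seen outside primates
    outside <- c("mouse", "rat", "horse", "dog", "cow")
    exposed_gene <- rowSums(m[, outside, drop = FALSE]) > 0
    lost_gene <- rowSums(m[, c("mouse", "rat"), drop = FALSE]) == 0
  } else {
    # present at the horse-dog-cow ancestor: some tip below it carries it
    exposed_gene <- rowSums(m[, c("horse", "dog", "cow"), drop = FALSE]) > 0
    lost_gene <- rowSums(m[, c("horse", "dog"), drop = FALSE]) == 0
  }
  names(exposed_gene) <- rownames(m); names(lost_gene) <- rownames(m)
  a <- net$edges$a; b <- net$edges$b
  exposed <- exposed_gene[a] & exposed_gene[b]
  events <- exposed & (lost_gene[a] | lost_gene[b])
  if (sum(exposed) == 0L) stop("no pairs exposed on branch ", branch)
  structure(list(branch = branch, type = "loss",
                 events = sum(events), exposure = sum(exposed),
                 ks = ks, rate = sum(events) / sum(exposed) / ks),
            class = "rate_estimate")
}

#' Ks-calibrated interaction gain rate on an origin branch
#'
#' Events are pairs whose latest-possible origin lies on the branch;
#' exposure is the number of pairs present at the branch's child node
#' (which includes the events themselves). The rate is
#' events / exposure / Ks.
#'
#' @param branch One of `np_branches("origin")`.
#' @param census An [origin_census()].
#' @param phylo A [mammal_phylogeny()].
#' @return A `rate_estimate` (see [loss_rate()]).
#' @export
gain_rate <- function(branch, census, phylo) {
  branch <- match.arg(branch, np_branches("origin"))
  ks <- phylo$ks[[branch]]
  if (ks <= 0) stop("origin branch has zero Ks")
  rk <- .np_origin_rank(branch)
  events <- census$counts[[branch]]
  exposure <- sum(census$counts[seq_len(rk)])
  if (exposure == 0L) stop("no pairs present at the child node of ", branch)
  structure(list(branch = branch, type = "gain",
                 events = events, exposure = exposure,
                 ks = ks, rate = events / exposure / ks),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("%s rate on %s: %d events / %d exposed / Ks %.4f = %.4g per PPI per unit Ks\n",
              x$type, x$branch, x$events, x$exposure, x$ks, x$rate))
  invisible(x)
}

#' Steady-state correction of the root presence fraction
#'
#' Under a steady-state network (edge count neither growing nor shrinking),
#' the gain rate per unit Ks should equal the loss rate per unit Ks, so a
#' loss rate estimated on a calibration stem doubles as an estimate of the
#' true gain rate on the lineage branches. The expected number of gains it
#' implies, \eqn{\sum_i g N_i Ks_i} over the five lineage branches
#' (\eqn{N_i} = pairs present at branch i's child node), is expressed as a
#' fraction of all pairs and the raw root-presence fraction is discounted
#' by it: corrected = raw x max(0, 1 - sum / N_total). With g = 0 the raw
#' fraction is returned unchanged.
#'
#' @param g Assumed true gain rate per PPI per unit Ks (a number or a
#'   `rate_estimate`).
#' @param census An [origin_census()].
#' @param phylo A [mammal_phylogeny()].
#' @return Object of class `steady_state`: list with `raw`, `corrected`,
#'   `g`, `expected_gains`, `per_branch` (data frame), and `method`
#'   metadata (linear discount; exposure at the child node).
#' @export
steady_state_correction <- function(g, census, phylo) {
  if (inherits(g, "rate_estimate")) g <- g$rate
  if (g < 0) stop("gain rate must be nonnegative")
  classes <- np_branches("origin")
  n_child <- cumsum(census$counts)          # pairs present at child node
  ks <- vapply(classes, function(cl) phylo$ks[[cl]], numeric(1))
  exp_gain <- g * n_child * ks
  raw <- unname(census$fractions[["root"]])
  corrected <- raw * max(0, 1 - sum(exp_gain) / census$n_pairs)
  structure(list(raw = raw, corrected = corrected, g = g,
                 expected_gains = sum(exp_gain),
                 per_branch = data.frame(class = classes,
                                         n_child = unname(n_child),
                                         ks = unname(ks),
                                         expected_gain = unname(exp_gain),
                                         stringsAsFactors = FALSE),
                 method = "linear discount; child-node exposure"),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(paste0("Steady-state correction (g = %.4g): raw root fraction ",
                     "%.1f%% -> corrected %.1f%%\n"),
              x$g, 100 * x$raw, 100 * x$corrected))
  invisible(x)
}
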