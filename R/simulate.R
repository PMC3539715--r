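# Synthetic-data generator. Produces complete, internally consistent input
# sets with the statistical structure the analyses assume -- gene birth on
# the human lineage with Ks-proportional ortholog loss, a heavy-tailed
# interactome, branch-wise omega with a planted pairwise rank correlation
# for interacting pairs, and global omega with planted edge assortativity
# -- recording every planted parameter for recovery testing.

#' Simulation configuration
#'
#' Returns the default simulation settings, overridable by name. Defaults
#' describe a reduced-scale mammalian interactome: a few hundred genes,
#' heavy-tailed degrees, overwhelmingly ancient gene origins with a small
#' recent fraction, and moderate Ks-proportional ortholog loss.
#'
#' @param ... Named overrides of any default.
#' @return List of class `sim_config`.
#' @export
np_sim_config <- function(...) {
  cfg <- list(
    seed = 1L,
    n_genes = 600L,
    mean_degree = 5,
    degree_exponent = 3,          # Pareto tail of the degree weights
    degree_sequence = NULL,       # optional exact degree sequence
    origin_probs = c(root = 0.95, euarchontoglires = 0.015,
                     primates = 0.012, `human-chimp` = 0.008, human = 0.015),
    loss_rate = 0.2,              # ortholog losses per branch per unit Ks
    age_degree_coupling = 2,      # >0 couples hub status to gene age
    coevo_rho = 0.3,              # target pairwise Spearman rho
    coevo_fraction = 0.5,         # fraction of edges carrying the signal
    coevo_branches = NULL,        # NULL = all 13 branches
    omega_gene_coverage = 0.85,   # genes with a usable branch-omega vector
    omega_missing = 0.05,         # per-cell missingness in the omega table
    omega_bulk_meanlog = log(0.15),
    omega_bulk_sdlog = 0.8,
    omega_p1 = 0.08,              # marginal mass above omega = 1
    omega_p5 = 0.01,              # marginal mass at or above omega = 5
    assortativity = 0.6,          # neighbour-smoothing strength s in [0,1]
    n_terms = 12L,                # annotation vocabulary size
    ks = c(human = 0.012, chimpanzee = 0.012, `human-chimp` = 0.02,
           macaque = 0.06, primates = 0.05, mouse = 0.16, rat = 0.16,
           `mouse-rat` = 0.18, euarchontoglires = 0.17, horse = 0.11,
           dog = 0.12, `horse-dog` = 0.09, cow = 0.17,
           laurasiatheria = 0.17)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ",
                        paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  if (abs(sum(cfg$origin_probs) - 1) > 1e-8) {
    stop("origin probabilities must sum to 1")
  }
  if (cfg$loss_rate < 0) stop("loss rate must be nonnegative")
  if (abs(cfg$coevo_rho) >= 1) stop("planted rho must lie in (-1, 1)")
  if (cfg$assortativity < 0 || cfg$assortativity > 1) {
    stop("assortativity strength must lie in [0, 1]")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate the calibrated phylogeny
#'
#' The fixed eight-mammal topology with the configured per-branch Ks.
#'
#' @param config A [np_sim_config()].
#' @return A [mammal_phylogeny()].
#' @export
simulate_phylogeny <- function(config = np_sim_config()) {
  if (any(config$ks <= 0)) stop("configured Ks must be positive")
  mammal_phylogeny(config$ks)
}

#' Sample gene origin classes
#'
#' @param config A [np_sim_config()].
#' @param seed Integer seed.
#' @return Named character vector (gene id -> origin class).
#' @export
simulate_gene_origins <- function(config = np_sim_config(),
                                  seed = config$seed) {
  set.seed(seed)
  genes <- sprintf("g%05d", seq_len(config$n_genes))
  cls <- sample(names(config$origin_probs), config$n_genes, replace = TRUE,
                prob = config$origin_probs)
  names(cls) <- genes
  cls
}

#' Simulate ortholog presence under Ks-proportional loss
#'
#' Each gene appears once on its origin branch and is present in every tip
#' of the origin clade unless lost: along every rooted branch below the
#' origin, the ortholog is lost with probability \eqn{1 - e^{-\lambda Ks}}
#' and losses are inherited by the whole subtree. Branches on the path to
#' the human tip are loss-protected (the gene universe is conditioned on
#' presence in human).
#'
#' @param phylo A [mammal_phylogeny()].
#' @param origins Named origin-class vector (see [simulate_gene_origins()]).
#' @param lambda Loss rate per branch per unit Ks (>= 0).
#' @param seed Integer seed.
#' @return List with `presence` (a [presence_matrix()]) and `losses` (data
#'   frame `gene`, `branch` of drawn loss events).
#' @export
simulate_presence <- function(phylo, origins, lambda, seed = 1L) {
  if (lambda < 0) stop("lambda must be nonnegative")
  set.seed(seed)
  genes <- names(origins)
  sp <- np_species()
  mat <- matrix(0L, length(genes), length(sp), dimnames = list(genes, sp))
  loss_gene <- character(0); loss_branch <- character(0)
  for (cl in unique(origins)) {
    g <- genes[origins == cl]
    clade <- .np_origin_clade(cl)
    mat[g, clade] <- 1L
    branches <- setdiff(.np_branches_below(cl), .np_human_path_below(cl))
    if (lambda > 0 && length(branches)) {
      p_loss <- 1 - exp(-lambda * vapply(branches, function(b)
        phylo$ks[[b]], numeric(1)))
      loss <- matrix(stats::runif(length(g) * length(branches)) <
                       rep(p_loss, each = length(g)),
                     nrow = length(g),
                     dimnames = list(g, branches))
      for (b in branches) {
        hit <- rownames(loss)[loss[, b]]
        if (length(hit)) {
          mat[hit, .np_branch_tips[[b]]] <- 0L
          loss_gene <- c(loss_gene, hit)
          loss_branch <- c(loss_branch, rep(b, length(hit)))
        }
      }
    }
  }
  mat[, "human"] <- 1L
  list(presence = presence_matrix(mat),
       losses = data.frame(gene = loss_gene, branch = loss_branch,
                           stringsAsFactors = FALSE))
}

# Havel-Hakimi construction of a simple graph with an exact degree
# sequence; errors if the sequence is not graphical.
.np_havel_hakimi <- function(deg) {
  n <- length(deg)
  if (sum(deg) %% 2 != 0) stop("infeasible degree sequence (odd sum)")
  res <- as.integer(deg)
  ea <- integer(0); eb <- integer(0)
  repeat {
    ord <- order(res, decreasing = TRUE)
    v <- ord[1]
    d <- res[v]
    if (d == 0L) break
    if (d > n - 1L) stop("infeasible degree sequence")
    targets <- ord[-1][seq_len(d)]
    if (anyNA(targets) || any(res[targets] == 0L)) {
      stop("infeasible degree sequence")
    }
    ea <- c(ea, rep(v, d)); eb <- c(eb, targets)
    res[v] <- 0L
    res[targets] <- res[targets] - 1L
  }
  cbind(ea, eb)
}

#' Simulate a heavy-tailed interaction network
#'
#' Draws per-gene fitness weights with a Pareto tail (exponent
#' `degree_exponent`) and samples edges with endpoint probabilities
#' proportional to fitness, rejecting self-loops and duplicates -- a
#' heavy-tailed simple graph. With `age_degree_coupling > 0` and origins
#' supplied, fitness is inflated for older genes, coupling hub status to
#' gene age. A fixed `degree_sequence` is instead realized exactly
#' (Havel-Hakimi construction followed by degree-preserving rewiring).
#'
#' @param config A [np_sim_config()].
#' @param origins Optional named origin-class vector for age coupling.
#' @param seed Integer seed.
#' @return A [ppi_network()] over the configured genes (genes left without
#'   any edge do not appear as nodes).
#' @export
simulate_network <- function(config = np_sim_config(), origins = NULL,
                             seed = config$seed) {
  set.seed(seed)
  genes <- if (!is.null(origins)) names(origins)
           else sprintf("g%05d", seq_len(config$n_genes))
  if (!is.null(config$degree_sequence)) {
    deg <- config$degree_sequence
    stopifnot(length(deg) == length(genes))
    ed <- .np_havel_hakimi(deg)
    net <- ppi_network(genes[ed[, 1]], genes[ed[, 2]], quiet = TRUE)
    net <- rewire_degree_preserving(net, 10)
    return(net)
  }
  n <- length(genes)
  gamma <- config$degree_exponent
  w <- stats::runif(n)^(-1 / (gamma - 1))     # Pareto(1, gamma - 1)
  w <- pmin(w, n / 4)                          # cap extreme hubs
  coupling <- if (!is.null(origins)) config$age_degree_coupling else 0
  p_within <- 1 - exp(-coupling)
  if (coupling > 0) {
    # hubs skew ancient (weight inflated with age), and a fraction
    # 1 - exp(-coupling) of each gene's interactions stay within its own
    # origin cohort, so interactions dating to young branches connect
    # young, sparsely-connected genes rather than borrowing old hubs
    oldness <- 1 - (.np_origin_rank(origins) - 1) / 4   # root 1 .. human 0
    w <- w * exp(coupling * oldness)
    class_members <- split(seq_len(n), origins)
  }
  m_target <- round(n * config$mean_degree / 2)
  got_a <- character(0); got_b <- character(0); keys <- character(0)
  tries <- 0L
  while (length(got_a) < m_target) {
    tries <- tries + 1L
    if (tries > 500L) stop("could not realize the requested edge count")
    need <- m_target - length(got_a)
    nc <- 2L * need + 8L
    ia <- sample.int(n, nc, replace = TRUE, prob = w)
    ib <- sample.int(n, nc, replace = TRUE, prob = w)
    if (coupling > 0) {
      within <- stats::runif(nc) < p_within
      for (cl in names(class_members)) {
        pool <- class_members[[cl]]
        sel <- which(within & origins[ia] == cl)
        if (length(sel) && length(pool) > 1L) {
          ib[sel] <- pool[sample.int(length(pool), length(sel),
                                     replace = TRUE, prob = w[pool])]
        }
      }
    }
    ca <- genes[ia]; cb <- genes[ib]
    ok <- ca != cb
    cp <- .np_canon_pairs(ca[ok], cb[ok])
    key <- .np_pair_key(cp$a, cp$b)
    keep <- !(key %in% keys) & !duplicated(key)
    take <- utils::head(which(keep), need)
    got_a <- c(got_a, cp$a[take]); got_b <- c(got_b, cp$b[take])
    keys <- c(keys, key[take])
  }
  ppi_network(got_a, got_b, quiet = TRUE)
}

# Monotone quantile function of the omega marginal: a lognormal bulk below
# 1, a uniform shoulder on [1, 5), and an exponential tail above 5, with
# configurable tail masses p1 (above 1) and p5 (at or above 5).
.np_omega_quantile <- function(u, meanlog, sdlog, p1, p5) {
  stopifnot(p1 >= p5, p1 < 1)
  m0 <- 1 - p1
  out <- numeric(length(u))
  lo <- u <= m0
  pl1 <- stats::plnorm(1, meanlog, sdlog)
  out[lo] <- stats::qlnorm(u[lo] / m0 * pl1, meanlog, sdlog)
  mid <- u > m0 & u <= 1 - p5
  if (p1 > p5) out[mid] <- 1 + 4 * (u[mid] - m0) / (p1 - p5)
  hi <- u > 1 - p5
  out[hi] <- 5 * exp((u[hi] - (1 - p5)) / max(p5, 1e-12))
  out
}

#' Simulate branch-wise selective constraints with planted co-evolution
#'
#' Every covered gene receives an \eqn{\omega} value per branch, drawn
#' through a Gaussian copula and a fixed monotone marginal transform
#' (right-skewed bulk near 0.1-0.3 plus configurable spike masses above 1
#' and 5). A disjoint matching of edges covering `coevo_fraction` of the
#' network is flagged: on the configured signal branches the two members'
#' latent normals are correlated at \eqn{r = 2\sin(\pi\rho^*/6)}, which
#' makes their population Spearman correlation exactly \eqn{\rho^*}
#' (monotone transforms preserve rank correlations). All other values are
#' independent.
#'
#' @param net A [ppi_network()].
#' @param phylo A [mammal_phylogeny()] (interface symmetry).
#' @param config A [np_sim_config()].
#' @param seed Integer seed.
#' @return List with `table` (a [branch_omega()]), `flagged` (data frame
#'   `a`, `b` of signal pairs), `latent_r` (the copula correlation) and
#'   `branches` (the signal branches).
#' @export
simulate_branch_omega <- function(net, phylo, config = np_sim_config(),
                                  seed = config$seed) {
  set.seed(seed)
  branches <- np_branches("omega")
  sig_branches <- if (is.null(config$coevo_branches)) branches
                  else intersect(branches, config$coevo_branches)
  genes <- net$nodes
  covered <- genes[stats::runif(length(genes)) < config$omega_gene_coverage]
  if (length(covered) < 2L) stop("omega coverage left fewer than two genes")
  Z <- matrix(stats::rnorm(length(covered) * length(branches)),
              nrow = length(covered), dimnames = list(covered, branches))
  # flag a disjoint matching of edges among covered genes
  el <- net$edges[net$edges$a %in% covered & net$edges$b %in% covered, ]
  el <- el[sample.int(nrow(el)), , drop = FALSE]
  n_flag <- round(config$coevo_fraction * nrow(el))
  used <- character(0); fa <- character(0); fb <- character(0)
  for (i in seq_len(nrow(el))) {
    if (length(fa) >= n_flag) break
    if (el$a[i] %in% used || el$b[i] %in% used) next
    fa <- c(fa, el$a[i]); fb <- c(fb, el$b[i])
    used <- c(used, el$a[i], el$b[i])
  }
  r <- 2 * sin(pi * config$coevo_rho / 6)
  if (length(fa) && length(sig_branches) && r != 0) {
    eps <- matrix(stats::rnorm(length(fa) * length(sig_branches)),
                  nrow = length(fa))
    Z[fb, sig_branches] <- r * Z[fa, sig_branches] + sqrt(1 - r^2) * eps
  }
  O <- .np_omega_quantile(stats::pnorm(Z), config$omega_bulk_meanlog,
                          config$omega_bulk_sdlog, config$omega_p1,
                          config$omega_p5)
  dim(O) <- dim(Z); dimnames(O) <- dimnames(Z)
  if (config$omega_missing > 0) {
    O[stats::runif(length(O)) < config$omega_missing] <- NA_real_
  }
  idx <- which(!is.na(O), arr.ind = TRUE)
  tab <- branch_omega(rownames(O)[idx[, 1]], colnames(O)[idx[, 2]], O[idx])
  list(table = tab,
       flagged = data.frame(a = fa, b = fb, stringsAsFactors = FALSE),
       latent_r = r, branches = sig_branches)
}

#' Simulate global selective constraints with planted assortativity
#'
#' Draws a latent standard-normal constraint per gene, blends it with the
#' mean latent value of the gene's closed neighbourhood at strength `s`
#' (`assortativity`), and maps the standardized blend through the omega
#' marginal. `s = 0` yields topology-independent constraints; `s = 1` on a
#' clique gives all members an identical value.
#'
#' @param net A [ppi_network()].
#' @param config A [np_sim_config()].
#' @param seed Integer seed.
#' @return List with `table` (a [gene_omega()]), `latent` (named numeric)
#'   and `s`.
#' @export
simulate_global_omega <- function(net, config = np_sim_config(),
                                  seed = config$seed) {
  set.seed(seed)
  genes <- net$nodes
  x <- stats::rnorm(length(genes)); names(x) <- genes
  s <- config$assortativity
  nb_sum <- numeric(length(genes)); names(nb_sum) <- genes
  nb_n <- integer(length(genes)); names(nb_n) <- genes
  for (col in c("a", "b")) {
    other <- if (col == "a") "b" else "a"
    add <- tapply(x[net$edges[[other]]], net$edges[[col]], sum)
    nb_sum[names(add)] <- nb_sum[names(add)] + add
    cnt <- table(net$edges[[col]])
    nb_n[names(cnt)] <- nb_n[names(cnt)] + as.integer(cnt)
  }
  closed_mean <- (nb_sum + x) / (nb_n + 1)
  blend <- (1 - s) * x + s * closed_mean
  sdv <- stats::sd(blend)
  # a numerically constant blend (e.g. s = 1 on a clique) maps to one value
  u <- if (isTRUE(sdv > 1e-10)) stats::pnorm((blend - mean(blend)) / sdv)
       else rep(0.5, length(blend))
  omega <- .np_omega_quantile(u, config$omega_bulk_meanlog,
                              config$omega_bulk_sdlog, config$omega_p1,
                              config$omega_p5)
  list(table = gene_omega(genes, omega), latent = x, s = s)
}

#' Simulate a flat annotation table
#'
#' Terms with geometrically declining base frequencies; the first term is
#' planted at three-fold frequency among genes with a primate-or-younger
#' origin so downstream enrichment has a recoverable signal.
#'
#' @param origins Named origin-class vector.
#' @param config A [np_sim_config()].
#' @param seed Integer seed.
#' @return Data frame `gene`, `term`.
#' @export
simulate_annotations <- function(origins, config = np_sim_config(),
                                 seed = config$seed) {
  set.seed(seed)
  genes <- names(origins)
  terms <- sprintf("T%02d", seq_len(config$n_terms))
  base <- 0.3 * 0.8^(seq_len(config$n_terms) - 1)
  young <- .np_origin_rank(origins) >= .np_origin_rank("primates")
  gl <- character(0); tl <- character(0)
  for (j in seq_along(terms)) {
    p <- rep(base[j], length(genes))
    if (j == 1L) p[young] <- pmin(1, 3 * p[young])
    hit <- stats::runif(length(genes)) < p
    gl <- c(gl, genes[hit]); tl <- c(tl, rep(terms[j], sum(hit)))
  }
  data.frame(gene = gl, term = tl, stringsAsFactors = FALSE)
}

#' Write a complete synthetic study fixture
#'
#' Generates an internally consistent input set (edge list, presence
#' matrix, Newick tree, branch roles, branch and global omega tables,
#' annotations) plus machine-readable ground truth, deterministic under
#' the configured seed.
#'
#' @param config A [np_sim_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisibly, a list with all generated in-memory objects and the
#'   file paths.
#' @export
make_study_fixture <- function(config = np_sim_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  phylo <- simulate_phylogeny(config)
  origins <- simulate_gene_origins(config, seed = config$seed)
  net <- simulate_network(config, origins, seed = config$seed + 1L)
  pres <- simulate_presence(phylo, origins, config$loss_rate,
                            seed = config$seed + 2L)
  bo <- simulate_branch_omega(net, phylo, config, seed = config$seed + 3L)
  go <- simulate_global_omega(net, config, seed = config$seed + 4L)
  ann <- simulate_annotations(origins, config, seed = config$seed + 5L)
  fp <- function(f) file.path(outdir, f)
  write_network(net, fp("network.tsv"))
  write_presence_matrix(pres$presence, fp("presence.tsv"))
  write_phylogeny(phylo, fp("tree.nwk"))
  write_branch_roles(np_default_roles(), fp("branch_roles.tsv"))
  write_branch_omega(bo$table, fp("branch_omega.tsv"))
  write_gene_omega(go$table, fp("gene_omega.tsv"))
  utils::write.table(ann, fp("annotations.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(gene = names(origins), origin = unname(origins),
               stringsAsFactors = FALSE),
    fp("truth_origins.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(pres$losses, fp("truth_losses.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(bo$flagged, fp("truth_coevolution_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(seed = config$seed, n_genes = config$n_genes,
                loss_rate = config$loss_rate,
                origin_probs = as.list(config$origin_probs),
                coevo_rho = config$coevo_rho, latent_r = bo$latent_r,
                coevo_branches = bo$branches,
                assortativity = go$s)
  yaml::write_yaml(truth, fp("truth_params.yaml"))
  invisible(list(phylo = phylo, origins = origins, net = net,
                 presence = pres$presence, losses = pres$losses,
                 branch_omega = bo, gene_omega = go, annotations = ann,
                 files = list.files(outdir, full.names = TRUE)))
}
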