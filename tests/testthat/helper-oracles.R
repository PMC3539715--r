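# Independent oracles used to freeze expected values. These deliberately
# re-derive everything from first principles (their own topology encoding,
# brute-force enumeration, closed forms) and never call the package
# internals they check.

# --- eight-mammal topology, encoded independently ------------------------
oracle_children <- list(
  root = c("euarchN", "laurN"),
  euarchN = c("primN", "mrN"),
  primN = c("hcN", "macaque"),
  hcN = c("human", "chimpanzee"),
  mrN = c("mouse", "rat"),
  laurN = c("hdN", "cow"),
  hdN = c("horse", "dog")
)
oracle_tips <- c("human", "chimpanzee", "macaque", "mouse", "rat",
                 "horse", "dog", "cow")
# origin placement (node whose subtree the gene occupies) -> class label
oracle_origin_nodes <- c(human = "human", hcN = "human-chimp",
                         primN = "primates", euarchN = "euarchontoglires",
                         root = "root")

oracle_descendant_nodes <- function(node) {
  if (is.null(oracle_children[[node]])) return(character(0))
  kids <- oracle_children[[node]]
  c(kids, unlist(lapply(kids, oracle_descendant_nodes), use.names = FALSE))
}

oracle_reachable_tips <- function(node, lost) {
  if (is.null(oracle_children[[node]])) return(node)
  out <- character(0)
  for (ch in oracle_children[[node]]) {
    if (!(ch %in% lost)) out <- c(out, oracle_reachable_tips(ch, lost))
  }
  out
}

# Enumerate every loss subset below each origin placement and collect the
# achievable presence patterns (patterns that retain human). Returns a
# list origin class -> set of pattern keys.
oracle_achievable_patterns <- function() {
  out <- list()
  for (node in names(oracle_origin_nodes)) {
    edges <- oracle_descendant_nodes(node)
    pats <- character(0)
    for (mask in 0:(2^length(edges) - 1)) {
      lost <- edges[bitwAnd(mask, 2^(seq_along(edges) - 1)) > 0]
      tips <- oracle_reachable_tips(node, lost)
      if ("human" %in% tips) {
        pats <- c(pats, paste(sort(tips), collapse = ","))
      }
    }
    out[[oracle_origin_nodes[[node]]]] <- unique(pats)
  }
  out
}

# cache: the enumeration is only done once per test run
.oracle_patterns <- NULL
oracle_gene_origin <- function(present_species) {
  if (is.null(.oracle_patterns)) {
    .oracle_patterns <<- oracle_achievable_patterns()
  }
  key <- paste(sort(present_species), collapse = ",")
  # youngest-first scan for the latest feasible single-appearance origin
  for (cl in c("human", "human-chimp", "primates", "euarchontoglires",
               "root")) {
    if (key %in% .oracle_patterns[[cl]]) return(cl)
  }
  stop("pattern not achievable under the single-appearance model: ", key)
}

oracle_pair_origin <- function(origin_a, origin_b) {
  ord <- c("root", "euarchontoglires", "primates", "human-chimp", "human")
  ord[max(match(origin_a, ord), match(origin_b, ord))]
}

# --- exact per-gene probabilities under the loss model -------------------
# For one origin class, enumerate every loss configuration over the
# non-protected branches (branch loss prob 1 - exp(-lambda * ks)) and
# accumulate the probabilities of: each inferred origin class, being
# exposed/lost on the two calibration stems.
oracle_class_probs <- function(origin_class, lambda, ks) {
  node <- names(oracle_origin_nodes)[oracle_origin_nodes == origin_class]
  protected <- list(root = c("euarchN", "primN", "hcN", "human"),
                    euarchontoglires = c("primN", "hcN", "human"),
                    primates = c("hcN", "human"),
                    `human-chimp` = "human",
                    human = character(0))[[origin_class]]
  edges <- setdiff(oracle_descendant_nodes(node), protected)
  # branch Ks keyed by the child node the edge subtends
  edge_ks <- c(human = ks[["human"]], chimpanzee = ks[["chimpanzee"]],
               hcN = ks[["human-chimp"]], macaque = ks[["macaque"]],
               primN = ks[["primates"]], mouse = ks[["mouse"]],
               rat = ks[["rat"]], mrN = ks[["mouse-rat"]],
               euarchN = ks[["euarchontoglires"]], horse = ks[["horse"]],
               dog = ks[["dog"]], hdN = ks[["horse-dog"]],
               cow = ks[["cow"]], laurN = ks[["laurasiatheria"]])
  p_loss <- 1 - exp(-lambda * edge_ks[edges])
  acc <- list(inferred = c(root = 0, euarchontoglires = 0, primates = 0,
                           `human-chimp` = 0, human = 0),
              exp_mr = 0, explost_mr = 0, exp_hd = 0, explost_hd = 0)
  n_e <- length(edges)
  for (mask in 0:(2^max(n_e, 0) - 1)) {
    sel <- if (n_e) bitwAnd(mask, 2^(seq_len(n_e) - 1)) > 0 else logical(0)
    pr <- prod(ifelse(sel, p_loss, 1 - p_loss))
    tips <- oracle_reachable_tips(node, edges[sel])
    inf_cl <- if (any(c("horse", "dog", "cow") %in% tips)) "root"
      else if (any(c("mouse", "rat") %in% tips)) "euarchontoglires"
      else if ("macaque" %in% tips) "primates"
      else if ("chimpanzee" %in% tips) "human-chimp" else "human"
    acc$inferred[[inf_cl]] <- acc$inferred[[inf_cl]] + pr
    exp_mr <- any(c("mouse", "rat", "horse", "dog", "cow") %in% tips)
    lost_mr <- !any(c("mouse", "rat") %in% tips)
    exp_hd <- any(c("horse", "dog", "cow") %in% tips)
    lost_hd <- !any(c("horse", "dog") %in% tips)
    acc$exp_mr <- acc$exp_mr + pr * exp_mr
    acc$explost_mr <- acc$explost_mr + pr * (exp_mr && lost_mr)
    acc$exp_hd <- acc$exp_hd + pr * exp_hd
    acc$explost_hd <- acc$explost_hd + pr * (exp_hd && lost_hd)
  }
  acc
}

# Expected loss and gain rates for a network whose endpoints draw their
# origin class from `probs` independently of topology.
oracle_expected_rates <- function(probs, lambda, ks) {
  per_class <- lapply(names(probs), oracle_class_probs, lambda = lambda,
                      ks = ks)
  names(per_class) <- names(probs)
  wsum <- function(field) {
    sum(vapply(names(probs), function(cl) {
      probs[[cl]] * per_class[[cl]][[field]]
    }, numeric(1)))
  }
  e_mr <- wsum("exp_mr"); el_mr <- wsum("explost_mr")
  e_hd <- wsum("exp_hd"); el_hd <- wsum("explost_hd")
  loss_mr <- (e_mr^2 - (e_mr - el_mr)^2) / e_mr^2 / ks[["mouse-rat"]]
  loss_hd <- (e_hd^2 - (e_hd - el_hd)^2) / e_hd^2 / ks[["horse-dog"]]
  inf <- Reduce(`+`, lapply(names(probs), function(cl) {
    probs[[cl]] * per_class[[cl]]$inferred
  }))
  ord <- c("root", "euarchontoglires", "primates", "human-chimp", "human")
  # a pair's inferred class is the younger of two independent genes', so
  # the pair-level cumulative probabilities are the squared gene-level ones
  cum2 <- cumsum(inf[ord])^2
  gain <- vapply(2:5, function(i) {
    (cum2[[i]] - cum2[[i - 1]]) / cum2[[i]] / ks[[ord[i]]]
  }, numeric(1))
  names(gain) <- ord[2:5]
  list(loss_mr = loss_mr, loss_hd = loss_hd, gain = gain,
       inferred = inf[ord])
}

# --- rank correlation, hypergeometric, chi-square ------------------------
# Spearman with average ranks, from the definition (positions of sorted
# values; ties get the mean of their positions).
oracle_spearman <- function(x, y) {
  avg_rank <- function(v) {
    vapply(seq_along(v), function(i) {
      smaller <- sum(v < v[i])
      ties <- sum(v == v[i])
      smaller + (ties + 1) / 2
    }, numeric(1))
  }
  rx <- avg_rank(x); ry <- avg_rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Hypergeometric tails by direct enumeration over choose().
oracle_hyper_tail_upper <- function(x, K, N, n) {
  ks <- x:min(K, n)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}
oracle_hyper_tail_lower <- function(x, K, N, n) {
  ks <- max(0, n - (N - K)):x
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# 1-df goodness-of-fit chi-square on a concordant count, one-sided for
# excess.
oracle_gof_chisq <- function(observed, expected, n) {
  chi <- (observed - expected)^2 / expected +
    ((n - observed) - (n - expected))^2 / (n - expected)
  p_two <- stats::pchisq(chi, df = 1, lower.tail = FALSE)
  list(chisq = chi,
       p = if (observed >= expected) p_two / 2 else 1 - p_two / 2)
}

# Expected sample Spearman (n = 13 branches) under the latent Gaussian
# copula with correlation r, by Monte Carlo.
oracle_copula_mean_spearman <- function(r, n_branches = 13,
                                        n_sim = 20000, seed = 424242) {
  set.seed(seed)
  mean(vapply(seq_len(n_sim), function(i) {
    z <- stats::rnorm(n_branches)
    e <- stats::rnorm(n_branches)
    x <- z
    y <- r * z + sqrt(1 - r^2) * e
    stats::cor(rank(x), rank(y))
  }, numeric(1)))
}
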