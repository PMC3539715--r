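# Mirrortree co-evolution analysis: Spearman correlation of paired
# branch-wise selective constraints for interacting proteins, tested
# against degree-proportional pseudo-pair nulls, plus the clade-removal
# sensitivity scan and the shared-directional-selection chi-square test.

# Per-pair engine. Returns a function(a, b) -> numeric vector of Spearman
# rho (NA = pair ineligible), plus an eligibility predicate for the
# pseudo-pair sampler. When the (sub)table is complete and the cutoff
# removes nothing, ranks are precomputed once per gene and each pair costs
# one dot product; otherwise branches are intersected and ranked per pair.
# Both routes compute the identical statistic.
.np_rho_engine <- function(table, cutoff, min_branches, excluded_branches) {
  O <- unclass(table)
  if (!is.null(excluded_branches)) {
    bad <- setdiff(excluded_branches, np_branches("omega"))
    if (length(bad)) stop("unknown branch label(s) to remove: ",
                          paste(bad, collapse = ", "))
    O <- O[, setdiff(colnames(O), excluded_branches), drop = FALSE]
  }
  if (ncol(O) == 0L) stop("all branches removed")
  genes <- rownames(O)
  fast <- !anyNA(O) && (is.infinite(cutoff) || max(O) < cutoff) &&
    ncol(O) >= min_branches
  if (fast) {
    k <- ncol(O)
    R <- t(apply(O, 1, rank))
    sds <- apply(R, 1, stats::sd)
    ok_gene <- sds > 0
    Rs <- (R - rowMeans(R)) / ifelse(sds > 0, sds, 1)
    rho_fun <- function(a, b) {
      ia <- match(a, genes); ib <- match(b, genes)
      out <- rowSums(Rs[ia, , drop = FALSE] * Rs[ib, , drop = FALSE]) / (k - 1)
      out[!(ok_gene[ia] & ok_gene[ib])] <- NA_real_
      out
    }
    elig_fun <- function(a, b) {
      ia <- match(a, genes); ib <- match(b, genes)
      !is.na(ia) & !is.na(ib) & ok_gene[ia] & ok_gene[ib]
    }
  } else {
    # rank via order() for the (typical) tie-free case; average ranks
    # otherwise -- identical result to rank() either way
    fast_rank <- function(v) {
      if (anyDuplicated(v)) return(rank(v))
      r <- integer(length(v))
      r[order(v)] <- seq_along(v)
      r
    }
    pair_rho <- function(i, j) {
      oa <- O[i, ]; ob <- O[j, ]
      keep <- !is.na(oa) & !is.na(ob) & oa < cutoff & ob < cutoff
      n <- sum(keep)
      if (n < min_branches) return(NA_real_)
      x <- fast_rank(oa[keep]); y <- fast_rank(ob[keep])
      x <- x - mean(x); y <- y - mean(y)
      den <- sqrt(sum(x * x) * sum(y * y))
      if (den == 0) return(NA_real_)   # constant vector: rho undefined
      sum(x * y) / den
    }
    # Batch route: joint-mask both members, push masked cells to +Inf and
    # recover within-row ranks from a single order() call per matrix; with
    # no ties the classic 1 - 6*sum(d^2)/(m(m^2-1)) formula applies. Rows
    # containing tied values fall back to the scalar route (average
    # ranks). Results are identical to pair_rho on every row.
    rho_fun <- function(a, b) {
      ia <- match(a, genes); ib <- match(b, genes)
      out <- rep(NA_real_, length(ia))
      known <- !is.na(ia) & !is.na(ib)
      if (!any(known)) return(out)
      A <- O[ia[known], , drop = FALSE]
      B <- O[ib[known], , drop = FALSE]
      n <- nrow(A); k <- ncol(A)
      valid <- !is.na(A) & !is.na(B) & A < cutoff & B < cutoff
      m <- rowSums(valid)
      A[!valid] <- Inf; B[!valid] <- Inf
      ri <- row(A)
      rank_rows <- function(M) {
        o <- order(ri, M)
        rk <- matrix(0L, n, k)
        rk[o] <- rep(seq_len(k), n)
        # rows with tied finite values need average ranks
        v <- M[o]; rs <- ri[o]
        tie <- v[-1] == v[-length(v)] & rs[-1] == rs[-length(v)] &
          is.finite(v[-1])
        list(rk = rk, tie_rows = unique(rs[-1][tie]))
      }
      ra <- rank_rows(A); rb <- rank_rows(B)
      d2 <- rowSums((ra$rk - rb$rk)^2 * valid)
      rho <- 1 - 6 * d2 / (m * (m^2 - 1))
      rho[m < min_branches] <- NA_real_
      redo <- union(ra$tie_rows, rb$tie_rows)
      redo <- redo[m[redo] >= min_branches]
      for (r in redo) rho[r] <- pair_rho(ia[known][r], ib[known][r])
      out[known] <- rho
      out
    }
    elig_fun <- function(a, b) !is.na(rho_fun(a, b))
  }
  list(rho = rho_fun, eligible = elig_fun, in_table = function(g) {
    g %in% genes
  })
}

#' Mean mirrortree correlation against pseudo-pair nulls
#'
#' Computes Spearman's rho between paired branch-wise \eqn{\omega} values
#' for every eligible interacting pair (both members in the omega table, at
#' least `min_branches` shared branches after the \eqn{\omega} cutoff,
#' non-constant ranks) and compares the mean rho to the distribution of
#' means from `n_null` pseudo-pair sets of the same size meeting the same
#' eligibility requirements. The one-sided empirical p-value asks whether
#' real interacting pairs co-evolve more than random non-interacting pairs
#' drawn from the same genes.
#'
#' @param net A [ppi_network()].
#' @param table A [branch_omega()] table.
#' @param n_null Number of pseudo-pair replicate sets (default 1000).
#' @param cutoff Per-branch omega cutoff (branches where either member's
#'   \eqn{\omega \ge} `cutoff` are dropped); `Inf` keeps everything.
#' @param min_branches Minimum shared branches per pair (default 6).
#' @param excluded_branches Optional branch labels removed from the table
#'   before the analysis (the clade-removal mechanism).
#' @param seed Integer seed; null replicate i uses seed + i.
#' @return Object of class `coevolution_result`: list with `per_pair` (data
#'   frame `a`, `b`, `rho`), `n_pairs` (eligible), `n_excluded`,
#'   `mean_rho`, `null_means`, `mean_of_means`, `difference`, `test`
#'   ([perm_result()]), plus the filter settings.
#' @export
mean_rho_test <- function(net, table, n_null = 1000, cutoff = Inf,
                          min_branches = 6, excluded_branches = NULL,
                          seed = 1L) {
  if (n_null < 1) stop("n_null must be >= 1")
  eng <- .np_rho_engine(table, cutoff, min_branches, excluded_branches)
  a <- net$edges$a; b <- net$edges$b
  in_tab <- eng$in_table(a) & eng$in_table(b)
  rho <- rep(NA_real_, length(a))
  rho[in_tab] <- eng$rho(a[in_tab], b[in_tab])
  ok <- !is.na(rho)
  n_eff <- sum(ok)
  if (n_eff < 1L) stop("no eligible interacting pairs after filtering")
  obs_mean <- mean(rho[ok])
  accept <- function(pa, pb) eng$eligible(pa, pb)
  null_means <- vapply(seq_len(n_null), function(i) {
    pp <- sample_pseudo_pairs(net, n_eff, seed = seed + i, accept = accept)
    mean(eng$rho(pp$a, pp$b))
  }, numeric(1))
  test <- perm_result(obs_mean, null_means, "greater", seed,
                      "mean Spearman rho")
  structure(list(
    per_pair = data.frame(a = a[ok], b = b[ok], rho = rho[ok],
                          stringsAsFactors = FALSE),
    n_pairs = n_eff, n_excluded = length(a) - n_eff,
    mean_rho = obs_mean, null_means = null_means,
    mean_of_means = mean(null_means),
    difference = obs_mean - mean(null_means),
    test = test, cutoff = cutoff, min_branches = min_branches,
    excluded_branches = excluded_branches, n_null = n_null, seed = seed),
    class = "coevolution_result")
}

#' @export
print.coevolution_result <- function(x, ...) {
  cat(sprintf("Mirrortree co-evolution: %d eligible pairs (%d excluded)\n",
              x$n_pairs, x$n_excluded))
  cat(sprintf("  mean rho %.4f vs null mean-of-means %.4f (difference %+.4f)\n",
              x$mean_rho, x$mean_of_means, x$difference))
  cat(sprintf("  empirical P %s (%d pseudo-pair sets)\n",
              format_p(x$test), x$n_null))
  invisible(x)
}

#' Default clade-to-branch removal map
#'
#' Removing a species removes its terminal branch's \eqn{\omega} values;
#' removing a clade removes its tip branches and the internal stems wholly
#' inside the clade. The shared basal branch is never removed.
#'
#' @return Named list of branch-label vectors.
#' @export
np_default_clades <- function() {
  list(
    Human = "human", Chimpanzee = "chimpanzee", Macaque = "macaque",
    Mouse = "mouse", Rat = "rat", Horse = "horse", Dog = "dog", Cow = "cow",
    `Human/Chimp` = c("human", "chimpanzee", "human-chimp"),
    Primates = c("human", "chimpanzee", "macaque", "human-chimp", "primates"),
    Rodents = c("mouse", "rat", "mouse-rat"),
    `Horse/Dog` = c("horse", "dog", "horse-dog"),
    `Horse/Dog/Cow` = c("horse", "dog", "cow", "horse-dog")
  )
}

#' Clade-removal sensitivity scan of the co-evolution signal
#'
#' Repeats [mean_rho_test()] after removing each clade's branches from the
#' omega table (pair eligibility re-evaluated each time), quantifying how
#' much each part of the tree contributes to the co-evolution signal. The
#' first row ("None") is the full-data analysis.
#'
#' @inheritParams mean_rho_test
#' @param clades Named list mapping clade labels to branch-label vectors
#'   (default [np_default_clades()]).
#' @return Object of class `clade_scan`: list with `results` (named list of
#'   `coevolution_result`) and `table` (data frame: clade, n_ppis, p,
#'   mean_rho, mean_of_means, difference).
#' @export
clade_removal_scan <- function(net, table, clades = np_default_clades(),
                               n_null = 1000, cutoff = 5, min_branches = 6,
                               seed = 1L) {
  runs <- c(list(None = NULL), clades)
  results <- lapply(runs, function(br) {
    mean_rho_test(net, table, n_null = n_null, cutoff = cutoff,
                  min_branches = min_branches, excluded_branches = br,
                  seed = seed)
  })
  tab <- data.frame(
    clade = names(runs),
    n_ppis = vapply(results, function(r) r$n_pairs, integer(1)),
    p = vapply(results, function(r) format_p(r$test), character(1)),
    mean_rho = vapply(results, function(r) r$mean_rho, numeric(1)),
    mean_of_means = vapply(results, function(r) r$mean_of_means, numeric(1)),
    difference = vapply(results, function(r) r$difference, numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(results = results, table = tab), class = "clade_scan")
}

#' @export
print.clade_scan <- function(x, ...) {
  cat("Clade-removal co-evolution scan\n")
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Shared directional selection on one branch
#'
#' For all interacting pairs with \eqn{\omega} estimates on the branch,
#' counts pairs where both members exceed the threshold and compares the
#' count to the expectation under independence, n f1 f2, where f1, f2 are
#' the marginal exceedance frequencies of first and second members
#' (canonical pair order). Significance is a 1-df chi-square goodness of
#' fit on the concordant count, one-sided for excess. Branches with too
#' few informative pairs (n below `min_pairs` or expected concordant count
#' below 5) are flagged and get no p-value.
#'
#' @param net A [ppi_network()].
#' @param table A [branch_omega()] table.
#' @param branch One of `np_branches("omega")`.
#' @param threshold \eqn{\omega} level defining an exceedance (1.0 for
#'   strict directional selection; 0.5 for relaxed constraint).
#' @param min_pairs Minimum pairs with both values present (default 20).
#' @return Object of class `shared_selection`: list with `branch`,
#'   `threshold`, `n`, `observed`, `expected`, `f1`, `f2`, `chisq`, `p`,
#'   `valid`, `method`.
#' @export
shared_selection_test <- function(net, table, branch, threshold = 1,
                                  min_pairs = 20) {
  branch <- match.arg(branch, np_branches("omega"))
  O <- unclass(table)
  a <- net$edges$a; b <- net$edges$b
  in_tab <- a %in% rownames(O) & b %in% rownames(O)
  v1 <- rep(NA_real_, length(a)); v2 <- v1
  v1[in_tab] <- O[a[in_tab], branch]
  v2[in_tab] <- O[b[in_tab], branch]
  ok <- !is.na(v1) & !is.na(v2)
  n <- sum(ok)
  f1 <- if (n) mean(v1[ok] > threshold) else NA_real_
  f2 <- if (n) mean(v2[ok] > threshold) else NA_real_
  observed <- if (n) sum(v1[ok] > threshold & v2[ok] > threshold) else 0L
  expected <- if (n) n * f1 * f2 else NA_real_
  valid <- n >= min_pairs && !is.na(expected) && expected >= 5 &&
    (n - expected) >= 5
  chisq <- p <- NA_real_
  if (valid) {
    chisq <- (observed - expected)^2 / expected +
      (observed - expected)^2 / (n - expected)
    p_two <- stats::pchisq(chisq, df = 1, lower.tail = FALSE)
    p <- if (observed >= expected) p_two / 2 else 1 - p_two / 2
  }
  structure(list(branch = branch, threshold = threshold, n = n,
                 observed = observed, expected = expected,
                 f1 = f1, f2 = f2, chisq = chisq, p = p, valid = valid,
                 method = "1-df goodness-of-fit on the concordant count, one-sided for excess"),
            class = "shared_selection")
}

#' @export
print.shared_selection <- function(x, ...) {
  cat(sprintf("Shared selection on %s (omega > %g): %d / %d pairs concordant, expected %.2f\n",
              x$branch, x$threshold, x$observed, x$n,
              ifelse(is.na(x$expected), 0, x$expected)))
  if (x$valid) cat(sprintf("  chi-square = %.3f, one-sided P = %.4g\n",
                           x$chisq, x$p))
  else cat("  too few observations for a valid test\n")
  invisible(x)
}

#' Shared-selection scan over all branches
#'
#' Runs [shared_selection_test()] on every branch of the unrooted tree at
#' one threshold and assembles a per-branch report (branch, n, observed,
#' expected, chi-square, p, valid).
#'
#' @inheritParams shared_selection_test
#' @param branches Branch labels to scan (default all 13).
#' @return Data frame, one row per branch.
#' @export
shared_selection_scan <- function(net, table, threshold = 1,
                                  branches = np_branches("omega"),
                                  min_pairs = 20) {
  rows <- lapply(branches, function(br) {
    r <- shared_selection_test(net, table, br, threshold, min_pairs)
    data.frame(branch = br, n = r$n, observed = r$observed,
               expected = r$expected, chisq = r$chisq, p = r$p,
               valid = r$valid, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
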