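#' Construct a branch-wise selective constraint table
#'
#' Per-gene, per-branch \eqn{\omega} (Ka/Ks) values, as produced by a
#' branch model of codon evolution on the unrooted eight-taxon tree (at most
#' thirteen branches per gene). Missing entries are explicit `NA`s, never
#' zero-filled.
#'
#' @param gene,branch,omega Parallel vectors defining the entries. Branch
#'   labels must come from `np_branches("omega")`; \eqn{\omega} must be
#'   nonnegative (large values are allowed; filtering happens downstream).
#' @return An object of class `branch_omega`: a numeric matrix (genes x 13
#'   branches) with `NA` for missing entries.
#' @export
branch_omega <- function(gene, branch, omega) {
  gene <- as.character(gene); branch <- as.character(branch)
  omega <- as.numeric(omega)
  stopifnot(length(gene) == length(branch), length(gene) == length(omega))
  if (anyNA(omega) || any(omega < 0)) stop("omega must be nonnegative")
  bad <- setdiff(unique(branch), np_branches("omega"))
  if (length(bad)) stop("unknown branch label(s): ",
                        paste(bad, collapse = ", "))
  key <- paste(gene, branch)
  if (anyDuplicated(key)) {
    stop("duplicate (gene, branch) entry: ", key[duplicated(key)][1])
  }
  genes <- sort(unique(gene))
  mat <- matrix(NA_real_, length(genes), length(np_branches("omega")),
                dimnames = list(genes, np_branches("omega")))
  mat[cbind(gene, branch)] <- omega
  structure(mat, class = c("branch_omega", class(mat)))
}

#' @export
print.branch_omega <- function(x, ...) {
  cat(sprintf("Branch-omega table: %d genes, %d branches, %.1f%% coverage\n",
              nrow(x), ncol(x), 100 * mean(!is.na(x))))
  invisible(x)
}

#' Read/write branch-wise omega tables
#'
#' Three-column TSV (`gene`, `branch`, `omega`). Duplicate (gene, branch)
#' rows and negative values are errors.
#'
#' @param path TSV path.
#' @return [branch_omega()] table.
#' @export
read_branch_omega <- function(path) {
  df <- .np_read_tsv_df(path, c("gene", "branch", "omega"))
  omega <- suppressWarnings(as.numeric(df$omega))
  if (anyNA(omega)) stop("non-numeric omega in ", path)
  branch_omega(df$gene, df$branch, omega)
}

#' @rdname read_branch_omega
#' @param tab A `branch_omega` table.
#' @export
write_branch_omega <- function(tab, path) {
  idx <- which(!is.na(tab), arr.ind = TRUE)
  df <- data.frame(gene = rownames(tab)[idx[, 1]],
                   branch = colnames(tab)[idx[, 2]],
                   omega = tab[idx], stringsAsFactors = FALSE)
  df <- df[order(df$gene, match(df$branch, np_branches("omega"))), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a per-gene global constraint table
#'
#' One whole-alignment \eqn{\omega} per gene (a one-ratio model fit),
#' used as the node weight in the constraint-assortativity statistic.
#'
#' @param gene Character vector of gene identifiers (no duplicates).
#' @param omega Nonnegative numeric vector.
#' @return Named numeric vector of class `gene_omega`.
#' @export
gene_omega <- function(gene, omega) {
  gene <- as.character(gene); omega <- as.numeric(omega)
  stopifnot(length(gene) == length(omega))
  if (anyNA(omega) || any(omega < 0)) stop("omega must be nonnegative")
  if (anyDuplicated(gene)) stop("duplicate gene in global omega table")
  names(omega) <- gene
  structure(omega, class = "gene_omega")
}

#' @rdname read_branch_omega
#' @export
read_gene_omega <- function(path) {
  df <- .np_read_tsv_df(path, c("gene", "omega"))
  omega <- suppressWarnings(as.numeric(df$omega))
  if (anyNA(omega)) stop("non-numeric omega in ", path)
  gene_omega(df$gene, omega)
}

#' @rdname read_branch_omega
#' @export
write_gene_omega <- function(tab, path) {
  utils::write.table(
    data.frame(gene = names(tab), omega = as.numeric(tab),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# generic fixed-column TSV reader
.np_read_tsv_df <- function(path, cols) {
  lines <- .np_read_tsv_lines(path)
  if (is.null(lines$header)) stop("empty table: ", path)
  hdr <- strsplit(lines$header, "\t", fixed = TRUE)[[1]]
  if (!all(cols %in% hdr)) {
    stop("expected columns ", paste(cols, collapse = ", "), " in ", path)
  }
  parts <- strsplit(lines$body, "\t", fixed = TRUE)
  if (any(lengths(parts) != length(hdr))) {
    bad <- which(lengths(parts) != length(hdr))[1]
    stop(sprintf("malformed row at line %d of %s", lines$lineno[bad], path))
  }
  out <- lapply(match(cols, hdr), function(i) vapply(parts, `[`, "", i))
  names(out) <- cols
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Build the mirrortree of an interacting pair
#'
#' Pairs the branch-wise \eqn{\omega} vectors of two genes over the
#' intersection of the branches for which both have estimates, in canonical
#' branch order.
#'
#' @param pair Character vector of two gene identifiers.
#' @param table A [branch_omega()] table containing both genes.
#' @return An object of class `mirrortree`: list with `pair`, `branches`,
#'   `omega_a`, `omega_b` (the vectors follow the canonical pair order,
#'   lexicographically smaller gene first).
#' @export
build_mirrortree <- function(pair, table) {
  stopifnot(length(pair) == 2L)
  cp <- .np_canon_pairs(pair[1], pair[2])
  miss <- setdiff(c(cp$a, cp$b), rownames(table))
  if (length(miss)) stop("gene(s) not in omega table: ",
                         paste(miss, collapse = ", "))
  oa <- table[cp$a, ]; ob <- table[cp$b, ]
  keep <- !is.na(oa) & !is.na(ob)
  structure(list(pair = c(cp$a, cp$b),
                 branches = np_branches("omega")[keep],
                 omega_a = unname(oa[keep]), omega_b = unname(ob[keep])),
            class = "mirrortree")
}

#' @export
print.mirrortree <- function(x, ...) {
  cat(sprintf("Mirrortree %s -- %s: %d shared branch(es)\n",
              x$pair[1], x$pair[2], length(x$branches)))
  invisible(x)
}

#' Drop high-variance branches from a mirrortree
#'
#' Removes every branch on which either member's \eqn{\omega} is at or
#' above `cutoff`; very large \eqn{\omega} estimates have large sampling
#' variances and can dominate correlation estimates.
#'
#' @param mirror A [build_mirrortree()] result.
#' @param cutoff Upper \eqn{\omega} bound (exclusive); `Inf` is the identity.
#' @return A filtered `mirrortree`.
#' @export
filter_omega <- function(mirror, cutoff = 5) {
  stopifnot(cutoff > 0)
  keep <- mirror$omega_a < cutoff & mirror$omega_b < cutoff
  mirror$branches <- mirror$branches[keep]
  mirror$omega_a <- mirror$omega_a[keep]
  mirror$omega_b <- mirror$omega_b[keep]
  mirror
}

#' Correlation of a mirrortree's paired omega vectors
#'
#' Spearman's rank correlation (average ranks for ties) or Pearson's
#' correlation between the paired branch-wise \eqn{\omega} values. Returns
#' `NA` (pair excluded) when fewer than `min_branches` branches are shared
#' or when either vector is constant (rank variance zero).
#'
#' @param mirror A `mirrortree`.
#' @param method `"spearman"` (default; robust to the highly skewed
#'   \eqn{\omega} distribution) or `"pearson"`.
#' @param min_branches Minimum number of paired branches (default 6).
#' @return Correlation in \[-1, 1\], or `NA` if undefined.
#' @export
pair_correlation <- function(mirror, method = c("spearman", "pearson"),
                             min_branches = 6) {
  method <- match.arg(method)
  stopifnot(min_branches >= 2)
  x <- mirror$omega_a; y <- mirror$omega_b
  if (length(x) < min_branches) return(NA_real_)
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) return(NA_real_)
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  stats::cor(x, y)
}
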