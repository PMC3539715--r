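#' Construct a protein-protein interaction network
#'
#' Builds a simple undirected graph over gene identifiers. Self-loops and
#' duplicate edges (in either orientation) are dropped with a logged count,
#' matching the convention that self-interactions are excluded from PPI
#' analyses. Pairs are stored canonically with the lexicographically smaller
#' gene first; the "first" member of a pair always refers to this order.
#'
#' @param a,b Character vectors of interacting gene identifiers (one edge per
#'   element).
#' @param quiet Suppress the dropped-row log message.
#' @return An object of class `ppi_network`: a list with elements `edges`
#'   (data frame with columns `a`, `b`), `nodes` (character) and `degree`
#'   (named integer, number of distinct neighbours per node).
#' @export
ppi_network <- function(a = character(0), b = character(0), quiet = FALSE) {
  stopifnot(length(a) == length(b))
  a <- as.character(a); b <- as.character(b)
  if (any(!nzchar(a)) || any(!nzchar(b)) || anyNA(a) || anyNA(b)) {
    stop("empty or missing gene identifiers in edge list")
  }
  n_in <- length(a)
  self <- a == b
  a <- a[!self]; b <- b[!self]
  cp <- .np_canon_pairs(a, b)
  key <- .np_pair_key(cp$a, cp$b)
  dup <- duplicated(key)
  edges <- data.frame(a = cp$a[!dup], b = cp$b[!dup],
                      stringsAsFactors = FALSE)
  if (!quiet && (sum(self) > 0L || sum(dup) > 0L)) {
    .np_log("read %d edge rows: dropped %d self-loop(s), %d duplicate(s)",
            n_in, sum(self), sum(dup))
  }
  nodes <- sort(unique(c(edges$a, edges$b)))
  deg <- integer(length(nodes)); names(deg) <- nodes
  if (nrow(edges)) {
    tab <- table(c(edges$a, edges$b))
    deg[names(tab)] <- as.integer(tab)
  }
  structure(list(edges = edges, nodes = nodes, degree = deg),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("PPI network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  if (length(x$degree)) {
    cat(sprintf("  degree: min %d, mean %.2f, max %d\n",
                min(x$degree), mean(x$degree), max(x$degree)))
  }
  invisible(x)
}

#' Number of edges of a PPI network
#' @param net A `ppi_network`.
#' @return Integer edge count.
#' @export
n_edges <- function(net) nrow(net$edges)

#' Node degrees
#' @param net A `ppi_network`.
#' @param genes Optional gene subset; unknown genes are an error.
#' @return Named integer vector of degrees.
#' @export
net_degree <- function(net, genes = NULL) {
  if (is.null(genes)) return(net$degree)
  miss <- setdiff(genes, net$nodes)
  if (length(miss)) stop("unknown gene(s): ", paste(miss, collapse = ", "))
  net$degree[genes]
}

# fast membership test for unordered pairs
.np_edge_keys <- function(net) .np_pair_key(net$edges$a, net$edges$b)

#' Test whether pairs are edges of the network
#' @param net A `ppi_network`.
#' @param a,b Gene identifier vectors (order-free).
#' @return Logical vector.
#' @export
has_edge <- function(net, a, b) {
  cp <- .np_canon_pairs(a, b)
  .np_pair_key(cp$a, cp$b) %in% .np_edge_keys(net)
}

#' Read a PPI edge list
#'
#' Reads a two-column TSV edge list (header `gene_a	gene_b`; `#` comment
#' lines ignored) into a simple undirected network. Self-loop and duplicate
#' rows are dropped with a logged count; an empty file yields an empty
#' network with a warning.
#'
#' @param path Path to the TSV file.
#' @return A [ppi_network()].
#' @export
read_network <- function(path) {
  lines <- .np_read_tsv_lines(path)
  if (length(lines$body) == 0L) {
    warning("empty edge list: ", path)
    return(ppi_network())
  }
  parts <- strsplit(lines$body, "\t", fixed = TRUE)
  bad <- which(vapply(parts, function(p) length(p) < 2L || !nzchar(p[1]) ||
                        !nzchar(p[2]), logical(1)))
  if (length(bad)) {
    stop(sprintf("malformed edge row at line %d of %s",
                 lines$lineno[bad[1]], path))
  }
  ppi_network(vapply(parts, `[`, "", 1L), vapply(parts, `[`, "", 2L))
}

#' Write a PPI edge list
#' @param net A `ppi_network`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path) {
  df <- net$edges
  names(df) <- c("gene_a", "gene_b")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Shared TSV plumbing: returns header line, body lines and original line
# numbers (comments and blank lines skipped).
.np_read_tsv_lines <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  if (!header) return(list(header = NULL, body = raw[keep], lineno = keep))
  if (length(keep) == 0L) return(list(header = NULL, body = character(0),
                                      lineno = integer(0)))
  list(header = raw[keep[1]], body = raw[keep[-1]], lineno = keep[-1])
}
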