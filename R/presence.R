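#' Construct an ortholog presence matrix
#'
#' Gene-by-species indicator matrix of ortholog presence. Genes are defined
#' from the reference (human) gene set, so every gene must be present in
#' human; species must be exactly the canonical eight-mammal set. Lookups of
#' unknown genes or species are errors, never silent absences.
#'
#' @param mat Numeric/logical matrix (genes in rows, species in columns,
#'   values 0/1) with row and column names.
#' @return An object of class `presence_matrix` (an integer 0/1 matrix).
#' @export
presence_matrix <- function(mat) {
  if (is.null(rownames(mat)) || is.null(colnames(mat))) {
    stop("presence matrix needs gene row names and species column names")
  }
  sp <- np_species()
  miss <- setdiff(sp, colnames(mat))
  if (length(miss)) stop("missing species column(s): ",
                         paste(miss, collapse = ", "))
  extra <- setdiff(colnames(mat), sp)
  if (length(extra)) stop("unknown species column(s): ",
                          paste(extra, collapse = ", "))
  mat <- mat[, sp, drop = FALSE]
  storage.mode(mat) <- "integer"
  if (anyNA(mat) || !all(mat %in% c(0L, 1L))) {
    stop("presence values must be 0 or 1")
  }
  if (any(mat[, "human"] == 0L)) {
    stop("gene(s) absent in human: ",
         paste(utils::head(rownames(mat)[mat[, "human"] == 0L], 5),
               collapse = ", "))
  }
  if (anyDuplicated(rownames(mat))) stop("duplicated gene identifiers")
  class(mat) <- c("presence_matrix", class(mat))
  mat
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("Presence matrix: %d genes x %d species (mean presence %.3f)\n",
              nrow(x), ncol(x), mean(x)))
  invisible(x)
}

#' Query ortholog presence
#' @param pm A `presence_matrix`.
#' @param gene,species Character vectors (recycled against each other).
#' @return Logical vector of presence indicators.
#' @export
is_present <- function(pm, gene, species) {
  bad_g <- setdiff(unique(gene), rownames(pm))
  if (length(bad_g)) stop("unknown gene(s): ", paste(bad_g, collapse = ", "))
  bad_s <- setdiff(unique(species), colnames(pm))
  if (length(bad_s)) stop("unknown species: ", paste(bad_s, collapse = ", "))
  pm[cbind(gene, species)] == 1L
}

#' Read an ortholog presence matrix
#'
#' TSV with a header row `gene` + species names and 0/1 entries. Values
#' outside \{0,1\} or genes absent in human are errors.
#'
#' @param path Path to the TSV file.
#' @return A [presence_matrix()].
#' @export
read_presence_matrix <- function(path) {
  lines <- .np_read_tsv_lines(path)
  if (is.null(lines$header)) stop("empty presence matrix: ", path)
  hdr <- strsplit(lines$header, "\t", fixed = TRUE)[[1]]
  species <- hdr[-1]
  parts <- strsplit(lines$body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(hdr))) {
    stop(sprintf("malformed presence row at line %d of %s",
                 lines$lineno[which(nfield != length(hdr))[1]], path))
  }
  genes <- vapply(parts, `[`, "", 1L)
  vals <- suppressWarnings(
    vapply(parts, function(p) as.integer(p[-1]), integer(length(species)))
  )
  if (anyNA(vals)) stop("non-numeric presence value in ", path)
  mat <- t(vals)
  dimnames(mat) <- list(genes, species)
  presence_matrix(mat)
}

#' Write an ortholog presence matrix
#' @param pm A `presence_matrix`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(pm, path) {
  df <- data.frame(gene = rownames(pm), unclass(pm)[, np_species(),
                                                    drop = FALSE],
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Status code of one interaction in one species
#'
#' Codes the state of a PPI in a non-reference species from the presence of
#' the two members' orthologs: 4 if both present, 2 if only the first
#' (canonically ordered) gene's ortholog is absent, 1 if only the second's
#' is absent, 0 if both absent.
#'
#' @param pair Character vector of two gene identifiers.
#' @param species Species name.
#' @param presence A [presence_matrix()].
#' @return Integer status code in \{0, 1, 2, 4\}.
#' @export
code_pair_status <- function(pair, species, presence) {
  stopifnot(length(pair) == 2L)
  cp <- .np_canon_pairs(pair[1], pair[2])
  p1 <- is_present(presence, cp$a, species)
  p2 <- is_present(presence, cp$b, species)
  .np_status_code(p1, p2)
}

# vectorized status coding from presence indicators of the canonical first
# and second members
.np_status_code <- function(p1, p2) {
  ifelse(p1 & p2, 4L, ifelse(!p1 & p2, 2L, ifelse(p1 & !p2, 1L, 0L)))
}
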