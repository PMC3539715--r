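#' Construct the calibrated eight-mammal phylogeny
#'
#' Fixed rooted topology `(((human,chimpanzee),macaque),(mouse,rat))` versus
#' `((horse,dog),cow)` with a mean-Ks length per branch (synonymous
#' substitutions per synonymous site, the near-neutral clock used to
#' calibrate gain/loss rates and branch ages). Because an unrooted
#' substitution model cannot split the basal edge, the Ks assigned to the
#' root origin class is defined as one half of the Ks separation between the
#' primate-rodent clade and the horse-dog-cow clade.
#'
#' @param ks Named numeric vector of branch Ks values covering the 14 rooted
#'   branches (`np_branches("rooted")`). All values must be nonnegative.
#' @param roles Optional named character vector mapping branch labels to
#'   roles (`"origin"`, `"loss"`, `"other"`); defaults to the canonical role
#'   assignment. Must tag exactly the five origin-eligible classes and the
#'   two loss-calibration stems.
#' @return An object of class `mammal_phylogeny` with elements `ks` (branch
#'   Ks, including the derived `root` class entry), `roles`, and `ages`
#'   (cumulative Ks from the human tip to each origin branch's midpoint).
#' @export
mammal_phylogeny <- function(ks, roles = NULL) {
  need <- np_branches("rooted")
  miss <- setdiff(need, names(ks))
  if (length(miss)) stop("missing Ks for branch(es): ",
                         paste(miss, collapse = ", "))
  ks <- ks[need]
  if (anyNA(ks) || any(ks < 0)) stop("branch Ks must be nonnegative")
  # half the basal (inter-clade) separation
  ks <- c(ks, root = unname(ks["euarchontoglires"] + ks["laurasiatheria"]) / 2)
  if (is.null(roles)) roles <- np_default_roles()
  .np_check_roles(roles)
  ladder <- c("human", "human-chimp", "primates", "euarchontoglires", "root")
  ages <- cumsum(c(0, ks[ladder[-5]])) + ks[ladder] / 2
  names(ages) <- rev(np_branches("origin"))
  structure(list(ks = ks, roles = roles, ages = ages),
            class = "mammal_phylogeny")
}

#' @export
print.mammal_phylogeny <- function(x, ...) {
  cat("Eight-mammal phylogeny (Ks-calibrated)\n")
  cat(sprintf("  root-class Ks (half basal separation): %.4f\n",
              x$ks[["root"]]))
  cat("  origin-branch ages (Ks from human tip to branch midpoint):\n")
  for (b in np_branches("origin")) {
    cat(sprintf("    %-18s %.4f\n", b, x$ages[[b]]))
  }
  invisible(x)
}

#' Default branch role assignment
#'
#' The five origin-eligible classes on the human lineage and the two
#' loss-calibration stems (shared branches not containing direct ancestors
#' of humans); all remaining branches are `"other"`.
#'
#' @return Named character vector over branch labels.
#' @export
np_default_roles <- function() {
  roles <- rep("other", length(np_branches("rooted")) + 1L)
  names(roles) <- c(np_branches("rooted"), "root")
  roles[np_branches("origin")] <- "origin"
  roles[np_branches("loss")] <- "loss"
  roles
}

.np_check_roles <- function(roles) {
  orig <- names(roles)[roles == "origin"]
  if (!setequal(orig, np_branches("origin"))) {
    stop("role map must tag exactly the five origin-eligible classes: ",
         paste(np_branches("origin"), collapse = ", "))
  }
  loss <- names(roles)[roles == "loss"]
  if (!setequal(loss, np_branches("loss"))) {
    stop("role map must tag exactly the two loss-calibration stems: ",
         paste(np_branches("loss"), collapse = ", "))
  }
  invisible(TRUE)
}

#' Read a Ks-calibrated phylogeny from Newick plus a role table
#'
#' The Newick tree must contain exactly the eight canonical tips with the
#' fixed topology; branch lengths are mean Ks. Both the rooted form (basal
#' split into two halves) and the unrooted form (single basal edge) are
#' accepted: in either case the root-class Ks is half the inter-clade
#' separation. Roles come from a two-column TSV (`branch`, `role`), not from
#' the tree file.
#'
#' @param newick Path to the Newick file.
#' @param roles Path to the role TSV, or a named character vector, or `NULL`
#'   for the canonical default.
#' @return A [mammal_phylogeny()].
#' @export
read_phylogeny <- function(newick, roles = NULL) {
  tr <- ape::read.tree(newick)
  if (is.null(tr)) stop("could not parse Newick file: ", newick)
  sp <- np_species()
  if (!setequal(tr$tip.label, sp)) {
    stop("tree tips must be exactly: ", paste(sp, collapse = ", "),
         " (missing: ", paste(setdiff(sp, tr$tip.label), collapse = ", "), ")")
  }
  if (is.null(tr$edge.length)) stop("tree has no branch lengths")
  if (any(tr$edge.length < 0)) stop("negative branch length in ", newick)
  labs <- .np_label_edges(tr)
  ks <- numeric(0)
  for (i in seq_along(labs)) {
    if (!is.na(labs[i])) ks[labs[i]] <- tr$edge.length[i]
  }
  # unrooted input: a single basal edge carries the whole inter-clade
  # separation; split it evenly so the root-class Ks comes out as half of it
  has_e <- "euarchontoglires" %in% names(ks)
  has_l <- "laurasiatheria" %in% names(ks)
  if (!(has_e && has_l)) {
    basal <- if ("basal" %in% names(ks)) ks[["basal"]]
             else if (has_l) ks[["laurasiatheria"]]
             else if (has_e) ks[["euarchontoglires"]]
             else stop("cannot locate the basal edge in ", newick)
    ks <- ks[!(names(ks) %in% "basal")]
    ks[["euarchontoglires"]] <- basal / 2
    ks[["laurasiatheria"]] <- basal / 2
  }
  miss <- setdiff(np_branches("rooted"), names(ks))
  if (length(miss)) {
    stop("tree topology does not match the canonical eight-mammal tree; ",
         "unresolved branch(es): ", paste(miss, collapse = ", "))
  }
  if (is.character(roles) && length(roles) == 1L && file.exists(roles)) {
    roles <- read_branch_roles(roles)
  }
  mammal_phylogeny(ks, roles)
}

# Map each ape edge to a canonical branch label via the tip set below it
# (or its complement, for arbitrarily rooted input). Returns NA for an edge
# that matches nothing, "basal" for the undivided inter-clade edge.
.np_label_edges <- function(tr) {
  ntip <- length(tr$tip.label)
  below <- vector("list", max(tr$edge))
  for (i in seq_len(ntip)) below[[i]] <- tr$tip.label[i]
  # fixed-point accumulation of tips below each node (tree is tiny)
  repeat {
    done <- TRUE
    for (e in seq_len(nrow(tr$edge))) {
      p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
      if (!is.null(below[[ch]])) {
        merged <- unique(c(below[[p]], below[[ch]]))
        if (!identical(merged, below[[p]])) {
          below[[p]] <- merged
          done <- FALSE
        }
      } else {
        done <- FALSE
      }
    }
    if (done) break
  }
  sp <- np_species()
  canon <- lapply(.np_branch_tips, sort)
  vapply(seq_len(nrow(tr$edge)), function(e) {
    tips <- sort(below[[tr$edge[e, 2]]])
    comp <- sort(setdiff(sp, tips))
    hit <- which(vapply(canon, identical, logical(1), tips))
    if (!length(hit)) hit <- which(vapply(canon, identical, logical(1), comp))
    if (length(hit)) return(names(canon)[hit[1]])
    # basal edge of an unrooted tree: laurasiatheria vs euarchontoglires
    if (identical(tips, canon$laurasiatheria) ||
        identical(comp, canon$laurasiatheria)) return("basal")
    NA_character_
  }, character(1))
}

#' Read or write a branch role table
#'
#' @param path Two-column TSV (`branch`, `role`).
#' @return Named character vector of roles.
#' @export
read_branch_roles <- function(path) {
  lines <- .np_read_tsv_lines(path)
  parts <- strsplit(lines$body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L)) stop("malformed role row in ", path)
  roles <- vapply(parts, `[`, "", 2L)
  names(roles) <- vapply(parts, `[`, "", 1L)
  bad <- setdiff(names(roles), c(np_branches("rooted"), "root"))
  if (length(bad)) stop("unknown branch label(s) in role table: ",
                        paste(bad, collapse = ", "))
  full <- np_default_roles()
  full[] <- "other"
  full[names(roles)] <- roles
  full
}

#' @rdname read_branch_roles
#' @param roles Named character role vector.
#' @export
write_branch_roles <- function(roles, path) {
  utils::write.table(
    data.frame(branch = names(roles), role = unname(roles),
               stringsAsFactors = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the phylogeny as a rooted Newick string
#' @param phylo A `mammal_phylogeny`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylogeny <- function(phylo, path) {
  k <- function(b) format(phylo$ks[[b]], digits = 12)
  nwk <- sprintf(
    paste0("((((human:%s,chimpanzee:%s):%s,macaque:%s):%s,",
           "(mouse:%s,rat:%s):%s):%s,",
           "((horse:%s,dog:%s):%s,cow:%s):%s);"),
    k("human"), k("chimpanzee"), k("human-chimp"), k("macaque"),
    k("primates"), k("mouse"), k("rat"), k("mouse-rat"),
    k("euarchontoglires"), k("horse"), k("dog"), k("horse-dog"),
    k("cow"), k("laurasiatheria"))
  writeLines(nwk, path)
  invisible(path)
}
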