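# Canonical eight-mammal topology used throughout:
#   (((human,chimpanzee),macaque),(mouse,rat)) | ((horse,dog),cow)
# All branch identities are fixed strings; the user's Newick is validated
# against this topology rather than parsed for structure.

#' Canonical species set
#'
#' The eight mammals of the fixed study topology, in canonical order
#' (human first: the network and presence matrix are defined from the human
#' gene set).
#'
#' @return Character vector of the eight species names.
#' @export
np_species <- function() {
  c("human", "chimpanzee", "macaque", "mouse", "rat", "horse", "dog", "cow")
}

# Rooted branches: each branch is named for the node it subtends; the value
# is the set of tips below it.  "euarchontoglires" and "laurasiatheria" are
# the two halves of the basal edge, indistinguishable in an unrooted model.
.np_branch_tips <- list(
  human             = "human",
  chimpanzee        = "chimpanzee",
  "human-chimp"     = c("human", "chimpanzee"),
  macaque           = "macaque",
  primates          = c("human", "chimpanzee", "macaque"),
  mouse             = "mouse",
  rat               = "rat",
  "mouse-rat"       = c("mouse", "rat"),
  euarchontoglires  = c("human", "chimpanzee", "macaque", "mouse", "rat"),
  horse             = "horse",
  dog               = "dog",
  "horse-dog"       = c("horse", "dog"),
  cow               = "cow",
  laurasiatheria    = c("horse", "dog", "cow")
)

#' Canonical branch labels
#'
#' @param set Which branch vocabulary: `"rooted"` (14 branches of the rooted
#'   tree), `"omega"` (the 13 branches of the unrooted tree on which
#'   branch-wise selective constraint is estimated: the two basal halves
#'   collapse into a single `"root"` edge), `"origin"` (the five
#'   origin-eligible classes on the human lineage, ordered oldest to
#'   youngest) or `"loss"` (the two loss-calibration stems).
#' @return Character vector of branch labels.
#' @export
np_branches <- function(set = c("rooted", "omega", "origin", "loss")) {
  set <- match.arg(set)
  switch(set,
    rooted = names(.np_branch_tips),
    omega  = c("human", "chimpanzee", "human-chimp", "macaque", "primates",
               "mouse", "rat", "mouse-rat", "horse", "dog", "horse-dog",
               "cow", "root"),
    origin = c("root", "euarchontoglires", "primates", "human-chimp", "human"),
    loss   = c("mouse-rat", "horse-dog")
  )
}

# Origin classes ordered oldest (1) to youngest (5).
.np_origin_rank <- function(class) {
  match(class, np_branches("origin"))
}

# Tips below the child node of an origin-eligible branch: a gene that
# originated on that branch can only ever be observed in these tips.
.np_origin_clade <- function(class) {
  switch(class,
    root               = np_species(),
    euarchontoglires   = .np_branch_tips[["euarchontoglires"]],
    primates           = .np_branch_tips[["primates"]],
    "human-chimp"      = .np_branch_tips[["human-chimp"]],
    human              = "human",
    stop("unknown origin class: ", class)
  )
}

# Rooted branches strictly below the child node of an origin class,
# i.e. the branches on which an ortholog born there can subsequently be lost.
.np_branches_below <- function(class) {
  clade <- .np_origin_clade(class)
  keep <- vapply(.np_branch_tips, function(t) {
    all(t %in% clade) && length(t) < length(clade)
  }, logical(1))
  names(.np_branch_tips)[keep]
}

# Rooted branches on the path from the child node of an origin class down to
# the human tip (exclusive of the origin branch itself).  These are
# loss-protected: the gene must survive to human.
.np_human_path_below <- function(class) {
  path <- c("euarchontoglires", "primates", "human-chimp", "human")
  switch(class,
    root = path,
    euarchontoglires = path[-1],
    primates = path[-(1:2)],
    "human-chimp" = path[-(1:3)],
    human = character(0)
  )
}

# canonical unordered pair representation: lexicographically smaller first
.np_canon_pairs <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  swap <- b < a
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

.np_pair_key <- function(a, b) paste(a, b, sep = "\r")

.np_log <- function(...) message("[netpaleo] ", sprintf(...))
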