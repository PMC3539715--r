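# Small programmatic fixtures shared across test files.

tiny_ks <- c(human = 0.01, chimpanzee = 0.01, `human-chimp` = 0.02,
             macaque = 0.06, primates = 0.05, mouse = 0.16, rat = 0.16,
             `mouse-rat` = 0.18, euarchontoglires = 0.17, horse = 0.11,
             dog = 0.12, `horse-dog` = 0.09, cow = 0.17,
             laurasiatheria = 0.17)

tiny_phylo <- function(ks = tiny_ks) mammal_phylogeny(ks)

# presence matrix from a named list gene -> character vector of species
presence_from_list <- function(spec) {
  mat <- matrix(0L, length(spec), 8,
                dimnames = list(names(spec), np_species()))
  for (g in names(spec)) mat[g, spec[[g]]] <- 1L
  mat[, "human"] <- 1L
  presence_matrix(mat)
}

# presence matrix where every gene is present in the given species sets,
# drawn at random (always including human)
random_presence <- function(n_genes, seed) {
  set.seed(seed)
  spec <- lapply(seq_len(n_genes), function(i) {
    others <- setdiff(np_species(), "human")
    c("human", sample(others, sample(0:7, 1)))
  })
  names(spec) <- sprintf("g%04d", seq_len(n_genes))
  presence_from_list(spec)
}

write_tsv_text <- function(lines, file = tempfile(fileext = ".tsv")) {
  writeLines(lines, file)
  file
}

# ring of 300 genes plus 10 off-ring hubs (h01..h10) each wired to 10
# distinct ring nodes: degrees 10 (hubs), 3 (100 targets), 2 (rest)
hub_ring_network <- function() {
  ring <- sprintf("m%03d", 1:300)
  a <- ring; b <- c(ring[-1], ring[1])
  hubs <- sprintf("h%02d", 1:10)
  ha <- rep(hubs, each = 10)
  hb <- sprintf("m%03d", 1:100)
  ppi_network(c(a, ha), c(b, hb), quiet = TRUE)
}
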