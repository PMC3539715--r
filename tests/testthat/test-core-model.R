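# Readers, writers and domain types.

test_that("edge lists are deduplicated, self-loops dropped, degrees right", {
  f <- write_tsv_text(c("gene_a\tgene_b", "A\tB", "B\tA", "C\tC"))
  expect_message(net <- read_network(f), "1 self-loop")
  expect_equal(n_edges(net), 1L)
  expect_equal(net$edges$a, "A")
  expect_equal(net$edges$b, "B")

  f2 <- write_tsv_text(c("gene_a\tgene_b", "A\tB", "A\tC"))
  net2 <- read_network(f2)
  expect_equal(unname(net_degree(net2, c("A", "B", "C"))), c(2L, 1L, 1L))
  expect_equal(sum(net2$degree), 2L * n_edges(net2))
  expect_true(all(has_edge(net2, c("B", "C"), c("A", "A"))))
  expect_false(has_edge(net2, "B", "C"))
})

test_that("empty and malformed edge lists are handled", {
  f <- write_tsv_text(c("gene_a\tgene_b"))
  expect_warning(net <- read_network(f), "empty")
  expect_equal(n_edges(net), 0L)
  f2 <- write_tsv_text(c("gene_a\tgene_b", "A\tB", "justonefield"))
  expect_error(read_network(f2), "line 3")
})

test_that("network round-trips through TSV exactly", {
  net <- ppi_network(c("gX", "gY", "gZ"), c("gY", "gZ", "gA"))
  f <- tempfile(fileext = ".tsv")
  write_network(net, f)
  back <- read_network(f)
  expect_identical(back$edges, net$edges)
  expect_identical(back$degree, net$degree)
})

test_that("presence matrix parsing enforces the invariants", {
  hdr <- paste(c("gene", np_species()), collapse = "\t")
  f <- write_tsv_text(c(hdr, paste(c("g1", 1, 1, 0, 0, 1, 1, 1, 1),
                                   collapse = "\t")))
  pm <- read_presence_matrix(f)
  expect_equal(sum(pm["g1", ]), 6)
  expect_true(is_present(pm, "g1", "human"))
  expect_false(is_present(pm, "g1", "macaque"))
  expect_error(is_present(pm, "nope", "human"), "unknown gene")
  expect_error(is_present(pm, "g1", "yeti"), "unknown species")

  f2 <- write_tsv_text(c(hdr, paste(c("g1", 0, 1, 1, 1, 1, 1, 1, 1),
                                    collapse = "\t")))
  expect_error(read_presence_matrix(f2), "absent in human")
  f3 <- write_tsv_text(c(hdr, paste(c("g1", 1, 1, 2, 0, 0, 0, 0, 0),
                                    collapse = "\t")))
  expect_error(read_presence_matrix(f3), "0 or 1")
  hdr_short <- paste(c("gene", np_species()[-8]), collapse = "\t")
  f4 <- write_tsv_text(c(hdr_short, paste(c("g1", rep(1, 7)),
                                          collapse = "\t")))
  expect_error(read_presence_matrix(f4), "missing species")
})

test_that("presence matrix round-trips through TSV exactly", {
  pm <- random_presence(25, seed = 7)
  f <- tempfile(fileext = ".tsv")
  write_presence_matrix(pm, f)
  expect_identical(unclass(read_presence_matrix(f)), unclass(pm))
})

test_that("interaction status codes follow the 4/2/1/0 convention", {
  pm <- presence_from_list(list(gA = c("human", "mouse"),
                                gB = c("human", "mouse", "rat")))
  # canonical first member is gA
  expect_equal(code_pair_status(c("gA", "gB"), "mouse", pm), 4L)
  expect_equal(code_pair_status(c("gB", "gA"), "rat", pm), 2L)  # gA absent
  expect_equal(code_pair_status(c("gA", "gB"), "horse", pm), 0L)
  pm2 <- presence_from_list(list(gA = c("human", "rat"), gB = "human"))
  expect_equal(code_pair_status(c("gA", "gB"), "rat", pm2), 1L)
  expect_error(code_pair_status(c("gA", "gX"), "rat", pm2), "unknown gene")
})

test_that("phylogeny IO: rooted round trip, unrooted basal halving, errors", {
  phy <- tiny_phylo()
  f <- tempfile(fileext = ".nwk")
  write_phylogeny(phy, f)
  back <- read_phylogeny(f)
  expect_equal(back$ks, phy$ks, tolerance = 1e-10)
  expect_equal(back$ks[["root"]], 0.17)
  expect_equal(names(back$ages), rev(np_branches("origin")))
  # ages decrease from the root class toward the human terminal
  expect_true(all(diff(back$ages[np_branches("origin")]) < 0))

  # unrooted tree: single basal edge of 0.8 -> root-class Ks 0.4
  unrooted <- paste0("((((human:0.01,chimpanzee:0.01):0.02,macaque:0.06)",
                     ":0.05,(mouse:0.16,rat:0.16):0.18):0,",
                     "((horse:0.11,dog:0.12):0.09,cow:0.17):0.8);")
  fu <- write_tsv_text(unrooted, tempfile(fileext = ".nwk"))
  phy_u <- read_phylogeny(fu)
  expect_equal(phy_u$ks[["root"]], 0.4)

  # missing tip
  bad <- sub("cow:0.17", "yak:0.17", unrooted, fixed = TRUE)
  expect_error(read_phylogeny(write_tsv_text(bad)), "cow")
  # negative branch length
  neg <- sub("dog:0.12", "dog:-0.1", unrooted, fixed = TRUE)
  expect_error(read_phylogeny(write_tsv_text(neg)), "negative")
})

test_that("branch role tables validate and round-trip", {
  roles <- np_default_roles()
  f <- tempfile(fileext = ".tsv")
  write_branch_roles(roles, f)
  expect_identical(read_branch_roles(f), roles)
  bad <- roles
  names(bad)[1] <- "gibbon"
  f2 <- tempfile(fileext = ".tsv")
  write_branch_roles(bad, f2)
  expect_error(read_branch_roles(f2), "unknown branch")
  incomplete <- roles
  incomplete["primates"] <- "other"
  expect_error(mammal_phylogeny(tiny_ks, incomplete), "origin-eligible")
})

test_that("omega tables: coverage, duplicates, negatives, round trip", {
  f <- write_tsv_text(c("gene\tbranch\tomega", "g1\thuman\t0.1",
                        "g1\tmouse\t0.5", "g1\troot\t7.9"))
  tab <- read_branch_omega(f)
  expect_equal(sum(!is.na(tab["g1", ])), 3)
  expect_equal(tab["g1", "root"], 7.9)   # filtering happens downstream

  fdup <- write_tsv_text(c("gene\tbranch\tomega", "g1\thuman\t0.1",
                           "g1\thuman\t0.2"))
  expect_error(read_branch_omega(fdup), "duplicate")
  fneg <- write_tsv_text(c("gene\tbranch\tomega", "g1\thuman\t-0.1"))
  expect_error(read_branch_omega(fneg), "nonnegative")

  f2 <- tempfile(fileext = ".tsv")
  write_branch_omega(tab, f2)
  expect_identical(unclass(read_branch_omega(f2)), unclass(tab))

  g <- gene_omega(c("g1", "g2"), c(0.2, 1.4))
  f3 <- tempfile(fileext = ".tsv")
  write_gene_omega(g, f3)
  expect_equal(unclass(read_gene_omega(f3)), unclass(g))
  expect_error(gene_omega(c("g1", "g1"), c(1, 2)), "duplicate")
})

test_that("mirrortrees pair over branch intersections and filter by omega", {
  br <- np_branches("omega")
  tab <- branch_omega(c(rep("gA", 13), rep("gB", 10)),
                      c(br, br[1:10]),
                      c(seq(0.1, 1.3, by = 0.1), seq(0.2, 2.0, by = 0.2)))
  m <- build_mirrortree(c("gA", "gB"), tab)
  expect_length(m$branches, 10)
  expect_identical(filter_omega(m, Inf), m)
  m2 <- filter_omega(m, 1.0)
  expect_true(all(m2$omega_a < 1 & m2$omega_b < 1))
  expect_length(filter_omega(m, 0.05)$branches, 0)

  tab2 <- branch_omega(c("gA", "gB"), c("human", "mouse"), c(0.1, 0.2))
  expect_length(build_mirrortree(c("gA", "gB"), tab2)$branches, 0)
  expect_error(build_mirrortree(c("gA", "gX"), tab2), "not in omega table")
})

test_that("pair correlation matches the rank-formula oracle and edge cases", {
  mk <- function(x, y) {
    structure(list(pair = c("a", "b"),
                   branches = np_branches("omega")[seq_along(x)],
                   omega_a = x, omega_b = y), class = "mirrortree")
  }
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(pair_correlation(mk(x, x * 3)), 1)
  expect_equal(pair_correlation(mk(x, rev(x))), -1)
  # (1..6) vs (1,2,3,4,6,5): rho = 1 - 6*2/(6*35) = 0.9428571...
  y <- c(1, 2, 3, 4, 6, 5)
  expect_equal(pair_correlation(mk(1:6, y)), 33 / 35)
  expect_equal(pair_correlation(mk(1:6, y)), oracle_spearman(1:6, y))
  expect_true(is.na(pair_correlation(mk(x[1:5], x[1:5]))))    # < 6 branches
  expect_true(is.na(pair_correlation(mk(rep(1, 6), x))))      # constant
  # Pearson available as an option
  expect_equal(pair_correlation(mk(x, 2 * x), method = "pearson"), 1)
})

test_that("Spearman is invariant under strictly monotone transforms", {
  set.seed(11)
  for (i in 1:25) {
    x <- rlnorm(13); y <- rlnorm(13)
    m0 <- structure(list(pair = c("a", "b"), branches = np_branches("omega"),
                         omega_a = x, omega_b = y), class = "mirrortree")
    m1 <- m0; m1$omega_a <- x^3; m1$omega_b <- exp(y)
    expect_equal(pair_correlation(m0), pair_correlation(m1))
    expect_equal(pair_correlation(m0), oracle_spearman(x, y))
  }
})
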