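# The generator: planted structure must be present and recoverable.

test_that("simulated phylogeny has the fixed topology and honors Ks", {
  cfg <- np_sim_config()
  phy <- simulate_phylogeny(cfg)
  expect_equal(sum(phy$roles == "origin"), 5)
  expect_equal(sum(phy$roles == "loss"), 2)
  ks2 <- replace(cfg$ks, "macaque", 0.123)
  phy2 <- simulate_phylogeny(np_sim_config(ks = ks2))
  f <- tempfile(fileext = ".nwk")
  write_phylogeny(phy2, f)
  back <- read_phylogeny(f)
  expect_equal(back$ks[["macaque"]], 0.123)
  expect_error(simulate_phylogeny(np_sim_config(ks = replace(cfg$ks,
                                                             "cow", 0))),
               "positive")
})

test_that("zero loss keeps every gene in its whole origin clade", {
  cfg <- np_sim_config(n_genes = 200L)
  phy <- simulate_phylogeny(cfg)
  org <- simulate_gene_origins(cfg, seed = 2)
  pres <- simulate_presence(phy, org, 0, seed = 3)
  expect_equal(nrow(pres$losses), 0L)
  for (cl in unique(org)) {
    clade <- netpaleo:::.np_origin_clade(cl)
    sub <- unclass(pres$presence)[names(org)[org == cl], , drop = FALSE]
    expect_true(all(sub[, clade] == 1L))
    expect_true(all(sub[, setdiff(np_species(), clade)] == 0L))
  }
  # human-terminal origin -> present in human only
  g_hum <- names(org)[org == "human"]
  expect_true(all(rowSums(unclass(pres$presence)[g_hum, , drop = FALSE])
                  == 1L))
})

test_that("per-branch loss frequencies match 1 - exp(-lambda * Ks)", {
  lambda <- 0.8
  cfg <- np_sim_config(n_genes = 5000L,
                       origin_probs = c(root = 1, euarchontoglires = 0,
                                        primates = 0, `human-chimp` = 0,
                                        human = 0))
  phy <- simulate_phylogeny(cfg)
  org <- simulate_gene_origins(cfg, seed = 11)
  pres <- simulate_presence(phy, org, lambda, seed = 12)
  m <- unclass(pres$presence)
  # chimp is lost iff its terminal branch is lost (everything above is
  # loss-protected for a root-origin gene)
  p_chimp <- 1 - exp(-lambda * cfg$ks[["chimpanzee"]])
  f_chimp <- mean(m[, "chimpanzee"] == 0L)
  expect_lt(abs(f_chimp - p_chimp), 3 * sqrt(p_chimp * (1 - p_chimp) / 5000))
  # mouse absence accumulates the mouse-rat stem and the mouse terminal
  p_mouse <- 1 - exp(-lambda * (cfg$ks[["mouse-rat"]] + cfg$ks[["mouse"]]))
  f_mouse <- mean(m[, "mouse"] == 0L)
  expect_lt(abs(f_mouse - p_mouse), 3 * sqrt(p_mouse * (1 - p_mouse) / 5000))
})

test_that("presence matrix is reconstructible from origins plus losses", {
  cfg <- np_sim_config(n_genes = 250L)
  phy <- simulate_phylogeny(cfg)
  org <- simulate_gene_origins(cfg, seed = 21)
  pres <- simulate_presence(phy, org, 0.6, seed = 22)
  rebuilt <- matrix(0L, length(org), 8,
                    dimnames = list(names(org), np_species()))
  for (g in names(org)) {
    tips <- netpaleo:::.np_origin_clade(org[[g]])
    for (br in pres$losses$branch[pres$losses$gene == g]) {
      tips <- setdiff(tips, netpaleo:::.np_branch_tips[[br]])
    }
    rebuilt[g, unique(c(tips, "human"))] <- 1L
  }
  expect_identical(rebuilt, unclass(pres$presence))
})

test_that("simulated networks are simple; fixed degree sequences are exact", {
  cfg <- np_sim_config(n_genes = 300L)
  net <- simulate_network(cfg, seed = 31)
  g <- igraph::graph_from_data_frame(net$edges, directed = FALSE)
  expect_true(igraph::is_simple(g))
  expect_equal(n_edges(net), round(300 * cfg$mean_degree / 2))

  deg <- rep(c(1L, 2L, 3L, 6L), times = c(40, 30, 20, 10))
  cfg2 <- np_sim_config(n_genes = 100L, degree_sequence = deg)
  net2 <- simulate_network(cfg2, seed = 32)
  expect_identical(sort(unname(net2$degree)), sort(deg))

  # age coupling: ancient genes end up better connected
  cfg3 <- np_sim_config(n_genes = 400L, age_degree_coupling = 2,
                        origin_probs = c(root = 0.5, euarchontoglires = 0,
                                         primates = 0, `human-chimp` = 0,
                                         human = 0.5))
  org <- simulate_gene_origins(cfg3, seed = 33)
  net3 <- simulate_network(cfg3, org, seed = 34)
  deg3 <- rep(0, length(org)); names(deg3) <- names(org)
  deg3[names(net3$degree)] <- net3$degree
  expect_gt(mean(deg3[org == "root"]), mean(deg3[org == "human"]))
})

test_that("planted rank correlation is recovered on flagged pairs", {
  cfg <- np_sim_config(n_genes = 1000L, mean_degree = 1,
                       degree_sequence = rep(1L, 1000), coevo_rho = 0.3,
                       coevo_fraction = 1, omega_missing = 0,
                       omega_gene_coverage = 1)
  phy <- simulate_phylogeny(cfg)
  net <- simulate_network(cfg, seed = 41)
  bo <- simulate_branch_omega(net, phy, cfg, seed = 42)
  expect_equal(nrow(bo$flagged), 500)
  rho <- vapply(seq_len(nrow(bo$flagged)), function(i) {
    pair_correlation(build_mirrortree(c(bo$flagged$a[i], bo$flagged$b[i]),
                                      bo$table))
  }, numeric(1))
  target <- oracle_copula_mean_spearman(bo$latent_r)
  expect_lt(abs(mean(rho) - target), 0.05)
  # rho* = 0: no correlation
  cfg0 <- np_sim_config(n_genes = 400L, coevo_rho = 0, coevo_fraction = 1,
                        omega_missing = 0, omega_gene_coverage = 1)
  net0 <- simulate_network(cfg0, seed = 43)
  bo0 <- simulate_branch_omega(net0, phy, cfg0, seed = 44)
  eng <- netpaleo:::.np_rho_engine(bo0$table, Inf, 6, NULL)
  expect_lt(abs(mean(eng$rho(net0$edges$a, net0$edges$b), na.rm = TRUE)),
            0.03)
})

test_that("omega marginal spikes obey the configured masses", {
  cfg <- np_sim_config(n_genes = 500L, omega_p1 = 0, omega_p5 = 0,
                       omega_missing = 0, omega_gene_coverage = 1)
  phy <- simulate_phylogeny(cfg)
  net <- simulate_network(cfg, seed = 51)
  bo <- simulate_branch_omega(net, phy, cfg, seed = 52)
  expect_lt(max(unclass(bo$table)), 1)
  cfg2 <- np_sim_config(n_genes = 500L, omega_p1 = 0.2, omega_p5 = 0.05,
                        omega_missing = 0, omega_gene_coverage = 1)
  bo2 <- simulate_branch_omega(net, phy, cfg2, seed = 52)
  O <- unclass(bo2$table)
  expect_lt(abs(mean(O > 1) - 0.2), 0.02)
  expect_lt(abs(mean(O >= 5) - 0.05), 0.01)
})

test_that("global omega: clique limit and planted assortativity direction", {
  clique <- ppi_network(rep(sprintf("k%d", 1:4), times = 4:1),
                        unlist(lapply(2:5, function(i)
                          sprintf("k%d", i:5))), quiet = TRUE)
  go1 <- simulate_global_omega(clique, np_sim_config(assortativity = 1),
                               seed = 61)
  expect_equal(length(unique(as.numeric(go1$table))), 1)
  expect_equal(network_weight(clique, go1$table)$w, 0)

  cfg <- np_sim_config(n_genes = 200L, assortativity = 0.5)
  net <- simulate_network(cfg, seed = 62)
  go <- simulate_global_omega(net, cfg, seed = 63)
  res <- constraint_assortativity_test(net, go$table, n_perm = 199,
                                       seed = 64)
  expect_lt(res$w, res$null_mean)
})

test_that("fixtures are byte-deterministic and re-readable", {
  cfg <- np_sim_config(n_genes = 120L, seed = 9L)
  d1 <- file.path(tempdir(), "fx1"); d2 <- file.path(tempdir(), "fx2")
  unlink(c(d1, d2), recursive = TRUE)
  make_study_fixture(cfg, d1)
  make_study_fixture(cfg, d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), info = f)
  }
  expect_no_warning({
    net <- read_network(file.path(d1, "network.tsv"))
    pres <- read_presence_matrix(file.path(d1, "presence.tsv"))
    phy <- read_phylogeny(file.path(d1, "tree.nwk"),
                          file.path(d1, "branch_roles.tsv"))
    bo <- read_branch_omega(file.path(d1, "branch_omega.tsv"))
    go <- read_gene_omega(file.path(d1, "gene_omega.tsv"))
    ann <- read_annotations(file.path(d1, "annotations.tsv"))
  })
  expect_true(all(net$nodes %in% rownames(pres)))
})
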